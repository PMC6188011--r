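---
title: "Counting fossil lineages under age uncertainty: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting fossil lineages under age uncertainty: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleorich)
```

This vignette is the package's own account of the model it implements: what
is being estimated, which conventions had to be fixed where the field has
none, and what the synthetic validation does and does not demonstrate.

## The estimation problem

A fossil taxon is dated through the rock units that contain it, so the raw
datum is an age *window* `[oldest, youngest]` in Ma, not an occurrence
time. A cladogram adds cross-taxon constraints: a lineage must be at least
as old as its sister's first appearance, so windows propagate through the
tree as *ghost lineages*. Standing richness at any time is therefore not
identifiable from the data; what is identifiable is a bracket.

**Maximum curve.** Assume every taxon spans its whole window. Tip first
appearance (FAD) is `oldest`, or the `lineage_oldest` override where a
referred specimen demonstrably extends the lineage (here: a Purisima
Formation *Valenictus* pushing that lineage's origin to 5.3 Ma — applied to
the maximum calibration only, since the specimen is not a dated occurrence
of the tip taxon itself). Each internal node takes the oldest FAD among its
descendant tips — the youngest node age consistent with the maximal
windows. Per time bin, the curve counts the lineage spans (tip durations
including their subtending ghost, plus positive-length internal edges)
whose age interval intersects the bin. This is occupancy counting in the
range-chart sense: a bin is credited with every lineage that overlaps it at
all, not the largest instantaneous count inside it.

**Minimum curve.** Each bin is optimised independently. A free taxon
contributes a single occurrence placed anywhere in its window, so outside
that point it may be unoriginated or extinct; a taxon known from several
rock units with non-overlapping ages must always occupy its *known range*
(here *Imagotaria downsi* 9.0–8.6 Ma and *Ontocetus emmonsi* 4.9–1.8 Ma);
node ages then follow as in the maximum calibration, and forced ghost
lineages are counted. Because bins are independent, the curve is a bin-wise
lower bound: no single global history need realise the whole curve. Taxa
flagged `max_only` (absent from the character matrix) are removed first.

**Envelope.** Both curves are computed per tree over the admitted set of
binary resolutions, and the per-bin extremum across trees is reported, so
topological uncertainty among equally parsimonious trees widens the
bracket.

## The exact minimum by dynamic programming

The minimum per bin is a discrete optimisation: only the relation of ages
to the bin's two edges matters, so each taxon's continuous choice reduces
to a finite candidate set — its window endpoints, its known-range
endpoints, and the bin edges where they fall inside the admissible
interval. `min_richness_curve()` runs a bottom-up dynamic program over the
tree whose state is the achievable node age (a value from the candidate
lattice) with the cheapest crossing count realising it; exactness relative
to full enumeration over the same candidate sets is asserted in the test
suite against an independent brute-force oracle for small trees. Candidate
tables stay tiny (a handful of values per node), so the full 173-bin,
12-tree envelope runs in seconds.

## Counting conventions

No published description fixes the discretisation details, so they are
explicit in `richness_convention()` and were chosen once, as a coherent
set, before the fixture analyses were frozen:

- **Bins are half-open `(old, young]`**: open at the older edge, closed at
  the younger, tiling the grid without overlap. `bin_side = "old"` flips
  the closure for sensitivity analysis.
- **Spans are closed intervals**; a span counts in every bin its interval
  intersects. A consequence worth knowing: a lineage ending at exactly the
  age where others begin is co-counted with them in the bin containing that
  age. This is what occupancy drawing does on a range chart.
- **Zero-length internal edges are never counted** (`count_zero_internal`
  toggles this). They arise whenever a stacked calibration gives parent and
  child the same age and represent no duration.
- **Point tip presences count** in the bin containing their age
  (`count_point_tips` toggles this).
- **The root's subtending stem is not counted**: the analysis counts
  lineages of the focal clade, and a stem above the first divergence is not
  one of them.
- **Taxa placed by a dashed attachment rule carry no imputed ghost.** The
  four valid taxa missing from the character matrix are grafted by explicit
  rules (a congener as sister to its sampled congener; *Pliopedia pacifica*
  on the stem of the tusked crown clade). Their FADs inform node ages —
  *Pliopedia* at 5.8 Ma genuinely segments the ghost path it attaches to —
  but the taxon's own span starts at its own FAD, not at the attachment
  node. An informally placed taxon should add its own possible duration,
  not manufacture a second ghost lineage; with the standard rule instead,
  *Valenictus imperialensis* would duplicate the already-extended
  *Valenictus* lineage over 5.3–5.2 Ma and push the global peak to ten.

Node-age ties are broken by value only; the order of tips in a Newick
string never affects a curve (asserted as a property test).

Numerical care: grid edges are rounded to nine decimals so that a range
endpoint quoted to 0.1 Ma compares exactly with the bin edge it sits on;
without this, floating-point drift in `17.3 - k*0.1` flips boundary-touch
counts unpredictably.

## The packaged odobenid fixtures

The range table holds the 22 valid walrus taxa with their published age
assessments; *Nanodobenus arandai* is excluded as the least
chronostratigraphically constrained taxon (a 6.5 Ma window from one site).
Regions follow each taxon's occurrences; *Ontocetus emmonsi* is Atlantic
and the extant walrus Arctic. For *Dusignathus seftoni* the table follows
the headline age range (3.6–2.5 Ma) where the supporting prose also
mentions a 4.2 Ma unit maximum; the headline values are the ones the
richness analysis was built on. The two *Pelagiarctos* forms are combined
into one operational taxon spanning 16.5–14.5 Ma.

The consensus cladogram is pectinate with three 3-way polytomies
(*Neotherium*/*Kamtschatarctos*; the *Dusignathus* species against the
tusked subfamily; *Protodobenus*/*Ontocetus* against the crown pair). Its
27 binary resolutions are filtered by whitelists of the locally admitted
arrangements — all three for the first polytomy, two each for the others —
leaving 12 trees. The shortest-tree descriptions this transcribes do not
uniquely determine the nine ingroup variants the original analysis worked
with, so the package deliberately uses the full admitted set; envelope
features are insensitive to the difference, and the per-tree agreement
counts (166 of 173 bins identical here) are reported, not asserted, for
that reason. Where the published figure could not be consulted directly,
the backbone follows the written results (with *Archaeodobenus* between the
basal polytomy and *Pelagiarctos*), and *Gomphotaria* sister to the
*Dusignathus* polytomy — the only arrangement compatible with exactly three
3-way polytomies in a strict consensus.

For the East-Pacific curve, taxa from other basins are pruned after
attachment; the extant circum-Arctic walrus is retained by default
(`also_keep = "Odobenus_rosmarus"`) because its Pleistocene record extends
into the region — a toggle, since the source is silent on the point.

The Messinian maximum is reported but intentionally not asserted anywhere:
the published account itself prints both eight and nine for that interval,
and the value is sensitive to the boundary-touch convention at 5.8 and
5.3 Ma.

## Maximum parsimony

`tree_length()` scores unordered characters by Fitch's set algorithm (a
polymorphic cell is *any-of* its observed states) and ordered characters by
an additive dynamic program with `|i − j|` costs (a polymorphic cell is the
spanning interval of its observed states; `?` and `-` constrain nothing).
Length is invariant to rooting. `heuristic_search()` builds trees by
random-addition stepwise insertion and hill-climbs with NNI, SPR or TBR
neighbourhoods (TBR additionally reroots the pruned subtree over each of
its edges), keeping all equally short distinct trees up to a cap; all
randomness flows from one seed. The defaults (10 addition replicates, TBR)
suit the matrix sizes the tests exercise; the published analysis scale
(1,000 additions) is a parameter, not a different code path. Equality with
exhaustive ancestral-state enumeration, with exhaustive tree enumeration at
five taxa, and with an independent Fitch/Sankoff implementation (phangorn)
is asserted in the suite. Bootstrap support resamples characters with
replacement and credits a replicate to every clade in the strict consensus
of that replicate's best trees.

Stored search results keep binary trees; collapsing unsupported branches
changes most-parsimonious-tree counts, which is why no tree count is
asserted anywhere.

## What the simulator emulates

`simulate_fossil_record()` grows a birth–death tree forward in time under
*budding* speciation: at a birth the mother species persists and a daughter
starts, so every species is a tip and every divergence coincides with some
species' true first appearance. Default rates (birth 0.4, death 0.3 per
lineage-Ma) give the short-lived species and modest clade sizes typical of
a marine-mammal record; the simulation is conditioned on reaching `n_tips`
species (retry on extinction), and the present falls between events so no
branch has zero duration. Each species yields one occurrence uniform on its
true range and a window that pads the occurrence with uniform slack
(default 1 Ma — the order of the odobenid windows) on each side, clipped at
0 Ma; `covering = TRUE` expands windows to contain the whole true range.

Under covering windows the maximum calibration starts every tip span no
later than its true first appearance, so the maximum curve is provably at
or above true standing richness bin-wise, and the suite checks the full
bracket (min ≤ true ≤ max) over twenty seeded replicates. Two honest
caveats. First, a persisting mother's FAD pulls its daughters' attachment
nodes up to the mother's first appearance, so the maximum curve echoes the
mother as a parallel ghost segment: even with windows equal to the true
ranges the maximum curve stays an over-count on those bins rather than
converging to the truth exactly. That slack is inherent in tree-based ghost
counting, not an implementation artifact, and the zero-slack test asserts
precisely what does hold: windows equal true ranges, last appearances are
recovered exactly, and spans begin no later than truth. Second, the
simulator models none of the biases the real record carries — preservation
tied to depositional environment, geographically uneven sampling,
correlated dating errors across taxa sharing a formation. Passing the
bracket on simulations therefore validates the counting machinery, not the
realism of any empirical curve.

`simulate_characters()` evolves Mk characters along the simulated tree
(uniform jumps for unordered, reflecting ±1 steps for ordered characters),
which gives the parsimony stage matrices whose generating tree is known; the
suite checks the generating tree scores no longer than random trees on
average.

## Known limitations

- The minimum curve is a per-bin bound, not a trajectory; its printed
  features depend on how aggressively each bin is optimised, and the exact
  optimum here can sit below a manual minimisation of the same data.
- Bin-occupancy counting makes one widening direction non-monotone: raising
  a taxon's `oldest` can lift a ghost edge's young end out of a bin whose
  coverage the tip spans already provided, lowering that bin by one while
  instantaneous counts only grow. Interpret single-bin wiggles accordingly.
- Agreement counts and most-parsimonious-tree counts are transcription- and
  convention-sensitive; the package reports them and asserts neither.
- The heuristic search rescans full neighbourhoods with complete rescoring;
  it is exact-minded and reproducible but not tuned for matrices beyond a
  few dozen taxa.
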