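#' Lineage-counting conventions
#'
#' The per-bin counting rules are stated nowhere in classical range-chart
#' practice, so they are explicit and tunable here. Under the normative
#' defaults a bin `(old, young]` is open at its older edge and closed at its
#' younger edge; a lineage span counts in a bin iff its closed age interval
#' intersects the bin; internal edges of zero duration (stacked calibrations,
#' where parent and child node take the same age) are never counted; a
#' point presence (a tip whose span collapses to one age) counts in the bin
#' containing that age.
#'
#' @param bin_side Which bin edge is closed: `"young"` (normative) or `"old"`.
#' @param count_point_tips Count zero-duration tip spans?
#' @param count_zero_internal Count zero-duration internal edges?
#' @return A list of class `richness_convention`.
#' @export
richness_convention <- function(bin_side = c("young", "old"),
                                count_point_tips = TRUE,
                                count_zero_internal = FALSE) {
  structure(list(bin_side = match.arg(bin_side),
                 count_point_tips = isTRUE(count_point_tips),
                 count_zero_internal = isTRUE(count_zero_internal)),
            class = "richness_convention")
}

# does the closed span [old, young] intersect the half-open bin?
span_hits_bin <- function(span_old, span_young, bin_old, bin_young, bin_side) {
  if (bin_side == "young") {
    span_old >= bin_young & span_young < bin_old
  } else {
    span_old > bin_young & span_young <= bin_old
  }
}

#' Maximum calibration of a cladogram against taxon age windows
#'
#' Under the maximum assumption every taxon spans its whole possible age
#' window: the tip's first appearance is its `oldest` age (or the
#' `lineage_oldest` override where a referred specimen extends the lineage),
#' its last appearance is its `youngest` age, and each internal node is as
#' old as the oldest first appearance among its descendant tips. Ghost
#' lineages arise wherever a node age, forced by one descendant, predates
#' another descendant's first appearance.
#'
#' @param tree A rooted `phylo` whose tips all have a row in `ranges`.
#' @param ranges A taxon range table.
#' @return An object of class `calibrated_tree`: the tree, per-node ages, and
#'   a `spans` tibble (one row per lineage: label, old and young end, kind).
#' @export
max_calibrate <- function(tree, ranges) {
  tree <- validate_cladogram(tree)
  ranges <- validate_taxon_ranges(ranges)
  missing_rng <- setdiff(tree$tip.label, ranges$taxon)
  if (length(missing_rng)) {
    stop("tip(s) without a range entry: ", paste(missing_rng, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(tree$tip.label, ranges$taxon)
  fad <- ifelse(is.na(ranges$lineage_oldest[idx]), ranges$oldest[idx],
                ranges$lineage_oldest[idx])
  lad <- ranges$youngest[idx]
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  age <- numeric(ntip + tree$Nnode)
  age[seq_len(ntip)] <- fad
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    age[p] <- max(age[p], age[ch])
  }
  is_tip <- tree$edge[, 2] <= ntip
  # taxa placed by a dashed attachment rule (max_only) inform node ages but
  # carry no imputed ghost of their own: their span starts at their own FAD
  dashed <- ranges$count_in[idx] == "max_only"
  child <- tree$edge[, 2]
  old_end <- age[tree$edge[, 1]]
  dash_edge <- is_tip & dashed[ifelse(is_tip, child, 1L)]
  old_end[dash_edge] <- fad[child[dash_edge]]
  spans <- tibble::tibble(
    label = ifelse(is_tip, tree$tip.label[tree$edge[, 2]],
                   paste0("node_", tree$edge[, 2])),
    old = old_end,
    young = ifelse(is_tip, lad[tree$edge[, 2]], age[tree$edge[, 2]]),
    kind = ifelse(is_tip, "tip", "internal")
  )
  structure(list(tree = tree, node_age = age, spans = spans,
                 root_age = age[ntip + 1L]),
            class = "calibrated_tree")
}

#' @export
print.calibrated_tree <- function(x, ...) {
  cat("Calibrated tree: ", length(x$tree$tip.label), " tips, root age ",
      x$root_age, " Ma, ", sum(x$spans$kind == "internal" &
                                 x$spans$old == x$spans$young),
      " zero-length internal edge(s)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname max_calibrate
#' @param x A `calibrated_tree`.
#' @param ... Unused.
#' @method tidy calibrated_tree
#' @export
tidy.calibrated_tree <- function(x, ...) x$spans

#' @rdname max_calibrate
#' @method glance calibrated_tree
#' @export
glance.calibrated_tree <- function(x, ...) {
  tibble::tibble(
    n_tips = length(x$tree$tip.label),
    root_age = x$root_age,
    n_zero_internal = sum(x$spans$kind == "internal" & x$spans$old == x$spans$young)
  )
}

new_richness_curve <- function(grid, counts, provenance) {
  out <- tibble::tibble(bin = grid$bin, bin_old = grid$bin_old,
                        bin_young = grid$bin_young,
                        count = as.integer(counts),
                        provenance = provenance)
  class(out) <- c("richness_curve", class(out))
  out
}

#' Maximum lineage-count curve
#'
#' Counts, for every bin of the grid, the lineage spans of a
#' maximum-calibrated tree (tips and positive-duration internal edges) whose
#' age interval intersects the bin.
#'
#' @param x A `calibrated_tree`, or a rooted `phylo` (then `ranges` must be
#'   supplied and the tree is calibrated first).
#' @param grid A [make_time_grid()] grid.
#' @param ranges A taxon range table (only when `x` is a `phylo`).
#' @param convention A [richness_convention()].
#' @return A `richness_curve` tibble (one row per bin, oldest first).
#' @export
max_richness_curve <- function(x, grid, ranges = NULL,
                               convention = richness_convention()) {
  ct <- if (inherits(x, "calibrated_tree")) x else max_calibrate(x, ranges)
  spans <- ct$spans
  zero <- spans$old == spans$young
  keep <- rep(TRUE, nrow(spans))
  if (!convention$count_zero_internal) keep <- keep & !(zero & spans$kind == "internal")
  if (!convention$count_point_tips) keep <- keep & !(zero & spans$kind == "tip")
  spans <- spans[keep, ]
  counts <- vapply(seq_len(nrow(grid)), function(i) {
    sum(span_hits_bin(spans$old, spans$young, grid$bin_old[i], grid$bin_young[i],
                      convention$bin_side))
  }, numeric(1))
  new_richness_curve(grid, counts, "max")
}

#' Minimum lineage-count curve
#'
#' For each bin independently, the smallest number of coexisting lineages
#' consistent with the topology and the age windows. Each free taxon is
#' reduced to a single occurrence that may sit anywhere in its window (so
#' outside the bin it can be unoriginated or already extinct); taxa with a
#' known range always occupy at least that range; node ages follow from the
#' chosen occurrences exactly as in the maximum calibration; ghost lineages
#' forced by the topology are counted. Because bins are optimised
#' independently, the resulting curve need not be realisable by any single
#' global history. Taxa flagged `count_in = "max_only"` are removed before
#' computation. The optimum is found by dynamic programming over the tree,
#' with per-taxon candidate ages restricted to window endpoints, known-range
#' endpoints and the bin's edges; this equals exhaustive search over those
#' same choices.
#'
#' @param tree A binary rooted `phylo`.
#' @inheritParams max_richness_curve
#' @return A `richness_curve` tibble with provenance `"min"`.
#' @export
min_richness_curve <- function(tree, ranges, grid,
                               convention = richness_convention()) {
  if (convention$bin_side != "young") {
    stop("the minimum curve is implemented under the normative bin convention",
         call. = FALSE)
  }
  tree <- validate_cladogram(tree)
  ranges <- validate_taxon_ranges(ranges)
  drop <- intersect(tree$tip.label,
                    ranges$taxon[ranges$count_in == "max_only"])
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  ntip <- length(tree$tip.label)
  if (tree$Nnode != ntip - 1L) {
    stop("minimum curve needs a binary tree", call. = FALSE)
  }
  missing_rng <- setdiff(tree$tip.label, ranges$taxon)
  if (length(missing_rng)) {
    stop("tip(s) without a range entry: ", paste(missing_rng, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(tree$tip.label, ranges$taxon)
  rng <- ranges[idx, ]
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2], factor(po$edge[, 1], levels = 1:(ntip + tree$Nnode)))
  node_order <- unique(po$edge[, 1])  # postorder: children before parents
  counts <- vapply(seq_len(nrow(grid)), function(i) {
    min_count_bin(grid$bin_old[i], grid$bin_young[i], ntip, kids, node_order, rng)
  }, numeric(1))
  new_richness_curve(grid, counts, "min")
}

# exact per-bin minimisation: bottom-up tables of (achievable node age ->
# minimum number of spans crossing the bin inside the subtree)
min_count_bin <- function(b_old, b_young, ntip, kids, node_order, rng) {
  tabs <- vector("list", ntip + length(node_order))
  # tip tables: candidate presence-start ages and whether the pendant span's
  # young end falls short of the bin's old edge (i.e. could be counted)
  for (i in seq_len(ntip)) {
    if (!is.na(rng$known_oldest[i])) {
      lo <- rng$known_oldest[i]; hi <- rng$oldest[i]
      s <- unique(c(lo, hi, b_old, b_young))
      s <- s[s >= lo & s <= hi]
      eflag <- rep(rng$known_youngest[i] < b_old, length(s))
    } else {
      lo <- rng$youngest[i]; hi <- rng$oldest[i]
      s <- unique(c(lo, hi, b_old, b_young))
      s <- s[s >= lo & s <= hi]
      eflag <- s < b_old
    }
    tabs[[i]] <- list(age = s, cost = numeric(length(s)), tip = TRUE,
                      eflag = eflag)
  }
  for (v in node_order) {
    ch <- kids[[v]]
    L <- tabs[[ch[1]]]; R <- tabs[[ch[2]]]
    nL <- length(L$age); nR <- length(R$age)
    a <- pmax(rep(L$age, times = nR), rep(R$age, each = nL))
    cost <- rep(L$cost, times = nR) + rep(R$cost, each = nL) +
      edge_cost(L, rep(seq_len(nL), times = nR), a, b_old, b_young) +
      edge_cost(R, rep(seq_len(nR), each = nL), a, b_old, b_young)
    # keep the cheapest realisation of each achievable node age
    u <- sort(unique(a))
    best <- vapply(u, function(val) min(cost[a == val]), numeric(1))
    tabs[[v]] <- list(age = u, cost = best, tip = FALSE)
  }
  root <- node_order[length(node_order)]
  min(tabs[[root]]$cost)
}

edge_cost <- function(child_tab, entry, parent_age, b_old, b_young) {
  if (child_tab$tip) {
    # pendant span [parent age, presence end]
    as.numeric(parent_age >= b_young & child_tab$eflag[entry])
  } else {
    # internal edge [parent age, child age]; zero-length edges never count
    a_c <- child_tab$age[entry]
    as.numeric(parent_age >= b_young & a_c < b_old & a_c < parent_age)
  }
}

#' Envelope curves over a set of trees
#'
#' Computes the per-tree maximum (or minimum) curve for every tree and takes
#' the per-bin extremum across trees, so that topological uncertainty among
#' equally parsimonious trees widens the richness envelope.
#'
#' @param trees A non-empty list of trees (`multiPhylo` or list of `phylo`).
#' @inheritParams min_richness_curve
#' @param mode `"max"` or `"min"`.
#' @return A `richness_curve` with provenance `"envelope_max"` or
#'   `"envelope_min"`.
#' @export
envelope_curve <- function(trees, ranges, grid, mode = c("max", "min"),
                           convention = richness_convention()) {
  mode <- match.arg(mode)
  if (length(trees) == 0) stop("empty tree set", call. = FALSE)
  counts <- per_tree_counts(trees, ranges, grid, mode, convention)
  env <- apply(counts, 1, if (mode == "max") max else min)
  new_richness_curve(grid, env, paste0("envelope_", mode))
}

per_tree_counts <- function(trees, ranges, grid, mode, convention) {
  vapply(trees, function(tr) {
    if (mode == "max") {
      max_richness_curve(tr, grid, ranges = ranges, convention = convention)$count
    } else {
      min_richness_curve(tr, ranges, grid, convention = convention)$count
    }
  }, numeric(nrow(grid)))
}

#' Agreement of per-tree maximum curves across a tree set
#'
#' Summarises how much of the envelope spread is due to topology: the number
#' of bins where all per-tree maximum counts agree exactly, and the number
#' where they spread over exactly one lineage.
#'
#' @inheritParams envelope_curve
#' @return A one-row tibble: `n_bins`, `n_identical`, `n_within_one`.
#' @export
agreement_summary <- function(trees, ranges, grid,
                              convention = richness_convention()) {
  if (length(trees) == 0) stop("empty tree set", call. = FALSE)
  counts <- per_tree_counts(trees, ranges, grid, "max", convention)
  spread <- apply(counts, 1, max) - apply(counts, 1, min)
  tibble::tibble(n_bins = nrow(grid),
                 n_identical = sum(spread == 0),
                 n_within_one = sum(spread == 1))
}

#' Tabulate a richness curve with stage labels
#'
#' @param curve A `richness_curve`.
#' @param stages A stage table (see [stage_table()]).
#' @return The curve tibble with a `stage` column looked up at bin midpoints.
#' @export
curve_to_table <- function(curve, stages = stage_table()) {
  mid <- (curve$bin_old + curve$bin_young) / 2
  dplyr::mutate(curve, stage = stage_of(mid, stages))
}

#' One-shot odobenid richness analysis
#'
#' Runs the packaged pipeline: enumerate the binary resolutions of the
#' consensus admitted by the shortest trees, attach the four `max_only`
#' taxa, and return the envelope maximum curve, the envelope minimum curve
#' (analyzed taxa only), and optionally a region-pruned envelope maximum.
#'
#' @param grid Time grid; defaults to 17.3--0.0 Ma at 0.1 Ma (173 bins).
#' @param region Optional region for an additional pruned maximum envelope.
#' @param also_keep Tips kept in the pruned curve regardless of region; the
#'   default retains the extant walrus, whose Pleistocene records extend into
#'   the East Pacific.
#' @param convention A [richness_convention()].
#' @param restrict Restrict resolutions to the published whitelists.
#' @return A `richness_curve` tibble stacking the curves, distinguished by
#'   `provenance` (`envelope_max`, `envelope_min`, and `pruned` if asked).
#' @export
odobenid_richness <- function(grid = make_time_grid(),
                              region = NULL,
                              also_keep = "Odobenus_rosmarus",
                              convention = richness_convention(),
                              restrict = TRUE) {
  ranges <- odobenid_ranges()
  trees <- odobenid_tree_set(restrict = restrict)
  with_extra <- lapply(trees, attach_max_only_taxa, ranges = ranges)
  out <- list(
    envelope_curve(with_extra, ranges, grid, "max", convention),
    envelope_curve(trees, ranges, grid, "min", convention)
  )
  if (!is.null(region)) {
    pruned <- lapply(with_extra, prune_to_region, ranges = ranges,
                     region = region, also_keep = also_keep)
    pc <- envelope_curve(pruned, ranges, grid, "max", convention)
    pc$provenance <- "pruned"
    out <- c(out, list(pc))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("richness_curve", setdiff(class(res), "richness_curve"))
  res
}

#' Plot richness curves
#'
#' Step plot of lineage counts against age (older ages to the left), one
#' line per provenance.
#'
#' @param object A `richness_curve` (possibly several stacked curves).
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @method autoplot richness_curve
#' @export
autoplot.richness_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$bin_old + .data$bin_young) / 2,
                               y = .data$count,
                               colour = .data$provenance)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (Ma)", y = "Lineages",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
#' @rdname autoplot.richness_curve
#' @param x A `richness_curve`.
#' @param y Unused.
plot.richness_curve <- function(x, y, ...) print(autoplot(x, ...))

#' @importFrom rlang .data
NULL
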