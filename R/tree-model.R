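#' Read and write rooted cladograms
#'
#' Thin wrappers around ape's Newick parser that enforce the invariants the
#' richness machinery relies on: unique tip labels, a single root, every
#' internal node with at least two children. Polytomies are preserved; branch
#' lengths, if present, are dropped (topologies here carry no time
#' information until calibrated against a range table).
#'
#' @param x A Newick string or the path to a Newick file.
#' @return A rooted `phylo` object without edge lengths.
#' @export
read_newick <- function(x) {
  txt <- if (length(x) == 1 && !grepl("\\(", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed Newick string", call. = FALSE)
  validate_cladogram(tree)
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @param path Optional path; when `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  tree <- validate_cladogram(tree)
  if (is.null(path)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = path)
    invisible(path)
  }
}

validate_cladogram <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  tree$edge.length <- NULL
  tree$node.label <- NULL
  tab <- tabulate(tree$edge[, 1], nbins = tree$Nnode + length(tree$tip.label))
  internal <- tab[(length(tree$tip.label) + 1):length(tab)]
  if (any(internal < 2)) {
    stop("internal node with fewer than two children", call. = FALSE)
  }
  tree
}

# ---- nested-list tree representation -------------------------------------
# A tree is either a tip label (character scalar) or an unnamed list of
# child subtrees. Rooted surgery (resolution enumeration, attachment,
# restriction) is done here; phylo is the public container.

phylo_to_nlist <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = 1:(ntip + tree$Nnode)))
  build <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    lapply(kids[[node]], build)
  }
  build(ntip + 1L)
}

nlist_to_newick <- function(nl) {
  render <- function(x) {
    if (is.character(x)) return(x)
    paste0("(", paste(vapply(x, render, character(1)), collapse = ","), ")")
  }
  paste0(render(nl), ";")
}

nlist_to_phylo <- function(nl) {
  ape::read.tree(text = nlist_to_newick(nl))
}

nlist_tips <- function(nl) {
  if (is.character(nl)) return(nl)
  unlist(lapply(nl, nlist_tips), use.names = FALSE)
}

# canonical form: children ordered by their alphabetically-first tip, so two
# topologies are equal iff their canonical strings are equal
canonical_newick <- function(nl) {
  canon <- function(x) {
    if (is.character(x)) return(list(key = x, str = x))
    parts <- lapply(x, canon)
    ord <- order(vapply(parts, `[[`, character(1), "key"))
    parts <- parts[ord]
    list(key = parts[[1]]$key,
         str = paste0("(", paste(vapply(parts, `[[`, character(1), "str"),
                                 collapse = ","), ")"))
  }
  paste0(canon(nl)$str, ";")
}

double_factorial_odd <- function(k) {
  # (2k-3)!! rooted binary topologies over k labelled children
  if (k <= 2) return(1)
  prod(seq(3, 2 * k - 3, by = 2))
}

# all rooted binary groupings of a list of subtrees
rooted_groupings <- function(items) {
  k <- length(items)
  if (k == 1) return(list(items[[1]]))
  if (k == 2) return(list(list(items[[1]], items[[2]])))
  out <- list()
  rest <- seq_len(k)[-1]
  for (m in 0:(k - 2)) {
    for (sub in utils::combn(rest, m, simplify = FALSE)) {
      left <- c(1L, sub)
      right <- setdiff(seq_len(k), left)
      for (l in rooted_groupings(items[left])) {
        for (r in rooted_groupings(items[right])) {
          out[[length(out) + 1L]] <- list(l, r)
        }
      }
    }
  }
  out
}

#' Enumerate binary resolutions of a tree with polytomies
#'
#' Every polytomy of `k` children admits `(2k-3)!!` rooted local resolutions
#' (child subtrees are kept intact); independent polytomies multiply. The
#' result enumerates every distinct binary tree obtainable this way.
#'
#' @param tree A rooted `phylo`, polytomies allowed.
#' @param max_trees Guard against combinatorial explosion; the product of the
#'   per-polytomy resolution counts must not exceed it.
#' @return A list of binary `phylo` trees (class `multiPhylo`).
#' @export
enumerate_resolutions <- function(tree, max_trees = 10000) {
  nl <- phylo_to_nlist(validate_cladogram(tree))
  count <- function(x) {
    if (is.character(x)) return(1)
    prod(vapply(x, count, numeric(1))) * double_factorial_odd(length(x))
  }
  n <- count(nl)
  if (n > max_trees) {
    stop("polytomy resolution would produce ", n, " trees (max_trees = ",
         max_trees, ")", call. = FALSE)
  }
  expand <- function(x) {
    if (is.character(x)) return(list(x))
    per_child <- lapply(x, expand)
    combos <- list(list())
    for (pc in per_child) {
      combos <- do.call(c, lapply(combos, function(cm) {
        lapply(pc, function(v) c(cm, list(v)))
      }))
    }
    do.call(c, lapply(combos, rooted_groupings))
  }
  out <- lapply(expand(nl), nlist_to_phylo)
  class(out) <- "multiPhylo"
  out
}

# rooted topology induced on a subset of tips (prune + collapse singles)
induced_nlist <- function(nl, tips) {
  prune <- function(x) {
    if (is.character(x)) {
      if (x %in% tips) return(x)
      return(NULL)
    }
    kept <- Filter(Negate(is.null), lapply(x, prune))
    if (length(kept) == 0) return(NULL)
    if (length(kept) == 1) return(kept[[1]])
    kept
  }
  prune(nl)
}

#' Filter a tree set by admitted local resolutions
#'
#' `constraints` is a list with one entry per constrained polytomy. Each
#' entry is a list with `children` (a list of character vectors, the tip sets
#' of the polytomy's children) and `admit` (a list of admitted local
#' topologies, each a nested list of child indices, e.g. `list(list(1, 2), 3)`
#' for "children 1 and 2 form a cherry"). Trees whose local resolution of any
#' constrained polytomy is not whitelisted are dropped.
#'
#' @param trees A list of binary `phylo` trees sharing a tip set.
#' @param constraints See Details.
#' @return The retained trees, a `multiPhylo`; error if none remain.
#' @export
restrict_resolutions <- function(trees, constraints) {
  keep <- vapply(trees, function(tr) {
    nl <- phylo_to_nlist(tr)
    all(vapply(constraints, function(con) {
      reps <- vapply(con$children, function(g) sort(g)[1], character(1))
      local <- induced_nlist(nl, reps)
      admitted <- vapply(con$admit, function(adm) {
        canonical_newick(index_to_nlist(adm, reps))
      }, character(1))
      canonical_newick(local) %in% admitted
    }, logical(1)))
  }, logical(1))
  if (!any(keep)) stop("no tree satisfies the resolution whitelist", call. = FALSE)
  out <- trees[keep]
  class(out) <- "multiPhylo"
  out
}

index_to_nlist <- function(adm, reps) {
  if (!is.list(adm)) return(reps[adm])
  lapply(adm, index_to_nlist, reps = reps)
}

#' Graft a taxon absent from the character matrix onto a tree
#'
#' `sister_to_tip` inserts the new taxon as the sister of an existing tip;
#' `on_stem_of_clade` inserts it on the edge subtending the most recent
#' common ancestor of the anchor tips (the clade's stem). Used for valid taxa
#' that were not scored in the matrix but whose approximate position is known
#' (e.g. a congener of a sampled species).
#'
#' @param tree A rooted `phylo`.
#' @param taxon New tip label; must not already be present.
#' @param anchor A tip label (for `sister_to_tip`) or a character vector of
#'   tip labels spanning the anchor clade (for `on_stem_of_clade`).
#' @param mode `"sister_to_tip"` or `"on_stem_of_clade"`.
#' @return The enlarged `phylo` (one more tip).
#' @export
attach_unsampled_taxon <- function(tree, taxon, anchor,
                                   mode = c("sister_to_tip", "on_stem_of_clade")) {
  mode <- match.arg(mode)
  tree <- validate_cladogram(tree)
  if (taxon %in% tree$tip.label) {
    stop("taxon ", taxon, " is already a tip", call. = FALSE)
  }
  missing_anchor <- setdiff(anchor, tree$tip.label)
  if (length(missing_anchor)) {
    stop("anchor tip(s) not in tree: ", paste(missing_anchor, collapse = ", "),
         call. = FALSE)
  }
  nl <- phylo_to_nlist(tree)
  if (mode == "sister_to_tip") {
    if (length(anchor) != 1) stop("sister_to_tip needs a single anchor tip", call. = FALSE)
    graft <- function(x) {
      if (is.character(x)) {
        if (x == anchor) return(list(x, taxon))
        return(x)
      }
      lapply(x, graft)
    }
    out <- graft(nl)
  } else {
    # walk down to the smallest subtree containing every anchor tip (the
    # MRCA) and insert the new taxon on that subtree's stem edge
    descend <- function(x) {
      if (is.character(x)) return(list(tree = list(x, taxon), at_self = FALSE))
      idx <- which(vapply(x, function(ch) all(anchor %in% nlist_tips(ch)),
                          logical(1)))
      if (length(idx) == 0) return(list(tree = x, at_self = TRUE))
      r <- descend(x[[idx]])
      x[[idx]] <- if (r$at_self) list(r$tree, taxon) else r$tree
      list(tree = x, at_self = FALSE)
    }
    r <- descend(nl)
    if (r$at_self) {
      stop("anchor clade has no stem edge (it spans the root)", call. = FALSE)
    }
    out <- r$tree
  }
  nlist_to_phylo(out)
}

#' @rdname attach_unsampled_taxon
#' @param ranges A taxon range table; every `count_in = "max_only"` row is
#'   attached by its own `attach_anchor`/`attach_mode` rule (a `+`-separated
#'   anchor names a clade by its tips).
#' @export
attach_max_only_taxa <- function(tree, ranges) {
  ranges <- validate_taxon_ranges(ranges)
  extra <- ranges[ranges$count_in == "max_only", ]
  for (i in seq_len(nrow(extra))) {
    anchor <- strsplit(extra$attach_anchor[i], "+", fixed = TRUE)[[1]]
    tree <- attach_unsampled_taxon(tree, extra$taxon[i], anchor,
                                   extra$attach_mode[i])
  }
  tree
}

#' Prune a tree to the taxa of one region
#'
#' Keeps the tips whose `region` matches, plus any tips named in `also_keep`
#' (e.g. an extant circum-Arctic taxon with records inside the focal region),
#' suppressing the internal nodes left with a single child.
#'
#' @param tree A rooted `phylo`.
#' @param ranges A taxon range table covering every tip.
#' @param region Region to keep.
#' @param also_keep Tips retained regardless of their region.
#' @return The pruned `phylo`; error if no tip qualifies.
#' @export
prune_to_region <- function(tree, ranges, region, also_keep = character()) {
  tree <- validate_cladogram(tree)
  ranges <- validate_taxon_ranges(ranges)
  missing_rng <- setdiff(tree$tip.label, ranges$taxon)
  if (length(missing_rng)) {
    stop("tip(s) without a range entry: ", paste(missing_rng, collapse = ", "),
         call. = FALSE)
  }
  reg <- ranges$region[match(tree$tip.label, ranges$taxon)]
  keep <- tree$tip.label[reg == region | tree$tip.label %in% also_keep]
  if (length(keep) == 0) stop("no tips from region ", region, call. = FALSE)
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

# ---- packaged odobenid trees ---------------------------------------------

#' Packaged odobenid consensus topology and tree set
#'
#' `odobenid_consensus()` returns the strict-consensus cladogram of the 18
#' analyzed odobenid taxa: a pectinate backbone with three 3-way polytomies
#' ({*N. mirum*, *K. sinelnikovae*, crownward}, {*D. seftoni*,
#' *D. santacruzensis*, Odobeninae} and {*P. japonicus*, *O. emmonsi*,
#' crown}). `odobenid_resolution_constraints()` encodes which local
#' resolutions of those polytomies occur among the shortest trees (all three
#' for the first; a monophyletic *Dusignathus* or *D. santacruzensis*
#' crownward for the second; a *P. japonicus* + *O. emmonsi* cherry or
#' *P. japonicus* one node more basal for the third).
#' `odobenid_tree_set()` enumerates the 27 binary resolutions and, by
#' default, keeps the ones admitted by those whitelists.
#'
#' @return A `phylo`, a constraints list, or a `multiPhylo`.
#' @export
odobenid_consensus <- function() {
  read_newick(system.file("extdata", "fig14_consensus.nwk",
                          package = "paleorich", mustWork = TRUE))
}

odobeninae_tips <- c("Aivukus_cedrosensis", "Protodobenus_japonicus",
                     "Ontocetus_emmonsi", "Valenictus_chulavistensis",
                     "Odobenus_rosmarus")

crownward_of_basal_polytomy <- c(
  "Archaeodobenus_akamatsui", "Pelagiarctos", "Titanotaria_orangensis",
  "Imagotaria_downsi", "Pontolis_magnus", "Gomphotaria_pugnax",
  "Dusignathus_seftoni", "Dusignathus_santacruzensis", odobeninae_tips)

#' @rdname odobenid_consensus
#' @export
odobenid_resolution_constraints <- function() {
  list(
    list(children = list("Neotherium_mirum", "Kamtschatarctos_sinelnikovae",
                         crownward_of_basal_polytomy),
         admit = list(list(list(1, 2), 3), list(1, list(2, 3)),
                      list(2, list(1, 3)))),
    list(children = list("Dusignathus_seftoni", "Dusignathus_santacruzensis",
                         odobeninae_tips),
         admit = list(list(list(1, 2), 3), list(1, list(2, 3)))),
    list(children = list("Protodobenus_japonicus", "Ontocetus_emmonsi",
                         c("Valenictus_chulavistensis", "Odobenus_rosmarus")),
         admit = list(list(list(1, 2), 3), list(1, list(2, 3))))
  )
}

#' @rdname odobenid_consensus
#' @param restrict Keep only the resolutions admitted by
#'   [odobenid_resolution_constraints()].
#' @export
odobenid_tree_set <- function(restrict = TRUE) {
  trees <- enumerate_resolutions(odobenid_consensus())
  if (restrict) {
    trees <- restrict_resolutions(trees, odobenid_resolution_constraints())
  }
  trees
}
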