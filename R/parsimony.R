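#' Discrete morphological character matrices
#'
#' Characters take integer states 0--9. A cell holds a state set: a
#' singleton, a polymorphism (several observed states), or missing (`?`, and
#' `-` which is scored as missing). Each character carries an ordered flag:
#' unordered characters cost one step per change (Fitch), ordered (additive)
#' characters cost `|i - j|` steps, with polymorphic cells scored as the
#' spanning interval of their observed states.
#'
#' @param states A list (one element per taxon) of lists of integer vectors
#'   (one per character; `integer(0)` = missing), or a character matrix of
#'   cell strings such as `"0"`, `"01"`, `"?"`.
#' @param taxa Taxon labels.
#' @param ordered Integer indices of the ordered characters, or a logical
#'   vector over characters.
#' @return An object of class `character_matrix`.
#' @export
character_matrix <- function(states, taxa = NULL, ordered = integer()) {
  if (is.matrix(states) && is.character(states)) {
    taxa <- taxa %||% rownames(states)
    states <- apply(states, 1, function(row) lapply(row, parse_cell),
                    simplify = FALSE)
  }
  if (is.null(taxa)) taxa <- names(states)
  stopifnot(!is.null(taxa), length(taxa) == length(states))
  n_char <- length(states[[1]])
  if (any(vapply(states, length, integer(1)) != n_char)) {
    stop("ragged matrix: all taxa need the same number of characters",
         call. = FALSE)
  }
  masks <- t(vapply(states, function(row) {
    vapply(row, function(cell) {
      if (length(cell) == 0) return(0L)  # missing sentinel
      if (any(cell < 0 | cell > 9)) stop("states must be 0-9", call. = FALSE)
      sum(bitwShiftL(1L, unique(cell)))
    }, integer(1))
  }, integer(n_char)))
  if (n_char == 1) masks <- matrix(masks, ncol = 1)
  rownames(masks) <- taxa
  ord <- logical(n_char)
  if (is.logical(ordered)) ord <- ordered else ord[ordered] <- TRUE
  structure(list(taxa = taxa, n_char = n_char, masks = masks, ordered = ord),
            class = "character_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cell <- function(s) {
  s <- gsub("[(){} ]", "", s)
  if (s %in% c("?", "-", "")) return(integer(0))
  as.integer(strsplit(s, "")[[1]])
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Character matrix: ", length(x$taxa), " taxa x ", x$n_char,
      " characters (", sum(x$ordered), " ordered)\n", sep = "")
  invisible(x)
}

#' Read a NEXUS morphological matrix
#'
#' Minimal reader for the DATA/CHARACTERS block of a NEXUS file: numeric
#' symbols, `?` missing, `-` (gap) treated as missing, `(...)`/`{...}`
#' polymorphism, interleaving allowed. Ordered flags are supplied by the
#' caller, not read from the file (assumptions blocks vary too much across
#' programs to trust).
#'
#' @param path Path to a NEXUS file.
#' @param ordered Indices of characters to score as ordered.
#' @return A [character_matrix()].
#' @export
read_nexus_matrix <- function(path, ordered = integer()) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)  # strip comments
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", txt, ignore.case = TRUE))
  nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", txt, ignore.case = TRUE))
  if (is.na(ntax) || is.na(nchar_)) {
    stop("missing DIMENSIONS NTAX/NCHAR", call. = FALSE)
  }
  m <- regmatches(txt, regexpr("(?is)MATRIX(.*?);", txt, perl = TRUE))[[1]]
  if (!length(m)) stop("no MATRIX block", call. = FALSE)
  body <- sub("(?is)^MATRIX", "", m, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  lines <- trimws(strsplit(body, "\n")[[1]])
  lines <- lines[nzchar(lines)]
  cells <- list()
  for (ln in lines) {
    nm <- sub("^('[^']+'|\\S+)\\s.*$", "\\1", ln)
    seq_part <- sub("^('[^']+'|\\S+)\\s+", "", ln)
    nm <- gsub("'", "", nm)
    nm <- gsub(" ", "_", nm)
    toks <- regmatches(seq_part,
                       gregexpr("\\([0-9 ]+\\)|\\{[0-9 ]+\\}|[0-9?\\-]", seq_part))[[1]]
    cells[[nm]] <- c(cells[[nm]], lapply(toks, parse_cell))
  }
  if (length(cells) != ntax) {
    stop("matrix has ", length(cells), " taxa but NTAX = ", ntax, call. = FALSE)
  }
  got <- vapply(cells, length, integer(1))
  if (any(got != nchar_)) {
    stop("taxon ", names(cells)[got != nchar_][1], " has ",
         got[got != nchar_][1], " characters but NCHAR = ", nchar_,
         call. = FALSE)
  }
  character_matrix(cells, ordered = ordered)
}

#' @rdname read_nexus_matrix
#' @param x A `character_matrix`.
#' @export
write_nexus_matrix <- function(x, path) {
  cell_str <- function(mask) {
    if (mask == 0L) return("?")
    st <- which(bitwAnd(mask, bitwShiftL(1L, 0:9)) > 0L) - 1L
    if (length(st) == 1) as.character(st) else
      paste0("(", paste(st, collapse = ""), ")")
  }
  rows <- vapply(seq_along(x$taxa), function(i) {
    paste0(x$taxa[i], "  ",
           paste(vapply(x$masks[i, ], cell_str, character(1)), collapse = ""))
  }, character(1))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               paste0("DIMENSIONS NTAX=", length(x$taxa),
                      " NCHAR=", x$n_char, ";"),
               "FORMAT SYMBOLS=\"0123456789\" MISSING=? GAP=-;",
               "MATRIX", rows, ";", "END;"), path)
  invisible(path)
}

# ---- scoring -------------------------------------------------------------

BIGCOST <- 1e9

subset_matrix <- function(cm, taxa) {
  missing_t <- setdiff(taxa, cm$taxa)
  if (length(missing_t)) {
    stop("tip(s) not in the matrix: ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  cm$masks <- cm$masks[taxa, , drop = FALSE]
  cm$taxa <- taxa
  cm
}

# Fitch (unordered, any-of sets) + additive Sankoff (ordered, interval sets)
# on a nested-list binary tree; missing cells constrain nothing
score_nlist <- function(nl, masks, ord) {
  iu <- which(!ord); io <- which(ord)
  full <- sum(bitwShiftL(1L, 0:9))
  tip_dp <- function(mask1) {
    # additive leaf costs over states 0..9: 0 inside the observed interval
    vapply(mask1, function(m) {
      if (m == 0L) return(rep(0, 10))
      st <- which(bitwAnd(m, bitwShiftL(1L, 0:9)) > 0L) - 1L
      ifelse(0:9 >= min(st) & 0:9 <= max(st), 0, BIGCOST)
    }, numeric(10))
  }
  steps <- 0
  rec <- function(x) {
    if (is.character(x)) {
      mk <- masks[x, iu]
      mk[mk == 0L] <- full
      return(list(mask = mk,
                  dp = if (length(io)) tip_dp(masks[x, io]) else NULL))
    }
    l <- rec(x[[1]]); r <- rec(x[[2]])
    inter <- bitwAnd(l$mask, r$mask)
    z <- inter == 0L
    steps <<- steps + sum(z)
    mask <- inter
    if (any(z)) mask[z] <- bitwOr(l$mask[z], r$mask[z])
    dp <- NULL
    if (length(io)) dp <- min_conv(l$dp) + min_conv(r$dp)
    list(mask = mask, dp = dp)
  }
  root <- rec(nl)
  extra <- if (length(io)) sum(apply(root$dp, 2, min)) else 0
  steps + extra
}

# D[s] = min_t C[t] + |s - t|, columns are characters
min_conv <- function(C) {
  for (s in 2:10) C[s, ] <- pmin(C[s, ], C[s - 1, ] + 1)
  for (s in 9:1) C[s, ] <- pmin(C[s, ], C[s + 1, ] + 1)
  C
}

#' Parsimony length of a tree
#'
#' Total number of character-state changes the matrix requires on the tree:
#' Fitch length for unordered characters (a polymorphic cell may take any of
#' its observed states), additive length for ordered characters (a
#' polymorphic cell is scored as the interval spanned by its observed
#' states). Parsimony length is a property of the unrooted topology, so the
#' rooting of `tree` does not matter. Trees with polytomies are scored as the
#' minimum over their binary resolutions.
#'
#' @param tree A `phylo` whose tips are all matrix taxa.
#' @param cm A [character_matrix()].
#' @return Number of steps (numeric scalar).
#' @export
tree_length <- function(tree, cm) {
  stopifnot(inherits(cm, "character_matrix"))
  tree <- validate_cladogram(tree)
  cm <- subset_matrix(cm, tree$tip.label)
  ntip <- length(tree$tip.label)
  if (ntip < 2) return(0)
  trees <- if (tree$Nnode == ntip - 1L) list(tree) else
    enumerate_resolutions(tree, max_trees = 10000)
  min(vapply(trees, function(tr) {
    score_nlist(phylo_to_nlist(tr), cm$masks, cm$ordered)
  }, numeric(1)))
}

# ---- tree moves on nested lists ------------------------------------------

# every way to insert `tip` on an edge of the (unrooted sense) tree
insert_everywhere <- function(nl, tip) {
  out <- list(list(nl, tip))
  recurse <- function(x, replace_in_parent) {
    res <- list(replace_in_parent(list(x, tip)))
    if (!is.character(x)) {
      res <- c(res,
               recurse(x[[1]], function(s) replace_in_parent(list(s, x[[2]]))),
               recurse(x[[2]], function(s) replace_in_parent(list(x[[1]], s))))
    }
    res
  }
  c(out, recurse(nl[[1]], function(s) list(s, nl[[2]])),
    recurse(nl[[2]], function(s) list(nl[[1]], s)))
}

# all (pruned subtree, remainder) pairs; the remainder has the unary node
# suppressed
prune_pairs <- function(nl) {
  out <- list()
  recurse <- function(x, context) {
    # context(s) rebuilds the whole tree with subtree x replaced by s;
    # pruning x leaves context applied to x's sibling
    if (is.character(x)) return()
    A <- x[[1]]; B <- x[[2]]
    out[[length(out) + 1L]] <<- list(sub = A, rest = context(B))
    out[[length(out) + 1L]] <<- list(sub = B, rest = context(A))
    recurse(A, function(s) context(list(s, B)))
    recurse(B, function(s) context(list(A, s)))
  }
  recurse(nl, identity)
  out
}

# all rootings of the unrooted topology underlying a rooted tree (used to
# reattach a pruned subtree by any of its edges for TBR)
reroot_all <- function(nl) {
  if (is.character(nl)) return(list(nl))
  out <- list(nl)
  walk <- function(node, context) {
    res <- list()
    if (!is.character(node)) {
      A <- node[[1]]; B <- node[[2]]
      res <- c(res, list(list(A, list(B, context))),
               list(list(B, list(A, context))),
               walk(A, list(B, context)), walk(B, list(A, context)))
    }
    res
  }
  c(out, walk(nl[[1]], nl[[2]]), walk(nl[[2]], nl[[1]]))
}

neighbours <- function(nl, swapper) {
  pairs <- prune_pairs(nl)
  out <- list()
  for (p in pairs) {
    if (is.character(p$rest)) next
    subs <- switch(swapper,
                   SPR = list(p$sub),
                   TBR = reroot_all(p$sub),
                   NNI = NULL)
    if (is.null(subs)) break
    for (s in subs) out <- c(out, insert_everywhere(p$rest, s))
  }
  if (swapper == "NNI") out <- nni_neighbours(nl)
  out
}

nni_neighbours <- function(nl) {
  out <- list()
  recurse <- function(x, context) {
    if (is.character(x)) return()
    A <- x[[1]]; B <- x[[2]]
    # swap across the edge above B (if internal), then above A
    if (!is.character(B)) {
      out[[length(out) + 1L]] <<- context(list(B[[1]], list(A, B[[2]])))
      out[[length(out) + 1L]] <<- context(list(B[[2]], list(B[[1]], A)))
    }
    if (!is.character(A)) {
      out[[length(out) + 1L]] <<- context(list(list(A[[1]], B), A[[2]]))
      out[[length(out) + 1L]] <<- context(list(list(A[[2]], B), A[[1]]))
    }
    recurse(A, function(s) context(list(s, B)))
    recurse(B, function(s) context(list(A, s)))
  }
  recurse(nl, identity)
  out
}

canonical_unrooted <- function(nl) {
  # canonical string of the unrooted topology: root on the stem of the
  # alphabetically first tip, then canonicalise
  tips <- sort(nlist_tips(nl))
  first <- tips[1]
  for (r in reroot_all(nl)) {
    if (is.list(r) && (identical(r[[1]], first) || identical(r[[2]], first))) {
      return(canonical_newick(r))
    }
  }
  canonical_newick(nl)
}

# ---- heuristic search ----------------------------------------------------

#' Heuristic maximum-parsimony search
#'
#' Random-addition-sequence stepwise building followed by branch-swapping
#' hill climbing (NNI, SPR or TBR), repeated over `replicates` addition
#' sequences; all distinct shortest trees found are retained, up to
#' `max_trees`. Reproducible for a fixed `seed`.
#'
#' @param cm A [character_matrix()].
#' @param outgroup Optional tip used to root the reported trees.
#' @param replicates Number of random addition sequences.
#' @param swapper Branch-swapping neighbourhood.
#' @param seed Integer seed.
#' @param max_trees Cap on stored equally short trees.
#' @return An object of class `parsimony_search`: best `length`, the list of
#'   best `trees` (`multiPhylo`), and the search `settings`.
#' @export
heuristic_search <- function(cm, outgroup = NULL, replicates = 10,
                             swapper = c("TBR", "SPR", "NNI"), seed = 1,
                             max_trees = 100) {
  swapper <- match.arg(swapper)
  stopifnot(inherits(cm, "character_matrix"))
  if (length(cm$taxa) < 4) stop("need at least 4 taxa", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  withr::with_seed(seed, {
    best_len <- Inf
    best <- list()   # canonical string -> nlist
    for (rep_i in seq_len(replicates)) {
      ord <- sample(cm$taxa)
      res <- search_one(ord, cm, swapper, max_trees)
      if (res$len < best_len) {
        best_len <- res$len
        best <- res$trees
      } else if (res$len == best_len) {
        best <- utils::modifyList(best, res$trees)
      }
      if (length(best) > max_trees) best <- best[seq_len(max_trees)]
    }
  })
  trees <- lapply(unname(best), nlist_to_phylo)
  if (!is.null(outgroup)) {
    trees <- lapply(trees, function(tr) {
      ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
    })
  }
  class(trees) <- "multiPhylo"
  structure(list(length = best_len, trees = trees,
                 settings = list(replicates = replicates, swapper = swapper,
                                 seed = seed, outgroup = outgroup,
                                 max_trees = max_trees)),
            class = "parsimony_search")
}

search_one <- function(ord, cm, swapper, max_trees) {
  len_of <- function(nl) score_nlist(nl, cm$masks, cm$ordered)
  cur <- list(list(ord[1], ord[2]), ord[3])
  for (tip in ord[-(1:3)]) {
    cands <- insert_everywhere(cur, tip)
    lens <- vapply(cands, len_of, numeric(1))
    cur <- cands[[which.min(lens)]]
  }
  best_len <- len_of(cur)
  best <- stats::setNames(list(cur), canonical_unrooted(cur))
  frontier <- best
  explored <- character()
  while (length(frontier) > 0 && length(best) <= max_trees) {
    key <- names(frontier)[1]
    nl <- frontier[[1]]
    frontier <- frontier[-1]
    if (key %in% explored) next
    explored <- c(explored, key)
    nb <- neighbours(nl, swapper)
    lens <- vapply(nb, len_of, numeric(1))
    if (min(lens) < best_len) {
      best_len <- min(lens)
      best <- list(); frontier <- list(); explored <- character()
      for (k in which(lens == best_len)) {
        ck <- canonical_unrooted(nb[[k]])
        if (is.null(best[[ck]])) best[[ck]] <- nb[[k]]
      }
      frontier <- best
    } else {
      for (k in which(lens == best_len)) {
        ck <- canonical_unrooted(nb[[k]])
        if (is.null(best[[ck]]) && length(best) < max_trees) {
          best[[ck]] <- nb[[k]]
          frontier[[ck]] <- nb[[k]]
        }
      }
    }
  }
  list(len = best_len, trees = best)
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat("Most parsimonious length: ", x$length, " steps (",
      length(x$trees), " tree(s) retained; ", x$settings$replicates,
      " addition replicates, ", x$settings$swapper, ")\n", sep = "")
  invisible(x)
}

#' @rdname heuristic_search
#' @param x A `parsimony_search`.
#' @param ... Unused.
#' @method tidy parsimony_search
#' @export
tidy.parsimony_search <- function(x, ...) {
  tibble::tibble(tree = seq_along(x$trees),
                 length = x$length,
                 newick = vapply(x$trees, ape::write.tree, character(1)))
}

#' @rdname heuristic_search
#' @method glance parsimony_search
#' @export
glance.parsimony_search <- function(x, ...) {
  tibble::tibble(length = x$length, n_trees = length(x$trees),
                 replicates = x$settings$replicates,
                 swapper = x$settings$swapper, seed = x$settings$seed)
}

#' Bootstrap support for bipartitions
#'
#' Resamples characters with replacement, reruns the heuristic search on
#' each pseudo-replicate, and reports for every observed clade the fraction
#' of replicates whose strict consensus of best trees contains it.
#'
#' @inheritParams heuristic_search
#' @param reps Number of bootstrap replicates.
#' @param replicates Addition sequences per replicate search.
#' @return A tibble: `clade` (sorted tip labels joined by `|`), `freq`.
#' @export
bootstrap_support <- function(cm, outgroup, reps = 100, seed = 1,
                              replicates = 2, swapper = "SPR") {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  tally <- new.env(parent = emptyenv())
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      cols <- sample.int(cm$n_char, cm$n_char, replace = TRUE)
      cm_b <- cm
      cm_b$masks <- cm$masks[, cols, drop = FALSE]
      cm_b$ordered <- cm$ordered[cols]
      fit <- heuristic_search(cm_b, outgroup = outgroup,
                              replicates = replicates, swapper = swapper,
                              seed = sample.int(.Machine$integer.max, 1))
      cons <- if (length(fit$trees) > 1) strict_consensus(fit$trees) else
        fit$trees[[1]]
      for (cl in rooted_clades(cons)) {
        key <- paste(sort(cl), collapse = "|")
        tally[[key]] <- (tally[[key]] %||% 0) + 1
      }
    }
  })
  keys <- ls(tally)
  tibble::tibble(clade = keys,
                 freq = vapply(keys, function(k) tally[[k]] / reps, numeric(1)))
}

rooted_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  lapply(pp, function(i) attr(pp, "labels")[i])
}

#' Strict consensus of a set of trees
#'
#' Retains exactly the clades present in every input tree.
#'
#' @param trees Trees sharing a tip set.
#' @return A `phylo`, possibly with polytomies.
#' @export
strict_consensus <- function(trees) {
  if (length(trees) == 0) stop("empty tree list", call. = FALSE)
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(tipsets, identical, logical(1), tipsets[[1]]))) {
    stop("trees have different tip sets", call. = FALSE)
  }
  if (length(trees) == 1) return(trees[[1]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = TRUE)
}
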