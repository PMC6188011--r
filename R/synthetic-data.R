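#' Simulate a fossil record with known truth
#'
#' Grows a birth--death tree forward in time under budding speciation (at a
#' birth event the mother species persists and a daughter species starts;
#' every species is therefore a tip of the resulting cladogram, and its true
#' range runs from its budding node to its death, 0 Ma for species alive at
#' the stopping time). The simulation retries on whole-tree extinction and
#' stops once `n_tips` species exist. One fossil occurrence is drawn
#' uniformly on each true range, and a per-taxon sampling window pads the
#' occurrence with independent uniform slack on each side (clipped at 0 Ma).
#' With `covering = TRUE` every window is expanded to contain its whole true
#' range: because budding places every divergence at some species' true
#' first appearance, covering windows let the maximum calibration recover
#' every node age, which is the regime under which the maximum/minimum
#' curves are guaranteed to bracket true standing richness. The root
#' species' segment before its first budding is unobservable from the tree
#' shape and is excluded from both its range and the true curve. The present
#' is placed between the stopping event and the next would-be event, so no
#' branch has zero duration.
#'
#' @param n_tips Number of terminal taxa (>= 3).
#' @param birth,death Per-lineage rates per Ma (> 0).
#' @param window_slack Maximum uniform padding, Ma.
#' @param covering Force windows to contain the true ranges.
#' @param seed Integer seed.
#' @param max_retries Retries allowed on early whole-tree extinction.
#' @return An object of class `simulated_record`: `tree` (a binary `phylo`
#'   with branch durations in Ma and a `node_age` vector, tips first),
#'   `taxa` (tibble with true FAD/LAD, occurrence and window per taxon),
#'   `ranges` (a taxon range table ready for the richness functions), and
#'   the `seed`.
#' @export
simulate_fossil_record <- function(n_tips, birth = 0.4, death = 0.3,
                                   window_slack = 1, covering = FALSE,
                                   seed = 1, max_retries = 100) {
  stopifnot(n_tips >= 3, birth > 0, death > 0, window_slack >= 0)
  withr::with_seed(seed, {
    sim <- NULL
    for (try_i in seq_len(max_retries)) {
      sim <- grow_bd_tree(n_tips, birth, death)
      if (!is.null(sim)) break
    }
    if (is.null(sim)) {
      stop("tree went extinct before reaching ", n_tips, " tips in ",
           max_retries, " attempts", call. = FALSE)
    }
    taxa <- sim$taxa
    taxa$occurrence <- stats::runif(nrow(taxa), taxa$true_lad, taxa$true_fad)
    taxa$oldest <- taxa$occurrence + stats::runif(nrow(taxa), 0, window_slack)
    taxa$youngest <- pmax(taxa$occurrence - stats::runif(nrow(taxa), 0, window_slack), 0)
    if (covering) {
      taxa$oldest <- pmax(taxa$oldest, taxa$true_fad)
      taxa$youngest <- pmin(taxa$youngest, taxa$true_lad)
    }
  })
  ranges <- validate_taxon_ranges(tibble::tibble(
    taxon = taxa$taxon, oldest = taxa$oldest, youngest = taxa$youngest,
    region = "EastPacific", analyzed = TRUE, count_in = "both"))
  structure(list(tree = sim$tree, taxa = taxa, ranges = ranges, seed = seed),
            class = "simulated_record")
}

# forward Gillespie birth-death with budding speciation; every species is
# one tip, its lineage threading through the budding nodes of its daughters
grow_bd_tree <- function(n_tips, birth, death) {
  origin <- 0; died <- NA_real_; parent <- 0L; alive <- TRUE
  t_now <- 0
  repeat {
    n_alive <- sum(alive)
    if (n_alive == 0) return(NULL)
    wait <- stats::rexp(1, n_alive * (birth + death))
    if (length(origin) >= n_tips) {
      t_present <- t_now + wait / 2
      break
    }
    t_now <- t_now + wait
    who <- if (n_alive == 1) which(alive) else sample(which(alive), 1)
    if (stats::runif(1) < birth / (birth + death)) {
      origin <- c(origin, t_now)
      died <- c(died, NA_real_)
      parent <- c(parent, who)
      alive <- c(alive, TRUE)
    } else {
      died[who] <- t_now
      alive[who] <- FALSE
    }
  }
  died[is.na(died)] <- t_present
  if (length(origin) != n_tips) return(NULL)
  labels <- paste0("t", seq_along(origin))
  # species s with daughters d1..dk (oldest first) renders as a pectinate
  # chain of budding nodes ending in s's own terminal segment
  render <- function(s) {
    ds <- which(parent == s)
    if (length(ds) == 0) return(paste0(labels[s], ":", died[s] - origin[s]))
    ds <- ds[order(origin[ds])]
    cur <- paste0(labels[s], ":", died[s] - origin[ds[length(ds)]])
    for (i in rev(seq_along(ds))) {
      top <- if (i == 1) origin[s] else origin[ds[i - 1]]
      cur <- paste0("(", render(ds[i]), ",", cur, "):", origin[ds[i]] - top)
    }
    cur
  }
  # species 1's stem before its first budding is dropped (no root edge)
  d1 <- which(parent == 1L)
  if (length(d1) == 0) return(NULL)
  txt <- render(1L)
  txt <- paste0(sub(":[-0-9.e]+$", "", txt), ";")
  tree <- ape::read.tree(text = txt)
  root_age <- t_present - min(origin[d1])
  depth <- ape::node.depth.edgelength(tree)
  tree$node_age <- root_age - depth
  tree$node_age[abs(tree$node_age) < 1e-9] <- 0
  taxa <- tibble::tibble(
    taxon = tree$tip.label,
    true_fad = t_present - origin[match(tree$tip.label, labels)],
    true_lad = t_present - died[match(tree$tip.label, labels)]
  )
  # the root species' observable record starts at the first divergence
  taxa$true_fad[taxa$taxon == labels[1]] <- root_age
  taxa$true_lad[abs(taxa$true_lad) < 1e-9] <- 0
  list(tree = tree, taxa = taxa)
}

#' True standing richness of a simulated record
#'
#' Counts, per bin, the species of the true tree whose true range (budding
#' to death) intersects the bin, under the same interval convention as
#' [max_richness_curve()]. Under budding speciation every lineage of the
#' tree belongs to some species' range, so species ranges are the complete
#' set of true lineage spans. The root species' stem before the first
#' divergence is not counted.
#'
#' @param record A [simulate_fossil_record()] result.
#' @param grid A [make_time_grid()] grid.
#' @param convention A [richness_convention()].
#' @return A `richness_curve` with provenance `"true"`.
#' @export
true_richness_curve <- function(record, grid,
                                convention = richness_convention()) {
  spans <- true_spans(record)
  counts <- vapply(seq_len(nrow(grid)), function(i) {
    sum(span_hits_bin(spans$old, spans$young, grid$bin_old[i],
                      grid$bin_young[i], convention$bin_side))
  }, numeric(1))
  new_richness_curve(grid, counts, "true")
}

true_spans <- function(record) {
  tibble::tibble(label = record$taxa$taxon,
                 old = record$taxa$true_fad,
                 young = record$taxa$true_lad,
                 kind = "tip")
}

#' Simulate discrete characters on a tree (Mk model)
#'
#' Evolves `n_chars` characters along the branches of a time-scaled tree by
#' a continuous-time Markov process at the given rate: unordered characters
#' jump to a uniformly chosen different state, ordered characters step
#' `+1`/`-1` (reflecting at the ends of the state scale). The first
#' `round(ordered_fraction * n_chars)` characters are evolved and flagged as
#' ordered.
#'
#' @param tree A `phylo` with `edge.length` in Ma (e.g. a simulated record's
#'   tree).
#' @param n_chars Number of characters.
#' @param rate Expected changes per Ma per character.
#' @param n_states Number of states (2--10).
#' @param ordered_fraction Fraction of ordered characters.
#' @param seed Integer seed.
#' @return A [character_matrix()].
#' @export
simulate_characters <- function(tree, n_chars, rate = 0.1, n_states = 3,
                                ordered_fraction = 0, seed = 1) {
  stopifnot(n_states >= 2, n_states <= 10, rate >= 0)
  if (is.null(tree$edge.length)) {
    stop("tree needs branch lengths (durations in Ma)", call. = FALSE)
  }
  n_ord <- round(ordered_fraction * n_chars)
  ord <- seq_len(n_chars) <= n_ord
  ntip <- length(tree$tip.label)
  withr::with_seed(seed, {
    states <- matrix(NA_integer_, ntip + tree$Nnode, n_chars)
    states[ntip + 1L, ] <- sample.int(n_states, n_chars, replace = TRUE) - 1L
    pre <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(pre$edge))) {
      p <- pre$edge[k, 1]; ch <- pre$edge[k, 2]
      len <- pre$edge.length[k]
      states[ch, ] <- vapply(seq_len(n_chars), function(j) {
        evolve_state(states[p, j], len, rate, n_states, ord[j])
      }, integer(1))
    }
  })
  cell_list <- lapply(seq_len(ntip), function(i) as.list(states[i, ]))
  names(cell_list) <- tree$tip.label
  character_matrix(cell_list, ordered = ord)
}

evolve_state <- function(s, len, rate, n_states, ordered) {
  n_ev <- stats::rpois(1, rate * len)
  for (e in seq_len(n_ev)) {
    if (ordered) {
      s <- if (s == 0L) 1L
      else if (s == n_states - 1L) s - 1L
      else s + sample(c(-1L, 1L), 1)
    } else {
      others <- setdiff(0:(n_states - 1L), s)
      s <- if (length(others) == 1) others else sample(others, 1)
    }
  }
  as.integer(s)
}

#' @export
print.simulated_record <- function(x, ...) {
  cat("Simulated fossil record: ", nrow(x$taxa), " taxa, root age ",
      round(max(x$tree$node_age), 3), " Ma (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
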