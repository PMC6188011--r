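# Independent brute-force oracles. These deliberately re-derive results from
# first principles (exhaustive enumeration, naive interval arithmetic) and
# share no code with the package internals they check.

# children list of a phylo, indexed by node id
phylo_kids <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[k, 2])
  }
  kids
}

# minimum per-bin lineage count by exhaustive search over per-taxon endpoint
# choices (window endpoints, known-range endpoints, bin edges where inside)
brute_min_count <- function(tree, ranges, bin_old, bin_young) {
  tips <- tree$tip.label
  rng <- ranges[match(tips, ranges$taxon), ]
  choices <- lapply(seq_along(tips), function(i) {
    if (!is.na(rng$known_oldest[i])) {
      s_cand <- unique(c(rng$known_oldest[i], rng$oldest[i], bin_old, bin_young))
      s_cand <- s_cand[s_cand >= rng$known_oldest[i] & s_cand <= rng$oldest[i]]
      e_cand <- unique(c(rng$youngest[i], rng$known_youngest[i], bin_old, bin_young))
      e_cand <- e_cand[e_cand >= rng$youngest[i] & e_cand <= rng$known_youngest[i]]
      expand.grid(s = s_cand, e = e_cand)
    } else {
      t_cand <- unique(c(rng$youngest[i], rng$oldest[i], bin_old, bin_young))
      t_cand <- t_cand[t_cand >= rng$youngest[i] & t_cand <= rng$oldest[i]]
      data.frame(s = t_cand, e = t_cand)
    }
  })
  ntip <- length(tips)
  kids <- phylo_kids(tree)
  count_config <- function(s, e) {
    age <- numeric(ntip + tree$Nnode)
    fill <- function(v) {
      if (v <= ntip) return(s[v])
      age[v] <<- max(vapply(kids[[v]], fill, numeric(1)))
      age[v]
    }
    fill(ntip + 1L)
    age[seq_len(ntip)] <- s
    n <- 0
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      if (ch <= ntip) {
        old <- age[p]; young <- e[ch]
      } else {
        old <- age[p]; young <- age[ch]
        if (old == young) next  # zero-length internal edge
      }
      if (old >= bin_young && young < bin_old) n <- n + 1
    }
    n
  }
  idx <- lapply(choices, function(d) seq_len(nrow(d)))
  grid <- expand.grid(idx)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    s <- vapply(seq_along(tips), function(i) choices[[i]]$s[grid[r, i]], numeric(1))
    e <- vapply(seq_along(tips), function(i) choices[[i]]$e[grid[r, i]], numeric(1))
    best <- min(best, count_config(s, e))
  }
  best
}

# exhaustive parsimony length: minimise over every assignment of single
# states to internal nodes
brute_parsimony_length <- function(tree, cm) {
  ntip <- length(tree$tip.label)
  masks <- cm$masks[tree$tip.label, , drop = FALSE]
  states_of <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:9)) > 0L) - 1L
  total <- 0
  for (j in seq_len(cm$n_char)) {
    obs <- unlist(lapply(masks[, j], states_of))
    if (length(obs) == 0) next
    smax <- max(obs)
    alphabet <- 0:smax
    n_int <- tree$Nnode
    assign_grid <- do.call(expand.grid, rep(list(alphabet), n_int))
    tipcost <- function(state, mask) {
      if (mask == 0L) return(0)
      st <- states_of(mask)
      if (cm$ordered[j]) {
        max(0, min(st) - state, state - max(st))
      } else {
        if (state %in% st) 0 else 1
      }
    }
    best <- Inf
    for (r in seq_len(nrow(assign_grid))) {
      anc <- as.numeric(assign_grid[r, ])
      cost <- 0
      for (k in seq_len(nrow(tree$edge))) {
        p <- anc[tree$edge[k, 1] - ntip]
        ch <- tree$edge[k, 2]
        cost <- cost + if (ch <= ntip) {
          tipcost(p, masks[ch, j])
        } else {
          q <- anc[ch - ntip]
          if (cm$ordered[j]) abs(p - q) else as.numeric(p != q)
        }
      }
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}

# every unrooted binary topology on a tip set, built by sequential edge
# insertion; returned rooted at the first tip's pendant edge
all_unrooted_topologies <- function(tips) {
  stopifnot(length(tips) >= 3)
  base <- list(list(tips[1], list(tips[2], tips[3])))
  insert_all <- function(nl, tip) {
    out <- list(list(nl, tip))
    rec <- function(x, rebuild) {
      res <- list(rebuild(list(x, tip)))
      if (is.list(x)) {
        res <- c(res,
                 rec(x[[1]], function(s) rebuild(list(s, x[[2]]))),
                 rec(x[[2]], function(s) rebuild(list(x[[1]], s))))
      }
      res
    }
    c(out, rec(nl[[1]], function(s) list(s, nl[[2]])),
      rec(nl[[2]], function(s) list(nl[[1]], s)))
  }
  trees <- base
  for (tip in tips[-(1:3)]) {
    trees <- do.call(c, lapply(trees, insert_all, tip = tip))
  }
  # dedupe as unrooted topologies via ape
  phy <- lapply(trees, function(nl) {
    render <- function(x) {
      if (is.character(x)) return(x)
      paste0("(", render(x[[1]]), ",", render(x[[2]]), ")")
    }
    ape::read.tree(text = paste0(render(nl), ";"))
  })
  keep <- !duplicated(vapply(phy, function(t) {
    ape::write.tree(ape::root(ape::unroot(t), outgroup = tips[1],
                              resolve.root = TRUE))
  }, character(1)))
  # also dedupe by unrooted topology distance 0
  phy <- phy[keep]
  uniq <- list()
  for (t in phy) {
    dup <- any(vapply(uniq, function(u) {
      ape::dist.topo(ape::unroot(t), ape::unroot(u)) == 0
    }, logical(1)))
    if (!dup) uniq[[length(uniq) + 1L]] <- t
  }
  uniq
}

# random small character matrix (cells can be polymorphic or missing)
random_matrix <- function(taxa, n_char, n_states = 3, p_missing = 0.1,
                          p_poly = 0.1, ordered = logical(n_char)) {
  cells <- lapply(taxa, function(t) {
    lapply(seq_len(n_char), function(j) {
      u <- runif(1)
      if (u < p_missing) return(integer(0))
      if (u < p_missing + p_poly) {
        sort(sample(0:(n_states - 1), 2))
      } else {
        sample(0:(n_states - 1), 1)
      }
    })
  })
  names(cells) <- taxa
  character_matrix(cells, ordered = ordered)
}

toy_ranges <- function(taxon, oldest, youngest, known_oldest = NA,
                       known_youngest = NA, ...) {
  validate_taxon_ranges(tibble::tibble(
    taxon = taxon, oldest = oldest, youngest = youngest,
    known_oldest = known_oldest, known_youngest = known_youngest,
    region = "EastPacific", analyzed = TRUE, count_in = "both", ...))
}
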