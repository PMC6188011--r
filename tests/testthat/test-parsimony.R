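nexus_fixture <- function() {
  tf <- withr::local_tempfile(fileext = ".nex", .local_envir = parent.frame())
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    "DIMENSIONS NTAX=4 NCHAR=5;",
    "FORMAT SYMBOLS=\"012\" MISSING=? GAP=-;",
    "MATRIX",
    "TaxA  00?1(01)",
    "TaxB  01-12",
    "'Tax C'  011{12}2",
    "TaxD  10002",
    ";",
    "END;"), tf)
  tf
}

test_that("nexus matrices parse cells, polymorphism and missing data", {
  cm <- read_nexus_matrix(nexus_fixture(), ordered = c(5))
  expect_equal(length(cm$taxa), 4)
  expect_equal(cm$n_char, 5)
  expect_true("Tax_C" %in% cm$taxa)
  expect_equal(sum(cm$ordered), 1)
  # '?' and '-' are missing (mask 0), sets keep their members
  expect_equal(unname(cm$masks["TaxA", 3]), 0L)
  expect_equal(unname(cm$masks["TaxB", 3]), 0L)
  expect_equal(unname(cm$masks["TaxA", 5]), bitwOr(1L, 2L))    # (01)
  expect_equal(unname(cm$masks["Tax_C", 4]), bitwOr(2L, 4L))   # {12}
})

test_that("nexus round-trip and dimension mismatches", {
  cm <- read_nexus_matrix(nexus_fixture())
  tf <- withr::local_tempfile(fileext = ".nex")
  write_nexus_matrix(cm, tf)
  cm2 <- read_nexus_matrix(tf)
  expect_equal(cm2$masks, cm$masks)
  bad <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=2 NCHAR=3;",
               "MATRIX", "A 01", "B 010", ";", "END;"), bad)
  expect_error(read_nexus_matrix(bad), "NCHAR")
})

test_that("tree length scores simple cases by hand", {
  cm <- character_matrix(list(A = list(0L), B = list(0L), C = list(1L), D = list(1L)))
  expect_equal(tree_length(read_newick("((A,B),(C,D));"), cm), 1)
  expect_equal(tree_length(read_newick("((A,C),(B,D));"), cm), 2)
  # ordered characters pay the linear cost between sister states
  cmo <- character_matrix(list(A = list(0L), B = list(2L), C = list(0L), D = list(0L)),
                          ordered = 1)
  expect_equal(tree_length(read_newick("((A,B),(C,D));"), cmo), 2)
  cmu <- character_matrix(list(A = list(0L), B = list(2L), C = list(0L), D = list(0L)))
  expect_equal(tree_length(read_newick("((A,B),(C,D));"), cmu), 1)
  # constant and all-missing characters are free
  cmc <- character_matrix(list(A = list(1L, integer(0)), B = list(1L, integer(0)),
                               C = list(1L, integer(0)), D = list(1L, integer(0))),
                          ordered = 2)
  expect_equal(tree_length(read_newick("((A,B),(C,D));"), cmc), 0)
})

test_that("tree length equals the exhaustive ancestral-state minimum", {
  set.seed(11)
  tree <- read_newick("(((A,B),C),(D,(E,F)));")
  for (rep_i in 1:4) {
    ord <- runif(5) < 0.4
    cm <- random_matrix(LETTERS[1:6], 5, n_states = 3, ordered = ord)
    expect_equal(tree_length(tree, cm), brute_parsimony_length(tree, cm),
                 info = paste("rep", rep_i))
  }
})

test_that("tree length is invariant under rerooting", {
  set.seed(3)
  cm <- random_matrix(LETTERS[1:6], 8, n_states = 4, ordered = c(rep(TRUE, 3), rep(FALSE, 5)))
  tree <- read_newick("(((A,B),C),(D,(E,F)));")
  len <- tree_length(tree, cm)
  for (tip in c("B", "D", "F")) {
    rerooted <- ape::root(ape::unroot(tree), outgroup = tip, resolve.root = TRUE)
    expect_equal(tree_length(rerooted, cm), len)
  }
})

test_that("tree length agrees with independent Fitch/Sankoff implementations", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  tree <- ape::unroot(read_newick("(((A,B),C),(D,(E,F)));"))
  # unordered: no polymorphism so phangorn's contrast handling matches
  cm <- random_matrix(LETTERS[1:6], 10, n_states = 3, p_missing = 0.1, p_poly = 0)
  states_chr <- apply(cm$masks, c(1, 2), function(m) {
    if (m == 0) "?" else as.character(which(bitwAnd(m, bitwShiftL(1L, 0:9)) > 0) - 1)
  })
  pd <- phangorn::phyDat(states_chr, type = "USER", levels = c("0", "1", "2"),
                         ambiguity = "?")
  expect_equal(tree_length(tree, cm),
               as.numeric(phangorn::parsimony(tree, pd, method = "fitch")))
  # ordered = sankoff with |i - j| costs
  cmo <- cm; cmo$ordered <- rep(TRUE, cm$n_char)
  cost <- outer(0:2, 0:2, function(i, j) abs(i - j))
  dimnames(cost) <- list(c("0", "1", "2"), c("0", "1", "2"))
  expect_equal(tree_length(tree, cmo),
               as.numeric(phangorn::parsimony(tree, pd, method = "sankoff",
                                              cost = cost)))
})

test_that("heuristic search finds the global optimum on 5-taxon instances", {
  set.seed(5)
  for (rep_i in 1:3) {
    cm <- random_matrix(LETTERS[1:5], 8, n_states = 3, p_missing = 0.05,
                        ordered = runif(8) < 0.3)
    all_trees <- all_unrooted_topologies(LETTERS[1:5])
    expect_length(all_trees, 15)
    exhaustive <- min(vapply(all_trees, tree_length, numeric(1), cm = cm))
    fit <- heuristic_search(cm, replicates = 3, swapper = "SPR", seed = rep_i)
    expect_equal(fit$length, exhaustive, info = paste("rep", rep_i))
  }
})

test_that("search is reproducible and swappers agree on small instances", {
  set.seed(9)
  cm <- random_matrix(LETTERS[1:6], 10, n_states = 3)
  f1 <- heuristic_search(cm, replicates = 2, swapper = "TBR", seed = 99)
  f2 <- heuristic_search(cm, replicates = 2, swapper = "TBR", seed = 99)
  expect_equal(f1$length, f2$length)
  expect_equal(lapply(f1$trees, ape::write.tree), lapply(f2$trees, ape::write.tree))
  f3 <- heuristic_search(cm, replicates = 3, swapper = "NNI", seed = 1)
  expect_equal(f3$length, f1$length)
  expect_error(heuristic_search(random_matrix(LETTERS[1:3], 4), seed = 1),
               "4 taxa")
  g <- glance(f1)
  expect_equal(g$length, f1$length)
  expect_equal(nrow(tidy(f1)), length(f1$trees))
})

test_that("bootstrap recovers a clade every character supports", {
  cells <- list(A = as.list(c(1L, 1L, 1L, 0L)), B = as.list(c(1L, 1L, 1L, 0L)),
                C = as.list(c(0L, 0L, 0L, 0L)), D = as.list(c(0L, 0L, 0L, 1L)),
                E = as.list(c(0L, 0L, 0L, 1L)))
  cm <- character_matrix(cells)
  bs <- bootstrap_support(cm, outgroup = "C", reps = 10, seed = 4)
  ab <- unname(bs$freq[bs$clade == "A|B"])
  expect_equal(ab, 1.0)
  expect_true(all(bs$freq >= 0 & bs$freq <= 1))
  bs2 <- bootstrap_support(cm, outgroup = "C", reps = 10, seed = 4)
  expect_equal(bs, bs2)
  expect_error(bootstrap_support(cm, outgroup = "C", reps = 0), "reps")
})

test_that("strict consensus keeps exactly the shared clades", {
  t1 <- read_newick("(((A,B),C),D);")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(strict_consensus(list(t1, t1))), ape::unroot(t1))), 0)
  t2 <- read_newick("(((A,C),B),D);")
  cons <- strict_consensus(list(t1, t2))
  # the conflicting cherry collapses into a trichotomy
  expect_equal(cons$Nnode, 2)
  expect_error(strict_consensus(list(t1, read_newick("((A,B),(C,X));"))),
               "tip sets")
})
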