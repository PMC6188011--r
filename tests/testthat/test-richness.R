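test_that("maximum calibration reproduces hand-worked node ages and spans", {
  tree <- read_newick("((A,B),C);")
  rng <- toy_ranges(c("A", "B", "C"), oldest = c(10, 6, 4), youngest = c(8, 5, 3))
  ct <- max_calibrate(tree, rng)
  expect_equal(ct$root_age, 10)
  sp <- ct$spans
  expect_equal(sp$old[sp$label == "A"], 10)
  expect_equal(sp$young[sp$label == "A"], 8)
  expect_equal(sp$old[sp$label == "B"], 10)  # ghost lineage back to the node
  expect_equal(sp$young[sp$label == "B"], 5)
  expect_equal(sp$old[sp$label == "C"], 10)
  expect_equal(sp$young[sp$label == "C"], 3)
  # the internal edge is zero-length (both nodes at 10 Ma)
  int <- sp[sp$kind == "internal", ]
  expect_equal(int$old, int$young)
  expect_error(max_calibrate(tree, rng[-1, ]), "without a range")
})

test_that("the maximum curve counts interval overlaps per bin", {
  tree <- read_newick("((A,B),C);")
  rng <- toy_ranges(c("A", "B", "C"), oldest = c(10, 6, 4), youngest = c(8, 5, 3))
  g <- make_time_grid(10, 3, 1)
  mc <- max_richness_curve(tree, g, ranges = rng)
  expect_equal(mc$count, c(3, 3, 2, 2, 2, 1, 1))
  # beyond the root everything is zero
  g2 <- make_time_grid(14, 11, 1)
  expect_equal(max_richness_curve(tree, g2, ranges = rng)$count, rep(0L, 3))
  # two tips with equal first appearances share the root age
  cherry <- max_calibrate(read_newick("(A,B);"),
                          toy_ranges(c("A", "B"), c(7, 7), c(2, 1)))
  expect_equal(cherry$root_age, 7)
  expect_equal(cherry$spans$old, c(7, 7))
})

test_that("maximum curve is invariant to tip order in the newick string", {
  rng <- toy_ranges(c("A", "B", "C", "D"), oldest = c(9, 7, 5, 3),
                    youngest = c(8, 4, 2, 1))
  g <- make_time_grid(10, 0, 0.5)
  c1 <- max_richness_curve(read_newick("((A,B),(C,D));"), g, ranges = rng)
  c2 <- max_richness_curve(read_newick("((D,C),(B,A));"), g, ranges = rng)
  expect_equal(c1$count, c2$count)
})

test_that("minimum curve solves the hand-checked cherry cases", {
  tree <- read_newick("(A,B);")
  rng <- toy_ranges(c("A", "B"), oldest = c(10, 0), youngest = c(9, 0))
  g <- make_time_grid(12, 0, 1)
  mn <- min_richness_curve(tree, rng, g)
  # in (11,10] A can be placed at 9.x, so nothing is alive yet
  expect_equal(mn$count[g$bin_old == 11], 0L)
  # in (5,4] B's ghost lineage is forced: the root is at least as old as A
  expect_equal(mn$count[g$bin_old == 5], 1L)
})

test_that("degenerate windows collapse the minimum onto the maximum", {
  tree <- read_newick("((A,B),(C,D));")
  rng <- toy_ranges(c("A", "B", "C", "D"), oldest = c(9, 7, 5, 3),
                    youngest = c(9, 7, 5, 3))
  g <- make_time_grid(10, 0, 0.5)
  expect_equal(min_richness_curve(tree, rng, g)$count,
               max_richness_curve(tree, g, ranges = rng)$count)
})

test_that("a known range always contributes to the bins it spans", {
  tree <- read_newick("((A,B),C);")
  rng <- toy_ranges(c("A", "B", "C"), oldest = c(10, 9, 4),
                    youngest = c(2, 1, 0),
                    known_oldest = c(8, NA, NA), known_youngest = c(6, NA, NA))
  g <- make_time_grid(10, 0, 1)
  mn <- min_richness_curve(tree, rng, g)
  expect_true(all(mn$count[g$bin_old %in% c(8, 7)] >= 1))
})

test_that("minimum curve equals exhaustive endpoint enumeration", {
  set.seed(42)
  for (rep_i in 1:6) {
    n <- sample(3:6, 1)
    topo <- all_unrooted_topologies(LETTERS[1:n])[[1]]
    topo <- ape::root(ape::unroot(topo), outgroup = "A", resolve.root = TRUE)
    old <- round(runif(n, 2, 10), 1)
    rng <- toy_ranges(LETTERS[1:n], oldest = old,
                      youngest = round(pmax(old - runif(n, 0.5, 6), 0), 1))
    g <- make_time_grid(11, 0, 1)
    mn <- min_richness_curve(topo, rng, g)
    for (b in seq_len(nrow(g))) {
      expect_equal(mn$count[b],
                   brute_min_count(topo, rng, g$bin_old[b], g$bin_young[b]),
                   info = paste("rep", rep_i, "bin", b))
    }
  }
})

test_that("minimum never exceeds maximum, and window widening is monotone", {
  set.seed(7)
  tree <- read_newick("(((A,B),C),(D,E));")
  instant_count <- function(ct, ages) {
    sp <- tidy(ct)
    sp <- sp[!(sp$kind == "internal" & sp$old == sp$young), ]
    vapply(ages, function(a) sum(sp$old >= a & sp$young <= a), numeric(1))
  }
  for (rep_i in 1:5) {
    old <- round(runif(5, 3, 12), 1)
    rng <- toy_ranges(LETTERS[1:5], oldest = old,
                      youngest = round(pmax(old - runif(5, 0.5, 5), 0), 1))
    g <- make_time_grid(13, 0, 0.5)
    mx <- max_richness_curve(tree, g, ranges = rng)
    mn <- min_richness_curve(tree, rng, g)
    expect_true(all(mn$count <= mx$count))
    # widening in the young direction leaves node ages alone: bin-monotone
    rng_y <- rng
    rng_y$youngest[3] <- max(rng_y$youngest[3] - 1, 0)
    expect_true(all(max_richness_curve(tree, g, ranges = rng_y)$count >= mx$count))
    # widening in either direction never loses a lineage at any instant,
    # and can only relax the minimum
    rng2 <- rng_y
    rng2$oldest[2] <- rng2$oldest[2] + 1
    ages <- seq(0, 13, by = 0.25)
    expect_true(all(instant_count(max_calibrate(tree, rng2), ages) >=
                      instant_count(max_calibrate(tree, rng), ages)))
    expect_true(all(min_richness_curve(tree, rng2, g)$count <= mn$count))
  }
})

test_that("envelopes are per-bin extrema over the tree set", {
  rng <- toy_ranges(c("A", "B", "C", "D"), oldest = c(9, 7, 5, 3),
                    youngest = c(8, 4, 2, 1))
  g <- make_time_grid(10, 0, 0.5)
  t1 <- read_newick("((A,B),(C,D));")
  t2 <- read_newick("(((A,B),C),D);")
  env <- envelope_curve(list(t1, t2), rng, g, "max")
  c1 <- max_richness_curve(t1, g, ranges = rng)$count
  c2 <- max_richness_curve(t2, g, ranges = rng)$count
  expect_equal(env$count, pmax(c1, c2))
  # identical trees: envelope equals the single-tree curve
  env_same <- envelope_curve(list(t1, t1), rng, g, "max")
  expect_equal(env_same$count, c1)
  # min envelope is bin-wise below every per-tree min curve
  envm <- envelope_curve(list(t1, t2), rng, g, "min")
  expect_true(all(envm$count <= min_richness_curve(t1, rng, g)$count))
  expect_true(all(envm$count <= min_richness_curve(t2, rng, g)$count))
  expect_error(envelope_curve(list(), rng, g), "empty")
})

test_that("agreement summary counts identical and within-one bins", {
  rng <- toy_ranges(c("A", "B", "C", "D"), oldest = c(9, 7, 5, 3),
                    youngest = c(8, 4, 2, 1))
  g <- make_time_grid(10, 0, 0.5)
  t1 <- read_newick("((A,B),(C,D));")
  ag1 <- agreement_summary(list(t1), rng, g)
  expect_equal(ag1$n_identical, nrow(g))
  expect_equal(ag1$n_within_one, 0)
  t2 <- read_newick("(((A,B),C),D);")
  ag2 <- agreement_summary(list(t1, t2), rng, g)
  c1 <- max_richness_curve(t1, g, ranges = rng)$count
  c2 <- max_richness_curve(t2, g, ranges = rng)$count
  expect_equal(ag2$n_identical, sum(c1 == c2))
  expect_equal(ag2$n_within_one, sum(abs(c1 - c2) == 1))
  expect_lte(ag2$n_identical + ag2$n_within_one, nrow(g))
})

test_that("region-pruned maximum curve never exceeds the full curve", {
  r <- odobenid_ranges()
  g <- make_time_grid()
  tree <- attach_max_only_taxa(odobenid_tree_set()[[1]], r)
  full <- max_richness_curve(tree, g, ranges = r)
  ep <- prune_to_region(tree, r, "EastPacific", also_keep = "Odobenus_rosmarus")
  pruned <- max_richness_curve(ep, g, ranges = r)
  expect_true(all(pruned$count <= full$count))
})

test_that("the crown-clade node calibrates to the oldest almejas taxa", {
  r <- odobenid_ranges()
  tree <- odobenid_tree_set()[[1]]
  ct <- max_calibrate(tree, r)
  # Neodobenia = Gomphotaria + Dusignathus spp. + Odobeninae; its node age is
  # driven by the 8.0 Ma maximum ages of Aivukus and D. santacruzensis
  neo <- c("Gomphotaria_pugnax", "Dusignathus_seftoni",
           "Dusignathus_santacruzensis", "Aivukus_cedrosensis",
           "Protodobenus_japonicus", "Ontocetus_emmonsi",
           "Valenictus_chulavistensis", "Odobenus_rosmarus")
  node <- ape::getMRCA(ct$tree, neo)
  expect_equal(ct$node_age[node], 8.0)
})

test_that("curves tabulate with stages and convention toggles change counts", {
  g <- make_time_grid()
  r <- odobenid_ranges()
  tree <- attach_max_only_taxa(odobenid_tree_set()[[1]], r)
  mc <- max_richness_curve(tree, g, ranges = r)
  tab <- curve_to_table(mc)
  expect_equal(nrow(tab), 173)
  expect_true(all(c("stage", "count") %in% names(tab)))
  expect_equal(sum(tab$count), sum(mc$count))
  # counting zero-length internal edges can only increase counts
  mc2 <- max_richness_curve(tree, g, ranges = r,
                            convention = richness_convention(count_zero_internal = TRUE))
  expect_true(all(mc2$count >= mc$count))
  # old-closed bins shift boundary-touching spans by one bin
  mc3 <- max_richness_curve(tree, g, ranges = r,
                            convention = richness_convention(bin_side = "old"))
  expect_equal(sum(mc3$count > 0) > 0, TRUE)
})

test_that("the one-shot odobenid analysis stacks the expected curves", {
  res <- odobenid_richness(grid = make_time_grid(17.3, 0, 0.1),
                           region = "EastPacific")
  expect_s3_class(res, "richness_curve")
  expect_setequal(unique(res$provenance),
                  c("envelope_max", "envelope_min", "pruned"))
  expect_equal(sum(res$provenance == "envelope_max"), 173)
  by_prov <- split(res$count, res$provenance)
  expect_true(all(by_prov$envelope_min <= by_prov$envelope_max))
  expect_true(all(by_prov$pruned <= by_prov$envelope_max))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
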