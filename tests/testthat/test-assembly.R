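test_that("plot partition obeys the set identities", {
  p <- partition_plot(c("A", "B", "C"), c("B", "C", "D"), "p1")
  expect_setequal(p$persist, c("B", "C"))
  expect_setequal(p$extinct, "A")
  expect_setequal(p$colonize, "D")

  p <- partition_plot(c("A", "B"), c("A", "B"))
  expect_length(p$extinct, 0)
  expect_length(p$colonize, 0)

  p <- partition_plot("A", "B")
  expect_length(p$persist, 0)
  expect_setequal(p$extinct, "A")
  expect_setequal(p$colonize, "B")

  # identities on random partitions
  set.seed(2)
  for (i in 1:20) {
    sp <- paste0("s", 1:15)
    sown <- sample(sp, 7); final <- sample(sp, 6)
    p <- partition_plot(sown, final)
    expect_setequal(union(p$persist, p$extinct), sown)
    expect_setequal(union(p$persist, p$colonize), final)
    expect_length(intersect(p$extinct, p$colonize), 0)
    expect_length(intersect(p$persist, p$extinct), 0)
  }
})

test_that("cross-group MNND equals the exhaustive min-scan", {
  d <- matrix(c(0, 1, 3, 1, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "D"), c("A", "B", "D")))
  expect_equal(cross_group_mnnd("D", c("A", "B"), d), 3)
  expect_error(cross_group_mnnd("A", c("A", "B"), d), "overlap")
  expect_error(cross_group_mnnd(character(), "A", d), "non-empty")

  set.seed(14)
  for (i in 1:20) {
    tr <- ape::rtree(8)
    dm <- patristic_matrix(tr)
    focal <- sample(tr$tip.label, 3)
    ref <- sample(setdiff(tr$tip.label, focal), 4)
    expect_equal(cross_group_mnnd(focal, ref, dm),
                 oracle_cross_mnnd(dm, focal, ref), tolerance = 1e-12)
  }
})

test_that("colonists that are close relatives of residents test as clustered", {
  tr <- clustered_fixture_tree()
  d <- patristic_matrix(tr)
  part <- partition_plot(sown = c("r1", "r2", "r3"),
                         final = c("r1", "r2", "r3", "c1", "c2", "c3"), "fx")
  r <- colonist_relatedness_test(part, pool = tr$tip.label, dist = d,
                                 n_rand = 999, seed = 6)
  expect_equal(r$observed, 0.02)  # each colonist 0.02 from its sister resident
  expect_equal(r$direction, "clustered")
  expect_lt(r$p, 0.05)
  expect_equal(r$n_focal, 3)
})

test_that("degenerate colonist null pools are flagged with zero sd", {
  tr <- cherry_tree()
  d <- patristic_matrix(tr)
  part <- partition_plot(sown = c("A", "B"), final = c("A", "B", "C"))
  # pool minus sown is exactly the observed colonist: every draw identical
  r <- colonist_relatedness_test(part, pool = c("A", "B", "C"), dist = d,
                                 n_rand = 49, seed = 3)
  expect_true(r$sd_zero)
  expect_equal(r$ses, 0)
})

test_that("clade exclusion removes legumes from focal set and null pool", {
  tr <- clustered_fixture_tree()
  tags <- stats::setNames(rep("other", length(tr$tip.label)), tr$tip.label)
  tags[c("d01", "d02", "d03", "c3")] <- "legume"
  d <- patristic_matrix(tr)
  # poison legume distances: any legume drawn into a null would propagate NA
  d_poison <- d
  legs <- names(tags)[tags == "legume"]
  d_poison[legs, ] <- NA_real_; d_poison[, legs] <- NA_real_
  part <- partition_plot(sown = c("r1", "r2", "r3"),
                         final = c("r1", "r2", "r3", "c1", "c3", "d04"), "fx")
  r <- colonist_relatedness_test(part, pool = tr$tip.label, dist = d_poison,
                                 tags = tags, exclude_tags = "legume",
                                 n_rand = 199, seed = 4)
  expect_true(all(is.finite(r$null_values)))
  expect_true(is.finite(r$observed))
  expect_equal(r$n_focal, 2)  # c3 dropped from the focal colonists
})

test_that("the established-residents variant counts other colonists", {
  tr <- clustered_fixture_tree()
  d <- patristic_matrix(tr)
  # colonists d01, d02 are 1.0 apart via their clade, far from residents
  part <- partition_plot(sown = c("r1", "r2"),
                         final = c("r1", "r2", "d01", "d02"), "fx")
  r_sown <- colonist_relatedness_test(part, tr$tip.label, d,
                                      residents = "sown", n_rand = 19, seed = 1)
  r_est <- colonist_relatedness_test(part, tr$tip.label, d,
                                     residents = "established", n_rand = 19,
                                     seed = 1)
  expect_equal(r_sown$observed,
               oracle_cross_mnnd(d, c("d01", "d02"), c("r1", "r2")))
  expect_equal(r_est$observed, d["d01", "d02"])  # nearest is the other colonist
  expect_lt(r_est$observed, r_sown$observed)
})

test_that("extinction null relabels within the sown set", {
  tr <- cherry_tree()
  d <- patristic_matrix(tr)
  # 1 extinct of 2 sown: both relabelings give the same statistic
  part <- partition_plot(sown = c("A", "B"), final = "B")
  r <- extinction_relatedness_test(part, d, n_rand = 99, seed = 5)
  expect_equal(r$observed, 2)
  expect_true(all(r$null_values == 2))
  expect_true(r$sd_zero)
  expect_equal(r$p, 1)

  # 3 sown, extinct = A: null values enumerate {2, 2, 4}
  part <- partition_plot(sown = c("A", "B", "C"), final = c("B", "C"))
  r <- extinction_relatedness_test(part, d, n_rand = 999, seed = 5)
  expect_equal(r$observed, 2)
  expect_setequal(unique(r$null_values), c(2, 4))
  expect_equal(mean(r$null_values), 8 / 3, tolerance = 0.1)
  expect_equal(r$p, 1)  # observed at the low mode, lower tail >> alpha

  expect_error(extinction_relatedness_test(
    partition_plot(c("A", "B"), c("A", "B")), d), "no extinctions")
  expect_error(extinction_relatedness_test(
    partition_plot(c("A", "B"), character()), d), "no surviving")
})

test_that("an isolated extinct species on a star tree sits in the upper tail", {
  tr <- read_phylogeny(text = "(A:1,B:1,C:1,D:10);")
  d <- patristic_matrix(tr)
  part <- partition_plot(sown = c("A", "B", "C", "D"), final = c("A", "B", "C"))
  r <- extinction_relatedness_test(part, d, n_rand = 999, seed = 7)
  expect_equal(r$observed, 11)
  expect_setequal(unique(r$null_values), c(2, 11))
  expect_gt(r$ses, 0)
  # p consistent with the rank rule applied to the enumerated null
  expect_equal(r$p, min(1, 2 * (min(sum(r$null_values <= 11),
                                    sum(r$null_values >= 11)) + 1) / 1000))
})

test_that("relatedness tests are calibrated under their own null process", {
  tree <- simulate_tree(sim_tree_config(seed = 3))
  tags <- attr(tree, "tags")
  dist <- patristic_matrix(tree)
  pool <- sort(tree$tip.label)
  n_plots <- 150
  ps <- with_seed(17, {
    sapply(seq_len(n_plots), function(i) {
      sown <- sample(pool, 8)
      colonists <- sample(setdiff(pool, sown), 3)
      extinct <- sample(sown, 3)
      part <- partition_plot(sown, union(setdiff(sown, extinct), colonists))
      c(col = colonist_relatedness_test(part, pool, dist, tags = tags,
                                        n_rand = 199)$p,
        ext = extinction_relatedness_test(part, dist, tags = tags,
                                          n_rand = 199)$p)
    })
  })
  # loose per-module bound; the strict band is checked at acceptance scale
  expect_lt(mean(ps["col", ] < 0.05), 0.12)
  expect_lt(mean(ps["ext", ] < 0.05), 0.12)
  expect_gt(suppressWarnings(stats::ks.test(ps["col", ], "punif"))$p.value, 0.01)
})

test_that("pool-level colonizer test flags a clade-restricted colonist set", {
  tree <- simulate_tree(sim_tree_config(seed = 8))
  tags <- attr(tree, "tags")
  dist <- patristic_matrix(tree)
  grasses <- names(tags)[tags == "grass"]
  r <- pool_dispersion_test(grasses, tree$tip.label, dist,
                            n_rand = 999, seed = 10)
  expect_equal(r$direction, "clustered")
  expect_lt(r$p, 0.05)

  r2 <- pool_dispersion_test(tree$tip.label, tree$tip.label, dist,
                             n_rand = 49, seed = 10)
  expect_true(r2$sd_zero)
  expect_equal(r2$ses, 0)
  expect_error(pool_dispersion_test("G01", tree$tip.label, dist), "at least 2")
})

test_that("results do not depend on species ordering in the inputs", {
  tr <- clustered_fixture_tree()
  d <- patristic_matrix(tr)
  sown <- c("r1", "r2", "d01"); final <- c("r1", "d01", "c1", "c2")
  p1 <- partition_plot(sown, final, "x")
  p2 <- partition_plot(rev(sown), rev(final), "x")
  perm <- sample(nrow(d))
  r1 <- colonist_relatedness_test(p1, tr$tip.label, d, n_rand = 99, seed = 2)
  r2 <- colonist_relatedness_test(p2, rev(tr$tip.label), d[perm, perm],
                                  n_rand = 99, seed = 2)
  expect_equal(r1$observed, r2$observed)
  expect_identical(r1$null_values, r2$null_values)
  e1 <- extinction_relatedness_test(p1, d, n_rand = 99, seed = 2)
  e2 <- extinction_relatedness_test(p2, d[perm, perm], n_rand = 99, seed = 2)
  expect_identical(e1$p, e2$p)
})

test_that("significant-plot counting matches known p-value fixtures", {
  mk <- function(p_target, obs, mu) {
    # construct a dispersion result with a prescribed tail count
    n <- 999
    k <- round(p_target * (n + 1) / 2 - 1)
    nv <- c(rep(obs - abs(obs) - 1, k), rep(mu + 1:(n - k)))
    dispersion_test(obs, nv)
  }
  res <- list(mk(0.002, 1, 5), mk(0.002, 1, 5), mk(0.5, 10, 5), mk(0.9, 5, 5))
  s <- count_significant(res, alpha = 0.05)
  expect_equal(s$n_tested, 4)
  expect_equal(s$n_clustered, 2)
  expect_equal(s$n_overdispersed, 0)
  expect_equal(s$expected_by_chance, 0L)
  expect_true(all(c("p_bh", "direction") %in% names(s$table)))
  expect_error(count_significant(list()), "no test results")

  # 41 non-significant results reproduce the expected-by-chance count of 2
  res41 <- replicate(41, dispersion_test(0, c(-(1:500), 1:500)),
                     simplify = FALSE)
  s41 <- count_significant(res41)
  expect_equal(s41$n_clustered + s41$n_overdispersed, 0)
  expect_equal(s41$expected_by_chance, 2L)
})
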