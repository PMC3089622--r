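test_that("Jaccard index matches hand values and is symmetric and bounded", {
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_error(jaccard(character(), character()), "empty")
  set.seed(3)
  sp <- paste0("s", 1:12)
  for (i in 1:20) {
    a <- sample(sp, sample(1:10, 1)); b <- sample(sp, sample(1:10, 1))
    j <- jaccard(a, b)
    expect_identical(j, jaccard(b, a))
    expect_gte(j, 0); expect_lte(j, 1)
  }
})

test_that("mean pairwise Jaccard handles the degenerate and hand cases", {
  ident <- community_table(list(p1 = c("A", "B"), p2 = c("A", "B"),
                                p3 = c("A", "B")))
  r <- mean_pairwise_jaccard(ident)
  expect_equal(r$mean, 1); expect_equal(r$se, 0); expect_equal(r$n_pairs, 3)

  disj <- community_table(list(p1 = "A", p2 = "B", p3 = "C"))
  r <- mean_pairwise_jaccard(disj)
  expect_equal(r$mean, 0); expect_equal(r$se, 0)

  three <- community_table(list(p1 = c("A", "B"), p2 = c("B", "C"),
                                p3 = c("A", "B", "C")))
  # pairs: (p1,p2)=1/3, (p1,p3)=2/3, (p2,p3)=2/3
  expect_equal(mean_pairwise_jaccard(three)$mean, (1/3 + 2/3 + 2/3) / 3)
  expect_error(mean_pairwise_jaccard(community_table(list(p1 = "A"))),
               "at least 2")
})

test_that("year comparison permutation test behaves at the boundaries", {
  c1 <- community_table(list(p1 = c("A", "B"), p2 = c("C", "D"),
                             p3 = c("E", "F"), p4 = c("G", "H")), "sown")
  same <- community_table(c1$plots, "final")
  r <- compare_jaccard_years(c1, same, n_perm = 99, seed = 1)
  expect_equal(r$delta, 0)
  expect_equal(r$p, 1)

  # strong convergence: disjoint plots become identical (12 plots, so the
  # only label assignments reproducing |delta| are flip-none and flip-all)
  sp <- paste0("s", 1:24)
  big1 <- community_table(stats::setNames(
    lapply(1:12, function(i) sp[(2 * i - 1):(2 * i)]),
    paste0("q", 1:12)), "sown")
  big2 <- community_table(stats::setNames(rep(list(sp[1:3]), 12),
                                          names(big1$plots)), "final")
  r <- compare_jaccard_years(big1, big2, n_perm = 999, seed = 2)
  expect_equal(r$mean1, 0)
  expect_equal(r$mean2, 1)
  expect_lt(r$p, 0.05)

  # antisymmetry under swapped censuses
  r_fwd <- compare_jaccard_years(big1, big2, n_perm = 99, seed = 3)
  r_rev <- compare_jaccard_years(big2, big1, n_perm = 99, seed = 3)
  expect_equal(r_fwd$delta, -r_rev$delta)

  bad <- community_table(list(zz = c("A", "B")), "final")
  expect_error(compare_jaccard_years(c1, bad), "same plots")
})

make_fixture_data <- function(final_plots = NULL) {
  tree <- simulate_tree(sim_tree_config(n_internal = 16, n_external = 4,
                                        n_grass = 6, n_legume = 4, seed = 2))
  tags <- attr(tree, "tags")
  tips <- tree$tip.label
  grasses <- names(tags)[tags == "grass"]
  forbs <- names(tags)[tags == "other"]
  legumes <- names(tags)[tags == "legume"]
  sown <- list(p1 = forbs[1],                       # monoculture, never legume
               p2 = c(grasses[1:2], forbs[2:3]),    # colonized by legume
               p3 = c(grasses[3], legumes[1], forbs[4:5]))  # initiated with
  if (is.null(final_plots))
    final_plots <- list(p1 = c(forbs[1], forbs[6]),
                        p2 = c(grasses[1:2], forbs[2:3], legumes[2]),
                        p3 = sown$p3)
  plots <- data.frame(plot_id = names(sown), sown_richness = lengths(sown),
                      biomass_year1 = c(100, 300, 400),
                      biomass_year2 = c(150, 500, 390))
  species <- data.frame(species_id = tips, clade_tag = unname(tags[tips]),
                        pool = "internal")
  assembly_data(tree, community_table(sown, "sown"),
                community_table(final_plots, "final"), plots, species)
}

test_that("change records compute deltas, flags and legume status", {
  d <- make_fixture_data()
  rec <- build_change_records(d)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$legume_status, c("never", "colonized-by", "initiated-with"))
  # monoculture MNND undefined, defined once a second species arrives
  expect_true(is.na(rec$sown_mnnd[1]))
  expect_false(is.na(rec$final_mnnd[1]))
  # unchanged plot: all deltas zero
  expect_equal(rec$d_pd[3], 0)
  expect_equal(rec$d_richness[3], 0)
  expect_equal(rec$d_mnnd[3], 0)
  # deltas equal independently recomputed metric differences
  for (i in 1:3) {
    id <- rec$plot_id[i]
    expect_equal(rec$d_pd[i],
                 community_pd(d$tree, d$final$plots[[id]]) -
                   community_pd(d$tree, d$sown$plots[[id]]), tolerance = 1e-12)
  }
  expect_equal(rec$d_biomass, c(50, 200, -10))
})

test_that("OLS fit matches the closed-form normal equations", {
  x <- 1:10; y <- 2 * x
  r <- suppressWarnings(ols_fit(x, y))  # exact fit: lm warns, by design
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$df, c(1, 8))

  set.seed(9)
  x <- rnorm(40); y <- 1.5 - 0.7 * x + rnorm(40, 0, 0.3)
  r <- ols_fit(x, y)
  beta <- cov(x, y) / var(x)
  alpha <- mean(y) - beta * mean(x)
  r2 <- cor(x, y)^2
  expect_equal(r$slope, beta, tolerance = 1e-12)
  expect_equal(r$intercept, alpha, tolerance = 1e-12)
  expect_equal(r$r_squared, r2, tolerance = 1e-12)
  expect_equal(r$f, (r$n - 2) * r2 / (1 - r2), tolerance = 1e-9)
  expect_equal(r$p, pf(r$f, 1, r$n - 2, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(ols_fit(rep(1, 5), 1:5), "constant")
  expect_error(ols_fit(1:3, 1:4), "lengths differ")
  r <- suppressWarnings(ols_fit(c(1:9, NA), c(2 * (1:9), 5)))
  expect_equal(r$n, 9); expect_equal(r$n_dropped, 1)
})

test_that("regression p-values are uniform when x and y are independent", {
  set.seed(31)
  ps <- replicate(200, ols_fit(rnorm(30), rnorm(30))$p)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("ANCOVA recovers noise-free coefficients and excludes never-legume plots", {
  rec <- data.frame(
    d_pd = c(0.1, 0.5, 1.2, 2.0, 0.3, 1.1, 0.8, 1.9),
    legume_status = c("initiated-with", "initiated-with", "colonized-by",
                      "colonized-by", "never", "never", "initiated-with",
                      "colonized-by"))
  rec$d_biomass <- 5 + 0 * rec$d_pd + 30 * (rec$legume_status == "colonized-by")
  r <- suppressWarnings(ancova_biomass(rec))  # noise-free: exact-fit warning
  expect_equal(r$n_used, 6); expect_equal(r$n_excluded, 2)
  cf <- stats::setNames(r$coefficients$estimate, r$coefficients$term)
  expect_equal(unname(cf["d_pd"]), 0, tolerance = 1e-10)
  expect_equal(unname(cf["legumecolonized-by"]), 30, tolerance = 1e-10)
  expect_equal(unname(cf["(Intercept)"]), 5, tolerance = 1e-10)

  # perfectly confounded design: warning and collinear flag
  rec2 <- data.frame(
    d_pd = c(1, 1, 1, 2, 2, 2),
    legume_status = rep(c("initiated-with", "colonized-by"), each = 3))
  rec2$d_biomass <- rnorm(6)
  expect_warning(r2 <- ancova_biomass(rec2), "collinear")
  expect_true(r2$collinear)

  expect_error(ancova_biomass(rec[rec$legume_status != "colonized-by", ]),
               "fewer than")
})

test_that("ANCOVA CIs achieve nominal coverage on simulated data", {
  set.seed(61)
  true_leg <- 25
  cover <- replicate(200, {
    n <- 40
    status <- sample(c("initiated-with", "colonized-by"), n, replace = TRUE)
    d_pd <- rnorm(n, 1 + 0.5 * (status == "colonized-by"), 0.5)
    rec <- data.frame(d_pd = d_pd, legume_status = status,
                      d_biomass = 10 + 4 * d_pd +
                        true_leg * (status == "colonized-by") + rnorm(n, 0, 8))
    ci <- stats::confint(ancova_biomass(rec)$lm)["legumecolonized-by", ]
    ci[1] <= true_leg && true_leg <= ci[2]
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("exact convergence to a common final composition gives slope -1", {
  d <- make_fixture_data(
    final_plots = list(p1 = c("F01", "G01", "L01"),
                       p2 = c("F01", "G01", "L01"),
                       p3 = c("F01", "G01", "L01")))
  rec <- build_change_records(d)
  r <- suppressWarnings(ols_fit(rec$sown_pd, rec$d_pd))
  expect_equal(r$slope, -1, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
})
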