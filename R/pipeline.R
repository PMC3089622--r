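# End-to-end orchestration: load -> metrics -> null models -> assembly
# tests -> change/productivity analyses -> report bundle. The interface is
# a pair of R functions (simulate_experiment() for inputs,
# run_full_analysis() for the pipeline) plus writers; every stage draws
# from its own seed stream derived from the master seed by a stable label.

#' Run the full community-assembly analysis
#'
#' Executes, over a validated [assembly_data()] bundle:
#' \enumerate{
#'   \item per-plot dispersion tests of the sown communities (PD and MNND
#'     against grass-constrained draws from the internal pool; monoculture
#'     nulls are unconstrained and MNND tests skip monocultures);
#'   \item pool-level tests: are the species that colonized (or went
#'     extinct in) at least one plot clustered across the regional pool;
#'   \item per-plot colonist relatedness tests (plots with >=
#'     `min_colonists` colonists), with optional legume exclusion and the
#'     colonists-as-established-residents variant;
#'   \item per-plot extinction relatedness tests, with optional grass
#'     exclusion and the colonists-as-established variant;
#'   \item significant-plot counts per test family against the
#'     expected-by-chance count;
#'   \item change records, Jaccard convergence, diversity-change
#'     regressions (change vs sown value for richness, PD, MNND),
#'     productivity regressions for both years and changes, and the
#'     legume-covariate ANCOVA.
#' }
#'
#' @param data An `"assembly_data"` bundle.
#' @param n_rand Randomizations per null test.
#' @param alpha Significance level for direction labels and counts.
#' @param seed Master seed; per-stage streams are derived from it.
#' @param exclude_legumes,exclude_grasses Also run the colonist test
#'   without legumes / the extinction test without grasses.
#' @param colonists_as_residents Also run both relatedness tests with
#'   colonists counted as established residents.
#' @param restricted_colonist_pool If `TRUE`, pseudo-colonists are drawn
#'   only from species observed to colonize at least one plot, rather than
#'   the full regional pool.
#' @param min_colonists Minimum colonists for a plot to enter the
#'   per-plot colonist tests (default 2: plots colonized by multiple
#'   species).
#' @param n_perm Permutations for the Jaccard year comparison.
#' @return An object of class `"assembly_analysis"`; see
#'   [write_analysis_bundle()] for the serialized layout.
#' @export
run_full_analysis <- function(data, n_rand = 1000L, alpha = 0.05,
                              seed = NULL, exclude_legumes = TRUE,
                              exclude_grasses = TRUE,
                              colonists_as_residents = TRUE,
                              restricted_colonist_pool = FALSE,
                              min_colonists = 2L, n_perm = 999L) {
  stopifnot(inherits(data, "assembly_data"))
  tree <- data$tree; dist <- data$dist; tags <- data$tags
  sseed <- function(label) if (is.null(seed)) NULL else stage_seed(seed, label)
  ids <- data$plots$plot_id
  parts <- lapply(ids, function(id) {
    fin <- if (id %in% names(data$final$plots)) data$final$plots[[id]]
           else character()
    partition_plot(data$sown$plots[[id]], fin, plot_id = id)
  })
  names(parts) <- ids

  ## 1. sown-community dispersion -------------------------------------
  sown_disp <- list()
  for (metric in c("PD", "MNND")) {
    res <- list()
    for (id in ids) {
      comm <- data$sown$plots[[id]]
      if (metric == "MNND" && length(comm) < 2L) next  # undefined, excluded
      spec <- null_constraints(
        data$internal_pool, tags = tags,
        require_tag = if (length(comm) >= 2L) "grass" else NULL,
        n_rand = n_rand, seed = sseed(paste0("sown-", metric, "-", id)))
      r <- null_test(comm, spec, tree, dist, metric = metric, alpha = alpha)
      r$plot_id <- id
      res[[id]] <- r
    }
    sown_disp[[metric]] <- list(results = res,
                                summary = count_significant(res, alpha))
  }

  ## 2. pool-level colonizer / extinction-prone dispersion -------------
  colonizers <- unique(unlist(lapply(parts, `[[`, "colonize")))
  extinct_sp <- unique(unlist(lapply(parts, `[[`, "extinct")))
  pool_tests <- list()
  if (length(colonizers) >= 2L)
    pool_tests$colonizers <- pool_dispersion_test(
      colonizers, data$regional_pool, dist, n_rand = n_rand,
      seed = sseed("pool-colonizers"), alpha = alpha)
  if (length(extinct_sp) >= 2L)
    pool_tests$extinctions <- pool_dispersion_test(
      extinct_sp, data$regional_pool, dist, n_rand = n_rand,
      seed = sseed("pool-extinctions"), alpha = alpha)

  ## 3. per-plot colonist tests ----------------------------------------
  colonist_pool <- if (restricted_colonist_pool) colonizers
                   else data$regional_pool
  run_colonist_family <- function(label, exclude_tags = NULL,
                                  residents = "sown") {
    res <- list()
    for (id in ids) {
      part <- parts[[id]]
      focal <- part$colonize
      if (length(exclude_tags))
        focal <- focal[!(tags[focal] %in% exclude_tags)]
      if (length(focal) < min_colonists) next
      pool_left <- setdiff(colonist_pool, part$sown)
      if (length(exclude_tags))
        pool_left <- pool_left[!(tags[pool_left] %in% exclude_tags)]
      if (length(pool_left) < length(focal)) next
      res[[id]] <- colonist_relatedness_test(
        part, colonist_pool, dist, tags = tags, residents = residents,
        exclude_tags = exclude_tags, n_rand = n_rand,
        seed = sseed(paste0("colonist-", label, "-", id)), alpha = alpha)
    }
    if (!length(res)) return(NULL)
    list(results = res, summary = count_significant(res, alpha))
  }
  colonist_tests <- list(all = run_colonist_family("all"))
  if (exclude_legumes)
    colonist_tests$no_legumes <- run_colonist_family("nolegume",
                                                     exclude_tags = "legume")
  if (colonists_as_residents)
    colonist_tests$established <- run_colonist_family("estab",
                                                      residents = "established")

  ## 4. per-plot extinction tests --------------------------------------
  run_extinction_family <- function(label, exclude_tags = NULL,
                                    survivors = "persist") {
    res <- list()
    for (id in ids) {
      part <- parts[[id]]
      ext <- part$extinct; per <- part$persist
      if (length(exclude_tags)) {
        ext <- ext[!(tags[ext] %in% exclude_tags)]
        per <- per[!(tags[per] %in% exclude_tags)]
      }
      if (!length(ext) || !length(per)) next
      res[[id]] <- extinction_relatedness_test(
        part, dist, tags = tags, survivors = survivors,
        exclude_tags = exclude_tags, n_rand = n_rand,
        seed = sseed(paste0("extinction-", label, "-", id)), alpha = alpha)
    }
    if (!length(res)) return(NULL)
    list(results = res, summary = count_significant(res, alpha))
  }
  extinction_tests <- list(all = run_extinction_family("all"))
  if (exclude_grasses)
    extinction_tests$no_grasses <- run_extinction_family("nograss",
                                                         exclude_tags = "grass")
  if (colonists_as_residents)
    extinction_tests$established <- run_extinction_family("estab",
                                                          survivors = "established")

  ## 5-6. change, convergence, productivity ----------------------------
  records <- build_change_records(data)
  jacc <- compare_jaccard_years(data$sown, data$final, n_perm = n_perm,
                                seed = sseed("jaccard"))
  convergence <- list(
    richness = ols_fit(records$sown_richness, records$d_richness,
                       "sown richness", "richness change"),
    pd = ols_fit(records$sown_pd, records$d_pd, "sown PD", "PD change"),
    mnnd = ols_fit(records$sown_mnnd, records$d_mnnd,
                   "sown MNND", "MNND change"))
  productivity <- list(
    pd_year1 = ols_fit(records$sown_pd, records$biomass_year1,
                       "sown PD", "biomass year 1"),
    richness_year1 = ols_fit(records$sown_richness, records$biomass_year1,
                             "sown richness", "biomass year 1"),
    pd_year2 = ols_fit(records$final_pd, records$biomass_year2,
                       "final PD", "biomass year 2"),
    richness_year2 = ols_fit(records$final_richness, records$biomass_year2,
                             "final richness", "biomass year 2"),
    d_pd = ols_fit(records$d_pd, records$d_biomass,
                   "PD change", "biomass change"),
    d_richness = ols_fit(records$d_richness, records$d_biomass,
                         "richness change", "biomass change"))
  ancova <- tryCatch(ancova_biomass(records),
                     error = function(e) structure(list(error = conditionMessage(e)),
                                                   class = "biomass_ancova_failed"))
  manifest <- list(package_version = as.character(utils::packageVersion("phyloassembly")),
                   seed = seed, n_rand = n_rand, alpha = alpha,
                   n_plots = length(ids),
                   options = list(exclude_legumes = exclude_legumes,
                                  exclude_grasses = exclude_grasses,
                                  colonists_as_residents = colonists_as_residents,
                                  restricted_colonist_pool = restricted_colonist_pool,
                                  min_colonists = min_colonists,
                                  n_perm = n_perm))
  structure(list(partitions = parts, sown_dispersion = sown_disp,
                 pool_tests = pool_tests, colonist_tests = colonist_tests,
                 extinction_tests = extinction_tests,
                 change_records = records, jaccard = jacc,
                 convergence = convergence, productivity = productivity,
                 ancova = ancova, manifest = manifest),
            class = "assembly_analysis")
}

#' @export
print.assembly_analysis <- function(x, ...) {
  cat("Community assembly analysis of", x$manifest$n_plots, "plots\n")
  cat(sprintf("  Jaccard: sown %.3f -> final %.3f (p = %.3g)\n",
              x$jaccard$mean1, x$jaccard$mean2, x$jaccard$p))
  cv <- x$convergence$pd
  cat(sprintf("  PD change ~ sown PD: slope %.3f, R^2 %.2f\n",
              cv$slope, cv$r_squared))
  for (fam in names(x$colonist_tests)) {
    s <- x$colonist_tests[[fam]]$summary
    if (!is.null(s))
      cat(sprintf("  colonist tests [%s]: %d/%d clustered, %d overdispersed (expect %d)\n",
                  fam, s$n_clustered, s$n_tested, s$n_overdispersed,
                  s$expected_by_chance))
  }
  for (fam in names(x$extinction_tests)) {
    s <- x$extinction_tests[[fam]]$summary
    if (!is.null(s))
      cat(sprintf("  extinction tests [%s]: %d/%d clustered, %d overdispersed (expect %d)\n",
                  fam, s$n_clustered, s$n_tested, s$n_overdispersed,
                  s$expected_by_chance))
  }
  if (inherits(x$ancova, "biomass_ancova")) print(x$ancova)
  invisible(x)
}

# flatten a dispersion-test family into one data frame row per plot
.family_table <- function(family, family_name) {
  tab <- family$summary$table
  tab$family <- family_name
  tab[, c("family", setdiff(names(tab), "family"))]
}

#' Write an analysis bundle to a directory
#'
#' Serializes the result tables as CSV/JSON: `sown_dispersion.csv`,
#' `colonist_tests.csv`, `extinction_tests.csv`, `significance_counts.csv`,
#' `change_records.csv`, `regressions.csv`, `pool_tests.csv`,
#' `ancova.json`, `jaccard.json` and `manifest.json`.
#'
#' @param analysis An `"assembly_analysis"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_bundle <- function(analysis, dir) {
  stopifnot(inherits(analysis, "assembly_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                           row.names = FALSE)
  wjson <- function(x, f) jsonlite::write_json(x, file.path(dir, f),
                                               auto_unbox = TRUE, digits = NA,
                                               pretty = TRUE)
  wcsv(do.call(rbind, lapply(names(analysis$sown_dispersion), function(m)
    .family_table(analysis$sown_dispersion[[m]], m))), "sown_dispersion.csv")
  ct <- analysis$colonist_tests[!vapply(analysis$colonist_tests, is.null,
                                        logical(1))]
  wcsv(do.call(rbind, lapply(names(ct), function(m)
    .family_table(ct[[m]], m))), "colonist_tests.csv")
  et <- analysis$extinction_tests[!vapply(analysis$extinction_tests, is.null,
                                          logical(1))]
  wcsv(do.call(rbind, lapply(names(et), function(m)
    .family_table(et[[m]], m))), "extinction_tests.csv")
  counts <- do.call(rbind, lapply(
    c(lapply(stats::setNames(names(analysis$sown_dispersion),
                             paste0("sown_", names(analysis$sown_dispersion))),
             function(m) analysis$sown_dispersion[[sub("^sown_", "", m)]]$summary),
      lapply(stats::setNames(names(ct), paste0("colonist_", names(ct))),
             function(m) ct[[sub("^colonist_", "", m)]]$summary),
      lapply(stats::setNames(names(et), paste0("extinction_", names(et))),
             function(m) et[[sub("^extinction_", "", m)]]$summary)),
    function(s) data.frame(n_tested = s$n_tested, n_clustered = s$n_clustered,
                           n_overdispersed = s$n_overdispersed,
                           expected_by_chance = s$expected_by_chance)))
  counts <- cbind(family = rownames(counts), counts)
  wcsv(counts, "significance_counts.csv")
  wcsv(as.data.frame(analysis$change_records), "change_records.csv")
  regs <- c(stats::setNames(analysis$convergence,
                            paste0("convergence_", names(analysis$convergence))),
            stats::setNames(analysis$productivity,
                            paste0("productivity_", names(analysis$productivity))))
  wcsv(do.call(rbind, lapply(names(regs), function(nm) {
    r <- regs[[nm]]
    data.frame(model = nm, y = r$ylab, x = r$xlab, slope = r$slope,
               intercept = r$intercept, f = r$f, df1 = r$df[1], df2 = r$df[2],
               r_squared = r$r_squared, p = r$p, n = r$n,
               n_dropped = r$n_dropped)
  })), "regressions.csv")
  if (length(analysis$pool_tests))
    wcsv(do.call(rbind, lapply(names(analysis$pool_tests), function(nm) {
      r <- analysis$pool_tests[[nm]]
      data.frame(test = nm, observed = r$observed, null_mean = r$null_mean,
                 null_sd = r$null_sd, ses = r$ses, p = r$p,
                 direction = r$direction)
    })), "pool_tests.csv")
  if (inherits(analysis$ancova, "biomass_ancova"))
    wjson(list(coefficients = analysis$ancova$coefficients,
               n_used = analysis$ancova$n_used,
               n_excluded = analysis$ancova$n_excluded,
               collinear = analysis$ancova$collinear), "ancova.json")
  else wjson(analysis$ancova, "ancova.json")
  wjson(analysis$jaccard, "jaccard.json")
  wjson(analysis$manifest, "manifest.json")
  invisible(dir)
}
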