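# Compositional and phylogenetic turnover, convergence regressions, and
# the diversity-productivity analyses (regression and legume-covariate
# ANCOVA).

#' Jaccard similarity of two species sets
#'
#' @param a,b Character vectors of species; their union must be non-empty.
#' @return |intersection| / |union|, in [0, 1].
#' @examples
#' jaccard(c("A", "B", "C"), c("B", "C", "D"))  # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  u <- length(union(a, b))
  if (u == 0L) stop("both sets empty: Jaccard undefined")
  length(intersect(a, b)) / u
}

# plots x species binary incidence matrix over a given species universe
.incidence <- function(plots, species) {
  m <- matrix(0L, length(plots), length(species),
              dimnames = list(names(plots), species))
  for (i in seq_along(plots)) m[i, match(plots[[i]], species)] <- 1L
  m
}

# all unordered pairwise Jaccard values from an incidence matrix
.pairwise_jaccard_values <- function(m) {
  inter <- tcrossprod(m)
  sz <- rowSums(m)
  un <- outer(sz, sz, "+") - inter
  if (any(un[upper.tri(un)] == 0))
    stop("a pair of empty plots: Jaccard undefined")
  (inter / un)[upper.tri(inter)]
}

#' Mean pairwise Jaccard similarity among plots of one census
#'
#' @param census A [community_table()] with >= 2 plots.
#' @return List with `mean`, `se` (standard error over pairs) and
#'   `n_pairs`.
#' @export
mean_pairwise_jaccard <- function(census) {
  stopifnot(inherits(census, "community_table"))
  plots <- census$plots
  if (length(plots) < 2L) stop("need at least 2 plots")
  species <- unique(unlist(plots, use.names = FALSE))
  vals <- .pairwise_jaccard_values(.incidence(plots, species))
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(length(vals)),
       n_pairs = length(vals))
}

#' Permutation test for change in mean pairwise Jaccard between censuses
#'
#' Compares mean among-plot compositional similarity at two censuses of the
#' same plots. The null swaps, independently per plot, which census a
#' plot's two compositions are labelled with, and recomputes the difference
#' in mean pairwise Jaccard; the two-tailed p is rank-based with the usual
#' +1 correction.
#'
#' @param census1,census2 `community_table`s over an identical plot set.
#' @param n_perm Number of label permutations.
#' @param seed Optional seed.
#' @return List: `mean1`, `mean2`, `delta` (mean2 - mean1), `p`, `n_perm`.
#' @export
compare_jaccard_years <- function(census1, census2, n_perm = 999L,
                                  seed = NULL) {
  stopifnot(inherits(census1, "community_table"),
            inherits(census2, "community_table"))
  ids <- names(census1$plots)
  if (!setequal(ids, names(census2$plots)))
    stop("the two censuses must cover the same plots")
  p1 <- census1$plots
  p2 <- census2$plots[ids]
  species <- unique(c(unlist(p1, use.names = FALSE),
                      unlist(p2, use.names = FALSE)))
  M1 <- .incidence(p1, species)
  M2 <- .incidence(p2, species)
  m1 <- mean(.pairwise_jaccard_values(M1))
  m2 <- mean(.pairwise_jaccard_values(M2))
  obs <- m2 - m1
  n <- length(ids)
  perm_delta <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      flip <- stats::runif(n) < 0.5
      A <- M1; A[flip, ] <- M2[flip, ]
      B <- M2; B[flip, ] <- M1[flip, ]
      mean(.pairwise_jaccard_values(B)) - mean(.pairwise_jaccard_values(A))
    }, numeric(1))
  })
  p <- min(1, (sum(abs(perm_delta) >= abs(obs)) + 1) / (n_perm + 1))
  list(mean1 = m1, mean2 = m2, delta = obs, p = p, n_perm = n_perm)
}

#' Per-plot diversity-change records
#'
#' For each plot, computes species richness, PD and MNND at the sown and
#' final censuses, their changes, biomass in both years with the change
#' (year 2 minus year 1, g/m^2), and the plot's legume status:
#' `"initiated-with"` if a legume was sown, `"colonized-by"` if none was
#' sown but one was present at the final census, `"never"` otherwise.
#' MNND is undefined for communities of fewer than two species and is
#' reported as `NA` there (monocultures are flagged, not scored).
#'
#' @param data An [assembly_data()] bundle.
#' @return A data frame of class `"change_records"`, one row per plot.
#' @export
build_change_records <- function(data) {
  stopifnot(inherits(data, "assembly_data"))
  tree <- data$tree; dist <- data$dist; tags <- data$tags
  ids <- data$plots$plot_id
  mnnd_or_na <- function(sp) if (length(sp) >= 2L) community_mnnd(dist, sp) else NA_real_
  pd_or_zero <- function(sp) if (length(sp)) community_pd(tree, sp) else 0
  rows <- lapply(ids, function(id) {
    sown <- data$sown$plots[[id]]
    final <- if (id %in% names(data$final$plots)) data$final$plots[[id]] else character()
    leg_sown <- any(tags[sown] == "legume")
    leg_final <- any(tags[final] == "legume")
    meta <- data$plots[data$plots$plot_id == id, ]
    data.frame(
      plot_id = id,
      sown_richness = length(sown), final_richness = length(final),
      sown_pd = pd_or_zero(sown), final_pd = pd_or_zero(final),
      sown_mnnd = mnnd_or_na(sown), final_mnnd = mnnd_or_na(final),
      biomass_year1 = meta$biomass_year1, biomass_year2 = meta$biomass_year2,
      legume_status = if (leg_sown) "initiated-with"
                      else if (leg_final) "colonized-by" else "never",
      stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec$d_richness <- rec$final_richness - rec$sown_richness
  rec$d_pd <- rec$final_pd - rec$sown_pd
  rec$d_mnnd <- rec$final_mnnd - rec$sown_mnnd
  rec$d_biomass <- rec$biomass_year2 - rec$biomass_year1
  class(rec) <- c("change_records", class(rec))
  rec
}

#' Simple linear regression with F-test summary
#'
#' Least-squares fit of `y ~ x` reporting the quantities used throughout
#' the diversity-change and productivity analyses: slope, intercept, F
#' statistic with its (1, n-2) degrees of freedom, R^2 and p. Rows with
#' missing values are dropped and the n actually used is reported, so
#' e.g. MNND regressions silently exclude monoculture plots.
#'
#' @param x,y Numeric vectors of equal length (n >= 3 after NA removal,
#'   `x` non-constant).
#' @param xlab,ylab Optional variable labels carried into the result.
#' @return Object of class `"ols_fit"`: `slope`, `intercept`, `f`, `df`
#'   (length-2), `r_squared`, `p`, `n`, `n_dropped`.
#' @export
ols_fit <- function(x, y, xlab = deparse(substitute(x)),
                    ylab = deparse(substitute(y))) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  keep <- stats::complete.cases(x, y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[[1]], fstat[[2]], fstat[[3]], lower.tail = FALSE)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 f = unname(fstat[[1]]),
                 df = c(unname(fstat[[2]]), unname(fstat[[3]])),
                 r_squared = sm$r.squared, p = unname(p),
                 n = n, n_dropped = n_dropped,
                 xlab = xlab, ylab = ylab, lm = fit),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("%s ~ %s: slope = %.4g, intercept = %.4g\n",
              x$ylab, x$xlab, x$slope, x$intercept))
  cat(sprintf("  F_%d,%d = %.4g, P = %.4g, R^2 = %.3g (n = %d%s)\n",
              x$df[1], x$df[2], x$f, x$p, x$r_squared, x$n,
              if (x$n_dropped) paste0(", ", x$n_dropped, " dropped") else ""))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Biomass-change ANCOVA with legume covariate
#'
#' Fits `d_biomass ~ d_pd + legume` where the binary covariate separates
#' plots that were initiated with a legume from plots initiated without one
#' but subsequently colonized by one. Plots never containing a legume are
#' excluded from the fit (they belong to neither covariate level). This is
#' the analysis separating a phylogenetic-diversity effect on productivity
#' change from the agronomic effect of nitrogen-fixer colonization, with
#' which PD gain is confounded when legumes sit on a long branch.
#'
#' @param records A [build_change_records()] data frame.
#' @param min_per_level Minimum plots required in each covariate level.
#' @return Object of class `"biomass_ancova"`: `coefficients` data frame
#'   (estimate, t, p per term), `n_used`, `n_excluded`, `collinear` flag,
#'   and the underlying `lm`.
#' @export
ancova_biomass <- function(records, min_per_level = 2L) {
  stopifnot(is.data.frame(records))
  need <- c("d_biomass", "d_pd", "legume_status")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  used <- records[records$legume_status != "never", ]
  n_excluded <- nrow(records) - nrow(used)
  lv <- table(factor(used$legume_status,
                     levels = c("initiated-with", "colonized-by")))
  if (any(lv < min_per_level))
    stop("covariate level(s) with fewer than ", min_per_level, " plots: ",
         paste(names(lv)[lv < min_per_level], collapse = ", "))
  used$legume <- factor(used$legume_status,
                        levels = c("initiated-with", "colonized-by"))
  fit <- stats::lm(d_biomass ~ d_pd + legume, data = used)
  collinear <- any(is.na(stats::coef(fit))) ||
    kappa(stats::model.matrix(fit), exact = TRUE) > 1e8
  if (collinear)
    warning("predictor and covariate are (nearly) collinear; ",
            "coefficients are not separable")
  ct <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1],
                      t = ct[, 3], p = ct[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, n_used = nrow(used),
                 n_excluded = n_excluded, collinear = collinear, lm = fit),
            class = "biomass_ancova")
}

#' @export
print.biomass_ancova <- function(x, ...) {
  cat(sprintf("Biomass-change ANCOVA (n = %d used, %d never-legume plots excluded)\n",
              x$n_used, x$n_excluded))
  print(x$coefficients, digits = 4)
  if (x$collinear) cat("  warning: near-collinear design\n")
  invisible(x)
}
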