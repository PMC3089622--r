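# Richness-preserving null communities drawn from a species pool under
# clade constraints, and the dispersion-test machinery (SES, rank-based
# two-tailed p) shared by every randomization test in the package.

#' Null-community constraint specification
#'
#' Describes the pool and constraints under which null communities are
#' drawn: an optional minimum count of a required clade tag (the field
#' experiment's rule that every polyculture contain at least one grass) and
#' optional clade exclusions (e.g. dropping legumes from a colonist pool).
#'
#' @param pool Character vector of species identifiers forming the sampling
#'   pool.
#' @param tags Named character vector mapping species to a clade tag
#'   (`"grass"`, `"legume"`, `"other"`). Species absent from `tags` are
#'   treated as `"other"`. Required when a tag constraint or exclusion is
#'   active.
#' @param require_tag Clade tag of which every draw must contain at least
#'   `require_n` species, or `NULL` for unconstrained draws.
#' @param require_n Minimum count of `require_tag` species per draw.
#' @param exclude_tags Character vector of clade tags removed from the pool
#'   before sampling.
#' @param n_rand Number of randomizations for tests using this spec.
#' @param seed Optional integer seed recorded in, and used by, tests run
#'   with this spec.
#' @return An object of class `"null_constraints"`.
#' @examples
#' spec <- null_constraints(c("g1", "f1", "f2"),
#'                          tags = c(g1 = "grass", f1 = "other", f2 = "other"),
#'                          require_tag = "grass")
#' sample_null_community(spec, 2)
#' @export
null_constraints <- function(pool, tags = NULL, require_tag = NULL,
                             require_n = 1L, exclude_tags = NULL,
                             n_rand = 1000L, seed = NULL) {
  pool <- sort(unique(as.character(pool)))  # canonical order: draws do not
  if (!length(pool)) stop("empty pool")     # depend on input file ordering
  if (n_rand < 1L) stop("n_rand must be positive")
  tag_of <- .tag_lookup(pool, tags)
  if (length(exclude_tags)) {
    pool <- pool[!(tag_of[pool] %in% exclude_tags)]
    if (!length(pool)) stop("pool empty after clade exclusions")
  }
  if (!is.null(require_tag)) {
    n_tagged <- sum(tag_of[pool] == require_tag)
    if (n_tagged < require_n)
      stop("constraint infeasible: pool holds ", n_tagged, " '", require_tag,
           "' species, ", require_n, " required")
  }
  structure(list(pool = pool, tags = tag_of, require_tag = require_tag,
                 require_n = as.integer(require_n),
                 exclude_tags = exclude_tags,
                 n_rand = as.integer(n_rand), seed = seed),
            class = "null_constraints")
}

.tag_lookup <- function(species, tags) {
  out <- rep("other", length(species))
  names(out) <- species
  if (!is.null(tags)) {
    hit <- intersect(species, names(tags))
    out[hit] <- unname(tags[hit])
  }
  out
}

#' Draw one constrained null community
#'
#' Uniform sample of `richness` species without replacement from the spec's
#' effective pool, conditioned on the clade constraint by rejection
#' sampling: draws violating the minimum-tag rule are discarded and
#' redrawn, which leaves the distribution uniform over all feasible
#' subsets.
#'
#' @param spec A [null_constraints()] object.
#' @param richness Community size to draw.
#' @return Character vector of `richness` species.
#' @export
sample_null_community <- function(spec, richness) {
  stopifnot(inherits(spec, "null_constraints"))
  richness <- as.integer(richness)
  if (richness < 1L) stop("richness must be positive")
  if (richness > length(spec$pool))
    stop("richness ", richness, " exceeds pool size ", length(spec$pool))
  if (is.null(spec$require_tag))
    return(sample(spec$pool, richness))
  is_req <- spec$tags[spec$pool] == spec$require_tag
  if (richness < spec$require_n)
    stop("richness smaller than required tag count")
  repeat {
    draw <- sample(spec$pool, richness)
    if (sum(is_req[match(draw, spec$pool)]) >= spec$require_n) return(draw)
  }
}

# n_rand draws as a list; sampling is the hot loop of every test, so the
# constrained case precomputes the tag indicator once
.sample_null_many <- function(spec, richness, n_rand) {
  pool <- spec$pool
  k <- as.integer(richness)
  if (k > length(pool))
    stop("richness ", k, " exceeds pool size ", length(pool))
  if (is.null(spec$require_tag)) {
    return(lapply(seq_len(n_rand), function(i) sample(pool, k)))
  }
  is_req <- spec$tags[pool] == spec$require_tag
  need <- spec$require_n
  if (sum(is_req) < need) stop("constraint infeasible")
  if (k < need) stop("richness smaller than required tag count")
  out <- vector("list", n_rand)
  for (i in seq_len(n_rand)) {
    repeat {
      idx <- sample.int(length(pool), k)
      if (sum(is_req[idx]) >= need) break
    }
    out[[i]] <- pool[idx]
  }
  out
}

#' Summarize an observed statistic against a null distribution
#'
#' Computes the standardized effect size SES = (observed - null mean) /
#' null sd and a two-tailed rank-based p-value,
#' p = 2 * min(n_le + 1, n_ge + 1) / (n_rand + 1) capped at 1, where n_le
#' and n_ge count null values <= and >= the observed value (ties counted on
#' both sides). A null distribution with zero spread is flagged
#' (`sd_zero = TRUE`) and reported with SES = 0 rather than erroring, so
#' batch runs over degenerate pools complete.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null statistic values.
#' @param alpha Significance level used only to assign the direction label.
#' @param metric Optional metric identifier carried in the result.
#' @return An object of class `"dispersion"`: observed, null mean/sd, SES,
#'   p, tail counts, direction (`"clustered"`, `"overdispersed"`,
#'   `"random"`), `sd_zero` flag and the null values.
#' @export
dispersion_test <- function(observed, null_values, alpha = 0.05,
                            metric = NA_character_) {
  null_values <- as.numeric(null_values)
  if (!length(null_values) || anyNA(null_values) || any(!is.finite(null_values)))
    stop("null distribution must be non-empty and finite")
  n <- length(null_values)
  mu <- mean(null_values)
  sdv <- stats::sd(null_values)
  sd_zero <- !is.finite(sdv) || sdv == 0
  ses <- if (sd_zero) 0 else (observed - mu) / sdv
  n_le <- sum(null_values <= observed)
  n_ge <- sum(null_values >= observed)
  p <- min(1, 2 * (min(n_le, n_ge) + 1) / (n + 1))
  direction <- "random"
  if (p < alpha && !sd_zero)
    direction <- if (observed < mu) "clustered" else "overdispersed"
  structure(list(observed = observed, null_mean = mu, null_sd = sdv,
                 ses = ses, p = p, n_le = n_le, n_ge = n_ge,
                 n_rand = n, alpha = alpha, direction = direction,
                 sd_zero = sd_zero, metric = metric,
                 null_values = null_values),
            class = "dispersion")
}

#' @export
print.dispersion <- function(x, ...) {
  cat("Phylogenetic dispersion test",
      if (!is.na(x$metric)) paste0(" (", x$metric, ")"), "\n", sep = "")
  cat(sprintf("  observed = %.6g, null mean = %.6g (sd %.6g), n_rand = %d\n",
              x$observed, x$null_mean, x$null_sd, x$n_rand))
  cat(sprintf("  SES = %.4g, two-tailed p = %.4g -> %s%s\n",
              x$ses, x$p, x$direction,
              if (x$sd_zero) " [null sd = 0]" else ""))
  invisible(x)
}

#' Null-model dispersion test for a plot community
#'
#' Compares an observed community metric (PD, MNND or MPD) to the
#' distribution of the same metric over `n_rand` null communities of equal
#' richness drawn from the spec's pool under its constraints. Following the
#' field design, callers typically constrain polyculture nulls to contain
#' at least one grass while leaving monoculture nulls unconstrained.
#'
#' @param community Character vector of tip labels (the observed plot).
#' @param spec A [null_constraints()] object (pool, constraint, `n_rand`,
#'   `seed`).
#' @param tree Validated `"phylo"` object (needed for PD).
#' @param dist Optional patristic matrix; computed from `tree` if missing.
#' @param metric One of `"PD"`, `"MNND"`, `"MPD"`.
#' @param alpha Significance level for the direction label.
#' @return A `"dispersion"` object (see [dispersion_test()]).
#' @export
null_test <- function(community, spec, tree, dist = NULL,
                      metric = c("PD", "MNND", "MPD"), alpha = 0.05) {
  metric <- match.arg(metric)
  stopifnot(inherits(spec, "null_constraints"))
  community <- unique(as.character(community))
  if (metric %in% c("MNND", "MPD") && length(community) < 2L)
    stop(metric, " undefined for communities of fewer than 2 species")
  if (is.null(dist)) dist <- patristic_matrix(tree)
  observed <- .community_metric(metric, tree, dist, community)
  null_values <- with_seed(spec$seed, {
    draws <- .sample_null_many(spec, length(community), spec$n_rand)
    vapply(draws, function(s) .community_metric(metric, tree, dist, s),
           numeric(1))
  })
  dispersion_test(observed, null_values, alpha = alpha, metric = metric)
}

#' Expected number of false positives
#'
#' Number of significant results expected by chance alone among `n_tests`
#' independent tests at level `alpha`: `n_tests * alpha`, rounded to the
#' nearest integer (halves away from zero). With 41 per-plot tests at
#' alpha = 0.05 two plots are expected to show signal by chance; with 55,
#' three.
#'
#' @param n_tests Number of tests performed.
#' @param alpha Significance level in (0, 1).
#' @return Integer expected count.
#' @examples
#' expected_false_positives(41, 0.05)  # 2
#' expected_false_positives(55, 0.05)  # 3
#' @export
expected_false_positives <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1L) stop("n_tests must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  as.integer(floor(n_tests * alpha + 0.5))
}

#' Run code under a temporary RNG seed
#'
#' Evaluates `expr` with the RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards; with `seed = NULL` the expression runs on the
#' current stream. Used so every test and simulator is reproducible from a
#' recorded seed without perturbing the session.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-stage seed derived from a master seed and a stage
# label, so adding a stage never perturbs earlier stages' draws
stage_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}
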