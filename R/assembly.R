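# Colonization/extinction partitioning and the per-plot relatedness tests.
#
# Species in each plot are classified against the two censuses: "persist"
# (sown and still present), "extinct" (sown, absent at the final census)
# and "colonize" (not sown, present at the final census). Colonist tests
# ask whether colonists are closer to (or farther from) plot residents than
# random recruits from the regional pool; extinction tests ask whether the
# species lost were a non-random subset of the sown community.

#' Partition a plot's species by fate
#'
#' @param sown Character vector of species sown in the plot.
#' @param final Character vector of species present at the final census.
#' @param plot_id Optional identifier carried through to results.
#' @return An object of class `"plot_partition"` with elements `sown`,
#'   `final`, `persist`, `extinct`, `colonize`.
#' @examples
#' partition_plot(c("A", "B", "C"), c("B", "C", "D"))
#' @export
partition_plot <- function(sown, final, plot_id = NA_character_) {
  sown <- unique(as.character(sown))
  final <- unique(as.character(final))
  structure(list(plot_id = plot_id, sown = sown, final = final,
                 persist = intersect(sown, final),
                 extinct = setdiff(sown, final),
                 colonize = setdiff(final, sown)),
            class = "plot_partition")
}

#' @export
print.plot_partition <- function(x, ...) {
  cat("Plot", if (!is.na(x$plot_id)) x$plot_id else "(unnamed)",
      ": sown", length(x$sown), "-> final", length(x$final), "\n")
  cat("  persist:", length(x$persist), " extinct:", length(x$extinct),
      " colonize:", length(x$colonize), "\n")
  invisible(x)
}

#' Mean nearest-neighbor distance from one species group to another
#'
#' Mean, over focal species, of the minimum patristic distance to any
#' reference species. This is the statistic of the colonist and extinction
#' tests: e.g. how close, on average, each colonist is to its nearest plot
#' resident. The groups must be disjoint and non-empty; a single focal
#' species is allowed (the mean is over one nearest-neighbor distance).
#'
#' @param focal Character vector of focal species (colonists or extinct).
#' @param reference Character vector of reference species (residents).
#' @param dist Patristic matrix from [patristic_matrix()].
#' @return Mean nearest-neighbor distance in branch-length units.
#' @export
cross_group_mnnd <- function(focal, reference, dist) {
  focal <- unique(as.character(focal))
  reference <- unique(as.character(reference))
  if (!length(focal) || !length(reference))
    stop("focal and reference groups must be non-empty")
  if (length(intersect(focal, reference)))
    stop("focal and reference groups overlap: ",
         paste(intersect(focal, reference), collapse = ", "))
  bad <- setdiff(c(focal, reference), rownames(dist))
  if (length(bad))
    stop("species not in distance matrix: ", paste(bad, collapse = ", "))
  sub <- dist[focal, reference, drop = FALSE]
  mean(apply(sub, 1L, min))
}

# statistic for the "colonists as established species" resident definition:
# each focal species' nearest neighbor may be another focal species
.mnnd_focal_vs_established <- function(focal, residents, dist) {
  if (length(focal) == 1L)
    return(cross_group_mnnd(focal, residents, dist))
  all_est <- union(residents, focal)
  sub <- dist[focal, all_est, drop = FALSE]
  sub[cbind(seq_along(focal), match(focal, all_est))] <- Inf
  mean(apply(sub, 1L, min))
}

#' Colonist relatedness test for one plot
#'
#' Tests whether the species that colonized a plot are more (clustered) or
#' less (overdispersed) closely related to the plot's residents than random
#' recruits of equal number drawn from the regional pool. The null draws
#' pseudo-colonists from `pool` minus the plot's sown species (and minus
#' any excluded clades), recomputing the same statistic each time.
#'
#' @param part A [partition_plot()] result with at least one colonist.
#' @param pool Character vector: the regional species pool from which
#'   pseudo-colonists are drawn.
#' @param dist Patristic matrix covering pool and plot species.
#' @param tags Named clade-tag vector (see [null_constraints()]); needed
#'   when `exclude_tags` is used.
#' @param residents `"sown"` (default) compares colonists to the sown
#'   species; `"established"` additionally counts other colonists as
#'   residents (the colonists-as-established-species variant, used because
#'   the sequence of colonizations and extinctions within the census
#'   interval is unknown).
#' @param exclude_tags Clade tags dropped from both the focal colonists and
#'   the null pool (e.g. `"legume"` to remove the legume clade's long
#'   branch from the analysis).
#' @param n_rand Number of null randomizations.
#' @param seed Optional seed for the null draws.
#' @param alpha Significance level for the direction label.
#' @return An object of class `c("relatedness_test", "dispersion")` with
#'   the dispersion fields plus `plot_id`, `focal_group`, `n_focal`,
#'   `n_residents` and an `options` record.
#' @export
colonist_relatedness_test <- function(part, pool, dist, tags = NULL,
                                      residents = c("sown", "established"),
                                      exclude_tags = NULL, n_rand = 1000L,
                                      seed = NULL, alpha = 0.05) {
  stopifnot(inherits(part, "plot_partition"))
  residents <- match.arg(residents)
  tag_of <- .tag_lookup(unique(c(pool, part$sown, part$final)), tags)
  focal <- part$colonize
  if (length(exclude_tags))
    focal <- focal[!(tag_of[focal] %in% exclude_tags)]
  if (!length(focal))
    stop("no colonists", if (length(exclude_tags)) " after clade exclusion")
  res_set <- part$sown
  if (!length(res_set)) stop("no resident species")
  null_pool <- sort(setdiff(pool, part$sown))  # canonical draw order
  if (length(exclude_tags))
    null_pool <- null_pool[!(tag_of[null_pool] %in% exclude_tags)]
  if (length(null_pool) < length(focal))
    stop("null pool smaller than the number of colonists")
  stat <- if (residents == "established") .mnnd_focal_vs_established
          else cross_group_mnnd
  observed <- stat(focal, res_set, dist)
  k <- length(focal)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_rand), function(i) {
      stat(sample(null_pool, k), res_set, dist)
    }, numeric(1))
  })
  out <- dispersion_test(observed, null_values, alpha = alpha,
                         metric = "colonist MNND")
  out$plot_id <- part$plot_id
  out$focal_group <- "colonize"
  out$n_focal <- k
  out$n_residents <- length(res_set)
  out$options <- list(residents = residents, exclude_tags = exclude_tags,
                      n_rand = n_rand, seed = seed)
  class(out) <- c("relatedness_test", class(out))
  out
}

#' Extinction relatedness test for one plot
#'
#' Tests whether the sown species that went extinct were phylogenetically
#' non-random with respect to the species that survived. The null holds
#' the number of extinctions fixed and relabels which sown species are
#' "extinct" (a hypergeometric relabeling within the sown set), matching
#' the question "do extinctions depend on plot phylogenetic structure".
#'
#' @param part A [partition_plot()] result with >= 1 extinct and >= 1
#'   persisting species.
#' @param dist Patristic matrix.
#' @param tags Named clade-tag vector, needed for `exclude_tags`.
#' @param survivors `"persist"` (default) compares extinct species to the
#'   sown survivors; `"established"` adds the plot's colonists to the
#'   survivor side (colonists-as-established-species variant).
#' @param exclude_tags Clade tags removed from the plot before the test
#'   (e.g. `"grass"` to look for a non-grass pattern).
#' @param n_rand,seed,alpha As in [colonist_relatedness_test()].
#' @return A `c("relatedness_test", "dispersion")` object.
#' @export
extinction_relatedness_test <- function(part, dist, tags = NULL,
                                        survivors = c("persist", "established"),
                                        exclude_tags = NULL, n_rand = 1000L,
                                        seed = NULL, alpha = 0.05) {
  stopifnot(inherits(part, "plot_partition"))
  survivors <- match.arg(survivors)
  tag_of <- .tag_lookup(unique(c(part$sown, part$final)), tags)
  keep <- function(x) if (length(exclude_tags))
    x[!(tag_of[x] %in% exclude_tags)] else x
  sown <- sort(keep(part$sown))
  extinct <- keep(part$extinct)
  persist <- keep(part$persist)
  colonize <- keep(part$colonize)
  if (!length(extinct))
    stop("no extinctions", if (length(exclude_tags)) " after clade exclusion")
  if (!length(persist))
    stop("no surviving sown species: extinction test undefined")
  extra <- if (survivors == "established") colonize else character()
  observed <- cross_group_mnnd(extinct, union(persist, extra), dist)
  n_ext <- length(extinct)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_rand), function(i) {
      pseudo_ext <- sample(sown, n_ext)
      cross_group_mnnd(pseudo_ext, union(setdiff(sown, pseudo_ext), extra),
                       dist)
    }, numeric(1))
  })
  out <- dispersion_test(observed, null_values, alpha = alpha,
                         metric = "extinction MNND")
  out$plot_id <- part$plot_id
  out$focal_group <- "extinct"
  out$n_focal <- n_ext
  out$n_residents <- length(persist) + length(extra)
  out$options <- list(survivors = survivors, exclude_tags = exclude_tags,
                      n_rand = n_rand, seed = seed)
  class(out) <- c("relatedness_test", class(out))
  out
}

#' @export
print.relatedness_test <- function(x, ...) {
  cat(sprintf("%s relatedness test, plot %s (n focal = %d, residents = %d)\n",
              x$focal_group, x$plot_id, x$n_focal, x$n_residents))
  NextMethod()
}

#' Pool-level colonizer (or extinction-prone species) dispersion test
#'
#' Asks whether the set of species that colonized (or went extinct in) at
#' least one plot is phylogenetically clustered or overdispersed across the
#' regional species pool: observed MNND of the focal set versus MNND of
#' equal-sized uniform draws from the pool (no grass constraint; this is a
#' pool-level, not a plot-level, test).
#'
#' @param focal Character vector of >= 2 focal species (e.g. all species
#'   observed to colonize anywhere).
#' @param pool Character vector: regional pool containing `focal`.
#' @param dist Patristic matrix.
#' @param n_rand,seed,alpha As elsewhere.
#' @return A `"dispersion"` object.
#' @export
pool_dispersion_test <- function(focal, pool, dist, n_rand = 1000L,
                                 seed = NULL, alpha = 0.05) {
  focal <- unique(as.character(focal))
  pool <- sort(unique(as.character(pool)))
  if (length(focal) < 2L) stop("need at least 2 focal species")
  bad <- setdiff(focal, pool)
  if (length(bad))
    stop("focal species not in pool: ", paste(bad, collapse = ", "))
  observed <- community_mnnd(dist, focal)
  k <- length(focal)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_rand), function(i) {
      community_mnnd(dist, sample(pool, k))
    }, numeric(1))
  })
  dispersion_test(observed, null_values, alpha = alpha, metric = "pool MNND")
}

#' Count significant plots by dispersion direction
#'
#' Summarizes a batch of per-plot tests: how many were significantly
#' clustered or overdispersed at `alpha`, against the number expected by
#' chance alone ([expected_false_positives()]). Benjamini-Hochberg adjusted
#' p-values are included for reference but the headline counts are
#' unadjusted, mirroring the compare-to-expected-count reading.
#'
#' @param results List of `"dispersion"`/`"relatedness_test"` objects.
#' @param alpha Significance level.
#' @return An object of class `"significance_summary"`: `n_tested`,
#'   `n_clustered`, `n_overdispersed`, `n_significant`, `expected_by_chance`,
#'   and a per-plot `table` data frame (with `p_bh`).
#' @export
count_significant <- function(results, alpha = 0.05) {
  if (!length(results)) stop("no test results to summarize")
  ok <- vapply(results, inherits, logical(1), what = "dispersion")
  if (!all(ok)) stop("all elements must be dispersion test results")
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(plot_id = if (!is.null(r$plot_id)) r$plot_id else NA_character_,
               observed = r$observed, null_mean = r$null_mean,
               null_sd = r$null_sd, ses = r$ses, p = r$p,
               sd_zero = r$sd_zero, stringsAsFactors = FALSE)
  }))
  tab$p_bh <- stats::p.adjust(tab$p, method = "BH")
  sig <- tab$p < alpha & !tab$sd_zero
  clustered <- sig & tab$observed < tab$null_mean
  over <- sig & tab$observed > tab$null_mean
  tab$direction <- ifelse(clustered, "clustered",
                          ifelse(over, "overdispersed", "random"))
  structure(list(n_tested = nrow(tab),
                 n_clustered = sum(clustered),
                 n_overdispersed = sum(over),
                 n_significant = sum(sig),
                 expected_by_chance = expected_false_positives(nrow(tab), alpha),
                 alpha = alpha, table = tab),
            class = "significance_summary")
}

#' @export
print.significance_summary <- function(x, ...) {
  cat(sprintf(paste0("%d plots tested at alpha = %g: %d clustered, ",
                     "%d overdispersed (%d expected by chance)\n"),
              x$n_tested, x$alpha, x$n_clustered, x$n_overdispersed,
              x$expected_by_chance))
  invisible(x)
}
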