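# Synthetic BIODEPTH-style experiment generator.
#
# Emulates the field design the analyses were built for: a regional pool
# of 60 grassland species (48 sown "internal" + 12 "external" colonists),
# with grass and legume clades, the legume clade sitting on a long stem;
# 59 plots sown at richness 1/2/4/8/32 from the internal pool with every
# polyculture holding at least one grass; one collapsed two-year
# colonization/extinction transition with grass-biased extinction and
# legume-biased, close-relative-weighted colonization; and biomass that
# increases with PD plus a legume bonus. All parameters are explicit and
# returned as ground truth so every analysis stage can be tested against
# known generating values.

#' Configuration for the synthetic regional-pool phylogeny
#'
#' @param n_internal,n_external Sizes of the sown (internal) pool and of
#'   the external colonist pool; internal + external species form the
#'   regional pool and the tree's tips.
#' @param n_grass,n_legume Tip counts of the grass and legume clades; the
#'   remainder are tagged `"other"` (forbs).
#' @param legume_stem_multiplier Factor (>= 1) applied to the legume
#'   clade's stem branch, making legumes distantly related to everything
#'   else — the structural feature that lets legume colonization dominate
#'   PD change.
#' @param birth Yule birth rate for each clade subtree.
#' @param total_length Total branch length the finished tree is rescaled
#'   to (branch-length units; sets the scale of PD and MNND values).
#' @param seed Optional seed.
#' @return List of class `"sim_tree_config"`.
#' @export
sim_tree_config <- function(n_internal = 48L, n_external = 12L,
                            n_grass = 12L, n_legume = 6L,
                            legume_stem_multiplier = 5, birth = 1,
                            total_length = 6, seed = NULL) {
  n_total <- n_internal + n_external
  if (n_grass + n_legume > n_total)
    stop("grass + legume clade sizes exceed total tips")
  if (n_grass < 1L || n_legume < 1L || n_total - n_grass - n_legume < 1L)
    stop("each clade (grass, legume, other) needs at least one tip")
  if (legume_stem_multiplier < 1) stop("legume_stem_multiplier must be >= 1")
  structure(list(n_internal = as.integer(n_internal),
                 n_external = as.integer(n_external),
                 n_grass = as.integer(n_grass),
                 n_legume = as.integer(n_legume),
                 legume_stem_multiplier = legume_stem_multiplier,
                 birth = birth, total_length = total_length, seed = seed),
            class = "sim_tree_config")
}

# Yule subtree rescaled to unit depth, tips renamed with a prefix
.sim_clade <- function(n, birth, prefix) {
  tr <- if (n == 1L) {
    structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "t1",
                   edge.length = 1, Nnode = 1L), class = "phylo")
  } else {
    ape::rphylo(n, birth = birth, death = 0)
  }
  depth <- max(ape::node.depth.edgelength(tr))
  if (depth > 0) tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("%s%02d", prefix, seq_len(n))
  tr
}

#' Simulate the tagged regional-pool phylogeny
#'
#' Grass, legume and forb clades are each grown as a pure-birth (Yule)
#' tree, rescaled to unit depth, and joined as ((forbs, grasses), legumes)
#' with the legume stem scaled by the configured multiplier. The whole
#' tree is then rescaled to `total_length`. Deterministic under the
#' config seed.
#'
#' @param config A [sim_tree_config()].
#' @return A `"phylo"` tree with a `tags` attribute (named vector:
#'   species -> grass/legume/other). Tip labels are `G..` (grass), `L..`
#'   (legume) and `F..` (forb).
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_tree_config"))
  n_total <- config$n_internal + config$n_external
  n_forb <- n_total - config$n_grass - config$n_legume
  tree <- with_seed(config$seed, {
    forb <- .sim_clade(n_forb, config$birth, "F")
    grass <- .sim_clade(config$n_grass, config$birth, "G")
    leg <- .sim_clade(config$n_legume, config$birth, "L")
    strip <- function(tr) sub(";$", "", ape::write.tree(tr))
    # unit-depth subtrees; inner (forb,grass) crown at depth 0.5 from root,
    # legume stem 0.5 * multiplier gives the long branch
    nwk <- sprintf("((%s:0.25,%s:0.25):0.25,%s:%s);",
                   strip(forb), strip(grass), strip(leg),
                   format(0.5 * config$legume_stem_multiplier, digits = 15))
    ape::read.tree(text = nwk)
  })
  tree$edge.length <- tree$edge.length *
    (config$total_length / sum(tree$edge.length))
  validate_phylogeny(tree)
  attr(tree, "tags") <- stats::setNames(
    c(rep("other", n_forb), rep("grass", config$n_grass),
      rep("legume", config$n_legume)),
    c(sprintf("F%02d", seq_len(n_forb)),
      sprintf("G%02d", seq_len(config$n_grass)),
      sprintf("L%02d", seq_len(config$n_legume))))
  tree
}

#' Configuration for the sown experimental design
#'
#' Defaults reproduce the usable-plot layout of the field experiment: 59
#' plots across sown richness 1, 2, 4, 8 and 32 (11 monocultures and 12
#' plots per polyculture level), every polyculture containing at least one
#' grass, all species drawn from the internal pool.
#'
#' @param richness_levels Sown richness treatments.
#' @param plots_per_level Number of plots at each level (recycled).
#' @param grass_required Enforce >= 1 grass per polyculture.
#' @param seed Optional seed.
#' @return List of class `"sim_experiment_config"`.
#' @export
sim_experiment_config <- function(richness_levels = c(1L, 2L, 4L, 8L, 32L),
                                  plots_per_level = c(11L, 12L, 12L, 12L, 12L),
                                  grass_required = TRUE, seed = NULL) {
  if (any(richness_levels < 1L)) stop("richness levels must be positive")
  plots_per_level <- rep_len(as.integer(plots_per_level),
                             length(richness_levels))
  structure(list(richness_levels = as.integer(richness_levels),
                 plots_per_level = plots_per_level,
                 grass_required = isTRUE(grass_required), seed = seed),
            class = "sim_experiment_config")
}

#' Simulate the sown plot compositions
#'
#' Each plot is a uniform draw of its treatment richness from the internal
#' pool, redrawn until it contains a grass when the constraint applies
#' (polycultures only; monocultures are unconstrained).
#'
#' @param tree Tagged tree from [simulate_tree()] (or any tree).
#' @param internal_pool Species available for sowing.
#' @param config A [sim_experiment_config()].
#' @param tags Named clade-tag vector; defaults to the tree's `tags`
#'   attribute.
#' @return A `community_table` (census `"sown"`) with plot ids `P01`, ...
#' @export
simulate_sown_design <- function(tree, internal_pool, config, tags = NULL) {
  stopifnot(inherits(config, "sim_experiment_config"))
  if (is.null(tags)) tags <- attr(tree, "tags")
  bad <- setdiff(internal_pool, tree$tip.label)
  if (length(bad)) stop("internal pool species not in tree: ",
                        paste(bad, collapse = ", "))
  if (max(config$richness_levels) > length(internal_pool))
    stop("richness level exceeds internal pool size")
  richness <- rep(config$richness_levels, config$plots_per_level)
  plots <- with_seed(config$seed, {
    lapply(richness, function(k) {
      if (k >= 2L && config$grass_required) {
        spec <- null_constraints(internal_pool, tags = tags,
                                 require_tag = "grass")
        sample_null_community(spec, k)
      } else {
        sample(internal_pool, k)
      }
    })
  })
  names(plots) <- sprintf("P%02d", seq_along(plots))
  community_table(plots, census = "sown")
}

#' Parameters of the colonization/extinction/biomass process
#'
#' All rates refer to the single collapsed transition between the sown and
#' final censuses (the two unweeded field seasons treated as one step).
#'
#' @param extinction_baseline Per-species probability that a sown
#'   non-grass species is absent at the final census. The default 0.19
#'   corresponds to roughly 10% of species lost per year over two years.
#' @param grass_extinction_multiplier Multiplier on the extinction
#'   probability of grass species (grasses were extinction-prone).
#' @param colonization_baseline Per-species, per-plot baseline
#'   colonization probability for pool species absent from the plot.
#' @param kernel_affinity,kernel_lambda,kernel_constant Colonization
#'   kernel: the success probability is
#'   `baseline * (affinity * exp(-d / lambda) + constant)`, with `d` the
#'   candidate's patristic distance to its nearest plot resident
#'   (branch-length units). The affinity term produces the close-relative
#'   colonist mode; the constant keeps distant colonization possible.
#' @param legume_colonization_bonus Multiplier on legume colonization
#'   probability (legumes were good colonists); probabilities are capped
#'   at 1.
#' @param biomass_intercept,biomass_pd_slope,biomass_legume_bonus,biomass_noise_sd
#'   Biomass model, g/m^2: `intercept + pd_slope * PD + legume_bonus *
#'   [legume present] + Normal(0, noise_sd)`, truncated at 0.
#' @param seed Optional seed.
#' @return List of class `"sim_dynamics_params"`.
#' @export
sim_dynamics_params <- function(extinction_baseline = 0.19,
                                grass_extinction_multiplier = 1.8,
                                colonization_baseline = 0.08,
                                kernel_affinity = 2,
                                kernel_lambda = 0.4,
                                kernel_constant = 0.5,
                                legume_colonization_bonus = 8,
                                biomass_intercept = 150,
                                biomass_pd_slope = 120,
                                biomass_legume_bonus = 150,
                                biomass_noise_sd = 80,
                                seed = NULL) {
  stopifnot(extinction_baseline >= 0, extinction_baseline <= 1,
            grass_extinction_multiplier >= 0,
            colonization_baseline >= 0, colonization_baseline <= 1,
            kernel_lambda > 0, biomass_noise_sd >= 0)
  structure(as.list(environment()), class = "sim_dynamics_params")
}

#' Simulate one colonization/extinction transition
#'
#' Each sown species goes extinct independently with probability
#' `extinction_baseline` (times the grass multiplier for grasses, capped
#' at 1); each pool species absent from the plot then colonizes with the
#' kernel-weighted probability described in [sim_dynamics_params()],
#' evaluated against the plot's surviving residents. Plots losing all
#' species can only be recolonized through the kernel's constant term.
#'
#' @param sown Sown-census `community_table`.
#' @param tree Regional-pool tree.
#' @param pool Regional pool from which colonists may arrive.
#' @param params A [sim_dynamics_params()].
#' @param tags Clade tags; defaults to the tree's `tags` attribute.
#' @param dist Optional precomputed patristic matrix.
#' @return Final-census `community_table` over the same plots.
#' @export
simulate_dynamics <- function(sown, tree, pool, params, tags = NULL,
                              dist = NULL) {
  stopifnot(inherits(sown, "community_table"),
            inherits(params, "sim_dynamics_params"))
  if (is.null(tags)) tags <- attr(tree, "tags")
  if (is.null(dist)) dist <- patristic_matrix(tree)
  tag_of <- .tag_lookup(unique(c(pool, unlist(sown$plots))), tags)
  p_ext <- function(sp) pmin(1, params$extinction_baseline *
    ifelse(tag_of[sp] == "grass", params$grass_extinction_multiplier, 1))
  final <- with_seed(params$seed, {
    lapply(sown$plots, function(resident) {
      survivors <- resident[stats::runif(length(resident)) >= p_ext(resident)]
      candidates <- setdiff(pool, resident)
      if (length(candidates)) {
        d_near <- if (length(survivors))
          apply(dist[candidates, survivors, drop = FALSE], 1L, min)
        else rep(Inf, length(candidates))
        kern <- params$kernel_affinity * exp(-d_near / params$kernel_lambda) +
          params$kernel_constant
        p_col <- pmin(1, params$colonization_baseline * kern *
          ifelse(tag_of[candidates] == "legume",
                 params$legume_colonization_bonus, 1))
        colonists <- candidates[stats::runif(length(candidates)) < p_col]
      } else colonists <- character()
      union(survivors, colonists)
    })
  })
  community_table(final, census = "final")
}

#' Simulate per-plot aboveground biomass
#'
#' @param census `community_table` giving each plot's composition in the
#'   harvest year.
#' @param tree Regional-pool tree.
#' @param params A [sim_dynamics_params()] (biomass fields used).
#' @param tags Clade tags; defaults to the tree's attribute.
#' @param seed Optional seed overriding `params$seed`.
#' @return Named numeric vector of biomass (g/m^2), truncated at 0; empty
#'   plots produce intercept-plus-noise around zero composition (PD 0).
#' @export
simulate_biomass <- function(census, tree, params, tags = NULL, seed = NULL) {
  stopifnot(inherits(census, "community_table"),
            inherits(params, "sim_dynamics_params"))
  if (is.null(tags)) tags <- attr(tree, "tags")
  pd <- vapply(census$plots,
               function(sp) if (length(sp)) community_pd(tree, sp) else 0,
               numeric(1))
  leg <- vapply(census$plots,
                function(sp) any(.tag_lookup(sp, tags) == "legume"),
                logical(1))
  mu <- params$biomass_intercept + params$biomass_pd_slope * pd +
    params$biomass_legume_bonus * as.numeric(leg)
  b <- with_seed(if (is.null(seed)) params$seed else seed,
                 mu + stats::rnorm(length(mu), 0, params$biomass_noise_sd))
  stats::setNames(pmax(0, b), names(census$plots))
}

#' Simulate a complete synthetic experiment
#'
#' Runs the full generator — tree, species metadata, sown design, one
#' colonization/extinction transition, and biomass for both census years —
#' and returns a validated [assembly_data()] bundle. Year-1 biomass is
#' generated from the sown composition, year-2 biomass from the final
#' composition. External-pool species (potential colonists never sown) are
#' drawn from the forb and legume clades, keeping all grasses available to
#' the sowing constraint. Each stage uses its own RNG stream derived from
#' `seed` by a stable label, so outputs are reproducible stage by stage.
#'
#' @param seed Master seed for the whole experiment.
#' @param tree_config,experiment_config,params Stage configurations; any
#'   seeds inside them are overridden by streams derived from `seed`
#'   unless `seed` is `NULL`.
#' @return An `"assembly_data"` object with a `ground_truth` attribute
#'   recording every generating parameter and stage seed.
#' @export
simulate_experiment <- function(seed = NULL,
                                tree_config = sim_tree_config(),
                                experiment_config = sim_experiment_config(),
                                params = sim_dynamics_params()) {
  if (!is.null(seed)) {
    tree_config$seed <- stage_seed(seed, "tree")
    experiment_config$seed <- stage_seed(seed, "design")
    params$seed <- stage_seed(seed, "dynamics")
  }
  tree <- simulate_tree(tree_config)
  tags <- attr(tree, "tags")
  tips <- tree$tip.label
  non_grass <- tips[tags[tips] != "grass"]
  if (tree_config$n_external > length(non_grass))
    stop("external pool larger than the non-grass tip set")
  external <- with_seed(
    if (is.null(tree_config$seed)) NULL else stage_seed(tree_config$seed, "external"),
    sample(non_grass, tree_config$n_external))
  internal <- setdiff(tips, external)
  species <- data.frame(species_id = tips,
                        clade_tag = unname(tags[tips]),
                        pool = ifelse(tips %in% external, "external", "internal"),
                        stringsAsFactors = FALSE)
  sown <- simulate_sown_design(tree, internal, experiment_config, tags = tags)
  final <- simulate_dynamics(sown, tree, tips, params, tags = tags)
  bio_seed <- function(label) if (is.null(params$seed)) NULL
                              else stage_seed(params$seed, label)
  b1 <- simulate_biomass(sown, tree, params, tags = tags,
                         seed = bio_seed("biomass1"))
  b2 <- simulate_biomass(final, tree, params, tags = tags,
                         seed = bio_seed("biomass2"))
  plots <- data.frame(plot_id = names(sown$plots),
                      sown_richness = unname(lengths(sown$plots)),
                      biomass_year1 = unname(b1[names(sown$plots)]),
                      biomass_year2 = unname(b2[names(sown$plots)]),
                      stringsAsFactors = FALSE)
  out <- assembly_data(tree, sown, final, plots, species)
  attr(out, "ground_truth") <- list(seed = seed,
                                    tree_config = unclass(tree_config),
                                    experiment_config = unclass(experiment_config),
                                    params = unclass(params))
  out
}
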