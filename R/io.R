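# Plot-by-species tables and the on-disk exchange formats.
#
# Compositions travel as long-format CSV (plot_id, species_id, census),
# plot metadata as plots.csv (plot_id, sown_richness, biomass_year1,
# biomass_year2) and species metadata as species.csv (species_id,
# clade_tag, pool). The in-memory container is a light S3 list keyed by
# plot.

#' Construct a community table for one census
#'
#' @param plots Named list: one character vector of species per plot.
#' @param census Census label, e.g. `"sown"` or `"final"`.
#' @return An object of class `"community_table"`.
#' @export
community_table <- function(plots, census = "sown") {
  if (is.null(names(plots)) || any(!nzchar(names(plots))))
    stop("plots must be a named list (plot_id -> species vector)")
  if (anyDuplicated(names(plots))) stop("duplicate plot_id")
  plots <- lapply(plots, function(x) unique(as.character(x)))
  structure(list(plots = plots, census = census), class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  rich <- lengths(x$plots)
  cat(sprintf("community_table: %d plots, census '%s', richness %d-%d\n",
              length(x$plots), x$census, min(rich), max(rich)))
  invisible(x)
}

#' Plot richness of a community table
#' @param x A `"community_table"`.
#' @return Named integer vector of species counts per plot.
#' @export
plot_richness <- function(x) {
  stopifnot(inherits(x, "community_table"))
  lengths(x$plots)
}

#' Read plot compositions from long-format CSV
#'
#' Expects columns `plot_id`, `species_id`, `census`. One
#' `community_table` is returned per census level present (or the one
#' selected by `census`).
#'
#' @param file CSV path.
#' @param census Optional single census to extract.
#' @return A `community_table`, or a named list of them (one per census).
#' @export
read_composition <- function(file, census = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("plot_id", "species_id", "census")
  if (!all(need %in% names(df)))
    stop("composition file must have columns: ", paste(need, collapse = ", "))
  make_ct <- function(sub, cen) {
    community_table(split(sub$species_id, sub$plot_id), census = cen)
  }
  if (!is.null(census)) {
    sub <- df[df$census == census, ]
    if (!nrow(sub)) stop("no rows for census '", census, "'")
    return(make_ct(sub, census))
  }
  lv <- unique(df$census)
  stats::setNames(lapply(lv, function(cen) make_ct(df[df$census == cen, ], cen)), lv)
}

#' Write one or more community tables to long-format CSV
#' @param ... `community_table` objects.
#' @param file Output CSV path.
#' @export
write_composition <- function(..., file) {
  cts <- list(...)
  rows <- do.call(rbind, lapply(cts, function(ct) {
    stopifnot(inherits(ct, "community_table"))
    data.frame(plot_id = rep(names(ct$plots), lengths(ct$plots)),
               species_id = unlist(ct$plots, use.names = FALSE),
               census = ct$census, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Read species metadata (clade tags and pool membership)
#'
#' @param file CSV with columns `species_id`, `clade_tag`
#'   (grass/legume/other), `pool` (internal/external).
#' @return Data frame with those columns, validated.
#' @export
read_species_metadata <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("species_id", "clade_tag", "pool")
  if (!all(need %in% names(df)))
    stop("species file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$species_id)) stop("duplicate species_id")
  if (!all(df$pool %in% c("internal", "external")))
    stop("pool must be 'internal' or 'external'")
  df
}

#' Read per-plot design and biomass metadata
#'
#' @param file CSV with columns `plot_id`, `sown_richness`,
#'   `biomass_year1`, `biomass_year2` (g/m^2).
#' @return Validated data frame.
#' @export
read_plot_metadata <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("plot_id", "sown_richness", "biomass_year1", "biomass_year2")
  if (!all(need %in% names(df)))
    stop("plots file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$plot_id)) stop("duplicate plot_id")
  df
}

#' Load and cross-validate a full assembly data set
#'
#' Reads the phylogeny and the three CSV tables and checks that every
#' species in any composition is a tip of the tree and listed in the
#' species metadata, and that plot identifiers agree across files.
#'
#' @param tree_file Newick file for the regional-pool phylogeny.
#' @param composition_file Long CSV with both `sown` and `final` censuses.
#' @param plots_file Plot metadata CSV.
#' @param species_file Species metadata CSV.
#' @return An object of class `"assembly_data"`: `tree`, `dist`, `sown`,
#'   `final`, `plots`, `species`, `tags` (named vector), and pools
#'   (`internal_pool`, `regional_pool`).
#' @export
read_assembly_data <- function(tree_file, composition_file, plots_file,
                               species_file) {
  tree <- read_phylogeny(tree_file)
  comps <- read_composition(composition_file)
  if (!all(c("sown", "final") %in% names(comps)))
    stop("composition file must contain 'sown' and 'final' censuses")
  plots <- read_plot_metadata(plots_file)
  species <- read_species_metadata(species_file)
  assembly_data(tree, comps$sown, comps$final, plots, species)
}

#' Assemble and validate an in-memory assembly data set
#'
#' Same validation as [read_assembly_data()] for components already in
#' memory (e.g. from the synthetic generator).
#'
#' @param tree `"phylo"` object.
#' @param sown,final `community_table` objects for the two censuses.
#' @param plots Plot metadata data frame.
#' @param species Species metadata data frame.
#' @return An `"assembly_data"` object.
#' @export
assembly_data <- function(tree, sown, final, plots, species) {
  validate_phylogeny(tree)
  stopifnot(inherits(sown, "community_table"), inherits(final, "community_table"))
  all_sp <- unique(c(unlist(sown$plots), unlist(final$plots)))
  not_tip <- setdiff(all_sp, tree$tip.label)
  if (length(not_tip))
    stop("species in compositions absent from tree: ",
         paste(not_tip, collapse = ", "))
  not_meta <- setdiff(all_sp, species$species_id)
  if (length(not_meta))
    stop("species in compositions absent from species metadata: ",
         paste(not_meta, collapse = ", "))
  if (!setequal(names(sown$plots), plots$plot_id))
    stop("plot_id mismatch between sown composition and plot metadata")
  if (length(setdiff(names(final$plots), plots$plot_id)))
    stop("final census contains unknown plot_id")
  tags <- stats::setNames(species$clade_tag, species$species_id)
  internal <- species$species_id[species$pool == "internal"]
  structure(list(tree = tree, dist = patristic_matrix(tree),
                 sown = sown, final = final, plots = plots,
                 species = species, tags = tags,
                 internal_pool = internal,
                 regional_pool = species$species_id),
            class = "assembly_data")
}

#' @export
print.assembly_data <- function(x, ...) {
  cat(sprintf(paste0("assembly_data: %d plots, %d-species regional pool ",
                     "(%d internal), tree of %d tips\n"),
              length(x$sown$plots), length(x$regional_pool),
              length(x$internal_pool), length(x$tree$tip.label)))
  invisible(x)
}

#' Write an assembly data set to a directory
#'
#' Emits exactly the files [read_assembly_data()] consumes: `tree.nwk`,
#' `composition.csv`, `plots.csv`, `species.csv`. If the data carry a
#' simulation ground truth it is written as `ground_truth.json`.
#'
#' @param data An `"assembly_data"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assembly_data <- function(data, dir) {
  stopifnot(inherits(data, "assembly_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(data$tree, file.path(dir, "tree.nwk"))
  write_composition(data$sown, data$final,
                    file = file.path(dir, "composition.csv"))
  utils::write.csv(data$plots, file.path(dir, "plots.csv"), row.names = FALSE)
  utils::write.csv(data$species, file.path(dir, "species.csv"),
                   row.names = FALSE)
  if (!is.null(attr(data, "ground_truth")))
    jsonlite::write_json(attr(data, "ground_truth"),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
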