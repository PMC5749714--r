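# Seeded synthetic-data generators.
#
# These emulate the structures the analysis pipeline assumes: binary
# incidence matrices with controllable fill, nestedness, checkerboard
# segregation, and marginal-proportional (drift-like) assembly; 9-rank
# taxonomies; site metadata with positively skewed length/depth
# distributions, coordinates in a box and visit counts; and categorical
# traits. All generators are deterministic given a seed, and by default
# condition incidence matrices on having no empty row or column so that
# fixtures never hit degenerate branches unintentionally.

#' Random (equiprobable) incidence matrix
#'
#' Occurrences are placed uniformly at random among cells, conditional on
#' no empty row or column (disable with `allow_degenerate = TRUE`).
#'
#' @param n_species,n_sites matrix dimensions.
#' @param fill total number of occurrences.
#' @param seed optional integer seed.
#' @param allow_degenerate if TRUE, skip the no-empty-row/column
#'   conditioning (useful for exercising error paths).
#' @return an [incidence_matrix()].
#' @export
gen_random_matrix <- function(n_species, n_sites, fill, seed = NULL,
                              allow_degenerate = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  ncell <- n_species * n_sites
  if (fill > ncell) stop("fill exceeds the number of cells")
  if (!allow_degenerate && fill < max(n_species, n_sites))
    stop("fill ", fill, " cannot avoid empty rows/columns")
  for (i in seq_len(MAX_REJECTIONS)) {
    out <- matrix(0L, n_species, n_sites)
    out[sample.int(ncell, fill)] <- 1L
    if (allow_degenerate || no_degenerate(out))
      return(incidence_matrix(out))
  }
  stop("could not draw a non-degenerate matrix in ", MAX_REJECTIONS,
       " attempts")
}

#' Nested incidence matrix with tunable noise
#'
#' At `noise = 0` produces a perfectly nested threshold matrix: species
#' are ranked, sites are ranked, and site j holds the top k_j species with
#' k_j strictly decreasing (k_1 = n_species), so every poorer site's
#' community is a true subset of every richer site's. NODF additionally
#' requires distinct marginal totals on both margins to score a pair, so
#' NODF = 100 is attained on the square stair case (`steepness = 1`,
#' `n_species = n_sites`, giving k = n, n-1, ..., 1); non-square or
#' steeper profiles remain perfectly nested in the subset sense but tie
#' some row totals and score below 100. `steepness` shapes the decay of
#' k_j (larger = steeper richness drop); `noise` flips that fraction of
#' randomly chosen cells.
#'
#' @param n_species,n_sites matrix dimensions.
#' @param steepness positive decay exponent for site richness (default 1).
#' @param noise fraction of cells to flip, in [0, 1).
#' @param seed optional integer seed.
#' @param condition if TRUE (default) redraw noise until no empty
#'   row/column.
#' @return an [incidence_matrix()].
#' @export
gen_nested_matrix <- function(n_species, n_sites, steepness = 1, noise = 0,
                              seed = NULL, condition = TRUE) {
  if (steepness <= 0) stop("steepness must be positive")
  if (noise < 0 || noise >= 1) stop("noise must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  k <- round(n_species * ((n_sites - seq_len(n_sites) + 1) / n_sites)^steepness)
  k[1] <- n_species
  # enforce strictly decreasing site richness where possible (floor at 1)
  for (j in seq_len(n_sites)[-1]) k[j] <- max(min(k[j], k[j - 1] - 1), 1)
  base <- vapply(k, function(kk) c(rep(1L, kk), rep(0L, n_species - kk)),
                 integer(n_species))
  if (noise == 0) return(incidence_matrix(base))
  nflip <- round(noise * length(base))
  for (i in seq_len(MAX_REJECTIONS)) {
    out <- base
    flip <- sample.int(length(out), nflip)
    out[flip] <- 1L - out[flip]
    if (!condition || no_degenerate(out)) return(incidence_matrix(out))
  }
  stop("could not draw a non-degenerate noisy matrix")
}

#' Checkerboard incidence matrix
#'
#' Species come in perfectly complementary pairs: within each pair one
#' species occupies one half of the sites and the other species the other
#' half, so every pair forms (n_sites/2)^2 checkerboard units — the
#' maximum possible given the marginals. The assignment of sites to
#' halves is a seeded random permutation.
#'
#' @param n_pairs number of species pairs (rows = 2 x n_pairs).
#' @param n_sites even number of sites.
#' @param seed optional integer seed.
#' @return an [incidence_matrix()].
#' @export
gen_checkerboard_matrix <- function(n_pairs, n_sites, seed = NULL) {
  if (n_sites %% 2 != 0) stop("n_sites must be even")
  if (!is.null(seed)) set.seed(seed)
  half <- n_sites / 2
  cols <- sample.int(n_sites)
  a_sites <- cols[seq_len(half)]
  out <- matrix(0L, 2 * n_pairs, n_sites)
  for (p in seq_len(n_pairs)) {
    out[2 * p - 1, a_sites] <- 1L
    out[2 * p, -a_sites] <- 1L
  }
  incidence_matrix(out)
}

#' Drift-assembled (passive-sampling) incidence matrix
#'
#' Each site draws its community from the regional pool without
#' replacement, with species selection probability proportional to its
#' pool weight and community size fixed by the site's capacity — a
#' mass-effects passive-sampling process, i.e. neutral colonisation
#' without dispersal limitation. Skewed pool weights produce the skewed
#' occupancy distributions typical of regional incidence data.
#'
#' @param pool_weights positive per-species colonisation weights.
#' @param site_capacities positive per-site community sizes (each at most
#'   the pool size).
#' @param seed optional integer seed.
#' @param drop_empty drop species that were never drawn (default TRUE).
#' @return an [incidence_matrix()].
#' @export
gen_drift_assembly <- function(pool_weights, site_capacities, seed = NULL,
                               drop_empty = TRUE) {
  if (any(pool_weights <= 0)) stop("pool weights must be positive")
  if (any(site_capacities <= 0)) stop("site capacities must be positive")
  n_sp <- length(pool_weights)
  if (any(site_capacities > n_sp))
    stop("site capacity exceeds the pool size")
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0L, n_sp, length(site_capacities))
  for (j in seq_along(site_capacities)) {
    out[sample.int(n_sp, site_capacities[j], prob = pool_weights), j] <- 1L
  }
  if (drop_empty) out <- out[rowSums(out) > 0, , drop = FALSE]
  incidence_matrix(out)
}

#' Random 9-rank taxonomy
#'
#' Builds a random classification tree over the eight internal ranks
#' (order ... subgenus; the species is the terminal ninth level). Each
#' species picks, rank by rank, one of `children_per_rank[k]` children of
#' its current taxon; taxon labels encode the full parent path, so the
#' table is tree-consistent by construction.
#'
#' @param n_species number of species (labelled `sp1 ...`).
#' @param children_per_rank integer vector of length 8: candidate children
#'   per parent at each rank (default `c(3, 2, 2, 3, 2, 2, 4, 2)`).
#' @param seed optional integer seed.
#' @return a validated taxonomy data.frame.
#' @export
gen_taxonomy <- function(n_species,
                         children_per_rank = c(3, 2, 2, 3, 2, 2, 4, 2),
                         seed = NULL) {
  if (length(children_per_rank) != length(TAXONOMIC_RANKS))
    stop("children_per_rank must have length ", length(TAXONOMIC_RANKS))
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(species_id = paste0("sp", seq_len(n_species)),
                    stringsAsFactors = FALSE)
  paths <- rep("t", n_species)
  for (k in seq_along(TAXONOMIC_RANKS)) {
    pick <- sample.int(children_per_rank[k], n_species, replace = TRUE)
    paths <- paste(paths, pick, sep = ".")
    out[[TAXONOMIC_RANKS[k]]] <- paths
  }
  validate_taxonomy(out)
}

#' Random cave metadata
#'
#' Generates site records with coordinates uniform in a bounding box,
#' log-normal (positively skewed) lengths and depths, uniform altitudes,
#' and visit counts drawn from a range within 1-12.
#'
#' @param n_sites number of sites (labelled `site1 ...`).
#' @param seed optional integer seed.
#' @param lon_range,lat_range coordinate box (defaults roughly match the
#'   Carpathian/Dobrogea karst region).
#' @param length_meanlog,length_sdlog log-scale parameters of cave length
#'   in metres.
#' @param depth_meanlog,depth_sdlog log-scale parameters of cave depth.
#' @param altitude_range altitude bounds in metres a.s.l.
#' @param visit_range integer bounds for visit counts (within 1-12).
#' @return a validated cave metadata data.frame.
#' @export
gen_cave_metadata <- function(n_sites, seed = NULL,
                              lon_range = c(21, 28.5),
                              lat_range = c(43.6, 48),
                              length_meanlog = log(150), length_sdlog = 1.2,
                              depth_meanlog = log(20), depth_sdlog = 1,
                              altitude_range = c(100, 1400),
                              visit_range = c(3, 12)) {
  if (!is.null(seed)) set.seed(seed)
  if (visit_range[1] < 1 || visit_range[2] > 12)
    stop("visit_range must lie within 1-12")
  df <- data.frame(
    site_id = paste0("site", seq_len(n_sites)),
    longitude = stats::runif(n_sites, lon_range[1], lon_range[2]),
    latitude = stats::runif(n_sites, lat_range[1], lat_range[2]),
    length_m = stats::rlnorm(n_sites, length_meanlog, length_sdlog),
    depth_m = stats::rlnorm(n_sites, depth_meanlog, depth_sdlog),
    altitude_m = stats::runif(n_sites, altitude_range[1], altitude_range[2]),
    visits = sample(seq(visit_range[1], visit_range[2]), n_sites,
                    replace = TRUE),
    stringsAsFactors = FALSE
  )
  validate_cave_metadata(df)
}

#' Random categorical trait table
#'
#' @param n_species number of species (labelled `sp1 ...`).
#' @param n_traits number of categorical traits.
#' @param levels number of levels per trait (recycled).
#' @param seed optional integer seed.
#' @return a trait data.frame: `species_id` plus `trait1 ...` columns.
#' @export
gen_traits <- function(n_species, n_traits = 3, levels = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  levels <- rep_len(levels, n_traits)
  out <- data.frame(species_id = paste0("sp", seq_len(n_species)),
                    stringsAsFactors = FALSE)
  for (t in seq_len(n_traits)) {
    out[[paste0("trait", t)]] <-
      paste0("L", sample.int(levels[t], n_species, replace = TRUE))
  }
  out
}

#' Full synthetic study at the scale of the cave-springtail dataset
#'
#' Bundles all generators into one drift-assembled metacommunity of 141
#' species across 189 sites: lognormal site capacities with median about
#' 4 and mean about 5.6 species per site (so beta_P is about 0.96 by
#' construction), lognormal pool weights, a 9-rank taxonomy, skewed cave
#' metadata and categorical traits. Site capacities scale weakly with the
#' generated cave length (richness-habitat-size coupling); species never
#' drawn are kept (re-assigned one occurrence at a random site) so the
#' pool size is exactly `n_species`.
#'
#' @param seed integer seed.
#' @param n_species,n_sites scenario dimensions (defaults 141 x 189).
#' @param capacity_meanlog,capacity_sdlog log-scale parameters of per-site
#'   community size.
#' @param weight_sdlog log-scale SD of pool colonisation weights.
#' @param length_effect exponent coupling site capacity to cave length.
#' @return a list with elements `matrix`, `metadata`, `taxonomy`,
#'   `traits`, all mutually consistent (passes [validate_dataset()]).
#' @examples
#' \donttest{
#' study <- cave_study_scenario(seed = 1)
#' diversity_summary(study$matrix)
#' }
#' @export
cave_study_scenario <- function(seed, n_species = 141, n_sites = 189,
                                 capacity_meanlog = log(4.2),
                                 capacity_sdlog = 0.75,
                                 weight_sdlog = 1.5,
                                 length_effect = 0.25) {
  set.seed(seed)
  metadata <- gen_cave_metadata(n_sites)
  base_cap <- stats::rlnorm(n_sites, capacity_meanlog, capacity_sdlog)
  cap <- pmax(1, round(base_cap *
                         (metadata$length_m / stats::median(metadata$length_m))^length_effect))
  cap <- pmin(cap, n_species)
  weights <- stats::rlnorm(n_species, 0, weight_sdlog)
  m <- gen_drift_assembly(weights, cap, drop_empty = FALSE)
  # keep the pool at exactly n_species: give never-drawn species one
  # occurrence at a random site
  empty <- which(rowSums(unclass(m)) == 0)
  if (length(empty)) {
    mm <- unclass(m)
    mm[cbind(empty, sample.int(n_sites, length(empty), replace = TRUE))] <- 1L
    m <- incidence_matrix(mm)
  }
  dimnames(m) <- list(paste0("sp", seq_len(n_species)), metadata$site_id)
  taxonomy <- gen_taxonomy(n_species)
  traits <- gen_traits(n_species)
  list(matrix = m, metadata = metadata, taxonomy = taxonomy, traits = traits)
}

#' Write a synthetic study to delimited files
#'
#' Writes the four tables of a [cave_study_scenario()]-style bundle to
#' `dir` as tab-delimited text (`incidence.tsv`, `metadata.tsv`,
#' `taxonomy.tsv`, `traits.tsv`), in the formats the readers of this
#' package expect.
#'
#' @param study a list with `matrix`, `metadata`, `taxonomy`, `traits`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_incidence_matrix(study$matrix, file.path(dir, "incidence.tsv"))
  for (nm in c("metadata", "taxonomy", "traits")) {
    utils::write.table(study[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
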