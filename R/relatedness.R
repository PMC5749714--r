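# Taxonomic relatedness from ranked classifications.
#
# A species' classification is its path through eight internal ranks
# (order ... subgenus); the species itself is the tip. The pairwise
# dissimilarity is the number of taxon nodes on the tree path between two
# tips: the lowest common taxon counted once plus every rank node below it
# on both descents, tips excluded. Missing ranks contribute no node.

#' The eight internal taxonomic ranks, broadest to finest
#'
#' Rank columns expected in a taxonomy table, in this fixed order; the
#' species itself is the terminal ninth level of the classification.
#'
#' @format a character vector of length 8.
#' @export
TAXONOMIC_RANKS <- c("order", "suborder", "superfamily", "family",
                     "subfamily", "tribe", "genus", "subgenus")

#' Read or validate a ranked taxonomy table
#'
#' A taxonomy table has a `species_id` column plus the eight internal rank
#' columns `order, suborder, superfamily, family, subfamily, tribe, genus,
#' subgenus` (the species itself is the ninth, terminal level). Empty cells
#' or NA mean the rank is absent for that species. Validation checks that
#' the implied tree is consistent: a taxon value never appears under two
#' different parent paths.
#'
#' @param path delimited text file (comma or tab, auto-detected) with the
#'   columns above.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab.
#' @return a validated taxonomy data.frame.
#' @export
read_taxonomy <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  validate_taxonomy(df)
}

#' @rdname read_taxonomy
#' @param taxonomy a data.frame to validate.
#' @export
validate_taxonomy <- function(taxonomy) {
  if (!"species_id" %in% names(taxonomy))
    stop("taxonomy lacks a species_id column")
  missing_ranks <- setdiff(TAXONOMIC_RANKS, names(taxonomy))
  if (length(missing_ranks))
    stop("taxonomy lacks rank columns: ", paste(missing_ranks, collapse = ", "))
  taxonomy$species_id <- as.character(taxonomy$species_id)
  if (anyDuplicated(taxonomy$species_id))
    stop("duplicate species in taxonomy: ",
         paste(unique(taxonomy$species_id[duplicated(taxonomy$species_id)]),
               collapse = ", "))
  # tree consistency: each (rank, value) must sit under a single parent path
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(taxonomy))) {
    path <- character()
    for (rk in TAXONOMIC_RANKS) {
      v <- taxonomy[[rk]][i]
      if (is.na(v) || !nzchar(v)) next
      key <- paste(rk, v, sep = "\r")
      parent <- paste(path, collapse = "\r")
      prev <- get0(key, envir = seen)
      if (is.null(prev)) {
        assign(key, parent, envir = seen)
      } else if (!identical(prev, parent)) {
        stop("inconsistent taxonomy: ", rk, " '", v,
             "' appears under two different parents")
      }
      path <- c(path, v)
    }
  }
  taxonomy
}

# classification path of one species: non-missing rank values, broad to fine
taxon_path <- function(taxonomy, species) {
  i <- match(species, taxonomy$species_id)
  if (is.na(i)) stop("species absent from taxonomy: ", species)
  vals <- vapply(TAXONOMIC_RANKS, function(rk) {
    v <- taxonomy[[rk]][i]
    if (is.null(v) || is.na(v) || !nzchar(as.character(v))) NA_character_
    else paste(rk, v, sep = "\r")
  }, character(1))
  vals[!is.na(vals)]
}

#' Taxonomic step distance between two species
#'
#' The number of taxon nodes on the classification-tree path between two
#' species: the lowest common taxon, counted once, plus every rank node
#' below it on both descents down to (but excluding) the species tips.
#' Ranks absent from a species' classification contribute no node. Two
#' species sharing everything down to the subgenus are 1 step apart (only
#' the subgenus node lies between them); species of different orders with
#' seven classified internal ranks each are 1 + 7 + 7 = 15 steps apart.
#' A species compared with itself has distance 0.
#'
#' @param species_a,species_b species ids present in the taxonomy.
#' @param taxonomy a validated taxonomy table (see [read_taxonomy()]).
#' @return nonnegative integer step count.
#' @export
taxonomic_distance <- function(species_a, species_b, taxonomy) {
  if (identical(species_a, species_b)) return(0L)
  pa <- taxon_path(taxonomy, species_a)
  pb <- taxon_path(taxonomy, species_b)
  k <- 0L
  while (k < length(pa) && k < length(pb) && pa[k + 1L] == pb[k + 1L])
    k <- k + 1L
  # 1 node for the lowest common taxon (the root pool if k = 0), plus the
  # remaining internal nodes on each descent
  1L + (length(pa) - k) + (length(pb) - k)
}

#' Pairwise taxonomic distance matrix
#'
#' @param taxonomy a validated taxonomy table.
#' @param species optional subset/order of species ids; defaults to all
#'   species in the taxonomy.
#' @return a symmetric integer matrix with zero diagonal, dimnames =
#'   species ids.
#' @export
distance_matrix <- function(taxonomy, species = NULL) {
  taxonomy <- validate_taxonomy(taxonomy)
  if (is.null(species)) species <- taxonomy$species_id
  n <- length(species)
  paths <- lapply(species, function(s) taxon_path(taxonomy, s))
  d <- matrix(0L, n, n, dimnames = list(species, species))
  for (i in seq_len(n - 1)) {
    pa <- paths[[i]]
    for (j in (i + 1):n) {
      pb <- paths[[j]]
      k <- 0L
      while (k < length(pa) && k < length(pb) && pa[k + 1L] == pb[k + 1L])
        k <- k + 1L
      d[i, j] <- d[j, i] <- 1L + (length(pa) - k) + (length(pb) - k)
    }
  }
  d
}

#' Mean pairwise taxonomic distance of a community
#'
#' @param community character vector of >= 2 species ids.
#' @param dmatrix a distance matrix from [distance_matrix()].
#' @return mean distance over all unordered pairs; communities of fewer
#'   than 2 species are an error (use [nri()] for the per-site workflow,
#'   which flags such sites instead).
#' @export
mpd <- function(community, dmatrix) {
  community <- unique(as.character(community))
  if (length(community) < 2) stop("MPD requires a community of >= 2 species")
  miss <- setdiff(community, rownames(dmatrix))
  if (length(miss)) stop("species absent from distance matrix: ",
                         paste(miss, collapse = ", "))
  sub <- dmatrix[community, community]
  mean(sub[upper.tri(sub)])
}

#' Net relatedness index (NRI) of a community
#'
#' Standardized effect size of the community's mean pairwise taxonomic
#' distance (MPD) against richness-matched random draws from the species
#' pool: NRI = (MPD_obs - mean_null)/SD_null. The SES sign is kept as is
#' (no negative complement), so NRI increases with decreasing relatedness:
#' positive values indicate taxonomic overdispersion, negative values
#' clustering. Null communities are equiprobable draws without replacement.
#'
#' @param community species present at one site (>= 2 of them).
#' @param pool the species pool to draw null communities from (a strict
#'   superset of the community; typically all species of the analysed
#'   matrix).
#' @param dmatrix taxonomic distance matrix covering the pool.
#' @param reps number of null draws (default 1000).
#' @param seed optional integer seed.
#' @return an object of class `nri_result`: `richness`, `mpd_obs`,
#'   `null_mean`, `null_sd`, `nri`, `p_lower`, `p_upper`. For communities
#'   of fewer than 2 species, or zero null variance, `nri` is NA with
#'   reason recorded.
#' @export
nri <- function(community, pool, dmatrix, reps = 1000, seed = NULL) {
  community <- unique(as.character(community))
  pool <- unique(as.character(pool))
  if (!all(community %in% pool)) stop("community must be a subset of the pool")
  if (length(community) < 2) {
    return(structure(list(richness = length(community), mpd_obs = NA_real_,
                          null_mean = NA_real_, null_sd = NA_real_,
                          nri = NA_real_, p_lower = NA_real_,
                          p_upper = NA_real_, reps = reps,
                          reason = "richness < 2"),
                     class = "nri_result"))
  }
  if (length(pool) <= length(community))
    stop("pool must be larger than the community")
  if (!is.null(seed)) set.seed(seed)
  k <- length(community)
  obs <- mpd(community, dmatrix)
  pd <- dmatrix[pool, pool]
  npairs <- k * (k - 1) / 2
  null_mpd <- vapply(seq_len(reps), function(i) {
    idx <- sample.int(length(pool), k)
    sub <- pd[idx, idx]
    sum(sub[upper.tri(sub)]) / npairs
  }, numeric(1))
  s <- ses(obs, null_mpd)
  structure(list(richness = k, mpd_obs = obs,
                 null_mean = s$null_mean, null_sd = s$null_sd,
                 nri = s$ses, p_lower = s$p_lower, p_upper = s$p_upper,
                 reps = reps,
                 reason = if (is.na(s$ses)) "zero null variance" else NA_character_),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat("Net relatedness index (richness", x$richness, ")\n")
  if (is.na(x$nri)) {
    cat("NRI undefined:", x$reason, "\n")
  } else {
    cat(sprintf("MPD_obs = %.3f, null %.3f (SD %.3f), NRI = %.3f\n",
                x$mpd_obs, x$null_mean, x$null_sd, x$nri))
    cat(sprintf("p_lower = %.4g, p_upper = %.4g (%d draws)\n",
                x$p_lower, x$p_upper, x$reps))
  }
  invisible(x)
}

#' Per-site NRI table for a whole incidence matrix
#'
#' Computes [nri()] for every site with richness >= 2, using all species of
#' the matrix as the pool.
#'
#' @param m an incidence matrix.
#' @param dmatrix taxonomic distance matrix covering the matrix's species.
#' @param reps,seed passed to [nri()].
#' @return a data.frame with one row per site: `site_id`, `richness`,
#'   `mpd_obs`, `nri`, `p_lower`, `p_upper` (NA rows for richness < 2).
#' @export
nri_table <- function(m, dmatrix, reps = 1000, seed = NULL) {
  m <- as_incidence(m)
  if (!is.null(seed)) set.seed(seed)
  pool <- rownames(m)
  rows <- lapply(colnames(m), function(site) {
    comm <- pool[unclass(m)[, site] == 1L]
    if (length(comm) >= 2 && length(comm) < length(pool)) {
      r <- nri(comm, pool, dmatrix, reps = reps)
      data.frame(site_id = site, richness = r$richness, mpd_obs = r$mpd_obs,
                 nri = r$nri, p_lower = r$p_lower, p_upper = r$p_upper,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(site_id = site, richness = length(comm), mpd_obs = NA_real_,
                 nri = NA_real_, p_lower = NA_real_, p_upper = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
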