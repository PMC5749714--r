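#' Construct an incidence (presence-absence) matrix
#'
#' An incidence matrix is a binary species-by-site table: rows are species,
#' columns are sites (caves), and a 1 records that the species was found in
#' the site. Row totals give species occupancy, column totals give site
#' richness, and the grand total is the matrix fill.
#'
#' @param x a numeric matrix (or object coercible to one) of 0/1 entries or
#'   nonnegative counts. Counts are binarized: any value > 0 becomes 1.
#' @param species_ids optional character vector of species labels; defaults
#'   to existing rownames or `sp1, sp2, ...`.
#' @param site_ids optional character vector of site labels; defaults to
#'   existing colnames or `site1, site2, ...`.
#'
#' @return an object of class `incidence_matrix`: an integer 0/1 matrix with
#'   unique dimnames.
#' @examples
#' m <- incidence_matrix(matrix(c(1, 0, 2, 0, 1, 1), nrow = 2))
#' matrix_fill(m)
#' @export
incidence_matrix <- function(x, species_ids = NULL, site_ids = NULL) {
  x <- as.matrix(x)
  if (length(x) == 0L) stop("incidence matrix must be non-empty")
  if (!is.numeric(x)) stop("incidence matrix entries must be numeric")
  if (anyNA(x)) stop("incidence matrix contains missing values")
  if (any(x < 0)) stop("incidence matrix entries must be nonnegative")
  m <- matrix(as.integer(x > 0), nrow = nrow(x))
  if (is.null(species_ids)) {
    species_ids <- rownames(x)
    if (is.null(species_ids)) species_ids <- paste0("sp", seq_len(nrow(m)))
  }
  if (is.null(site_ids)) {
    site_ids <- colnames(x)
    if (is.null(site_ids)) site_ids <- paste0("site", seq_len(ncol(m)))
  }
  species_ids <- as.character(species_ids)
  site_ids <- as.character(site_ids)
  if (length(species_ids) != nrow(m)) stop("species_ids length must match row count")
  if (length(site_ids) != ncol(m)) stop("site_ids length must match column count")
  if (anyDuplicated(species_ids))
    stop("duplicate species labels: ",
         paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "))
  if (anyDuplicated(site_ids))
    stop("duplicate site labels: ",
         paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  dimnames(m) <- list(species_ids, site_ids)
  class(m) <- c("incidence_matrix", class(m))
  m
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("Incidence matrix:", nrow(x), "species x", ncol(x), "sites\n")
  f <- sum(x)
  cat("Fill:", f, sprintf("(%.1f%% of cells)\n", 100 * f / length(x)))
  cat("Site richness: median", stats::median(colSums(unclass(x))),
      "range", min(colSums(unclass(x))), "-", max(colSums(unclass(x))), "\n")
  invisible(x)
}

#' Marginal totals and fill of an incidence matrix
#'
#' `species_occupancy()` returns the row totals r_i (number of sites each
#' species occupies), `site_richness_counts()` the column totals c_j (number
#' of species per site), and `matrix_fill()` the total number of occurrences F.
#'
#' @param m an incidence matrix (binary matrix; coerced via
#'   [incidence_matrix()] if not already one).
#' @return a named integer vector (occupancy, richness) or a single integer
#'   (fill).
#' @export
species_occupancy <- function(m) {
  m <- as_incidence(m)
  rowSums(unclass(m))
}

#' @rdname species_occupancy
#' @export
site_richness_counts <- function(m) {
  m <- as_incidence(m)
  colSums(unclass(m))
}

#' @rdname species_occupancy
#' @export
matrix_fill <- function(m) {
  m <- as_incidence(m)
  sum(unclass(m))
}

# coerce without re-labelling when already validated
as_incidence <- function(m) {
  if (inherits(m, "incidence_matrix")) return(m)
  incidence_matrix(m)
}

#' Read an incidence matrix from a delimited text file
#'
#' The file layout is: first row = site ids, first column = species ids
#' (or the transpose, with `species_as_rows = FALSE`). Cells must parse to
#' nonnegative numbers; counts are binarized (> 0 becomes 1).
#'
#' @param path path to a comma- or tab-delimited text file.
#' @param species_as_rows logical; if `FALSE` the file stores sites as rows
#'   and is transposed on read.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return an [incidence_matrix()].
#' @export
read_incidence_matrix <- function(path, species_as_rows = TRUE, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "")
  x <- as.matrix(df)
  suppressWarnings(vals <- as.numeric(x))
  if (anyNA(vals)) {
    bad <- which(is.na(matrix(vals, nrow(x))), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at row '", rownames(df)[bad[1]],
         "', column '", colnames(df)[bad[2]], "'")
  }
  m <- matrix(vals, nrow = nrow(x), dimnames = dimnames(x))
  if (!species_as_rows) m <- t(m)
  incidence_matrix(m)
}

#' Write an incidence matrix to a delimited text file
#'
#' Inverse of [read_incidence_matrix()]: first row holds site ids, first
#' column species ids. Reading the file back reproduces entries, row order
#' and labels exactly.
#'
#' @param m an incidence matrix.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @export
write_incidence_matrix <- function(m, path, sep = "\t") {
  m <- as_incidence(m)
  df <- data.frame(species_id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Sampling-intensity class from the number of cave visits
#'
#' Caves are classified by survey effort into four classes: 1-3 visits ->
#' class 1 (less sampled), 4-6 -> 2, 7-9 -> 3, 10-12 -> 4 (very highly
#' sampled). Visit counts outside 1-12 are rejected rather than clamped,
#' since the classification is defined only on that range.
#'
#' @param visits integer vector of visit counts (1-12).
#' @return integer vector of classes 1-4.
#' @examples
#' assign_sampling_class(c(2, 5, 11))
#' @export
assign_sampling_class <- function(visits) {
  if (anyNA(visits) || any(visits != as.integer(visits)))
    stop("visits must be whole numbers")
  if (any(visits < 1) || any(visits > 12))
    stop("visits outside the defined range 1-12: ",
         paste(visits[visits < 1 | visits > 12], collapse = ", "))
  as.integer((visits - 1) %/% 3L + 1L)
}

#' Read cave metadata
#'
#' Expects a delimited text file with header columns `site_id, longitude,
#' latitude, length_m, depth_m, altitude_m, visits`. Missing length, depth
#' or altitude values are permitted (empty cells or NA); coordinates and
#' visits must be present. A `sampling_class` column is derived from visits.
#'
#' @param path path to a delimited text file (comma or tab, auto-detected).
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab.
#' @return a data.frame of cave records.
#' @export
read_cave_metadata <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_cave_metadata(df)
}

#' @rdname read_cave_metadata
#' @param df a data.frame to validate in place of a file.
#' @export
validate_cave_metadata <- function(df) {
  needed <- c("site_id", "longitude", "latitude", "visits")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("metadata lacks required columns: ", paste(missing_cols, collapse = ", "))
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id))
    stop("duplicate site ids in metadata: ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE) ||
      any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE))
    stop("coordinates outside plausible bounds")
  if (!is.null(df$length_m) && any(df$length_m <= 0, na.rm = TRUE))
    stop("cave length must be positive")
  if (!is.null(df$depth_m) && any(df$depth_m < 0, na.rm = TRUE))
    stop("cave depth must be nonnegative")
  df$sampling_class <- assign_sampling_class(df$visits)
  df
}

#' Restrict an incidence matrix to sufficiently surveyed sites
#'
#' Drops sites surveyed fewer than `min_visits` times (the survey-effort
#' exclusion rule), then drops species left with zero occurrences; the
#' dropped species are reported via an attribute and a message.
#'
#' @param m an incidence matrix.
#' @param metadata cave metadata with `site_id` and `visits` (every site of
#'   `m` must have a record).
#' @param min_visits minimum number of visits to retain a site (default 3).
#' @return the filtered incidence matrix; attribute `"dropped_species"`
#'   lists species removed because filtering emptied their rows.
#' @export
filter_by_visits <- function(m, metadata, min_visits = 3) {
  m <- as_incidence(m)
  metadata$site_id <- as.character(metadata$site_id)
  missing_sites <- setdiff(colnames(m), metadata$site_id)
  if (length(missing_sites))
    stop("no metadata for sites: ", paste(missing_sites, collapse = ", "))
  visits <- metadata$visits[match(colnames(m), metadata$site_id)]
  keep_sites <- visits >= min_visits
  if (!any(keep_sites)) stop("no site has visits >= ", min_visits)
  sub <- unclass(m)[, keep_sites, drop = FALSE]
  empty <- rowSums(sub) == 0
  dropped <- rownames(sub)[empty]
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " species with no occurrence in retained sites: ",
            paste(dropped, collapse = ", "))
    sub <- sub[!empty, , drop = FALSE]
  }
  out <- incidence_matrix(sub)
  attr(out, "dropped_species") <- dropped
  out
}

#' Cross-validate an incidence matrix against its companion tables
#'
#' Report-only consistency check: lists species/sites present in one table
#' but absent from another (orphans in each direction). Never raises an
#' error; an empty `issues` list means the bundle is consistent.
#'
#' @param m an incidence matrix.
#' @param metadata optional cave metadata data.frame (`site_id` column).
#' @param taxonomy optional taxonomy table (`species_id` column).
#' @param traits optional trait table (`species_id` column).
#' @return an object of class `dataset_validation` with elements `issues`
#'   (character vector) and `ok` (logical).
#' @export
validate_dataset <- function(m, metadata = NULL, taxonomy = NULL, traits = NULL) {
  m <- as_incidence(m)
  issues <- character()
  orphan <- function(found, expected, what, where) {
    miss <- setdiff(expected, found)
    if (length(miss))
      sprintf("%s missing from %s: %s", what, where, paste(miss, collapse = ", "))
    else character()
  }
  if (!is.null(metadata)) {
    ids <- as.character(metadata$site_id)
    issues <- c(issues,
                orphan(ids, colnames(m), "sites", "metadata"),
                orphan(colnames(m), ids, "metadata sites", "incidence matrix"))
  }
  for (nm in c("taxonomy", "traits")) {
    tab <- switch(nm, taxonomy = taxonomy, traits = traits)
    if (is.null(tab)) next
    ids <- as.character(tab$species_id)
    issues <- c(issues,
                orphan(ids, rownames(m), "species", nm),
                orphan(rownames(m), ids, paste(nm, "species"), "incidence matrix"))
  }
  structure(list(issues = issues, ok = length(issues) == 0L),
            class = "dataset_validation")
}

#' @export
print.dataset_validation <- function(x, ...) {
  if (x$ok) {
    cat("Dataset consistent: no issues found\n")
  } else {
    cat("Dataset validation found", length(x$issues), "issue(s):\n")
    for (i in x$issues) cat(" -", i, "\n")
  }
  invisible(x)
}
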