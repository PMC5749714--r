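#' Checkerboard units for a species pair
#'
#' The number of checkerboard units between species a and b is
#' CU = (r_a - S)(r_b - S), where r are the species' occupancies and S the
#' number of jointly occupied sites. CU equals the number of 2x2 submatrices
#' of the form {{1,0},{0,1}} or {{0,1},{1,0}} that the pair forms across
#' sites; it is zero exactly when one species' sites contain the other's.
#'
#' @param m an incidence matrix.
#' @param species_a,species_b species labels (or row indices).
#' @return the checkerboard-unit count (nonnegative integer).
#' @examples
#' m <- incidence_matrix(rbind(a = c(1, 1, 0, 0), b = c(0, 1, 1, 0)))
#' checkerboard_units(m, "a", "b")
#' @export
checkerboard_units <- function(m, species_a, species_b) {
  m <- as_incidence(m)
  idx <- function(s) {
    if (is.character(s)) {
      i <- match(s, rownames(m))
      if (is.na(i)) stop("unknown species label: ", s)
      i
    } else as.integer(s)
  }
  a <- unclass(m)[idx(species_a), ]
  b <- unclass(m)[idx(species_b), ]
  s <- sum(a & b)
  (sum(a) - s) * (sum(b) - s)
}

# full species x species checkerboard-unit matrix (upper triangle meaningful)
pair_cu_matrix <- function(m) {
  mm <- unclass(m)
  r <- rowSums(mm)
  s <- tcrossprod(mm)
  (matrix(r, nrow(mm), nrow(mm)) - s) *
    (matrix(r, nrow(mm), nrow(mm), byrow = TRUE) - s)
}

#' Matrix-wide C-score
#'
#' The C-score is the mean number of checkerboard units over all unordered
#' species pairs; larger values indicate stronger segregation (negative
#' co-occurrence) among species.
#'
#' @param m an incidence matrix with at least two species.
#' @return the mean checkerboard-unit count per species pair.
#' @examples
#' c_score(diag(2))  # the 2x2 checkerboard: 1
#' @export
c_score <- function(m) {
  m <- as_incidence(m)
  n <- nrow(m)
  if (n < 2) stop("C-score requires at least 2 species")
  cu <- pair_cu_matrix(m)
  sum(cu[upper.tri(cu)]) / (n * (n - 1) / 2)
}

#' NODF nestedness metric
#'
#' Nestedness by Overlap and Decreasing Fill, on a 0-100 scale. For every
#' unordered pair of rows whose totals differ, the paired nestedness is
#' 100 x (shared sites)/(smaller row total); pairs with equal totals (no
#' "decreasing fill") contribute 0. The same is computed over column pairs
#' with column totals, and NODF is the grand sum divided by the number of
#' row pairs plus column pairs. Because the richer member of each pair is
#' decided by marginal totals, not physical position, the score is invariant
#' to row and column permutations.
#'
#' @param m an incidence matrix with at least 2 rows and 2 columns.
#' @return NODF score in [0, 100].
#' @export
nodf <- function(m) {
  m <- as_incidence(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("NODF requires at least a 2x2 matrix")
  if (sum(m) == 0) stop("NODF undefined for an empty matrix")
  paired_sum <- function(x) {
    tot <- rowSums(x)
    s <- tcrossprod(x)
    n <- nrow(x)
    ti <- matrix(tot, n, n)
    tj <- t(ti)
    lo <- pmin(ti, tj)
    contrib <- ifelse(ti != tj & lo > 0, 100 * s / pmax(lo, 1e-12), 0)
    sum(contrib[upper.tri(contrib)])
  }
  mm <- unclass(m)
  nr <- nrow(mm); nc <- ncol(mm)
  (paired_sum(mm) + paired_sum(t(mm))) /
    (nr * (nr - 1) / 2 + nc * (nc - 1) / 2)
}

#' Pairwise C-scores with standardized effect sizes from a null ensemble
#'
#' Computes, for every unordered species pair, the observed checkerboard
#' units and the pair's null distribution across the ensemble, returning
#' the standardized effect size SES = (Obs - Exp)/StDev_Exp and empirical
#' tail probabilities with the add-one rule. Pairs whose null distribution
#' has zero variance are flagged (SES = NA); their tail probabilities are
#' still reported.
#'
#' @param m the observed incidence matrix.
#' @param ensemble a [null_ensemble()] built from the same matrix.
#' @return a data.frame of class `pair_cooccurrence` with columns
#'   `species_a`, `species_b`, `shared`, `cu`, `null_mean`, `null_sd`,
#'   `ses`, `p_lower`, `p_upper`.
#' @export
pairwise_c_scores <- function(m, ensemble) {
  m <- as_incidence(m)
  if (!inherits(ensemble, "null_ensemble")) stop("ensemble must be a null_ensemble")
  if (!identical(dim(ensemble$matrices[[1]]), dim(unclass(m))) ||
      !identical(rownames(ensemble$matrices[[1]]), rownames(m)))
    stop("ensemble does not match the matrix (dimensions or species set differ)")
  n <- nrow(m)
  if (n < 2) stop("need at least 2 species")
  up <- upper.tri(matrix(0, n, n))
  obs_cu <- pair_cu_matrix(m)[up]
  shared <- tcrossprod(unclass(m))[up]
  reps <- length(ensemble$matrices)
  null_cu <- vapply(ensemble$matrices,
                    function(x) pair_cu_matrix(x)[up],
                    numeric(sum(up)))
  if (is.null(dim(null_cu))) null_cu <- matrix(null_cu, nrow = 1)
  mu <- rowMeans(null_cu)
  sdv <- apply(null_cu, 1, stats::sd)
  ses <- ifelse(sdv > 0, (obs_cu - mu) / sdv, NA_real_)
  p_up <- (rowSums(null_cu >= obs_cu) + 1) / (reps + 1)
  p_lo <- (rowSums(null_cu <= obs_cu) + 1) / (reps + 1)
  ij <- which(up, arr.ind = TRUE)
  out <- data.frame(species_a = rownames(m)[ij[, 1]],
                    species_b = rownames(m)[ij[, 2]],
                    shared = shared,
                    cu = obs_cu,
                    null_mean = mu,
                    null_sd = sdv,
                    ses = ses,
                    p_lower = p_lo,
                    p_upper = p_up,
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_cooccurrence", class(out))
  out
}
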