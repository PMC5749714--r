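# Null-model randomization engines for binary incidence matrices.
#
# All engines conserve the total fill F exactly. EE and PP redistribute
# occurrences over cells (equiprobably / proportionally to row x column
# totals); FF conserves row and column totals exactly via checkerboard
# swaps. Degenerate outputs (empty row or column) are excluded by
# whole-matrix rejection sampling so downstream metrics (NODF, species
# pools) stay well defined.

MAX_REJECTIONS <- 10000L

new_null_matrix <- function(entries, template) {
  dimnames(entries) <- dimnames(template)
  storage.mode(entries) <- "integer"
  entries
}

no_degenerate <- function(x) all(rowSums(x) > 0) && all(colSums(x) > 0)

#' Equiprobable (EE) randomization
#'
#' Places the observed number of occurrences F uniformly at random among
#' the cells of a matrix with the observed dimensions, resampling until no
#' row or column is empty. Every species and every site is treated as
#' equivalent: the null of a community with no differences in colonisation
#' probability or site capacity.
#'
#' @param m an incidence matrix.
#' @param seed optional integer seed.
#' @param condition if TRUE (default), resample whole matrices until no
#'   row or column is empty (capped rejection sampling). For very sparse
#'   matrices — many species with a single occurrence — the conditional
#'   distribution is practically unsamplable and `condition = FALSE`
#'   yields the plain unconstrained null.
#' @return a randomized binary matrix with the same dimensions and fill.
#' @export
randomize_ee <- function(m, seed = NULL, condition = TRUE) {
  m <- as_incidence(m)
  if (!is.null(seed)) set.seed(seed)
  f <- matrix_fill(m)
  nr <- nrow(m); nc <- ncol(m)
  if (condition && f < max(nr, nc))
    stop("fill ", f, " cannot avoid empty rows/columns in a ",
         nr, "x", nc, " matrix")
  for (i in seq_len(MAX_REJECTIONS)) {
    out <- matrix(0L, nr, nc)
    out[sample.int(nr * nc, f)] <- 1L
    if (!condition || no_degenerate(out)) return(new_null_matrix(out, m))
  }
  stop("could not draw a matrix without empty rows/columns in ",
       MAX_REJECTIONS, " attempts")
}

#' Proportional (PP) randomization
#'
#' Places F occurrences by sequential draws without replacement with cell
#' selection probability proportional to r_i x c_j (observed row total
#' times column total, renormalized over unoccupied cells after each draw),
#' resampling whole matrices until no row or column is empty. This is the
#' drift null: colonisation probability follows regional occupancy and site
#' capacity, with no further structure.
#'
#' @inheritParams randomize_ee
#' @return a randomized binary matrix with the same dimensions and fill.
#' @export
randomize_pp <- function(m, seed = NULL, condition = TRUE) {
  m <- as_incidence(m)
  if (!is.null(seed)) set.seed(seed)
  f <- matrix_fill(m)
  nr <- nrow(m); nc <- ncol(m)
  if (condition && f < max(nr, nc))
    stop("fill ", f, " cannot avoid empty rows/columns in a ",
         nr, "x", nc, " matrix")
  w <- as.vector(outer(species_occupancy(m), site_richness_counts(m)))
  for (i in seq_len(MAX_REJECTIONS)) {
    out <- matrix(0L, nr, nc)
    out[sample.int(nr * nc, f, prob = w)] <- 1L
    if (!condition || no_degenerate(out)) return(new_null_matrix(out, m))
  }
  stop("could not draw a matrix without empty rows/columns in ",
       MAX_REJECTIONS, " attempts")
}

#' Fixed-fixed (FF) randomization by checkerboard swaps
#'
#' Sequential swap algorithm: repeatedly picks a random pair of rows, finds
#' the columns where they form a 2x2 checkerboard ({{1,0},{0,1}} or
#' {{0,1},{1,0}}), and flips one such submatrix. Row and column totals are
#' preserved exactly at every step. If the matrix admits no swappable
#' submatrix the input is returned with a warning.
#'
#' @inheritParams randomize_ee
#' @param n_swaps number of successful swaps to perform.
#' @return a binary matrix with identical row and column totals.
#' @export
randomize_ff <- function(m, n_swaps = NULL, seed = NULL) {
  m <- as_incidence(m)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_swaps)) n_swaps <- 10L * matrix_fill(m)
  out <- unclass(m)
  storage.mode(out) <- "integer"
  done <- ff_swaps(out, n_swaps)
  if (attr(done, "swaps") == 0L && n_swaps > 0L)
    warning("no swappable checkerboard submatrix found; matrix returned unchanged")
  attr(done, "swaps") <- NULL
  new_null_matrix(done, m)
}

# perform up to n successful checkerboard swaps in place; gives up after a
# long run of failed attempts (matrix without any checkerboard)
ff_swaps <- function(x, n) {
  nr <- nrow(x)
  swaps <- 0L
  failed <- 0L
  max_failed <- max(10000L, 100L * nr)
  while (swaps < n && failed < max_failed) {
    rows <- sample.int(nr, 2L)
    a <- x[rows[1L], ]; b <- x[rows[2L], ]
    ca <- which(a == 1L & b == 0L)
    cb <- which(a == 0L & b == 1L)
    if (length(ca) && length(cb)) {
      j1 <- if (length(ca) == 1L) ca else sample(ca, 1L)
      j2 <- if (length(cb) == 1L) cb else sample(cb, 1L)
      x[rows[1L], c(j1, j2)] <- c(0L, 1L)
      x[rows[2L], c(j1, j2)] <- c(1L, 0L)
      swaps <- swaps + 1L
      failed <- 0L
    } else {
      failed <- failed + 1L
    }
  }
  attr(x, "swaps") <- swaps
  x
}

#' Build an ensemble of randomized matrices
#'
#' Generates `reps` randomizations of `m` under one null model. The default
#' of 200 replicates is the standard ensemble size for the co-occurrence
#' tests in this package. Given the same (seed, model, reps) the ensemble
#' is fully reproducible. Under FF the ensemble is a thinned Markov chain:
#' a burn-in of `burn_in` successful swaps, then one saved matrix every
#' `thin` swaps.
#'
#' @param m an incidence matrix.
#' @param model one of `"EE"`, `"PP"`, `"FF"`.
#' @param reps number of null matrices (default 200).
#' @param seed optional integer seed.
#' @param burn_in,thin FF chain controls; defaults 10 x fill and fill.
#' @param condition passed to the EE/PP randomizers (see
#'   [randomize_ee()]); ignored for FF, which conserves marginals exactly.
#' @return an object of class `null_ensemble` with elements `model`,
#'   `reps`, `seed` and `matrices` (a list of binary matrices).
#' @export
build_ensemble <- function(m, model = c("EE", "PP", "FF"), reps = 200,
                           seed = NULL, burn_in = NULL, thin = NULL,
                           condition = TRUE) {
  m <- as_incidence(m)
  model <- match.arg(model)
  if (reps < 1) stop("reps must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  f <- matrix_fill(m)
  mats <- if (model == "FF") {
    if (is.null(burn_in)) burn_in <- 10L * f
    if (is.null(thin)) thin <- f
    x <- unclass(m)
    storage.mode(x) <- "integer"
    x <- ff_swaps(x, burn_in)
    if (attr(x, "swaps") == 0L)
      warning("no swappable checkerboard submatrix found; FF ensemble is degenerate")
    attr(x, "swaps") <- NULL
    lapply(seq_len(reps), function(i) {
      x <<- ff_swaps(x, thin)
      attr(x, "swaps") <- NULL
      new_null_matrix(x, m)
    })
  } else {
    randomizer <- switch(model, EE = randomize_ee, PP = randomize_pp)
    lapply(seq_len(reps), function(i) randomizer(m, condition = condition))
  }
  structure(list(model = model, reps = reps, seed = seed, matrices = mats),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  d <- dim(x$matrices[[1]])
  cat("Null ensemble:", x$reps, x$model, "randomizations of a",
      d[1], "x", d[2], "matrix\n")
  if (!is.null(x$seed)) cat("Seed:", x$seed, "\n")
  invisible(x)
}

#' Standardized effect size against a null distribution
#'
#' SES = (Obs - Exp)/StDev_Exp, where Exp and StDev_Exp are the mean and
#' sample standard deviation (n - 1 denominator) of the metric over the
#' null ensemble. Under an approximately normal null, |SES| > 1.96 flags a
#' two-sided 5% deviation. Empirical tail probabilities use the add-one
#' rule p_upper = (#{null >= Obs} + 1)/(reps + 1) (and analogously for the
#' lower tail), so p = 0 never occurs. If the null values have zero
#' variance the SES is undefined (NA) but the tail probabilities are still
#' returned.
#'
#' @param observed observed metric value.
#' @param null_values numeric vector of the metric on >= 2 null matrices.
#' @return an object of class `ses_result` with elements `observed`,
#'   `null_mean`, `null_sd`, `ses`, `p_lower`, `p_upper`, `reps`.
#' @export
ses <- function(observed, null_values) {
  null_values <- null_values[!is.na(null_values)]
  reps <- length(null_values)
  if (reps < 2) stop("need at least 2 null values")
  mu <- mean(null_values)
  sdv <- stats::sd(null_values)
  structure(list(observed = observed,
                 null_mean = mu,
                 null_sd = sdv,
                 ses = if (sdv > 0) (observed - mu) / sdv else NA_real_,
                 p_lower = (sum(null_values <= observed) + 1) / (reps + 1),
                 p_upper = (sum(null_values >= observed) + 1) / (reps + 1),
                 reps = reps),
            class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  cat(sprintf("Obs = %.4f, Exp = %.4f (SD %.4f), %d null values\n",
              x$observed, x$null_mean, x$null_sd, x$reps))
  if (is.na(x$ses)) {
    cat("SES undefined (zero null variance)\n")
  } else {
    cat(sprintf("SES = %.3f  (p_lower = %.4g, p_upper = %.4g)\n",
                x$ses, x$p_lower, x$p_upper))
  }
  invisible(x)
}

#' Null-model test of a matrix-level co-occurrence metric
#'
#' Convenience wrapper: computes a metric on the observed matrix and on a
#' freshly built null ensemble, and returns its standardized effect size.
#'
#' @param m an incidence matrix.
#' @param statistic `"cscore"` (segregation) or `"nodf"` (nestedness), or
#'   any function of a binary matrix returning a scalar.
#' @param model null model passed to [build_ensemble()].
#' @param reps,seed,... passed to [build_ensemble()].
#' @return a [ses()] result with attribute `"statistic"`.
#' @examples
#' m <- gen_random_matrix(15, 12, fill = 60, seed = 7)
#' null_model_test(m, "cscore", model = "EE", reps = 50, seed = 7)
#' @export
null_model_test <- function(m, statistic = c("cscore", "nodf"),
                            model = c("EE", "PP", "FF"), reps = 200,
                            seed = NULL, ...) {
  m <- as_incidence(m)
  stat_fun <- if (is.function(statistic)) {
    statistic
  } else {
    switch(match.arg(statistic), cscore = c_score, nodf = nodf)
  }
  stat_name <- if (is.function(statistic)) "custom" else match.arg(statistic)
  ens <- build_ensemble(m, model = model, reps = reps, seed = seed, ...)
  out <- ses(stat_fun(m), vapply(ens$matrices, stat_fun, numeric(1)))
  attr(out, "statistic") <- stat_name
  attr(out, "model") <- ens$model
  out
}
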