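#' Per-site species richness and its summary
#'
#' @param m an incidence matrix.
#' @return a list with `richness` (named per-site counts) and `summary`
#'   (mean, median, min, max).
#' @export
site_richness <- function(m) {
  m <- as_incidence(m)
  r <- site_richness_counts(m)
  list(richness = r,
       summary = c(mean = mean(r), median = stats::median(r),
                   min = min(r), max = max(r)))
}

#' Proportional species turnover (beta_P)
#'
#' beta_P = 1 - alpha/gamma, the proportion of the regional species pool
#' (gamma) absent from a local community of richness alpha. Computed per
#' site (beta_j = 1 - c_j/gamma) and averaged; the reported uncertainty is
#' the standard error of the per-site values, and the mean equals
#' 1 - mean(alpha)/gamma by linearity.
#'
#' @param m an incidence matrix.
#' @return a list with `mean`, `se`, the per-site values `beta_j`, `alpha`
#'   (mean per-site richness) and `gamma` (pool richness).
#' @examples
#' m <- gen_random_matrix(30, 20, fill = 120, seed = 1)
#' beta_p(m)$mean
#' @export
beta_p <- function(m) {
  m <- as_incidence(m)
  gamma <- nrow(m)
  cj <- site_richness_counts(m)
  beta_j <- 1 - cj / gamma
  list(mean = mean(beta_j),
       se = stats::sd(beta_j) / sqrt(length(beta_j)),
       beta_j = beta_j,
       alpha = mean(cj),
       gamma = gamma)
}

#' Occupancy, single-site endemics, and widespread species
#'
#' `occupancy()` returns the number of sites each species occupies.
#' `count_single_site_endemics()` counts species restricted to exactly one
#' site. `count_species_above_fraction()` counts species occupying strictly
#' more than `fraction` of the sites (strict inequality, so "more than half"
#' is `fraction = 0.5`).
#'
#' @param m an incidence matrix.
#' @param fraction a proportion in (0, 1).
#' @return named integer vector (occupancy) or a single count.
#' @export
occupancy <- function(m) species_occupancy(m)

#' @rdname occupancy
#' @export
count_single_site_endemics <- function(m) {
  sum(species_occupancy(m) == 1L)
}

#' @rdname occupancy
#' @export
count_species_above_fraction <- function(m, fraction) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  m <- as_incidence(m)
  sum(species_occupancy(m) > fraction * ncol(m))
}

#' Allometric richness scaling exponent
#'
#' Solves gamma = alpha * N^z for z, i.e. z = ln(gamma/alpha)/ln(N): the
#' exponent of the regional-to-local species-sample-size relationship.
#' Values above ~0.3 indicate strong turnover between isolated sites.
#'
#' @param gamma regional (pool) species richness.
#' @param alpha local (per-site) species richness; must not exceed gamma.
#' @param n_sites number of sites N (>= 2).
#' @return the dimensionless exponent z.
#' @examples
#' allometric_z(141, 4, 189)
#' @export
allometric_z <- function(gamma, alpha, n_sites) {
  if (alpha < 1 || gamma < alpha) stop("need gamma >= alpha >= 1")
  if (n_sites < 2) stop("need at least 2 sites")
  log(gamma / alpha) / log(n_sites)
}

#' Power-law fit of richness against a site covariate, with permutation test
#'
#' Ordinary least squares of ln(response) on ln(predictor) — the allometric
#' (power-law) model response = a * predictor^b. Significance of r-squared
#' is assessed by permuting the response across sites: p = (b + 1)/(n_perm
#' + 1) where b counts permutations with r-squared at least the observed.
#' Sites with missing predictor values are excluded pairwise.
#'
#' @param response positive per-site values (e.g. species richness).
#' @param predictor positive per-site covariate (e.g. cave length in m).
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed for the permutation stream.
#' @return an object of class `power_law_fit`: exponent, intercept (on the
#'   log scale), `r_squared`, `p_perm`, `n` (sites used).
#' @export
power_law_fit <- function(response, predictor, n_perm = 999, seed = NULL) {
  keep <- !is.na(response) & !is.na(predictor)
  response <- response[keep]
  predictor <- predictor[keep]
  if (length(response) < 3) stop("fewer than 3 usable sites")
  if (any(predictor <= 0)) stop("predictor must be positive at included sites")
  if (any(response <= 0)) stop("response must be positive at included sites")
  if (!is.null(seed)) set.seed(seed)
  ly <- log(response)
  lx <- log(predictor)
  fit <- stats::lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  r2_perm <- vapply(seq_len(n_perm), function(i) {
    summary(stats::lm(sample(ly) ~ lx))$r.squared
  }, numeric(1))
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 p_perm = (sum(r2_perm >= r2) + 1) / (n_perm + 1),
                 n = length(response),
                 n_perm = n_perm),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Power-law (log-log OLS) fit, n =", x$n, "sites\n")
  cat(sprintf("  exponent b = %.3f, r^2 = %.3f, permutation P = %.4g (%d perms)\n",
              x$exponent, x$r_squared, x$p_perm, x$n_perm))
  invisible(x)
}

#' Diversity summary of an incidence matrix
#'
#' Bundles the richness summary, beta_P, endemism counts and the allometric
#' exponent into one report object.
#'
#' @param m an incidence matrix.
#' @return an object of class `diversity_summary`.
#' @export
diversity_summary <- function(m) {
  m <- as_incidence(m)
  sr <- site_richness(m)
  bp <- beta_p(m)
  structure(list(
    gamma = nrow(m),
    n_sites = ncol(m),
    alpha_mean = unname(sr$summary["mean"]),
    alpha_median = unname(sr$summary["median"]),
    alpha_min = unname(sr$summary["min"]),
    alpha_max = unname(sr$summary["max"]),
    beta_p_mean = bp$mean,
    beta_p_se = bp$se,
    endemics = count_single_site_endemics(m),
    widespread_half = count_species_above_fraction(m, 0.5),
    z_slope = allometric_z(nrow(m), unname(sr$summary["mean"]), ncol(m))
  ), class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("Diversity summary:", x$gamma, "species x", x$n_sites, "sites\n")
  cat(sprintf("  alpha: mean %.2f, median %g, range %g-%g\n",
              x$alpha_mean, x$alpha_median, x$alpha_min, x$alpha_max))
  cat(sprintf("  beta_P = %.2f +/- %.2f\n", x$beta_p_mean, x$beta_p_se))
  cat(sprintf("  single-site endemics: %d (%.1f%%)\n",
              x$endemics, 100 * x$endemics / x$gamma))
  cat(sprintf("  species in > half the sites: %d\n", x$widespread_half))
  cat(sprintf("  allometric exponent z = %.2f\n", x$z_slope))
  invisible(x)
}
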