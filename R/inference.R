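#' Main-effects linear model with partial eta-squared
#'
#' Fits a least-squares model with main effects only and reports, per
#' term, the partial sum of squares (the term's increment over the model
#' without it — Type III for a main-effects model), partial eta-squared
#' = SS_term/(SS_term + SS_residual), the F-test p-value, and for
#' single-df terms the sign of the coefficient. Partial eta-squared is
#' invariant to affine rescaling of the response.
#'
#' @param formula a model formula with main effects (no interactions).
#' @param data a data.frame; rows with missing values in the model
#'   variables are dropped (pairwise to this model).
#' @return an object of class `glm_eta2` with a per-term `table`
#'   (data.frame: term, df, ss, eta2, sign, p, stars) and residual df/ss.
#' @examples
#' d <- data.frame(y = rnorm(50), x = rnorm(50))
#' glm_eta2(y ~ x, d)
#' @export
glm_eta2 <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  fit <- stats::lm(formula, data = mf)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  term_labels <- attr(stats::terms(fit), "term.labels")
  if (length(term_labels) == 0) stop("model has no terms")
  dr <- stats::drop1(fit, test = "F")
  ss_res <- stats::deviance(fit)
  df_res <- stats::df.residual(fit)
  rows <- dr[-1, , drop = FALSE]  # first row is <none>
  ss <- rows[["Sum of Sq"]]
  # guard a numerically zero-variance response: everything explains nothing
  y <- stats::model.response(mf)
  sst <- sum((y - mean(y))^2)
  eta2 <- if (sst < 1e-10 * max(1, mean(y)^2)) {
    rep(0, length(ss))
  } else {
    ifelse(ss + ss_res > 0, ss / (ss + ss_res), 0)
  }
  asg <- attr(stats::model.matrix(fit), "assign")
  sign_of <- vapply(seq_along(term_labels), function(k) {
    cols <- which(asg == k)
    if (length(cols) == 1L) {
      cf <- stats::coef(fit)[cols]
      if (cf > 0) "+" else if (cf < 0) "-" else "0"
    } else ""
  }, character(1))
  p <- rows[["Pr(>F)"]]
  structure(list(
    table = data.frame(term = term_labels,
                       df = rows[["Df"]],
                       ss = ss,
                       eta2 = eta2,
                       sign = sign_of,
                       p = p,
                       stars = p_stars(p),
                       stringsAsFactors = FALSE),
    ss_residual = ss_res,
    df_residual = df_res,
    n = nrow(mf),
    formula = formula,
    fit = fit
  ), class = "glm_eta2")
}

p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' @export
print.glm_eta2 <- function(x, ...) {
  cat("Main-effects linear model:", deparse(x$formula), "\n")
  cat("n =", x$n, " residual df =", x$df_residual, "\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    sgn <- if (nzchar(tab$sign[i])) paste0("(", tab$sign[i], ") ") else ""
    cat(sprintf("  %-18s %s%.3f%s  (P = %.4g)\n",
                tab$term[i], sgn, tab$eta2[i], tab$stars[i], tab$p[i]))
  }
  cat("  (partial eta^2; ** P < 0.01, *** P < 0.001)\n")
  invisible(x)
}

#' @export
summary.glm_eta2 <- function(object, ...) object$table

#' Pre-screen species pairs for significant co-occurrence deviations
#'
#' Keeps only pairs whose empirical tail probability falls below `alpha`
#' in either direction: `p_lower < alpha` tags a pair "aggregated" (fewer
#' checkerboards than the null), `p_upper < alpha` tags it "segregated".
#' Most species pairs do not interact, so downstream trait models are run
#' on this screened subset only.
#'
#' @param pairs a `pair_cooccurrence` data.frame from
#'   [pairwise_c_scores()].
#' @param alpha significance threshold (default 0.05).
#' @return the filtered data.frame with an added `direction` column.
#' @export
screen_significant_pairs <- function(pairs, alpha = 0.05) {
  if (!all(c("p_lower", "p_upper") %in% names(pairs)))
    stop("pairs must carry p_lower and p_upper columns")
  keep <- pairs$p_lower < alpha | pairs$p_upper < alpha
  out <- pairs[keep, , drop = FALSE]
  out$direction <- ifelse(out$p_upper < alpha & out$p_lower < alpha,
                          ifelse(out$p_upper <= out$p_lower,
                                 "segregated", "aggregated"),
                          ifelse(out$p_upper < alpha,
                                 "segregated", "aggregated"))
  rownames(out) <- NULL
  out
}

#' Trait-identity ANOVA on screened pair SES values
#'
#' For every retained species pair and every categorical trait, codes the
#' pair 1 if both species share the trait level and 0 otherwise, then fits
#' a main-effects ANOVA of the pair's C-score SES on these identity codes
#' and reports partial eta-squared per trait. Traits whose identity code
#' is constant across the pairs are dropped with a warning. Pairs with
#' undefined SES are excluded.
#'
#' @param pairs a (screened) `pair_cooccurrence` data.frame with `ses`.
#' @param traits a trait table: `species_id` plus one column per
#'   categorical trait.
#' @return a [glm_eta2()] object; its `table` has one row per usable
#'   trait.
#' @export
trait_identity_anova <- function(pairs, traits) {
  if (!"species_id" %in% names(traits))
    stop("traits must carry a species_id column")
  trait_names <- setdiff(names(traits), "species_id")
  if (!length(trait_names)) stop("no trait columns")
  pairs <- pairs[!is.na(pairs$ses), , drop = FALSE]
  if (nrow(pairs) < 3) stop("too few pairs with defined SES")
  sp <- as.character(traits$species_id)
  miss <- setdiff(unique(c(pairs$species_a, pairs$species_b)), sp)
  if (length(miss)) stop("species without trait values: ",
                         paste(miss, collapse = ", "))
  ia <- match(pairs$species_a, sp)
  ib <- match(pairs$species_b, sp)
  codes <- lapply(trait_names, function(tr)
    as.integer(traits[[tr]][ia] == traits[[tr]][ib]))
  names(codes) <- trait_names
  d <- data.frame(ses = pairs$ses, codes, check.names = FALSE)
  usable <- trait_names[vapply(trait_names, function(tr)
    length(unique(d[[tr]])) > 1, logical(1))]
  dropped <- setdiff(trait_names, usable)
  if (length(dropped))
    warning("constant identity code, trait(s) dropped: ",
            paste(dropped, collapse = ", "))
  if (!length(usable)) stop("no trait with a non-constant identity code")
  f <- stats::as.formula(paste("ses ~",
                               paste(sprintf("`%s`", usable), collapse = " + ")))
  glm_eta2(f, d)
}
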