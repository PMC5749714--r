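#' Longitude-sorted shifting windows
#'
#' Sorts sites by longitude (ties broken by latitude, then site id, so the
#' ordering is deterministic) and assigns the first `n_windows x
#' window_size` sites to consecutive non-overlapping windows. Surplus
#' sites at the high-longitude end remain unassigned (window NA) and are
#' reported via an attribute.
#'
#' @param metadata cave metadata with `site_id`, `longitude`, `latitude`.
#' @param window_size sites per window (default 20).
#' @param n_windows number of windows; default is as many full windows as
#'   fit (`floor(n/window_size)`).
#' @return a data.frame `site_id`, `longitude`, `window` (integer or NA),
#'   sorted by longitude; attribute `"unassigned"` lists surplus site ids.
#' @export
make_windows <- function(metadata, window_size = 20, n_windows = NULL) {
  n <- nrow(metadata)
  if (is.null(n_windows)) n_windows <- n %/% window_size
  if (n < window_size * n_windows)
    stop("need at least ", window_size * n_windows, " sites, have ", n)
  if (n_windows < 1) stop("n_windows must be at least 1")
  ord <- order(metadata$longitude, metadata$latitude,
               as.character(metadata$site_id))
  out <- data.frame(site_id = as.character(metadata$site_id)[ord],
                    longitude = metadata$longitude[ord],
                    window = NA_integer_,
                    stringsAsFactors = FALSE)
  used <- window_size * n_windows
  out$window[seq_len(used)] <- rep(seq_len(n_windows), each = window_size)
  attr(out, "unassigned") <- out$site_id[is.na(out$window)]
  out
}

#' Per-window co-occurrence metrics with standardized effect sizes
#'
#' For every window, restricts the incidence matrix to the window's sites,
#' drops species with no occurrence there, and computes the C-score and
#' NODF standardized effect sizes under each requested null model with its
#' own ensemble. Windows whose submatrix has fewer than 2 species (or
#' fewer than 2 occupied sites) are flagged and skipped. An OLS regression
#' of each SES series on window pooled richness, with a permutation test
#' of its r-squared, summarizes the richness dependence.
#'
#' @param m an incidence matrix covering all window sites.
#' @param windows window assignment from [make_windows()].
#' @param models character vector of null models (subset of EE/PP/FF).
#' @param reps ensemble size per window and model (default 200).
#' @param seed optional integer seed for the whole analysis.
#' @param n_perm permutations for the SES-vs-richness regressions.
#' @param condition passed to the EE/PP randomizers. Window submatrices
#'   are typically very sparse (many single-occurrence species), which
#'   makes the no-empty-row conditional null practically unsamplable, so
#'   the default here is the unconstrained null (`FALSE`).
#' @return object of class `window_analysis`: `$windows` (one row per
#'   window: index, pooled richness, n species, and `cscore_ses_<model>`,
#'   `nodf_ses_<model>` columns) and `$regressions` (slope, r-squared and
#'   permutation p of SES on richness for each metric x model).
#' @export
window_metrics <- function(m, windows, models = c("EE", "PP"), reps = 200,
                           seed = NULL, n_perm = 999, condition = FALSE) {
  m <- as_incidence(m)
  if (!is.null(seed)) set.seed(seed)
  models <- match.arg(models, c("EE", "PP", "FF"), several.ok = TRUE)
  idx <- sort(unique(windows$window[!is.na(windows$window)]))
  miss <- setdiff(windows$site_id[!is.na(windows$window)], colnames(m))
  if (length(miss)) stop("window sites absent from matrix: ",
                         paste(miss, collapse = ", "))
  rows <- lapply(idx, function(w) {
    sites <- windows$site_id[!is.na(windows$window) & windows$window == w]
    sub <- unclass(m)[, sites, drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    rec <- data.frame(window = w, n_sites = length(sites),
                      pooled_richness = nrow(sub))
    degenerate <- nrow(sub) < 2 || sum(colSums(sub) > 0) < 2
    for (mod in models) {
      cs <- ns <- NA_real_
      if (!degenerate) {
        subm <- incidence_matrix(sub)
        ens <- build_ensemble(subm, model = mod, reps = reps,
                              condition = condition)
        cs <- ses(c_score(subm),
                  vapply(ens$matrices, c_score, numeric(1)))$ses
        ns <- ses(nodf(subm),
                  vapply(ens$matrices, nodf, numeric(1)))$ses
      }
      rec[[paste0("cscore_ses_", mod)]] <- cs
      rec[[paste0("nodf_ses_", mod)]] <- ns
    }
    rec
  })
  tab <- do.call(rbind, rows)
  regress <- list()
  for (col in grep("_ses_", names(tab), value = TRUE)) {
    y <- tab[[col]]
    x <- tab$pooled_richness
    ok <- !is.na(y)
    if (sum(ok) >= 3) {
      fit <- stats::lm(y[ok] ~ x[ok])
      r2 <- summary(fit)$r.squared
      perm <- vapply(seq_len(n_perm), function(i)
        summary(stats::lm(sample(y[ok]) ~ x[ok]))$r.squared, numeric(1))
      regress[[col]] <- list(slope = unname(stats::coef(fit)[2]),
                             r_squared = r2,
                             p_perm = (sum(perm >= r2) + 1) / (n_perm + 1))
    }
  }
  structure(list(windows = tab, regressions = regress,
                 models = models, reps = reps),
            class = "window_analysis")
}

#' @export
print.window_analysis <- function(x, ...) {
  cat("Shifting-window co-occurrence analysis:", nrow(x$windows),
      "windows,", x$reps, "reps per ensemble\n")
  print(x$windows, digits = 3)
  if (length(x$regressions)) {
    cat("\nSES vs pooled richness (OLS + permutation test):\n")
    for (nm in names(x$regressions)) {
      r <- x$regressions[[nm]]
      cat(sprintf("  %-16s slope %+.3f, r^2 = %.3f, P = %.4g\n",
                  nm, r$slope, r$r_squared, r$p_perm))
    }
  }
  invisible(x)
}

#' Dominant spatial eigenvector (EV1) of the inter-site distance matrix
#'
#' Extracts the first axis of a principal-coordinates analysis of the
#' Euclidean distances between site coordinates (squared distances,
#' double-centred, leading eigenvector scaled by the square root of its
#' eigenvalue) — the standard spatial covariate for regression models on
#' site attributes. Scores are centred and oriented so that they correlate
#' positively with longitude (sign fixed by the first site when longitude
#' carries no signal). `method = "raw"` instead takes the leading
#' eigenvector of the raw distance matrix, centred.
#'
#' @param metadata cave metadata with `site_id`, `longitude`, `latitude`.
#' @param method `"pcoa"` (default) or `"raw"`.
#' @return a data.frame `site_id`, `ev1`.
#' @export
ev1 <- function(metadata, method = c("pcoa", "raw")) {
  method <- match.arg(method)
  if (nrow(metadata) < 3) stop("need at least 3 sites")
  coords <- cbind(metadata$longitude, metadata$latitude)
  if (anyNA(coords)) stop("missing coordinates")
  if (all(apply(coords, 2, function(z) diff(range(z)) == 0)))
    stop("all sites have identical coordinates")
  d <- as.matrix(stats::dist(coords))
  scores <- if (method == "pcoa") {
    g <- -0.5 * d^2
    g <- sweep(g, 1, rowMeans(g))
    g <- sweep(g, 2, colMeans(g))
    e <- eigen((g + t(g)) / 2, symmetric = TRUE)
    e$vectors[, 1] * sqrt(max(e$values[1], 0))
  } else {
    e <- eigen(d, symmetric = TRUE)
    v <- e$vectors[, which.max(abs(e$values))]
    v - mean(v)
  }
  cr <- suppressWarnings(stats::cor(scores, metadata$longitude))
  if (!is.na(cr) && cr < 0) scores <- -scores
  if ((is.na(cr) || cr == 0) && scores[1] < 0) scores <- -scores
  data.frame(site_id = as.character(metadata$site_id),
             ev1 = scores - mean(scores),
             stringsAsFactors = FALSE)
}
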