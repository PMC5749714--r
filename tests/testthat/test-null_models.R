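test_that("all null engines conserve fill; FF conserves all marginals", {
  set.seed(31)
  for (i in 1:8) {
    m <- gen_random_matrix(sample(5:15, 1), sample(5:15, 1), fill = 40)
    ee <- randomize_ee(m)
    pp <- randomize_pp(m)
    ff <- randomize_ff(m, n_swaps = 50)
    expect_identical(sum(ee), matrix_fill(m))
    expect_identical(sum(pp), matrix_fill(m))
    expect_identical(dim(ee), dim(unclass(m)))
    expect_true(all(rowSums(ee) > 0) && all(colSums(ee) > 0))
    expect_true(all(rowSums(pp) > 0) && all(colSums(pp) > 0))
    expect_identical(rowSums(ff), rowSums(unclass(m)))
    expect_identical(colSums(ff), colSums(unclass(m)))
  }
})

test_that("EE returns the unique configuration for an all-ones matrix", {
  m <- incidence_matrix(matrix(1, 4, 5))
  expect_identical(unclass(randomize_ee(m, seed = 1)), unclass(m))
  # infeasible no-empty constraint is detected
  expect_error(randomize_ee(incidence_matrix(diag(5)[, 1:2])), "empty")
})

test_that("EE cell-occupancy frequencies are uniform under the constraint", {
  m <- gen_random_matrix(10, 10, fill = 30, seed = 17)
  reps <- 800
  set.seed(18)
  freq <- matrix(0, 10, 10)
  for (i in seq_len(reps)) freq <- freq + randomize_ee(m)
  p <- freq / reps
  # fill 30 of 100 cells: each cell occupied ~30% of draws; allow 4
  # binomial SDs plus the slight no-empty conditioning
  tol <- 4 * sqrt(0.3 * 0.7 / reps)
  expect_true(all(abs(p - mean(p)) < tol + 0.02))
})

test_that("PP reduces to EE with flat marginals and tracks skewed ones", {
  # equal row and column totals: weights are constant
  m <- incidence_matrix(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1),
                              c(1, 0, 1, 0), c(0, 1, 0, 1)))
  expect_true(all(outer(species_occupancy(m), site_richness_counts(m)) ==
                    outer(species_occupancy(m),
                          site_richness_counts(m))[1, 1]))
  # skewed occupancies: null mean row totals follow observed row totals
  set.seed(41)
  skew <- gen_drift_assembly(rlnorm(15, 0, 1.5), rep(6, 20),
                             drop_empty = FALSE)
  skew <- incidence_matrix(unclass(skew)[rowSums(unclass(skew)) > 0, ])
  rs <- replicate(400, rowSums(randomize_pp(skew)))
  expect_gt(cor(rowMeans(rs), species_occupancy(skew), method = "spearman"),
            0.9)
})

test_that("FF swaps flip checkerboards and warn when none exist", {
  cb <- incidence_matrix(diag(2))
  flipped <- randomize_ff(cb, n_swaps = 1, seed = 5)
  expect_equal(unclass(flipped), matrix(c(0L, 1L, 1L, 0L), 2),
               ignore_attr = TRUE)
  nested <- incidence_matrix(rbind(c(1, 1), c(1, 1)))
  expect_warning(randomize_ff(nested, n_swaps = 3), "no swappable")
})

test_that("FF chains reach every configuration with the observed marginals", {
  # 3x3 with unit marginals: the 6 permutation matrices are the full
  # support; a long thinned chain must visit all of them
  m <- incidence_matrix(diag(3))
  ens <- build_ensemble(m, "FF", reps = 300, seed = 61, burn_in = 20,
                        thin = 5)
  keys <- unique(vapply(ens$matrices, function(x) paste(x, collapse = ""),
                        character(1)))
  expect_identical(length(keys), 6L)
})

test_that("ensembles are reproducible and validated", {
  m <- gen_random_matrix(8, 10, fill = 30, seed = 3)
  e1 <- build_ensemble(m, "PP", reps = 10, seed = 99)
  e2 <- build_ensemble(m, "PP", reps = 10, seed = 99)
  expect_identical(e1$matrices, e2$matrices)
  expect_error(build_ensemble(m, "EE", reps = 0), "at least 1")
})

test_that("SES arithmetic follows the definition and the add-one rule", {
  nulls <- c(10, 12, 14, 16, 18)
  s0 <- ses(mean(nulls), nulls)
  expect_equal(s0$ses, 0)
  s2 <- ses(mean(nulls) + 2 * sd(nulls), nulls)
  expect_equal(s2$ses, 2)
  big <- ses(100, rnorm(200))
  expect_equal(big$p_upper, 1 / 201)
  expect_equal(big$p_lower, 1)
  const <- ses(5, rep(3, 50))
  expect_true(is.na(const$ses))
  expect_equal(const$p_upper, 1 / 51)
  expect_error(ses(1, 2), "at least 2")
})

test_that("EE SES is larger in magnitude than PP SES on drift matrices", {
  set.seed(73)
  mag_ee <- mag_pp <- numeric(6)
  for (i in 1:6) {
    m <- gen_drift_assembly(rlnorm(25, 0, 1.5),
                            pmax(2, rpois(30, 8)))
    mag_ee[i] <- abs(null_model_test(m, "cscore", "EE", reps = 100,
                                     condition = FALSE)$ses)
    mag_pp[i] <- abs(null_model_test(m, "cscore", "PP", reps = 100,
                                     condition = FALSE)$ses)
  }
  expect_gt(mean(mag_ee), mean(mag_pp))
})
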