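test_that("partial eta^2 reduces to R^2 for a single predictor", {
  set.seed(37)
  d <- data.frame(x = rnorm(60))
  d$y <- 0.8 * d$x + rnorm(60)
  g <- glm_eta2(y ~ x, d)
  expect_equal(g$table$eta2, summary(lm(y ~ x, d))$r.squared)
  expect_identical(g$table$sign, "+")
  # affine rescaling of the response leaves eta^2 unchanged
  d$y2 <- 100 * d$y - 7
  g2 <- glm_eta2(y2 ~ x, d)
  expect_equal(g2$table$eta2, g$table$eta2)
  expect_equal(g2$table$p, g$table$p)
})

test_that("constant response gives zero eta^2; collinearity is named", {
  d <- data.frame(y = rep(2, 20), x = rnorm(20), z = rnorm(20))
  g <- suppressWarnings(glm_eta2(y ~ x + z, d))
  expect_true(all(g$table$eta2 == 0))
  d2 <- data.frame(y = rnorm(20), x = rnorm(20))
  d2$x2 <- 2 * d2$x
  expect_error(glm_eta2(y ~ x + x2, d2), "collinear")
})

test_that("partial SS uses term deletion (each term's increment)", {
  set.seed(43)
  d <- data.frame(a = rnorm(80), b = rnorm(80), c = rnorm(80))
  d$y <- d$a + 0.5 * d$b + rnorm(80)
  g <- glm_eta2(y ~ a + b + c, d)
  full <- lm(y ~ a + b + c, d)
  for (i in seq_len(3)) {
    reduced <- lm(stats::reformulate(setdiff(c("a", "b", "c"),
                                             g$table$term[i]), "y"), d)
    expect_equal(g$table$ss[i], deviance(reduced) - deviance(full))
  }
})

test_that("screening keeps only significant tails and labels direction", {
  pairs <- data.frame(species_a = c("a", "b", "c"),
                      species_b = c("b", "c", "a"),
                      ses = c(3, -3, 0),
                      p_lower = c(0.99, 0.004, 0.4),
                      p_upper = c(0.004, 0.99, 0.6))
  kept <- screen_significant_pairs(pairs, alpha = 0.05)
  expect_identical(nrow(kept), 2L)
  expect_identical(kept$direction, c("segregated", "aggregated"))
})

test_that("screening retains about the nominal fraction on null data", {
  m <- gen_random_matrix(30, 40, fill = 240, seed = 47)
  ens <- build_ensemble(m, "EE", reps = 200, seed = 48)
  pairs <- pairwise_c_scores(m, ens)
  frac <- nrow(screen_significant_pairs(pairs)) / nrow(pairs)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.12)
})

test_that("trait ANOVA recovers a planted trait effect", {
  set.seed(53)
  n_pairs <- 150
  traits <- gen_traits(40, n_traits = 2, levels = 2)
  ij <- t(combn(40, 2))[sample(choose(40, 2), n_pairs), ]
  share1 <- traits$trait1[ij[, 1]] == traits$trait1[ij[, 2]]
  pairs <- data.frame(species_a = traits$species_id[ij[, 1]],
                      species_b = traits$species_id[ij[, 2]],
                      ses = 1.5 * share1 + rnorm(n_pairs, 0, 0.8))
  g <- trait_identity_anova(pairs, traits)
  t1 <- g$table[g$table$term == "trait1", ]
  expect_gt(t1$eta2, max(g$table$eta2[g$table$term != "trait1"]))
  expect_identical(t1$sign, "+")
  expect_lt(t1$p, 0.001)
})

test_that("trait ANOVA drops constant identity codes and errors when none vary", {
  traits <- data.frame(species_id = c("a", "b", "c", "d"),
                       same = "X",
                       varies = c("u", "u", "v", "v"),
                       stringsAsFactors = FALSE)
  pairs <- data.frame(species_a = c("a", "a", "b", "c"),
                      species_b = c("b", "c", "d", "d"),
                      ses = c(1, -1, 0.5, 0.2))
  expect_warning(g <- trait_identity_anova(pairs, traits), "same")
  expect_identical(g$table$term, "varies")
  all_same <- data.frame(species_id = c("a", "b", "c", "d"), t1 = "X",
                         stringsAsFactors = FALSE)
  expect_error(suppressWarnings(trait_identity_anova(pairs, all_same)),
               "non-constant")
})

test_that("random traits yield roughly uniform trait p-values", {
  set.seed(59)
  hits <- 0
  n_tests <- 0
  for (rep in 1:10) {
    traits <- gen_traits(30, n_traits = 3, levels = 2)
    ij <- t(combn(30, 2))[sample(choose(30, 2), 100), ]
    pairs <- data.frame(species_a = traits$species_id[ij[, 1]],
                        species_b = traits$species_id[ij[, 2]],
                        ses = rnorm(100))
    g <- trait_identity_anova(pairs, traits)
    hits <- hits + sum(g$table$p < 0.05)
    n_tests <- n_tests + nrow(g$table)
  }
  expect_lt(hits / n_tests, 0.15)
})

test_that("permutation and F-test rejections agree on clear cases", {
  set.seed(61)
  agree <- 0
  for (rep in 1:10) {
    L <- rlnorm(60, 4, 1)
    strong <- rep <= 5
    rich <- pmax(1, round(3 * L^(if (strong) 0.4 else 0) *
                            rlnorm(60, 0, 0.3)))
    perm_p <- power_law_fit(rich, L, n_perm = 199)$p_perm
    f_p <- glm_eta2(y ~ x, data.frame(y = log(rich), x = log(L)))$table$p
    agree <- agree + ((perm_p < 0.05) == (f_p < 0.05))
  }
  expect_gte(agree, 9)
})
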