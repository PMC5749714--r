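test_that("step distance follows the path-node convention", {
  tax <- printed_pair_taxonomy()
  expect_identical(taxonomic_distance("Anurida_subarctica",
                                      "Anurida_subarctica", tax), 0L)
  expect_identical(taxonomic_distance("Anurida_subarctica",
                                      "Lepidocyrtus_selvaticus", tax), 15L)
  # two species sharing all eight ranks: only the subgenus node between them
  tax2 <- data.frame(species_id = c("a", "b"),
                     order = "O", suborder = "SO", superfamily = "SF",
                     family = "F", subfamily = "SUF", tribe = "T",
                     genus = "G", subgenus = "SG",
                     stringsAsFactors = FALSE)
  expect_identical(taxonomic_distance("a", "b", tax2), 1L)
  expect_error(taxonomic_distance("a", "ghost", tax2), "absent")
})

test_that("distance grows with the depth of the split", {
  tax <- data.frame(
    species_id = c("a", "b", "c"),
    order = c("O1", "O1", "O2"), suborder = NA,
    superfamily = c("SF1", "SF1", "SF2"),
    family = c("F1", "F2", "F3"),
    subfamily = NA, tribe = NA,
    genus = c("G1", "G2", "G3"), subgenus = NA,
    stringsAsFactors = FALSE
  )
  d_family <- taxonomic_distance("a", "b", tax)   # split below superfamily
  d_order <- taxonomic_distance("a", "c", tax)    # split at the root
  expect_lt(d_family, d_order)
  # a & b: LCA = superfamily, two nodes below it per side (family, genus)
  expect_identical(d_family, 5L)
  # a & c: LCA = root, four nodes per side
  expect_identical(d_order, 9L)
})

test_that("distance matrices are symmetric, zero-diagonal, ultrametric-consistent", {
  for (seed in c(2, 3)) {
    tax <- gen_taxonomy(15, seed = seed)
    d <- distance_matrix(tax)
    expect_identical(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d[upper.tri(d)] >= 1))
    sp <- rownames(d)
    set.seed(seed)
    for (k in 1:30) {
      abc <- sample(sp, 3)
      expect_lte(d[abc[1], abc[3]],
                 max(d[abc[1], abc[2]], d[abc[2], abc[3]]))
    }
  }
  # congeneric same-subgenus species are exchangeable
  tax3 <- data.frame(species_id = c("x", "y", "z"),
                     order = "O", suborder = "SO", superfamily = "SF",
                     family = "F", subfamily = "SUF", tribe = "T",
                     genus = "G", subgenus = "SG", stringsAsFactors = FALSE)
  d3 <- distance_matrix(tax3)
  expect_true(all(d3[upper.tri(d3)] == 1))
})

test_that("taxonomy validation flags a child under two parents", {
  tax <- gen_taxonomy(10, seed = 4)
  tax$genus[2] <- tax$genus[1]
  tax$family[2] <- paste0(tax$family[1], "_other")
  expect_error(validate_taxonomy(tax), "two different parents")
})

test_that("MPD equals the brute-force pair average and matches picante", {
  tax <- gen_taxonomy(12, seed = 6)
  d <- distance_matrix(tax)
  comm <- c("sp2", "sp5", "sp7", "sp11")
  expect_equal(mpd(comm, d), oracle_mpd(comm, d))
  expect_identical(mpd(c("sp1", "sp2"), d), d["sp1", "sp2"] + 0)
  skip_if_not_installed("picante")
  inc <- matrix(as.numeric(rownames(d) %in% comm), 1,
                dimnames = list("site", rownames(d)))
  expect_equal(mpd(comm, d), picante::mpd(inc, d))
})

test_that("NRI sign convention: distant pairs score positive, no flip", {
  tax <- gen_taxonomy(20, seed = 8)
  d <- distance_matrix(tax)
  pool <- rownames(d)
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  r <- nri(pool[far], pool, d, reps = 300, seed = 9)
  expect_gt(r$nri, 0)
  near <- which(d == min(d[upper.tri(d)]), arr.ind = TRUE)[1, ]
  r2 <- nri(pool[near], pool, d, reps = 300, seed = 10)
  expect_lt(r2$nri, r$nri)
})

test_that("NRI flags degenerate communities instead of failing", {
  tax <- gen_taxonomy(8, seed = 11)
  d <- distance_matrix(tax)
  single <- nri("sp1", rownames(d), d, reps = 50, seed = 1)
  expect_true(is.na(single$nri))
  expect_identical(single$reason, "richness < 2")
  expect_error(nri(rownames(d), rownames(d), d), "larger than")
})

test_that("per-site NRI table covers every site and matches richness", {
  set.seed(12)
  m <- gen_random_matrix(20, 10, fill = 60)
  tax <- gen_taxonomy(20)
  d <- distance_matrix(tax)
  tab <- nri_table(m, d, reps = 100, seed = 13)
  expect_identical(tab$site_id, colnames(m))
  expect_equal(tab$richness, unname(site_richness_counts(m)))
  expect_true(all(is.na(tab$nri[tab$richness < 2])))
  expect_true(all(!is.na(tab$nri[tab$richness >= 2]) |
                    tab$richness >= nrow(m)))
})
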