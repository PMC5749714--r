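test_that("construction validates and binarizes", {
  m <- incidence_matrix(matrix(c(1, 0, 5, 0, 1, 1), nrow = 2))
  expect_true(all(unclass(m) %in% 0:1))
  expect_identical(matrix_fill(m), 4L)
  # binarization is idempotent
  expect_identical(unclass(incidence_matrix(unclass(m))), unclass(m))
  expect_error(incidence_matrix(matrix(1, 2, 2,
                                       dimnames = list(c("a", "a"), c("x", "y")))),
               "duplicate species")
  expect_error(incidence_matrix(matrix(c(1, NA), 1)), "missing")
  expect_error(incidence_matrix(matrix(-1, 1, 1)), "nonnegative")
})

test_that("file round-trip preserves entries, order, and labels", {
  set.seed(8)
  m <- incidence_matrix(random_binary(7, 4),
                        species_ids = paste0("Species ", 1:7),
                        site_ids = paste0("Cave-", 1:4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_incidence_matrix(m, path)
  m2 <- read_incidence_matrix(path)
  expect_identical(unclass(m2), unclass(m))
  # transpose orientation
  path2 <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(site_id = colnames(m), t(unclass(m)), check.names = FALSE)
  utils::write.table(df, path2, sep = ",", row.names = FALSE, quote = FALSE)
  m3 <- read_incidence_matrix(path2, species_as_rows = FALSE)
  expect_identical(unclass(m3), unclass(m))
})

test_that("counts binarize on read and bad cells are located", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_id,c1,c2", "spA,5,0", "spB,1,1"), path)
  m <- read_incidence_matrix(path)
  expect_identical(unclass(m)["spA", "c1"], 1L)
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_id,c1,c2", "spA,x,0", "spB,1,1"), path2)
  expect_error(read_incidence_matrix(path2), "spA.*c1")
})

test_that("sampling classes follow the visit brackets and reject 0 or >12", {
  expect_identical(assign_sampling_class(c(1, 2, 3)), c(1L, 1L, 1L))
  expect_identical(assign_sampling_class(c(4, 5, 6)), c(2L, 2L, 2L))
  expect_identical(assign_sampling_class(c(7, 9)), c(3L, 3L))
  expect_identical(assign_sampling_class(c(10, 11, 12)), c(4L, 4L, 4L))
  expect_error(assign_sampling_class(0), "1-12")
  expect_error(assign_sampling_class(13), "1-12")
})

test_that("visit filtering keeps well-surveyed sites and drops emptied species", {
  m <- incidence_matrix(rbind(rare = c(1, 0, 0, 0),
                              common = c(1, 1, 1, 1)),
                        site_ids = paste0("s", 1:4))
  meta <- data.frame(site_id = paste0("s", 1:4), visits = c(1, 2, 3, 4))
  expect_message(f <- filter_by_visits(m, meta), "rare")
  expect_identical(colnames(f), c("s3", "s4"))
  expect_identical(rownames(f), "common")
  expect_identical(attr(f, "dropped_species"), "rare")
  # no-op when every site qualifies
  meta2 <- transform(meta, visits = c(3, 5, 8, 12))
  expect_equal(unclass(filter_by_visits(m, meta2)), unclass(m),
               ignore_attr = TRUE)
  # monotone: larger threshold never keeps more sites
  n3 <- ncol(suppressMessages(filter_by_visits(m, meta, min_visits = 2)))
  n4 <- ncol(suppressMessages(filter_by_visits(m, meta, min_visits = 3)))
  expect_lte(n4, n3)
  expect_error(filter_by_visits(m, meta[-2, ]), "s2")
})

test_that("dataset validation reports orphans in both directions", {
  b <- tiny_bundle()
  v <- validate_dataset(b$matrix, b$metadata, b$taxonomy, b$traits)
  expect_true(v$ok)
  expect_length(v$issues, 0)
  v2 <- validate_dataset(b$matrix, b$metadata, b$taxonomy[-1, ], b$traits)
  expect_false(v2$ok)
  expect_match(v2$issues, "sp1", all = FALSE)
  meta_extra <- rbind(b$metadata,
                      transform(b$metadata[1, ], site_id = "ghost"))
  v3 <- validate_dataset(b$matrix, meta_extra, b$taxonomy, b$traits)
  expect_match(v3$issues, "ghost", all = FALSE)
})

test_that("cave metadata validation derives classes and checks bounds", {
  b <- tiny_bundle()
  md <- validate_cave_metadata(b$metadata)
  expect_identical(md$sampling_class, assign_sampling_class(md$visits))
  bad <- transform(b$metadata, longitude = longitude + 400)
  expect_error(validate_cave_metadata(bad), "bounds")
  bad2 <- transform(b$metadata, length_m = -1)
  expect_error(validate_cave_metadata(bad2), "positive")
})
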