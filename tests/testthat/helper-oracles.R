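# Independent brute-force oracles, written directly from the metric
# definitions; deliberately naive (explicit enumeration) so they share no
# code path with the package implementations.

# count 2x2 checkerboard submatrices of a species pair by enumerating all
# site pairs
oracle_pair_checkerboards <- function(m, i, j) {
  n_sites <- ncol(m)
  acc <- 0L
  for (s1 in seq_len(n_sites - 1)) for (s2 in (s1 + 1):n_sites) {
    a <- c(m[i, s1], m[i, s2])
    b <- c(m[j, s1], m[j, s2])
    if ((all(a == c(1, 0)) && all(b == c(0, 1))) ||
        (all(a == c(0, 1)) && all(b == c(1, 0)))) acc <- acc + 1L
  }
  acc
}

oracle_cscore <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + oracle_pair_checkerboards(m, i, j)
  tot / (n * (n - 1) / 2)
}

oracle_nodf <- function(m) {
  half <- function(x) {
    fills <- rowSums(x)
    acc <- 0
    np <- 0
    for (i in seq_len(nrow(x) - 1)) for (j in (i + 1):nrow(x)) {
      np <- np + 1
      hi <- if (fills[i] >= fills[j]) i else j
      lo <- if (fills[i] >= fills[j]) j else i
      if (fills[hi] > fills[lo] && fills[lo] > 0)
        acc <- acc + 100 * sum(x[hi, ] == 1 & x[lo, ] == 1) / fills[lo]
    }
    list(sum = acc, pairs = np)
  }
  r <- half(m)
  c <- half(t(m))
  (r$sum + c$sum) / (r$pairs + c$pairs)
}

oracle_mpd <- function(community, d) {
  acc <- 0
  np <- 0
  k <- length(community)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    acc <- acc + d[community[i], community[j]]
    np <- np + 1
  }
  acc / np
}

# random binary matrix without the package generators
random_binary <- function(nr, nc, p = 0.4) {
  matrix(rbinom(nr * nc, 1, p), nr, nc)
}

# the two fully printed ranked classifications of the worked distance
# example (suborder unrecorded for both species)
printed_pair_taxonomy <- function() {
  data.frame(
    species_id = c("Anurida_subarctica", "Lepidocyrtus_selvaticus"),
    order = c("Poduromorpha", "Entomobryomorpha"),
    suborder = NA_character_,
    superfamily = c("Neanuroidea", "Entomobryoidea"),
    family = c("Neanuridae", "Lepidocyrtidae"),
    subfamily = c("Pseudachorutinae", "Lepidocyrtinae"),
    tribe = c("Pseudachorutini", "Lepidocyrtini"),
    genus = c("Anurida", "Lepidocyrtus"),
    subgenus = c("Anurida", "Lanocyrtus"),
    stringsAsFactors = FALSE
  )
}

# small consistent synthetic bundle for data-validation tests
tiny_bundle <- function(seed = 1) {
  set.seed(seed)
  m <- incidence_matrix(random_binary(6, 5, 0.5) + diag(0, 6, 5),
                        species_ids = paste0("sp", 1:6),
                        site_ids = paste0("site", 1:5))
  meta <- data.frame(site_id = paste0("site", 1:5),
                     longitude = runif(5, 21, 28),
                     latitude = runif(5, 44, 47),
                     length_m = rlnorm(5, log(100), 1),
                     depth_m = rlnorm(5, log(15), 1),
                     altitude_m = runif(5, 200, 900),
                     visits = c(1, 3, 4, 7, 12))
  tax <- gen_taxonomy(6)
  traits <- gen_traits(6, 2, 3)
  list(matrix = m, metadata = meta, taxonomy = tax, traits = traits)
}
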