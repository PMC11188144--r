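# k-mer sets, sketches, containment, intersection, ANI.

test_that("canonical_kmers handles canonicalization, N windows, short input", {
  expect_equal(canonical_kmers("ACGT", 3), c("ACG", "ACG"))
  expect_equal(canonical_kmers("AAAA", 2), rep("AA", 3))
  expect_equal(canonical_kmers("ACNGT", 3), character(0))
  expect_equal(canonical_kmers("AC", 3), character(0))
  expect_equal(canonical_kmers("acgt", 3), c("ACG", "ACG"))
})

test_that("build_kmer_set matches brute-force enumeration and is strand/set invariant", {
  g <- rand_dna(1000, seed = 11)
  ks <- build_kmer_set(g, k = 28)
  expect_equal(length(ks$hashes), length(oracle_kmer_set(g, 28)))
  # duplicates and reverse complements change nothing
  expect_identical(build_kmer_set(c(g, g), k = 28)$hashes, ks$hashes)
  expect_identical(build_kmer_set(oracle_revcomp(g), k = 28)$hashes,
                   ks$hashes)
  # hash count never exceeds valid window count
  expect_lte(length(ks$hashes), nchar(g) - 28 + 1)
  expect_error(build_kmer_set(character(0)))
})

test_that("bottom_sketch saturates, returns global min, and merges", {
  g <- rand_dna(2000, seed = 3)
  ks <- build_kmer_set(g, k = 21)
  expect_identical(bottom_sketch(ks, 10 * length(ks$hashes))$hashes,
                   ks$hashes)
  expect_identical(bottom_sketch(ks, 1)$hashes, min(ks$hashes))
  # mergeability: sketch of concatenation = bottom-s of union of sketches
  g2 <- rand_dna(2000, seed = 4)
  s <- 50
  sk_cat <- bottom_sketch(build_kmer_set(c(g, g2), k = 21), s)
  sk_union <- head(sort(unique(c(
    bottom_sketch(ks, s)$hashes,
    bottom_sketch(build_kmer_set(g2, k = 21), s)$hashes))), s)
  expect_identical(sk_cat$hashes, sk_union)
})

test_that("containment: subset invariant, sketch estimate near exact, unrelated ~ 0", {
  g <- rand_dna(10000, seed = 7)
  ks <- build_kmer_set(g, k = 21)
  expect_equal(containment(bottom_sketch(ks, 1e6), ks), 1.0)
  # 99%-identical pair: sketch containment within 0.1 of exact containment
  mut <- oracle_mutate(g, 0.01, seed = 8)
  km <- build_kmer_set(mut$sequence, k = 21)
  est <- containment(bottom_sketch(ks, 400), km)
  exact <- mean(ks$hashes %in% km$hashes)
  expect_lt(abs(est - exact), 0.1)
  # unrelated genome
  other <- rand_dna(10000, seed = 9)
  reads <- tile_reads(other, 400, 100, seed = 10)
  cont <- containment(bottom_sketch(build_kmer_set(g, k = 28), 400),
                      build_kmer_set(reads, k = 28))
  expect_lt(cont, 0.01)
  # error-free high-depth reads contain the whole source
  own_reads <- c(tile_reads(g, 2000, 100, seed = 12),
                 setNames(substring(g, nchar(g) - 99, nchar(g)), "tail"),
                 setNames(substring(g, 1, 100), "head"))
  expect_gte(containment(bottom_sketch(ks, 1e6),
                         build_kmer_set(own_reads, k = 21)), 0.999)
  # empty sketch errors
  ns <- build_kmer_set("NNNNNNNNNN", k = 8)
  expect_error(containment(bottom_sketch(ns, 10), ks))
})

test_that("containment is monotone non-increasing in mutation rate", {
  g <- rand_dna(20000, seed = 21)
  sk <- bottom_sketch(build_kmer_set(g, k = 21), 500)
  rates <- seq(0, 0.09, by = 0.01)
  conts <- vapply(seq_along(rates), function(i) {
    mut <- oracle_mutate(g, rates[i], seed = 100 + i)
    reads <- tile_reads(mut$sequence, 2000, 100, seed = 200 + i)
    containment(sk, build_kmer_set(reads, k = 21))
  }, numeric(1))
  expect_lt(cor(rates, conts, method = "spearman"), -0.9)
})

test_that("kmer_intersection_size equals brute-force string intersection", {
  expect_equal(kmer_intersection_size(build_kmer_set("AAAAAA", k = 4),
                                      build_kmer_set("CCCCCC", k = 4)), 0)
  g <- rand_dna(3000, seed = 31)
  ks <- build_kmer_set(g, k = 28)
  expect_equal(kmer_intersection_size(ks, ks), length(ks$hashes))
  for (i in 1:5) {
    a <- rand_dna(2000, seed = 40 + i)
    mosaic <- paste0(substring(a, 1, 1000), rand_dna(1000, seed = 50 + i))
    reads <- tile_reads(mosaic, 300, 80, seed = 60 + i)
    got <- kmer_intersection_size(build_kmer_set(a, k = 28),
                                  build_kmer_set(reads, k = 28))
    want <- length(intersect(oracle_kmer_set(a, 28),
                             oracle_kmer_set(reads, 28)))
    expect_equal(got, want)
  }
})

test_that("estimate_ani: self = 100, unrelated undetected/low, symmetric", {
  g <- rand_dna(50000, seed = 71)
  expect_equal(estimate_ani(g, g), 100)
  h <- rand_dna(50000, seed = 72)
  ani <- estimate_ani(g, h, k = 21)
  expect_true(is.na(ani) || ani < 80)
  m <- oracle_mutate(g, 0.02, seed = 73)$sequence
  expect_identical(estimate_ani(g, m), estimate_ani(m, g))
})

test_that("estimate_ani recovers ~3% divergence within the expected band", {
  g <- rand_dna(100000, seed = 81)
  anis <- vapply(1:8, function(i) {
    m <- oracle_mutate(g, 0.03, seed = 500 + i)$sequence
    estimate_ani(g, m, k = 21, s = 1000)
  }, numeric(1))
  expect_true(all(anis >= 95.5 & anis <= 98.5))
})

test_that("sketch serialization round-trips", {
  ks <- build_kmer_set(rand_dna(500, seed = 91), k = 21,
                       source_id = "roundtrip")
  sk <- bottom_sketch(ks, 25)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_sketch(sk, p)
  back <- read_sketch(p)
  expect_s3_class(back, "minhash_sketch")
  expect_identical(back$hashes, sk$hashes)
  expect_identical(back$k, sk$k)
  expect_identical(back$source_id, "roundtrip")
  write_sketch(ks, p)
  expect_s3_class(read_sketch(p), "kmer_set")
})
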