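# Synthetic community generator: determinism, planted truth, statistics.

test_that("generate_genome plants disjoint markers deterministically", {
  g <- generate_genome(100000, marker_count = 40, marker_length = 600,
                       seed = 7)
  expect_equal(nchar(g$sequence), 100000)
  expect_equal(nrow(g$annotations), 40)
  ann <- g$annotations[order(g$annotations$start), ]
  expect_true(all(ann$end[-40] <= ann$start[-1]))  # disjoint
  expect_true(all(ann$end - ann$start == 600))
  g2 <- generate_genome(100000, marker_count = 40, marker_length = 600,
                        seed = 7)
  expect_identical(g$sequence, g2$sequence)
  expect_identical(g$annotations, g2$annotations)
  expect_error(generate_genome(10000, marker_count = 40,
                               marker_length = 600), "infeasible")
})

test_that("homologous families stay near-identical at low divergence", {
  ga <- generate_genome(60000, marker_count = 10, marker_length = 600,
                        marker_divergence = 0.005, seed = 1,
                        genome_id = "ga")
  gb <- generate_genome(60000, marker_count = 10, marker_length = 600,
                        marker_divergence = 0.005, seed = 2,
                        genome_id = "gb")
  for (f in c(1, 5, 10)) {
    sa <- with(ga$annotations[ga$annotations$family == f, ],
               substring(ga$sequence, start + 1, end))
    sb <- with(gb$annotations[gb$annotations$family == f, ],
               substring(gb$sequence, start + 1, end))
    expect_gte(pairwise_identity(sa, sb), 0.98)  # ~1% expected divergence
  }
})

test_that("mutate_genome: zero rates are identity; counts are binomial", {
  g <- rand_dna(50000, seed = 11)
  m0 <- mutate_genome(g, 0, 0, seed = 12)
  expect_identical(m0$sequence, g)
  expect_equal(nrow(m0$variants), 0)
  m <- mutate_genome(g, 0.03, 0, seed = 13)
  n_sub <- sum(m$variants$type == "snp")
  expect_lt(abs(n_sub - 50000 * 0.03), 3 * sqrt(50000 * 0.03 * 0.97))
  # the variant list is the exact truth
  ch_in <- strsplit(g, "")[[1]]
  ch_out <- strsplit(m$sequence, "")[[1]]
  snp <- m$variants[m$variants$type == "snp", ]
  expect_identical(ch_in[snp$position], snp$ref)
  expect_identical(ch_out[snp$position], snp$alt)
  # indels change length consistently with truth
  mi <- mutate_genome(g, 0, 0.001, seed = 14)
  delta <- sum(nchar(mi$variants$alt)) - sum(nchar(mi$variants$ref))
  expect_equal(nchar(mi$sequence) - nchar(g), delta)
})

test_that("simulate_reads: error-free reads are exact substrings; stats match", {
  g <- rand_dna(20000, seed = 21)
  truth <- list(sample_strains = c(g = g), abundances = c(g = 1))
  sim <- simulate_reads(truth, depth = 5, error_rate = 0, paired = FALSE,
                        seed = 22)
  expect_true(all(vapply(sim$reads, function(r)
    grepl(r, g, fixed = TRUE) || grepl(oracle_revcomp(r), g, fixed = TRUE),
    logical(1))))
  # abundance-weighted pair counts within 3 binomial SDs
  h <- rand_dna(20000, seed = 23)
  truth2 <- list(sample_strains = c(a = g, b = h),
                 abundances = c(a = 0.8, b = 0.2))
  sim2 <- simulate_reads(truth2, total_pairs = 5000, seed = 24)
  nA <- sum(sim2$origins$genome_id == "a") / 2
  expect_lt(abs(nA - 4000), 3 * sqrt(5000 * 0.8 * 0.2))
  # mean depth within 10% of target at 20x
  sim3 <- simulate_reads(truth, depth = 20, error_rate = 0, seed = 25)
  mean_depth <- sum(nchar(sim3$reads)) / nchar(g)
  expect_lt(abs(mean_depth - 20) / 20, 0.1)
  # determinism and sidecar completeness
  sim4 <- simulate_reads(truth, depth = 5, error_rate = 0.01, seed = 26)
  sim5 <- simulate_reads(truth, depth = 5, error_rate = 0.01, seed = 26)
  expect_identical(sim4$reads, sim5$reads)
  expect_setequal(names(sim4$reads), sim4$origins$read_id)
})

test_that("error-free origins round-trip through the aligner", {
  truth <- make_community(seed = 31, length_range = c(40e3, 60e3), marker_length = 400)
  sim <- simulate_reads(truth, total_pairs = 300, error_rate = 0, seed = 32)
  correct <- 0L
  for (g in unique(sim$origins$genome_id)) {
    ids <- sim$origins$read_id[sim$origins$genome_id == g]
    aln <- map_reads(sim$reads[ids],
                     setNames(truth$sample_strains[g], g))
    o <- sim$origins[match(aln$read_id, sim$origins$read_id), ]
    correct <- correct + sum(aln$start == o$position)
  }
  expect_gte(correct / length(sim$reads), 0.99)
})

test_that("community: strains in band, species unrelated, decoys absent", {
  truth <- make_community(seed = 41, length_range = c(40e3, 60e3), marker_length = 400)
  expect_setequal(truth$present_ids,
                  c("sp1_ref1", "sp2_ref1", "sp3_ref1", "sp4_ref1"))
  expect_setequal(truth$decoy_ids, c("decoy1", "decoy2"))
  expect_equal(sum(truth$abundances), 1)
  a12 <- estimate_ani(truth$genomes[["sp1_ref1"]],
                      truth$genomes[["sp1_ref2"]])
  a13 <- estimate_ani(truth$genomes[["sp1_ref1"]],
                      truth$genomes[["sp1_ref3"]])
  expect_true(a12 >= 97 && a12 <= 99.5)
  expect_true(a13 >= 96.5 && a13 <= 99.5)
  x <- estimate_ani(truth$genomes[["sp1_ref1"]],
                    truth$genomes[["sp2_ref1"]])
  expect_true(is.na(x) || x < 85)
  # full determinism
  truth2 <- make_community(seed = 41, length_range = c(40e3, 60e3), marker_length = 400)
  expect_identical(truth$genomes, truth2$genomes)
  expect_identical(truth$sample_strains, truth2$sample_strains)
})

test_that("write_community emits standard text formats", {
  truth <- make_community(seed = 51, n_species = 2, n_strains = 1,
                          n_decoys = 0, length_range = c(40e3, 50e3), marker_length = 400)
  sim <- simulate_reads(truth, total_pairs = 50, seed = 52)
  dir <- withr::local_tempdir()
  paths <- write_community(truth, sim, dir)
  expect_identical(read_genomes(paths[["genomes"]]), truth$genomes)
  back <- read_fastq(paths[["reads"]])
  expect_identical(as.character(back), unname(sim$reads[names(back)]))
  ann <- read.delim(paths[["annotations"]])
  expect_equal(nrow(ann), nrow(truth$annotations))
})
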