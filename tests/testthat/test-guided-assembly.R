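# Greedy within-cluster assembly, contig extraction, AGP, termination.

# Reads tiling an interval [start, end) of seq exactly (error-free,
# stepping so every position is covered).
tiling_reads <- function(seq, start, end, len = 100, step = 50,
                         prefix = "t") {
  starts <- seq(start, end - len, by = step)
  if (tail(starts, 1) != end - len) starts <- c(starts, end - len)
  setNames(substring(seq, starts + 1, starts + len),
           sprintf("%s_%d", prefix, seq_along(starts)))
}

test_that("order_next_genome is greedy on containment", {
  gA <- rand_dna(20000, seed = 1)
  gB <- rand_dna(20000, seed = 2)
  reads <- tile_reads(gA, 300, 100, seed = 3)
  rk <- build_kmer_set(reads, k = 21)
  expect_equal(order_next_genome(c(A = gA), rk), "A")
  expect_equal(order_next_genome(c(A = gA, B = gB), rk), "A")
})

test_that("contigs come from covered runs; short runs are dropped with their reads", {
  g <- rand_dna(20000, seed = 11)
  # covered runs of 600, 450 and 800 bases
  reads <- c(tiling_reads(g, 1000, 1600, prefix = "a"),
             tiling_reads(g, 5000, 5450, prefix = "b"),
             tiling_reads(g, 9000, 9800, prefix = "c"))
  res <- assemble_against_reference(reads, c(g = g))
  expect_equal(nrow(res$contigs), 2)
  expect_equal(res$contigs$guide_start, c(1000, 9000))
  expect_equal(res$contigs$guide_end, c(1600, 9800))
  expect_identical(res$contigs$sequence,
                   substring(g, c(1001, 9001), c(1600, 9800)))
  # 450 bp run discarded and its reads NOT used
  expect_false(any(startsWith(res$used_read_ids, "b")))
  expect_setequal(res$used_read_ids,
                  names(reads)[!startsWith(names(reads), "b")])
  # a lone 100 bp read yields nothing
  lone <- assemble_against_reference(reads["a_1"], c(g = g))
  expect_equal(nrow(lone$contigs), 0)
  expect_length(lone$used_read_ids, 0)
})

test_that("AGP records tile the guide and round-trip the contigs", {
  g <- rand_dna(20000, seed = 21)
  reads <- tiling_reads(g, 0, 10000, prefix = "x")
  res <- assemble_against_reference(reads, c(g = g))
  agp <- res$agp
  expect_equal(nrow(agp), 2)
  expect_equal(agp$component_type, c("W", "N"))
  expect_equal(agp$object_beg, c(1L, 10001L))
  expect_equal(agp$object_end, c(10000L, 20000L))
  # coordinates strictly increasing, alternating parts, full tiling
  expect_true(all(diff(agp$object_beg) > 0))
  expect_equal(agp$object_beg[-1], head(agp$object_end, -1) + 1L)

  # round-trip through the file format reconstructs contigs byte-identically
  p <- withr::local_tempfile(fileext = ".agp")
  write_agp(agp, p)
  back <- read_agp(p)
  w <- back[back$component_type == "W", ]
  rebuilt <- substring(g, w$object_beg, w$object_end)
  expect_identical(rebuilt, res$contigs$sequence)
})

test_that("termination criteria fire in order with the singleton exception", {
  cfg <- metaguide_config()
  fake_result <- function(lens) {
    list(contigs = data.frame(
      contig_id = sprintf("c%d", seq_along(lens)),
      sequence = strrep("A", lens), guide_genome_id = "g",
      guide_start = 0L, guide_end = lens, stringsAsFactors = FALSE))
  }
  # 4% of guide in a 3-genome cluster: stop + discard
  d <- check_termination(fake_result(4000), guide_length = 100000,
                         cluster_size = 3, reads_remaining = 10,
                         genomes_remaining = 2, config = cfg)
  expect_equal(d$stop_reason, "cumulative_below_5pct")
  expect_false(d$keep_last)
  # longest contig 1,999 bp in a multi-genome cluster
  d2 <- check_termination(fake_result(c(1999, 1999, 1999)),
                          guide_length = 20000, cluster_size = 2,
                          reads_remaining = 10, genomes_remaining = 1,
                          config = cfg)
  expect_equal(d2$stop_reason, "longest_below_2kb")
  expect_false(d2$keep_last)
  # exactly 2,000 bp does not fire criterion (iv)
  d3 <- check_termination(fake_result(c(2000, 2000)), guide_length = 20000,
                          cluster_size = 2, reads_remaining = 10,
                          genomes_remaining = 1, config = cfg)
  expect_equal(d3$stop_reason, "none")
  # singleton cluster retains a failing assembly
  d4 <- check_termination(fake_result(1500), guide_length = 100000,
                          cluster_size = 1, reads_remaining = 10,
                          genomes_remaining = 0, config = cfg)
  expect_true(d4$keep_last)
  expect_equal(d4$stop_reason, "all_references_assembled")
  # all reads assembled wins over reference exhaustion
  d5 <- check_termination(fake_result(10000), guide_length = 20000,
                          cluster_size = 2, reads_remaining = 0,
                          genomes_remaining = 1, config = cfg)
  expect_equal(d5$stop_reason, "all_reads_assembled")
})

test_that("assemble_cluster consumes reads, logs per genome, conserves ids", {
  base <- rand_dna(40000, seed = 31)
  strain <- oracle_mutate(base, 0.03, seed = 32)$sequence
  genomes <- c(A = base, B = strain)
  cl <- cluster_by_ani(genomes)
  expect_length(cl, 1)
  # sample is an exact copy of A
  truth <- list(sample_strains = c(A = base), abundances = c(A = 1))
  sim <- simulate_reads(truth, depth = 15, error_rate = 0, seed = 33)
  res <- assemble_cluster(cl[[1]], genomes, sim$reads)
  expect_equal(res$log$genome_id[1], "A")
  expect_gte(res$log$pct_guide[1], 90)
  # read partition invariant
  expect_length(intersect(res$used_read_ids,
                          setdiff(names(sim$reads), res$used_read_ids)), 0)
  expect_true(all(res$used_read_ids %in% names(sim$reads)))
  # contigs are exact guide substrings (pre-polish)
  for (i in seq_len(nrow(res$contigs))) {
    gid <- res$contigs$guide_genome_id[i]
    expect_identical(res$contigs$sequence[i],
                     substring(genomes[[gid]],
                               res$contigs$guide_start[i] + 1,
                               res$contigs$guide_end[i]))
  }
  # log fields mirror the per-genome report contract
  expect_true(all(c("bases_assembled", "pct_guide", "contigs_gt2kb",
                    "longest_contig", "ng25") %in% names(res$log)))
})

test_that("strain preference: the diverged guide is chosen first", {
  ok <- 0L
  for (rep in 1:6) {
    base <- rand_dna(30000, seed = 600 + rep)
    A <- base
    B <- oracle_mutate(base, 0.035, seed = 700 + rep)$sequence
    sample_strain <- oracle_mutate(base, 0.01, seed = 800 + rep)$sequence
    reads <- tile_reads(sample_strain, 600, 100, seed = 900 + rep)
    rk <- build_kmer_set(reads, k = 21)
    pick <- order_next_genome(c(A = A, B = B), rk)
    # exact-containment oracle must agree
    oracle_pick <- if (oracle_containment(A, reads, 21) >=
                       oracle_containment(B, reads, 21)) "A" else "B"
    expect_equal(pick, oracle_pick)
    ok <- ok + (pick == "A")
  }
  expect_gte(ok / 6, 0.95)
})
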