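# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (string-level, exhaustive) and never call
# the code paths they check.

rand_dna <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else metaguide:::with_seed(seed, gen())
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(ch)
           paste(rev(ch), collapse = ""), character(1)))
}

# String-level canonical k-mer set (not hashed).
oracle_kmer_set <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) next
    kms <- substring(s, 1:(n - k + 1), k:n)
    ok <- !grepl("[^ACGT]", kms)
    kms <- kms[ok]
    rcs <- oracle_revcomp(kms)
    out <- c(out, pmin(kms, rcs))
  }
  unique(out)
}

# Brute-force best ungapped alignment over all offsets and both strands.
# Mirrors the aligner's tie-breaks: best matches, then leftmost offset,
# then '+' strand. Returns NULL when best identity < min_identity.
oracle_align <- function(read, target, min_identity = 0.85) {
  read <- toupper(read); target <- toupper(target)
  rlen <- nchar(read); tlen <- nchar(target)
  if (rlen > tlen) return(NULL)
  tch <- strsplit(target, "")[[1]]
  best <- list(matches = -1L)
  for (strand in c("+", "-")) {
    rch <- strsplit(if (strand == "+") read else oracle_revcomp(read),
                    "")[[1]]
    for (off in 0:(tlen - rlen)) {
      m <- sum(rch == tch[(off + 1):(off + rlen)])
      if (m > best$matches ||
          (m == best$matches &&
           (off < best$start ||
            (off == best$start && strand == "+" && best$strand == "-")))) {
        best <- list(matches = m, start = off, strand = strand)
      }
    }
  }
  if (best$matches / rlen < min_identity) return(NULL)
  best
}

# Exhaustive NG25: try every contig length as the cutoff c.
oracle_ng25 <- function(lens, genome_size) {
  if (length(lens) == 0) return(NA_real_)
  cand <- sort(unique(lens), decreasing = TRUE)
  for (c in cand) {
    if (sum(lens[lens >= c]) > genome_size / 4) return(c)
  }
  NA_real_
}

# Exact containment of a genome's full canonical k-mer set in a read set,
# at the string level.
oracle_containment <- function(genome, reads, k) {
  gk <- oracle_kmer_set(genome, k)
  rk <- oracle_kmer_set(reads, k)
  mean(gk %in% rk)
}

# Substitution-only mutant with the planted truth, independent of
# metaguide::mutate_genome.
oracle_mutate <- function(seq, rate, seed) {
  metaguide:::with_seed(seed, {
    ch <- strsplit(toupper(seq), "")[[1]]
    pos <- which(runif(length(ch)) < rate)
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    list(sequence = paste(ch, collapse = ""), positions = pos)
  })
}

# Uniform error-free single-end reads from one sequence.
tile_reads <- function(seq, n, len, seed, prefix = "t") {
  metaguide:::with_seed(seed, {
    starts <- sample.int(nchar(seq) - len + 1, n, replace = TRUE)
    setNames(substring(seq, starts, starts + len - 1),
             sprintf("%s%d", prefix, seq_len(n)))
  })
}

# Lazily-built shared end-to-end fixture (community + 20x reads), reused
# by the heavier acceptance criteria so the simulation cost is paid once.
.e2e_cache <- new.env(parent = emptyenv())
e2e_fixture <- function() {
  if (is.null(.e2e_cache$fix)) {
    truth <- make_community(seed = 20240901)
    sim <- simulate_reads(truth, depth = 20,
                          seed = metaguide:::child_seed(20240901, "reads"))
    .e2e_cache$fix <- list(truth = truth, sim = sim)
  }
  .e2e_cache$fix
}
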