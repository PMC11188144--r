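# Canonical k-mer sets, bottom-s MinHash sketches, containment and ANI.
# These are the internal stand-ins for Mash ('mash screen'), KMC (exact
# k-mer intersection) and Skani (ANI estimation). Hashes are a seeded
# 64-bit mix masked to 53 bits so they are exact in R doubles; the seed is
# a config constant, making every run bit-reproducible.

#' Canonical k-mers of a sequence
#'
#' Returns, in positional order, min(window, revcomp(window)) for every
#' k-long window that contains only A/C/G/T (case-insensitive). Windows
#' containing N are skipped; `k` longer than the sequence yields an empty
#' vector.
#'
#' @param sequence a single DNA string.
#' @param k k-mer length (1..32).
#' @return character vector of canonical k-mers (one per valid window).
#' @export
canonical_kmers <- function(sequence, k) {
  stopifnot(k >= 1)
  if (k > 32) stop("k must be <= 32")
  .canonical_kmers_cpp(toupper(as.character(sequence)[1]), as.integer(k))
}

#' Exact canonical k-mer hash set
#'
#' Hashes every canonical k-mer of every input sequence with a fixed,
#' seeded 64-bit mixing function (masked to 53 bits) and returns the
#' deduplicated, sorted set.
#'
#' @param sequences character vector (or `DNAStringSet`) of sequences.
#' @param k k-mer length; default 28, the exact-intersection convention.
#' @param hash_seed integer hash seed (config constant).
#' @param source_id identifier of the sequence collection.
#' @return an object of class `kmer_set` with fields `k`, `seed`,
#'   `hashes` (sorted numeric), `source_id`.
#' @export
build_kmer_set <- function(sequences, k = 28, hash_seed = 42,
                           source_id = "") {
  sequences <- as_seq_vector(sequences)
  if (length(sequences) == 0) stop("empty sequence list")
  structure(list(
    k = as.integer(k), seed = as.numeric(hash_seed),
    hashes = .kmer_hashes_cpp(sequences, as.integer(k),
                              as.numeric(hash_seed)),
    source_id = as.character(source_id)), class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> k=%d seed=%.0f |hashes|=%d source=%s\n",
              x$k, x$seed, length(x$hashes), x$source_id))
  invisible(x)
}

#' Bottom-s MinHash sketch
#'
#' The s numerically smallest hash values of a k-mer set (all of them when
#' fewer than s exist). A sketch is always a subset of the full set, and
#' the sketch of a concatenation is the bottom-s of the union of sketches.
#'
#' @param kmer_set a [build_kmer_set()] result.
#' @param s sketch size (>= 1).
#' @return an object of class `minhash_sketch` (`k`, `s`, `seed`, `hashes`,
#'   `source_id`).
#' @export
bottom_sketch <- function(kmer_set, s) {
  stopifnot(inherits(kmer_set, "kmer_set"), s >= 1)
  structure(list(
    k = kmer_set$k, s = as.integer(s), seed = kmer_set$seed,
    hashes = head(kmer_set$hashes, s), source_id = kmer_set$source_id),
    class = "minhash_sketch")
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat(sprintf("<minhash_sketch> k=%d s=%d |hashes|=%d source=%s\n",
              x$k, x$s, length(x$hashes), x$source_id))
  invisible(x)
}

check_compatible <- function(a, b) {
  if (a$k != b$k || a$seed != b$seed)
    stop("k-mer sets/sketches use different k or hash seed")
}

#' Containment of a sketch in a k-mer set
#'
#' The screen-style statistic: the fraction of the reference's sketch
#' hashes found in the read k-mer set, estimating how much of the
#' reference is present in the reads.
#'
#' @param reference_sketch a [bottom_sketch()] of the reference.
#' @param read_kmers a [build_kmer_set()] of the reads (same k and seed).
#' @return fraction in \[0, 1\].
#' @export
containment <- function(reference_sketch, read_kmers) {
  stopifnot(inherits(reference_sketch, "minhash_sketch"),
            inherits(read_kmers, "kmer_set"))
  check_compatible(reference_sketch, read_kmers)
  if (length(reference_sketch$hashes) == 0)
    stop("unsketchable reference: empty sketch (all-N or shorter than k)")
  mean(reference_sketch$hashes %in% read_kmers$hashes)
}

#' Exact k-mer intersection size
#'
#' Cardinality of the intersection of two exact canonical k-mer hash sets
#' (never sketched); used to prioritize genome clusters against the
#' unassigned reads.
#'
#' @param cluster_kmers,unassigned_read_kmers two compatible `kmer_set`s.
#' @return nonnegative integer count.
#' @export
kmer_intersection_size <- function(cluster_kmers, unassigned_read_kmers) {
  stopifnot(inherits(cluster_kmers, "kmer_set"),
            inherits(unassigned_read_kmers, "kmer_set"))
  check_compatible(cluster_kmers, unassigned_read_kmers)
  sum(cluster_kmers$hashes %in% unassigned_read_kmers$hashes)
}

# Jaccard index estimated on the merged bottom-s sketch of two sketches.
sketch_jaccard <- function(sa, sb) {
  check_compatible(sa, sb)
  s <- min(sa$s, sb$s)
  merged <- head(sort(unique(c(sa$hashes, sb$hashes))), s)
  if (length(merged) == 0) return(NA_real_)
  shared <- sum(merged %in% sa$hashes & merged %in% sb$hashes)
  shared / length(merged)
}

#' MinHash ANI estimate between two genomes
#'
#' Average nucleotide identity estimated from the MinHash Jaccard index J
#' via the Mash distance transform ANI = 100 * (1 + ln(2J / (1 + J)) / k).
#' Symmetric by construction. Returns `NA` ("undetected") when the sketches
#' share no hashes — the genomes are unrelated at this k.
#'
#' @param genome_a,genome_b DNA strings (or lists with a `$sequence`).
#' @param k sketch k-mer length (default 21).
#' @param s sketch size (default 1000).
#' @param hash_seed hash seed (config constant).
#' @return percent identity in \[0, 100\], or `NA_real_` when undetected.
#' @export
estimate_ani <- function(genome_a, genome_b, k = 21, s = 1000,
                         hash_seed = 42) {
  seq_of <- function(g) {
    if (is.list(g) && !is.null(g$sequence)) g$sequence else g
  }
  ka <- build_kmer_set(seq_of(genome_a), k = k, hash_seed = hash_seed)
  kb <- build_kmer_set(seq_of(genome_b), k = k, hash_seed = hash_seed)
  ani_from_sets(ka, kb, s)
}

# Shared core so precomputed k-mer sets can be reused in clustering.
ani_from_sets <- function(ka, kb, s) {
  j <- sketch_jaccard(bottom_sketch(ka, s), bottom_sketch(kb, s))
  if (is.na(j) || j == 0) return(NA_real_)
  ani <- 100 * (1 + log(2 * j / (1 + j)) / ka$k)
  max(0, min(100, ani))
}

#' Serialize a sketch or k-mer set to a versioned tabular file
#'
#' One hash per line; a header records the format version, k, s, hash seed
#' and source id so incompatible sketches are never silently compared.
#'
#' @param x a `minhash_sketch` or `kmer_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sketch <- function(x, path) {
  stopifnot(inherits(x, "minhash_sketch") || inherits(x, "kmer_set"))
  s <- if (inherits(x, "minhash_sketch")) x$s else NA_integer_
  hdr <- sprintf("#metaguide_sketch\tv1\tk=%d\ts=%s\tseed=%.0f\tsource_id=%s",
                 x$k, ifelse(is.na(s), "NA", s), x$seed, x$source_id)
  writeLines(c(hdr, sprintf("%.0f", x$hashes)), path)
  invisible(path)
}

#' Read a sketch written by [write_sketch()]
#'
#' @param path file path.
#' @return `minhash_sketch` or `kmer_set`, depending on what was written.
#' @export
read_sketch <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#metaguide_sketch"))
    stop("not a metaguide sketch file: ", path)
  f <- strsplit(lines[1], "\t")[[1]]
  kv <- function(key) sub(paste0("^", key, "="), "",
                          f[startsWith(f, paste0(key, "="))])
  hashes <- as.numeric(lines[-1])
  s <- kv("s")
  base <- list(k = as.integer(kv("k")), seed = as.numeric(kv("seed")),
               hashes = hashes, source_id = kv("source_id"))
  if (s == "NA") structure(base, class = "kmer_set")
  else structure(c(base[1], list(s = as.integer(s)), base[-1]),
                 class = "minhash_sketch")
}
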