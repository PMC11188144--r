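# Deterministic desk-scale short-read alignment (the sr-preset stand-in)
# and per-base coverage tracks. The aligner is exact-seed anchored and
# ungapped: small indels between sample and reference surface as unmapped
# reads and are recovered at polishing time via split-anchored realignment.

#' Map reads to one or more targets
#'
#' For each read (and its reverse complement), exact seeds of length
#' `seed_length` anchor candidate placements on each target; the
#' best-identity ungapped extension of the full read is reported iff its
#' identity is at least `min_identity`. At most one alignment per read per
#' target is kept (best identity; ties resolved to the leftmost coordinate,
#' then the '+' strand). Unmapped reads are simply absent. Placements that
#' would run off a target's end are not considered.
#'
#' @param reads named character vector (or `DNAStringSet`) of reads.
#' @param targets named character vector (or `DNAStringSet`) of targets.
#' @param min_identity minimum matches/length to report (default 0.85:
#'   tolerates ~95% ANI strain divergence plus 1% sequencing error on
#'   100 bp reads).
#' @param seed_length exact-seed length (default 21).
#' @return a data.frame of class `read_alignments` with columns `read_id`,
#'   `target_id`, `start`, `end` (0-based half-open), `strand`, `matches`,
#'   `aligned_length`, and `edits` (mismatches as "pos:base", comma
#'   separated, 0-based target positions, read base as aligned).
#' @export
map_reads <- function(reads, targets, min_identity = 0.85,
                      seed_length = 21) {
  reads <- as_seq_vector(reads)
  targets <- as_seq_vector(targets)
  if (length(reads) && is.null(names(reads)))
    names(reads) <- paste0("read", seq_along(reads))
  if (is.null(names(targets)))
    names(targets) <- paste0("target", seq_along(targets))
  raw <- .map_reads_cpp(unname(reads), unname(targets),
                        as.numeric(min_identity), as.integer(seed_length))
  out <- data.frame(
    read_id = names(reads)[raw$read],
    target_id = names(targets)[raw$target],
    start = raw$start,
    end = raw$start + raw$len,
    strand = ifelse(raw$strand == 0L, "+", "-"),
    matches = raw$matches,
    aligned_length = raw$len,
    edits = raw$edits,
    stringsAsFactors = FALSE)
  class(out) <- c("read_alignments", "data.frame")
  out
}

#' Per-base depth from a set of alignments
#'
#' @param alignments a [map_reads()] result (rows for one target).
#' @param target_length length of the target in bases.
#' @return object of class `coverage_track`: list with `target_id` and
#'   integer `depth` of length `target_length`.
#' @export
coverage_track <- function(alignments, target_length) {
  target_length <- as.integer(target_length)
  depth <- integer(target_length)
  if (nrow(alignments)) {
    if (length(unique(alignments$target_id)) > 1)
      stop("coverage_track expects alignments to a single target")
    if (any(alignments$start < 0) || any(alignments$end > target_length))
      stop("alignment interval out of bounds [0, ", target_length, ")")
    st <- tabulate(alignments$start + 1L, nbins = target_length)
    en <- tabulate(alignments$end + 1L, nbins = target_length + 1L)
    depth <- cumsum(st - en[seq_len(target_length)])
  }
  structure(list(
    target_id = if (nrow(alignments)) alignments$target_id[1] else NA_character_,
    depth = as.integer(depth)), class = "coverage_track")
}

#' Breadth of coverage over an interval
#'
#' Fraction of positions in a 0-based half-open interval with depth >= 1.
#' Note the selection rule applies this strictly: a gene is covered only
#' when breadth *exceeds* the threshold.
#'
#' @param track a [coverage_track()].
#' @param interval integer pair `c(start, end)`, 0-based half-open;
#'   defaults to the whole track.
#' @return fraction in \[0, 1\].
#' @export
breadth <- function(track, interval = c(0L, length(track$depth))) {
  stopifnot(inherits(track, "coverage_track"))
  start <- as.integer(interval[1]); end <- as.integer(interval[2])
  if (end <= start) stop("empty interval")
  if (start < 0 || end > length(track$depth)) stop("interval out of track")
  mean(track$depth[(start + 1L):end] >= 1L)
}

# Maximal runs of positions with depth >= 1, as 0-based half-open
# intervals (data.frame start/end).
covered_runs <- function(track) {
  cov <- track$depth >= 1L
  if (!any(cov)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Export alignments as minimal SAM
#'
#' Header plus mandatory fields with an ungapped CIGAR, for inspection
#' with standard tools. Reverse-strand reads are written as the aligned
#' (reverse-complemented) sequence with flag 16.
#'
#' @param alignments a [map_reads()] result.
#' @param reads the reads that were mapped (named character vector).
#' @param targets the targets that were mapped against.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, targets, path) {
  reads <- as_seq_vector(reads); targets <- as_seq_vector(targets)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(targets), nchar(targets)),
             con)
  if (nrow(alignments)) {
    seqs <- reads[alignments$read_id]
    rev <- alignments$strand == "-"
    seqs[rev] <- revcomp(seqs[rev])
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       alignments$read_id, ifelse(rev, 16L, 0L),
                       alignments$target_id, alignments$start + 1L,
                       alignments$aligned_length, seqs), con)
  }
  invisible(path)
}
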