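# Sample-specific reference selection: screen reads against marker-cluster
# representatives and retain genomes whose marker complement is covered.
# Depth plays no direct role — only breadth — so a genome qualifies as
# soon as most of its markers are blanketed by reads.

#' Screen reads against the marker index
#'
#' Reads are mapped to cluster representative sequences only; a
#' representative's coverage track is inherited by every member gene of
#' its cluster, and a member gene counts as covered iff breadth on the
#' representative strictly exceeds `breadth_threshold`. A read may align
#' to representatives of multiple clusters. Profiles are computed for
#' every genome appearing in the index.
#'
#' @param reads named character vector of reads (or FASTQ via
#'   [read_fastq()]).
#' @param index a `marker_index`.
#' @param breadth_threshold strict lower bound on per-gene breadth
#'   (default 0.90: breadth must *exceed* 90%).
#' @param min_identity,seed_length aligner parameters (see [map_reads()]).
#' @return data.frame of class `marker_profiles`: `genome_id`,
#'   `families_covered`, `family_total`, `fraction_covered`, plus the
#'   covered family sets as the `"covered_families"` attribute (named list).
#' @export
screen_markers <- function(reads, index, breadth_threshold = 0.90,
                           min_identity = 0.85, seed_length = 21) {
  stopifnot(inherits(index, "marker_index"),
            nrow(index$representatives) > 0)
  reps <- setNames(index$representatives$sequence,
                   index$representatives$rep_id)
  aln <- map_reads(reads, reps, min_identity = min_identity,
                   seed_length = seed_length)
  covered_reps <- character(0)
  if (nrow(aln)) {
    for (rid in unique(aln$target_id)) {
      sub <- aln[aln$target_id == rid, , drop = FALSE]
      tr <- coverage_track(sub, nchar(reps[[rid]]))
      if (breadth(tr) > breadth_threshold)
        covered_reps <- c(covered_reps, rid)
    }
  }
  mem <- index$membership
  genome_ids <- sort(unique(mem$genome_id))
  cov_fam <- lapply(genome_ids, function(g) {
    rows <- mem$genome_id == g & mem$rep_id %in% covered_reps
    sort(unique(mem$family[rows]))
  })
  names(cov_fam) <- genome_ids
  out <- data.frame(
    genome_id = genome_ids,
    families_covered = vapply(cov_fam, length, integer(1)),
    family_total = index$family_count,
    stringsAsFactors = FALSE)
  out$fraction_covered <- out$families_covered / out$family_total
  rownames(out) <- NULL
  attr(out, "covered_families") <- cov_fam
  class(out) <- c("marker_profiles", "data.frame")
  out
}

#' Select reference genomes from marker-coverage profiles
#'
#' A genome is retained when its fraction of covered marker families is at
#' least `min_fraction` (inclusive, "at least 75%"); the per-gene breadth
#' rule upstream is strict ("exceeds 90%"). The denominator is the fixed
#' universal family count, not the number of families annotated for the
#' genome, so genomes with missing annotations are penalized.
#'
#' @param profiles a [screen_markers()] result.
#' @param min_fraction inclusive selection threshold (default 0.75).
#' @return character vector of selected genome ids, sorted by fraction
#'   covered (descending) then id (ascending). An empty vector is a legal
#'   outcome and carries attribute `no_reference_recruited = TRUE` so the
#'   pipeline can terminate gracefully.
#' @export
select_references <- function(profiles, min_fraction = 0.75) {
  keep <- profiles$fraction_covered >= min_fraction
  sel <- profiles[keep, , drop = FALSE]
  sel <- sel[order(-sel$fraction_covered, sel$genome_id), , drop = FALSE]
  out <- sel$genome_id
  if (length(out) == 0) attr(out, "no_reference_recruited") <- TRUE
  out
}

#' Write marker-coverage profiles as a tabular report
#'
#' @param profiles a [screen_markers()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  write.table(as.data.frame(profiles), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
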