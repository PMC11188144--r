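# Pileup majority-consensus polishing: the goal is to reconstruct the
# sequence of the sampled organism rather than recapitulate the reference
# guide. Supporting reads are realigned to each contig; reads failing the
# ungapped aligner are split-anchored to detect one short indel. At each
# position with enough depth, the majority symbol (base, deletion, or
# base plus insertion) replaces the contig symbol; everything else keeps
# the reference base.

# Parse "pos:base,pos:base" edit strings into a two-column data.frame.
parse_edits <- function(edit_strings) {
  nz <- edit_strings[nzchar(edit_strings)]
  if (length(nz) == 0)
    return(data.frame(pos = integer(0), base = character(0)))
  parts <- unlist(strsplit(nz, ",", fixed = TRUE))
  pos <- as.integer(sub(":.*", "", parts))
  base <- sub(".*:", "", parts)
  data.frame(pos = pos, base = base, stringsAsFactors = FALSE)
}

#' Build a per-position pileup for one contig
#'
#' Reads are realigned to the contig with the internal ungapped aligner;
#' reads whose best ungapped placement fails the identity threshold are
#' split-anchored on their first and last `seed_length` bases to detect a
#' single indel of at most `max_indel` bases, contributing deletion marks
#' or insertion observations plus flank coverage.
#'
#' @param contig_seq the contig sequence (single string).
#' @param reads named character vector of the contig's supporting reads.
#' @param config a [metaguide_config()].
#' @return object of class `pileup`: list with `counts` (4 x L matrix,
#'   rows A/C/G/T), `del` (length-L deletion marks), `ins` (named list:
#'   position after which insertion occurs -> table of inserted strings),
#'   `depth` (reads contributing a base or deletion mark per position),
#'   `n_reads` (alignments contributing).
#' @export
build_pileup <- function(contig_seq, reads, config = metaguide_config()) {
  contig_seq <- toupper(as.character(contig_seq)[1])
  L <- nchar(contig_seq)
  counts <- matrix(0L, nrow = 4, ncol = L,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  del <- integer(L)
  ins <- list()
  n_aln <- 0L
  depth <- integer(L)
  mism <- integer(L)
  edit_rows <- list()

  add_interval <- function(s, e) {  # 0-based half-open
    if (e > s) depth[(s + 1L):e] <<- depth[(s + 1L):e] + 1L
  }

  if (length(reads)) {
    aln <- map_reads(reads, c(contig = contig_seq),
                     min_identity = config$min_identity,
                     seed_length = config$seed_length)
    if (nrow(aln)) {
      n_aln <- n_aln + nrow(aln)
      delta <- tabulate(aln$start + 1L, nbins = L) -
        tabulate(aln$end + 1L, nbins = L + 1L)[seq_len(L)]
      depth <- depth + cumsum(delta)
      edit_rows[[1]] <- parse_edits(aln$edits)
    }
    unmapped <- setdiff(names(reads), if (nrow(aln)) aln$read_id else character(0))
    for (rid in unmapped) {
      hit <- .indel_align_cpp(reads[[rid]], contig_seq,
                              as.integer(config$seed_length),
                              as.integer(config$max_indel),
                              as.numeric(config$min_identity))
      if (!isTRUE(hit$found)) next
      n_aln <- n_aln + 1L
      add_interval(hit$left_interval[1], hit$left_interval[2])
      add_interval(hit$right_interval[1], hit$right_interval[2])
      edit_rows[[length(edit_rows) + 1L]] <-
        parse_edits(c(hit$edits_left, hit$edits_right))
      if (hit$indel_len > 0) {  # deletion of target bases
        dpos <- hit$left_start + hit$breakpoint
        ix <- (dpos + 1L):(dpos + hit$indel_len)
        del[ix] <- del[ix] + 1L
      } else {                  # insertion after target position
        key <- as.character(hit$left_start + hit$breakpoint - 1L)
        cur <- ins[[key]]
        if (is.null(cur)) cur <- integer(0)
        cur[hit$ins_seq] <- (if (hit$ins_seq %in% names(cur))
          cur[[hit$ins_seq]] else 0L) + 1L
        ins[[key]] <- cur
      }
    }
  }

  edits <- if (length(edit_rows)) do.call(rbind, edit_rows)
           else data.frame(pos = integer(0), base = character(0))
  # base counts: matched depth goes to the contig base, mismatches to the
  # read base
  if (nrow(edits)) {
    edits <- edits[edits$base %in% rownames(counts), , drop = FALSE]
    tab <- table(factor(edits$base, levels = rownames(counts)),
                 factor(edits$pos, levels = as.character(seq_len(L) - 1L)))
    counts <- counts + matrix(as.integer(tab), nrow = 4,
                              dimnames = dimnames(counts))
    mism <- as.integer(colSums(tab))
  }
  ref_chars <- strsplit(contig_seq, "")[[1]]
  match_depth <- depth - mism
  ok <- ref_chars %in% rownames(counts)
  ridx <- match(ref_chars[ok], rownames(counts))
  cidx <- which(ok)
  counts[cbind(ridx, cidx)] <- counts[cbind(ridx, cidx)] +
    match_depth[ok]
  structure(list(counts = counts, del = del, ins = ins,
                 depth = depth + del, n_reads = n_aln,
                 ref = ref_chars), class = "pileup")
}

#' Majority-consensus polish of one contig
#'
#' At each position with total depth at least `min_depth`, the symbol
#' (base, deletion, or following insertion) supported by at least the
#' `majority` fraction of overlapping reads replaces the contig symbol;
#' ties at exactly the threshold favor the existing base (conservative).
#' Positions below `min_depth` or without a majority keep the reference
#' base and are tallied as `unchanged_low_depth`.
#'
#' @param contig_seq the contig sequence.
#' @param pileup a [build_pileup()] result for this contig.
#' @param min_depth minimum evidence depth (default 2).
#' @param majority required supporting fraction (default 0.6).
#' @return list with `sequence` (polished string, length may change via
#'   indels) and `report` (data.frame `position` (1-based on the input
#'   contig), `type` in snp/del/ins, `ref`, `alt`, `support`, `depth`)
#'   plus `unchanged_low_depth`.
#' @export
consensus_polish <- function(contig_seq, pileup, min_depth = 2,
                             majority = 0.6) {
  stopifnot(inherits(pileup, "pileup"))
  contig_seq <- toupper(as.character(contig_seq)[1])
  L <- nchar(contig_seq)
  ref <- pileup$ref
  depth <- pileup$depth
  counts <- pileup$counts
  out <- ref
  drop_pos <- logical(L)
  changes <- list()
  low_depth <- 0L

  # candidate positions: where some non-reference symbol has any support
  ref_idx <- match(ref, rownames(counts))
  ref_count <- ifelse(is.na(ref_idx), 0L,
                      counts[cbind(ref_idx, seq_len(L))])
  nonref <- colSums(counts) + pileup$del - ref_count
  cand <- which(nonref > 0)
  for (p in cand) {
    d <- depth[p]
    if (d < min_depth) { low_depth <- low_depth + 1L; next }
    sym_counts <- c(counts[, p], DEL = pileup$del[p])
    best <- which.max(sym_counts)   # first max: A<C<G<T<DEL order, stable
    sup <- sym_counts[[best]]
    sym <- names(sym_counts)[best]
    if (sym == ref[p]) next
    if (sup / d < majority) next
    # a literal tie in support between challenger and reference base is
    # resolved conservatively toward the reference
    if (sup == ref_count[p]) next
    if (sym == "DEL") {
      drop_pos[p] <- TRUE
      changes[[length(changes) + 1L]] <- data.frame(
        position = p, type = "del", ref = ref[p], alt = "-",
        support = sup, depth = d, stringsAsFactors = FALSE)
    } else {
      out[p] <- sym
      changes[[length(changes) + 1L]] <- data.frame(
        position = p, type = "snp", ref = ref[p], alt = sym,
        support = sup, depth = d, stringsAsFactors = FALSE)
    }
  }

  ins_after <- rep(NA_character_, L + 1L)  # index i = after position i-1
  for (key in names(pileup$ins)) {
    p <- as.integer(key)  # 0-based position the insertion follows
    if (p < 0 || p >= L) next
    d <- depth[p + 1L]
    if (d < min_depth) { low_depth <- low_depth + 1L; next }
    tab <- pileup$ins[[key]]
    best <- which.max(tab)
    if (tab[[best]] / d >= majority) {
      ins_after[p + 2L] <- names(tab)[best]
      changes[[length(changes) + 1L]] <- data.frame(
        position = p + 1L, type = "ins", ref = ref[p + 1L],
        alt = names(tab)[best], support = tab[[best]], depth = d,
        stringsAsFactors = FALSE)
    }
  }

  pieces <- out
  pieces[drop_pos] <- ""
  has_ins <- which(!is.na(ins_after))
  for (i in has_ins) {
    if (i <= L) pieces[i] <- paste0(ins_after[i], pieces[i])
  }
  polished <- paste0(paste(pieces, collapse = ""),
                     if (!is.na(ins_after[L + 1L])) ins_after[L + 1L] else "")
  report <- if (length(changes)) do.call(rbind, changes)
            else data.frame(position = integer(0), type = character(0),
                            ref = character(0), alt = character(0),
                            support = integer(0), depth = integer(0))
  list(sequence = polished, report = report,
       unchanged_low_depth = low_depth)
}

#' Polish a set of contigs with their supporting reads
#'
#' @param contigs contig data.frame from [assemble_cluster()] (with the
#'   `"supporting_reads"` attribute).
#' @param reads the full read set (named character vector).
#' @param config a [metaguide_config()].
#' @return list with `contigs` (same frame, `sequence` replaced by the
#'   polished sequence; original kept as `unpolished_sequence`) and
#'   `report` (row-bound change reports with a `contig_id` column).
#' @export
polish_contigs <- function(contigs, reads, config = metaguide_config()) {
  supp <- attr(contigs, "supporting_reads")
  reports <- list()
  polished <- contigs
  polished$unpolished_sequence <- contigs$sequence
  for (i in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[i]
    rs <- reads[intersect(supp[[cid]], names(reads))]
    pu <- build_pileup(contigs$sequence[i], rs, config)
    res <- consensus_polish(contigs$sequence[i], pu,
                            min_depth = config$polish_min_depth,
                            majority = config$polish_majority)
    polished$sequence[i] <- res$sequence
    if (nrow(res$report)) {
      res$report$contig_id <- cid
      reports[[length(reports) + 1L]] <- res$report
    }
  }
  report <- if (length(reports)) do.call(rbind, reports)
            else data.frame(position = integer(0), type = character(0),
                            ref = character(0), alt = character(0),
                            support = integer(0), depth = integer(0),
                            contig_id = character(0))
  attr(polished, "supporting_reads") <- supp
  list(contigs = polished, report = report)
}
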