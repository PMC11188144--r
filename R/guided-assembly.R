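# Cluster-based greedy assembly: within a species cluster, order the
# references by MinHash containment with the unassigned reads, recruit
# reads against each guide in turn, carve contigs out of the covered
# reference segments, and stop at the first of the four termination
# criteria: (i) all reads assembled, (ii) all references assembled,
# (iii) cumulative contig length below 5% of the guide, (iv) longest
# contig shorter than 2 kb. Singleton clusters retain their assembly even
# when (iii)/(iv) fire.

#' Choose the next guide genome within a cluster
#'
#' Greedy set-cover step: the member genome whose sketch has maximal
#' containment in the unassigned-read k-mer set (ties: longer genome,
#' then id ascending).
#'
#' @param remaining_genomes named character vector of candidate guide
#'   sequences still unprocessed in the cluster.
#' @param read_kmers `kmer_set` of the unassigned reads at the sketch k.
#' @param s sketch size (default 1000).
#' @return the chosen genome id.
#' @export
order_next_genome <- function(remaining_genomes, read_kmers, s = 1000) {
  stopifnot(length(remaining_genomes) >= 1)
  ids <- names(remaining_genomes)
  cont <- vapply(ids, function(g) {
    sk <- bottom_sketch(
      build_kmer_set(remaining_genomes[[g]], k = read_kmers$k,
                     hash_seed = read_kmers$seed, source_id = g), s)
    containment(sk, read_kmers)
  }, numeric(1))
  lens <- nchar(remaining_genomes)
  ids[order(-cont, -lens, ids)][1]
}

#' Assemble unassigned reads against one guide genome
#'
#' Maps the reads to the guide, computes the coverage track, and turns
#' every maximal depth >= 1 run of at least `min_contig` bases into a
#' contig carrying the guide's sequence over the run. Shorter runs are
#' discarded and their reads are NOT marked used (they return to the
#' unassigned pool). AGP v2.1 records tile the full guide, alternating
#' contig (W) parts and N gaps over uncovered or discarded runs.
#'
#' @param reads named character vector of unassigned reads.
#' @param guide single named character: the guide genome sequence.
#' @param config a [metaguide_config()].
#' @return list with `contigs` (data.frame `contig_id`, `sequence`,
#'   `guide_genome_id`, `guide_start`, `guide_end`, and supporting read
#'   ids as the `"supporting_reads"` attribute, a named list),
#'   `agp` (data.frame of AGP records), `used_read_ids`,
#'   `alignments` (the retained reads' alignments, for polishing).
#' @export
assemble_against_reference <- function(reads, guide, config = metaguide_config()) {
  guide_id <- names(guide)[1]
  stopifnot(!is.null(guide_id))
  glen <- nchar(guide[[1]])
  empty <- list(
    contigs = empty_contigs(), agp = agp_records(guide_id, glen, NULL),
    used_read_ids = character(0),
    alignments = NULL)
  if (length(reads) == 0) return(empty)
  aln <- map_reads(reads, guide, min_identity = config$min_identity,
                   seed_length = config$seed_length)
  if (nrow(aln) == 0) return(empty)
  track <- coverage_track(aln, glen)
  runs <- covered_runs(track)
  runs <- runs[runs$end - runs$start >= config$min_contig, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)

  # each alignment lies entirely inside exactly one covered run; findInterval
  # against run starts locates it
  run_ix <- findInterval(aln$start, runs$start)
  inside <- run_ix >= 1 & aln$end <= runs$end[pmax(run_ix, 1L)]
  keep_aln <- aln[inside, , drop = FALSE]
  run_of <- run_ix[inside]

  contig_ids <- sprintf("%s_%d", guide_id, seq_len(nrow(runs)))
  contigs <- data.frame(
    contig_id = contig_ids,
    sequence = substring(guide[[1]], runs$start + 1L, runs$end),
    guide_genome_id = guide_id,
    guide_start = runs$start, guide_end = runs$end,
    stringsAsFactors = FALSE)
  attr(contigs, "supporting_reads") <-
    setNames(split(keep_aln$read_id, factor(run_of, levels = seq_len(nrow(runs)))),
             contig_ids)
  list(contigs = contigs,
       agp = agp_records(guide_id, glen, runs, contig_ids),
       used_read_ids = unique(keep_aln$read_id),
       alignments = keep_aln)
}

empty_contigs <- function() {
  out <- data.frame(contig_id = character(0), sequence = character(0),
                    guide_genome_id = character(0),
                    guide_start = integer(0), guide_end = integer(0),
                    stringsAsFactors = FALSE)
  attr(out, "supporting_reads") <- list()
  out
}

# AGP v2.1 rows tiling [1, glen] for one guide: W parts for retained runs
# (0-based half-open in `runs`), N gaps elsewhere.
agp_records <- function(object_id, glen, runs, contig_ids = character(0)) {
  rows <- list()
  pos <- 1L  # 1-based next free coordinate
  part <- 0L
  add <- function(row) rows[[length(rows) + 1L]] <<- row
  n_runs <- if (is.null(runs)) 0L else nrow(runs)
  if (n_runs) for (i in seq_len(n_runs)) {
    s1 <- runs$start[i] + 1L; e1 <- runs$end[i]
    if (s1 > pos) {
      part <- part + 1L
      add(data.frame(object = object_id, object_beg = pos,
                     object_end = s1 - 1L, part_number = part,
                     component_type = "N", component_id = as.character(s1 - pos),
                     component_beg = "contig", component_end = "no",
                     orientation = "na", stringsAsFactors = FALSE))
    }
    part <- part + 1L
    add(data.frame(object = object_id, object_beg = s1, object_end = e1,
                   part_number = part, component_type = "W",
                   component_id = contig_ids[i],
                   component_beg = "1", component_end = as.character(e1 - s1 + 1L),
                   orientation = "+", stringsAsFactors = FALSE))
    pos <- e1 + 1L
  }
  if (pos <= glen) {
    part <- part + 1L
    add(data.frame(object = object_id, object_beg = pos, object_end = glen,
                   part_number = part, component_type = "N",
                   component_id = as.character(glen - pos + 1L),
                   component_beg = "contig", component_end = "no",
                   orientation = "na", stringsAsFactors = FALSE))
  }
  if (length(rows) == 0) return(data.frame(
    object = character(0), object_beg = integer(0), object_end = integer(0),
    part_number = integer(0), component_type = character(0),
    component_id = character(0), component_beg = character(0),
    component_end = character(0), orientation = character(0),
    stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Write AGP v2.1
#'
#' @param agp data.frame of AGP records (possibly several guides).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  if (nrow(agp))
    writeLines(do.call(paste, c(agp, sep = "\t")), con)
  invisible(path)
}

#' Read an AGP file written by [write_agp()]
#'
#' @param path AGP path.
#' @return data.frame with the nine AGP columns.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) return(agp_records("x", 0L, NULL)[0, ])
  df <- read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  names(df) <- c("object", "object_beg", "object_end", "part_number",
                 "component_type", "component_id", "component_beg",
                 "component_end", "orientation")
  df$object_beg <- as.integer(df$object_beg)
  df$object_end <- as.integer(df$object_end)
  df$part_number <- as.integer(df$part_number)
  df
}

#' Evaluate the four cluster termination criteria
#'
#' Checked after each per-guide assembly, in order: (i) all reads
#' assembled, (ii) all references in the cluster assembled, (iii) the
#' cumulative contig length of this guide's assembly fails to reach 5% of
#' the guide's length, (iv) the longest contig is shorter than 2,000 bp.
#' Criteria (iii)/(iv) are diminishing-returns detectors: in multi-genome
#' clusters they additionally discard the offending guide's result; a
#' singleton cluster retains its assembly regardless.
#'
#' @param last_result an [assemble_against_reference()] result.
#' @param guide_length length of the guide just assembled.
#' @param cluster_size number of genomes in the cluster.
#' @param reads_remaining count of unassigned reads after applying the
#'   result (when kept).
#' @param genomes_remaining count of cluster genomes not yet used as
#'   guides.
#' @param config a [metaguide_config()].
#' @return list(`stop_reason` = one of `"none"`, `"all_reads_assembled"`,
#'   `"all_references_assembled"`, `"cumulative_below_5pct"`,
#'   `"longest_below_2kb"`; `keep_last` = logical).
#' @export
check_termination <- function(last_result, guide_length, cluster_size,
                              reads_remaining, genomes_remaining,
                              config = metaguide_config()) {
  lens <- nchar(last_result$contigs$sequence)
  cum_frac <- sum(lens) / guide_length
  longest <- if (length(lens)) max(lens) else 0L
  iii <- cum_frac < config$min_cumulative_fraction
  iv <- longest < config$min_longest_contig
  if ((iii || iv) && cluster_size > 1) {
    return(list(stop_reason = if (iii) "cumulative_below_5pct"
                else "longest_below_2kb",
                keep_last = FALSE))
  }
  keep <- TRUE
  if (reads_remaining == 0)
    return(list(stop_reason = "all_reads_assembled", keep_last = keep))
  if (genomes_remaining == 0)
    return(list(stop_reason = "all_references_assembled", keep_last = keep))
  if (iii) return(list(stop_reason = "cumulative_below_5pct", keep_last = keep))
  if (iv) return(list(stop_reason = "longest_below_2kb", keep_last = keep))
  list(stop_reason = "none", keep_last = keep)
}

#' Assemble a whole genome cluster
#'
#' Loops [order_next_genome()] -> [assemble_against_reference()] ->
#' [check_termination()], consuming used reads between iterations, and
#' emits a per-genome log (bases assembled, % of the guide, contigs over
#' 2 kb, longest contig, NG25).
#'
#' @param cluster a `genome_cluster`.
#' @param genomes named character vector containing (at least) the cluster
#'   members' sequences.
#' @param reads named character vector of currently unassigned reads.
#' @param config a [metaguide_config()].
#' @return list with `contigs`, `agp`, `used_read_ids`, `stop_reason`,
#'   `log` (per-genome data.frame), `alignments` (named list by guide, for
#'   polishing).
#' @export
assemble_cluster <- function(cluster, genomes, reads,
                             config = metaguide_config()) {
  remaining <- genomes[cluster$genome_ids]
  cluster_size <- length(remaining)
  contigs <- empty_contigs()
  supp <- list()
  agp <- NULL
  used <- character(0)
  aln_by_guide <- list()
  log_rows <- list()
  stop_reason <- "none"
  pool <- reads
  while (length(remaining) > 0) {
    if (length(pool) == 0) { stop_reason <- "all_reads_assembled"; break }
    rk <- build_kmer_set(pool, k = config$k_sketch,
                         hash_seed = config$hash_seed,
                         source_id = "unassigned")
    gid <- order_next_genome(remaining, rk, s = config$sketch_size)
    guide <- remaining[gid]
    res <- assemble_against_reference(pool, guide, config)
    remaining <- remaining[setdiff(names(remaining), gid)]
    dec <- check_termination(
      res, nchar(guide[[1]]), cluster_size,
      reads_remaining = length(pool) - length(res$used_read_ids),
      genomes_remaining = length(remaining), config = config)
    lens <- nchar(res$contigs$sequence)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      cluster_id = cluster$cluster_id, genome_id = gid,
      bases_assembled = sum(lens),
      pct_guide = 100 * sum(lens) / nchar(guide[[1]]),
      contigs_gt2kb = sum(lens > 2000),
      longest_contig = if (length(lens)) max(lens) else 0L,
      ng25 = {
        v <- ng25(lens, nchar(guide[[1]]))
        if (is.na(v)) NA_integer_ else as.integer(v)
      },
      kept = dec$keep_last, stop_reason = dec$stop_reason,
      stringsAsFactors = FALSE)
    if (dec$keep_last && nrow(res$contigs)) {
      supp <- c(supp, attr(res$contigs, "supporting_reads"))
      contigs <- rbind(contigs, res$contigs)
      agp <- rbind(agp, res$agp)
      used <- c(used, res$used_read_ids)
      pool <- pool[setdiff(names(pool), res$used_read_ids)]
      aln_by_guide[[gid]] <- res$alignments
    }
    if (dec$stop_reason != "none") { stop_reason <- dec$stop_reason; break }
  }
  if (stop_reason == "none") stop_reason <- "all_references_assembled"
  attr(contigs, "supporting_reads") <- supp
  list(contigs = contigs, agp = agp, used_read_ids = used,
       stop_reason = stop_reason,
       log = if (length(log_rows)) do.call(rbind, log_rows) else NULL,
       alignments = aln_by_guide)
}
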