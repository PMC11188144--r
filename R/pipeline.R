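# End-to-end orchestration: screen -> select -> cluster -> prioritized
# cluster assembly -> polish, with standard outputs (contigs FASTA,
# polished FASTA, AGP v2.1, references-used report, change report, unused
# reads FASTQ) and the evaluation metrics NG25 and fraction of reads
# mapped. Every numeric constant of the method lives in the config.

#' Pipeline configuration
#'
#' Houses every tunable constant. Defaults: k = 28 for exact intersection
#' counting, k = 21 / sketch size 1000 for containment and ANI sketches,
#' 99% marker clustering identity, per-gene breadth strictly above 0.90,
#' marker fraction at least 0.75, 95% ANI species threshold, 500 bp
#' minimum contig, 2 kb / 5% diminishing-returns termination, aligner
#' identity 0.85 with 21 bp seeds, polishing depth 2 / majority 0.6 with
#' max 10 bp indels, hash seed 42.
#'
#' @param ... named overrides of any default.
#' @return object of class `metaguide_config`.
#' @export
metaguide_config <- function(...) {
  cfg <- list(
    k_intersection = 28L, k_sketch = 21L, sketch_size = 1000L,
    marker_identity = 0.99, marker_breadth = 0.90,
    min_marker_fraction = 0.75, ani_threshold = 95,
    min_contig = 500L, min_longest_contig = 2000L,
    min_cumulative_fraction = 0.05,
    min_identity = 0.85, seed_length = 21L,
    polish_min_depth = 2L, polish_majority = 0.6, max_indel = 10L,
    hash_seed = 42, threads = 1L, family_count = 40L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  fr <- c("marker_identity", "marker_breadth", "min_marker_fraction",
          "min_cumulative_fraction", "min_identity", "polish_majority")
  stopifnot(all(unlist(cfg[fr]) >= 0), all(unlist(cfg[fr]) <= 1),
            cfg$min_contig > 0, cfg$min_longest_contig > 0,
            cfg$ani_threshold > 0, cfg$ani_threshold <= 100)
  structure(cfg, class = "metaguide_config")
}

#' @export
print.metaguide_config <- function(x, ...) {
  cat("<metaguide_config>\n")
  for (n in names(x)) cat(sprintf("  %-24s %s\n", n, format(x[[n]])))
  invisible(x)
}

#' Write / read a config file (JSON)
#'
#' @param config a [metaguide_config()].
#' @param path file path.
#' @return the config (read) or `path` invisibly (write).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(metaguide_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' NG25 of a contig set against a known genome size
#'
#' The size of the largest contig c such that the total length of contigs
#' longer than or equal to c exceeds a quarter of the genome size;
#' `NA` ("undefined") when the total never exceeds it.
#'
#' @param contig_lengths integer vector of contig lengths.
#' @param genome_size known genome size (> 0).
#' @return a length in bases, or `NA_real_` when undefined.
#' @export
ng25 <- function(contig_lengths, genome_size) {
  stopifnot(genome_size > 0)
  if (length(contig_lengths) == 0) return(NA_real_)
  lens <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  hit <- which(cumsum(lens) > genome_size / 4)
  if (length(hit) == 0) return(NA_real_)
  lens[hit[1]]
}

#' Fraction of reads mapped
#'
#' used / total, exactly.
#'
#' @param used number of reads used in the assembly process.
#' @param total total reads in the sample (> 0).
#' @return fraction in \[0, 1\].
#' @export
fraction_reads_mapped <- function(used, total) {
  if (total <= 0) stop("total read count must be positive")
  stopifnot(used >= 0, used <= total)
  used / total
}

#' Run the full reference-guided assembly pipeline
#'
#' Stages: build (or accept) the marker index; screen reads against marker
#' representatives; select reference genomes covering at least 75% of the
#' marker families; cluster the selection at 95% ANI; assemble clusters in
#' order of exact k-mer intersection with the unassigned reads; polish
#' contigs by pileup majority consensus; export everything, including all
#' reads not used by any cluster (for downstream de novo assembly). An
#' empty selection is a legal outcome: the run stops gracefully with an
#' explicit no-reference-recruited summary.
#'
#' @param reads named character vector of reads, or FASTQ path(s).
#' @param genomes named character vector of reference genomes, or FASTA
#'   path(s).
#' @param marker_annotations annotation table (path or data.frame); ignored
#'   when `marker_index` is given.
#' @param marker_index optional prebuilt [build_marker_index()] result.
#' @param config a [metaguide_config()].
#' @param out_dir optional output directory; when given, all standard
#'   output files are written there.
#' @return object of class `run_summary`: list with `contigs` (polished),
#'   `agp`, `per_genome_log`, `cluster_log`, `references_used`,
#'   `used_read_ids` (mate-expanded), `unused_read_ids`,
#'   `aligned_read_count`, `fraction_reads_mapped`, `total_bases_assembled`,
#'   `contig_count`, `polish_report`, `no_reference_recruited`, `profiles`.
#' @export
run_pipeline <- function(reads, genomes, marker_annotations = NULL,
                         marker_index = NULL,
                         config = metaguide_config(), out_dir = NULL) {
  qualities <- NULL
  if (is.character(reads) && is.null(names(reads)) &&
      all(file.exists(reads))) {
    reads <- read_fastq(reads)
  }
  qualities <- attr(reads, "qualities")
  reads <- as_seq_vector(reads)
  if (is.character(genomes) && is.null(names(genomes)) &&
      all(file.exists(genomes)))
    genomes <- read_genomes(genomes)
  genomes <- as_seq_vector(genomes)

  if (is.null(marker_index)) {
    stopifnot(!is.null(marker_annotations))
    marker_index <- build_marker_index(
      genomes, marker_annotations,
      identity_threshold = config$marker_identity,
      family_count = config$family_count)
  }

  all_ids <- names(reads)
  summary_base <- list(config = config, total_reads = length(reads))

  empty_summary <- function(profiles) {
    out <- c(summary_base, list(
      profiles = profiles, references_used = character(0),
      contigs = empty_contigs(), agp = agp_records("none", 0L, NULL)[0, ],
      per_genome_log = NULL, cluster_log = NULL,
      used_read_ids = character(0), unused_read_ids = all_ids,
      aligned_read_count = 0L, fraction_reads_mapped = 0,
      total_bases_assembled = 0, contig_count = 0L,
      polish_report = NULL, no_reference_recruited = TRUE,
      stop_reasons = character(0)))
    class(out) <- "run_summary"
    out
  }

  if (length(reads) == 0) {
    res <- empty_summary(NULL)
    if (!is.null(out_dir)) write_outputs(res, reads, qualities, out_dir)
    return(res)
  }

  profiles <- screen_markers(reads, marker_index,
                             breadth_threshold = config$marker_breadth,
                             min_identity = config$min_identity,
                             seed_length = config$seed_length)
  selected <- select_references(profiles,
                                min_fraction = config$min_marker_fraction)
  if (length(selected) == 0) {
    res <- empty_summary(profiles)
    if (!is.null(out_dir)) write_outputs(res, reads, qualities, out_dir)
    return(res)
  }

  clusters <- cluster_by_ani(genomes[selected],
                             ani_threshold = config$ani_threshold,
                             k = config$k_sketch, s = config$sketch_size,
                             hash_seed = config$hash_seed,
                             k_intersection = config$k_intersection)

  unassigned <- reads
  remaining <- clusters
  contigs <- empty_contigs(); supp <- list()
  agp <- NULL; logs <- list(); clog <- list()
  used <- character(0); stop_reasons <- character(0)
  aln_store <- list()
  order_i <- 0L
  while (length(remaining) > 0 && length(unassigned) > 0) {
    rk <- build_kmer_set(unassigned, k = config$k_intersection,
                         hash_seed = config$hash_seed,
                         source_id = "unassigned")
    nx <- next_cluster(remaining, rk)
    if (identical(nx, "done")) break
    order_i <- order_i + 1L
    res <- assemble_cluster(nx, genomes, unassigned, config)
    remaining <- Filter(function(cl) cl$cluster_id != nx$cluster_id,
                        remaining)
    clog[[length(clog) + 1L]] <- data.frame(
      cluster_id = nx$cluster_id,
      members = paste(nx$genome_ids, collapse = ","),
      priority = nx$priority, order_processed = order_i,
      stop_reason = res$stop_reason, stringsAsFactors = FALSE)
    if (nrow(res$contigs)) {
      supp <- c(supp, attr(res$contigs, "supporting_reads"))
      contigs <- rbind(contigs, res$contigs)
      agp <- rbind(agp, res$agp)
    }
    if (!is.null(res$log)) logs[[length(logs) + 1L]] <- res$log
    used <- c(used, res$used_read_ids)
    stop_reasons <- c(stop_reasons, res$stop_reason)
    unassigned <- unassigned[setdiff(names(unassigned), res$used_read_ids)]
  }
  skipped <- vapply(remaining, function(cl) cl$cluster_id, numeric(1))
  for (cid in skipped)
    clog[[length(clog) + 1L]] <- data.frame(
      cluster_id = cid,
      members = paste(clusters[[which(vapply(clusters, function(x)
        x$cluster_id, numeric(1)) == cid)]]$genome_ids, collapse = ","),
      priority = 0, order_processed = NA_integer_,
      stop_reason = "skipped", stringsAsFactors = FALSE)

  attr(contigs, "supporting_reads") <- supp
  pol <- polish_contigs(contigs, reads, config)

  used_expanded <- expand_mates(unique(used), all_ids)
  unused <- setdiff(all_ids, used_expanded)
  lens <- nchar(pol$contigs$sequence)
  res <- c(summary_base, list(
    profiles = profiles,
    references_used = sort(unique(contigs$guide_genome_id)),
    contigs = pol$contigs,
    agp = agp,
    per_genome_log = if (length(logs)) do.call(rbind, logs) else NULL,
    cluster_log = if (length(clog)) do.call(rbind, clog) else NULL,
    used_read_ids = used_expanded,
    unused_read_ids = unused,
    aligned_read_count = length(unique(used)),
    fraction_reads_mapped =
      fraction_reads_mapped(length(used_expanded), length(all_ids)),
    total_bases_assembled = sum(lens),
    contig_count = length(lens),
    polish_report = pol$report,
    no_reference_recruited = FALSE,
    stop_reasons = stop_reasons))
  class(res) <- "run_summary"
  if (!is.null(out_dir)) write_outputs(res, reads, qualities, out_dir)
  res
}

#' @export
print.run_summary <- function(x, ...) {
  cat("<run_summary>\n")
  if (x$no_reference_recruited) {
    cat("  no reference recruited: nothing to assemble\n")
  } else {
    cat(sprintf("  references used:      %d (%s)\n",
                length(x$references_used),
                paste(x$references_used, collapse = ", ")))
    cat(sprintf("  contigs:              %d (%.0f bases)\n",
                x$contig_count, x$total_bases_assembled))
    cat(sprintf("  fraction reads mapped: %.4f\n", x$fraction_reads_mapped))
  }
  invisible(x)
}

# Write the standard output files for a run.
write_outputs <- function(summary, reads, qualities, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  ct <- summary$contigs
  if (!is.null(ct$unpolished_sequence))
    write_fasta(setNames(ct$unpolished_sequence, ct$contig_id),
                p("contigs.fasta"))
  else write_fasta(setNames(ct$sequence, ct$contig_id), p("contigs.fasta"))
  write_fasta(setNames(ct$sequence, ct$contig_id),
              p("contigs.polished.fasta"))
  write_agp(if (is.null(summary$agp)) agp_records("none", 0L, NULL)[0, ]
            else summary$agp, p("assembly.agp"))
  writeLines(summary$references_used, p("references_used.txt"))
  if (!is.null(summary$per_genome_log))
    write.table(summary$per_genome_log, p("assembly_log.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(summary$cluster_log))
    write.table(summary$cluster_log, p("cluster_log.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(summary$polish_report))
    write.table(summary$polish_report, p("polish_changes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(summary$profiles)) write_profiles(summary$profiles,
                                                 p("marker_profiles.tsv"))
  unused <- summary$unused_read_ids
  q <- NULL
  if (!is.null(qualities) && length(reads))
    q <- qualities[match(unused, names(reads))]
  write_fastq(reads[unused], p("unused_reads.fastq"), qualities = q)
  writeLines(summary$used_read_ids, p("used_read_ids.txt"))
  jsonlite::write_json(list(
    no_reference_recruited = summary$no_reference_recruited,
    total_reads = summary$total_reads,
    references_used = summary$references_used,
    contig_count = summary$contig_count,
    total_bases_assembled = summary$total_bases_assembled,
    aligned_read_count = summary$aligned_read_count,
    fraction_reads_mapped = summary$fraction_reads_mapped,
    stop_reasons = summary$stop_reasons),
    p("summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
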