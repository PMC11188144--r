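# Marker-gene index: extract annotated single-copy marker sequences from
# reference genomes and cluster them per family at 99% identity, keeping
# cluster founders as representatives (the cd-hit-est -c 0.99 stand-in).
# The index is reusable across runs and is the alignment target set for
# sample-specific reference selection.

#' Load marker-gene annotations and materialize sequences
#'
#' Consumes a tabular annotation file (stand-in for upstream marker-gene
#' detection): tab-separated with header `genome_id`, `family`, `start`,
#' `end` (0-based half-open). BED is also accepted (chrom, start, end,
#' name) with the family number in the name column.
#'
#' @param genomes named character vector of genome sequences, or FASTA
#'   paths (read via [read_genomes()]).
#' @param annotations path to the annotation table, or a data.frame with
#'   the same columns.
#' @return data.frame of class `marker_genes`: `genome_id`, `family`,
#'   `start`, `end`, `sequence`, `gene_id`.
#' @export
load_marker_annotations <- function(genomes, annotations) {
  if (is.character(genomes) && all(file.exists(genomes)) &&
      is.null(names(genomes)))
    genomes <- read_genomes(genomes)
  genomes <- as_seq_vector(genomes)
  ann <- annotations
  if (is.character(ann)) {
    first <- readLines(ann, n = 1)
    if (grepl("^genome_id\t", first)) {
      ann <- read.delim(ann, stringsAsFactors = FALSE)
    } else {  # BED: chrom start end name
      ann <- read.delim(ann, header = FALSE, stringsAsFactors = FALSE)[, 1:4]
      names(ann) <- c("genome_id", "start", "end", "family")
      ann <- ann[, c("genome_id", "family", "start", "end")]
    }
  }
  if (nrow(ann) == 0)
    return(structure(
      data.frame(genome_id = character(0), family = integer(0),
                 start = integer(0), end = integer(0),
                 sequence = character(0), gene_id = character(0)),
      class = c("marker_genes", "data.frame")))
  ann$family <- as.integer(ann$family)
  ann$start <- as.integer(ann$start); ann$end <- as.integer(ann$end)
  for (i in seq_len(nrow(ann))) {
    g <- ann$genome_id[i]
    if (!g %in% names(genomes))
      stop("annotation row ", i, ": unknown genome id '", g, "'")
    if (ann$start[i] < 0 || ann$end[i] > nchar(genomes[[g]]) ||
        ann$end[i] <= ann$start[i])
      stop("annotation row ", i, ": interval [", ann$start[i], ", ",
           ann$end[i], ") out of bounds for genome '", g, "'")
  }
  key <- paste(ann$genome_id, ann$family)
  if (anyDuplicated(key))
    stop("duplicate (genome, family) pair at annotation row ",
         which(duplicated(key))[1], ": markers are single-copy")
  ann$sequence <- substring(genomes[ann$genome_id], ann$start + 1L, ann$end)
  ann$gene_id <- paste0(ann$genome_id, "|", ann$family)
  structure(ann[, c("genome_id", "family", "start", "end", "sequence",
                    "gene_id")],
            class = c("marker_genes", "data.frame"))
}

#' Pairwise identity of two marker sequences
#'
#' matches / alignment columns of the minimum-edit banded global alignment
#' (band 5% of the longer length, floor 10, widened by the length
#' difference). This is the declared identity definition behind the 99%
#' marker clustering threshold.
#'
#' @param a,b DNA strings.
#' @return identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  .banded_identity_cpp(as.character(a)[1], as.character(b)[1], 0.05)
}

#' Greedy per-family identity clustering of marker genes
#'
#' Within each marker family independently, genes are processed
#' longest-first (ties: gene id ascending); each gene joins the first
#' existing representative it matches at `identity_threshold` or better,
#' otherwise founds a new cluster. Representatives are cluster founders,
#' matching the greedy incremental convention.
#'
#' @param genes a [load_marker_annotations()] result.
#' @param identity_threshold minimum identity to join a cluster
#'   (default 0.99).
#' @param family_count number of marker families in the universal set
#'   (default 40).
#' @return object of class `marker_index`: list with `representatives`
#'   (marker_genes rows, plus `rep_id`), `membership` (data.frame
#'   `gene_id`, `genome_id`, `family`, `rep_id`), `family_count`,
#'   `identity_threshold`.
#' @export
greedy_identity_cluster <- function(genes, identity_threshold = 0.99,
                                    family_count = 40) {
  stopifnot(nrow(genes) > 0)
  membership <- vector("list", 0)
  rep_rows <- vector("list", 0)
  for (fam in sort(unique(genes$family))) {
    fg <- genes[genes$family == fam, , drop = FALSE]
    ord <- order(-nchar(fg$sequence), fg$gene_id)
    fg <- fg[ord, , drop = FALSE]
    reps <- integer(0)  # row indices into fg
    assign_to <- integer(nrow(fg))
    for (i in seq_len(nrow(fg))) {
      hit <- 0L
      for (r in reps) {
        ident <- pairwise_identity(fg$sequence[i], fg$sequence[r])
        if (ident >= identity_threshold) { hit <- r; break }
      }
      if (hit == 0L) { reps <- c(reps, i); hit <- i }
      assign_to[i] <- hit
    }
    rep_ids <- paste0("rep|", fg$gene_id[reps])
    names(rep_ids) <- as.character(reps)
    rep_rows[[length(rep_rows) + 1L]] <-
      cbind(fg[reps, , drop = FALSE],
            rep_id = rep_ids, stringsAsFactors = FALSE)
    membership[[length(membership) + 1L]] <- data.frame(
      gene_id = fg$gene_id, genome_id = fg$genome_id, family = fg$family,
      rep_id = rep_ids[as.character(assign_to)], stringsAsFactors = FALSE)
  }
  representatives <- do.call(rbind, rep_rows)
  rownames(representatives) <- NULL
  membership <- do.call(rbind, membership)
  rownames(membership) <- NULL
  structure(list(representatives = representatives,
                 membership = membership,
                 family_count = as.integer(family_count),
                 identity_threshold = identity_threshold),
            class = "marker_index")
}

#' @export
print.marker_index <- function(x, ...) {
  cat(sprintf(
    "<marker_index> %d genes in %d clusters across %d families (threshold %.2f)\n",
    nrow(x$membership), nrow(x$representatives),
    length(unique(x$membership$family)), x$identity_threshold))
  invisible(x)
}

#' Build the marker index from genomes plus annotations
#'
#' Convenience wrapper: [load_marker_annotations()] then
#' [greedy_identity_cluster()].
#'
#' @inheritParams load_marker_annotations
#' @inheritParams greedy_identity_cluster
#' @return a `marker_index`.
#' @export
build_marker_index <- function(genomes, annotations,
                               identity_threshold = 0.99,
                               family_count = 40) {
  greedy_identity_cluster(
    load_marker_annotations(genomes, annotations),
    identity_threshold = identity_threshold, family_count = family_count)
}

#' Persist a marker index (representative FASTA + membership table)
#'
#' @param index a `marker_index`.
#' @param prefix output path prefix; writes `<prefix>.representatives.fasta`
#'   and `<prefix>.membership.tsv`.
#' @return the two paths, invisibly.
#' @export
write_marker_index <- function(index, prefix) {
  fa <- paste0(prefix, ".representatives.fasta")
  tsv <- paste0(prefix, ".membership.tsv")
  write_fasta(setNames(index$representatives$sequence,
                       index$representatives$rep_id), fa)
  meta <- index$membership
  meta$family_count <- index$family_count
  meta$identity_threshold <- index$identity_threshold
  write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, tsv))
}

#' Load a marker index written by [write_marker_index()]
#'
#' @param prefix the prefix passed to [write_marker_index()].
#' @return a `marker_index` (representative sequences re-read from FASTA;
#'   interval columns are not persisted).
#' @export
read_marker_index <- function(prefix) {
  fa <- read_genomes(paste0(prefix, ".representatives.fasta"))
  meta <- read.delim(paste0(prefix, ".membership.tsv"),
                     stringsAsFactors = FALSE)
  reps <- meta[meta$rep_id %in% paste0("rep|", meta$gene_id) &
                 paste0("rep|", meta$gene_id) == meta$rep_id, , drop = FALSE]
  representatives <- data.frame(
    genome_id = reps$genome_id, family = reps$family,
    start = NA_integer_, end = NA_integer_,
    sequence = unname(fa[reps$rep_id]), gene_id = reps$gene_id,
    rep_id = reps$rep_id, stringsAsFactors = FALSE)
  structure(list(
    representatives = representatives,
    membership = meta[, c("gene_id", "genome_id", "family", "rep_id")],
    family_count = meta$family_count[1],
    identity_threshold = meta$identity_threshold[1]),
    class = "marker_index")
}
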