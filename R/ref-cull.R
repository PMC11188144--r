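# Reference culling: group the selected genomes into species-level
# clusters by single-linkage at 95% ANI, then iteratively hand clusters to
# the assembler in order of exact k-mer intersection with the currently
# unassigned reads (recomputed before each selection, so priorities only
# ever shrink as reads are consumed).

#' Cluster selected genomes at an ANI threshold
#'
#' Builds the graph with an edge wherever [estimate_ani()] is at least
#' `ani_threshold` and returns its connected components (single linkage:
#' intra-cluster pairs need only be connected, not pairwise similar).
#' Cluster ids are assigned by the lexicographically smallest member id.
#'
#' @param genomes named character vector of selected genome sequences.
#' @param ani_threshold percent ANI defining the species boundary
#'   (default 95).
#' @param k,s,hash_seed sketching parameters (see [estimate_ani()]).
#' @param k_intersection k-mer length of each cluster's exact k-mer set,
#'   used later for prioritization (default 28).
#' @return list of `genome_cluster` objects: `cluster_id`, `genome_ids`,
#'   `longest_genome_id`, `kmer_set` (the union set at the intersection k),
#'   `priority` (NA until ranked).
#' @export
cluster_by_ani <- function(genomes, ani_threshold = 95, k = 21, s = 1000,
                           hash_seed = 42, k_intersection = 28) {
  genomes <- as_seq_vector(genomes)
  n <- length(genomes)
  stopifnot(n >= 1)
  ids <- names(genomes)
  ksets <- lapply(genomes, build_kmer_set, k = k, hash_seed = hash_seed)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ani <- ani_from_sets(ksets[[i]], ksets[[j]], s)
      if (!is.na(ani) && ani >= ani_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  # deterministic cluster ids by smallest member id
  comp_min <- vapply(comps, function(ix) min(ids[ix]), character(1))
  comps <- comps[order(comp_min)]
  lapply(seq_along(comps), function(ci) {
    ix <- comps[[ci]]
    members <- sort(ids[ix])
    lens <- nchar(genomes[members])
    longest <- members[order(-lens, members)][1]
    structure(list(
      cluster_id = ci,
      genome_ids = members,
      longest_genome_id = longest,
      kmer_set = build_kmer_set(genomes[members], k = k_intersection,
                                hash_seed = hash_seed,
                                source_id = paste0("cluster", ci)),
      priority = NA_real_), class = "genome_cluster")
  })
}

#' @export
print.genome_cluster <- function(x, ...) {
  cat(sprintf("<genome_cluster #%d> %d genomes (%s), priority %s\n",
              x$cluster_id, length(x$genome_ids),
              paste(x$genome_ids, collapse = ", "),
              ifelse(is.na(x$priority), "unranked", x$priority)))
  invisible(x)
}

#' Pick the next cluster to assemble
#'
#' Recomputes each unprocessed cluster's exact k-mer intersection with the
#' unassigned-read k-mer set and returns the argmax (ties: smaller cluster
#' id). Returns the string `"done"` when no cluster intersects the reads
#' at all; clusters never reaching a positive priority are reported as
#' skipped by the pipeline.
#'
#' @param clusters list of unprocessed `genome_cluster`s.
#' @param unassigned_reads `kmer_set` of the unassigned reads, built at
#'   the intersection k (28).
#' @return the chosen `genome_cluster` (with `priority` filled in), or
#'   `"done"`.
#' @export
next_cluster <- function(clusters, unassigned_reads) {
  if (length(clusters) == 0) return("done")
  pri <- vapply(clusters, function(cl)
    as.numeric(kmer_intersection_size(cl$kmer_set, unassigned_reads)),
    numeric(1))
  if (all(pri == 0)) return("done")
  ids <- vapply(clusters, function(cl) cl$cluster_id, numeric(1))
  best <- order(-pri, ids)[1]
  cl <- clusters[[best]]
  cl$priority <- pri[best]
  cl
}

#' Write the cluster report
#'
#' @param clusters list of `genome_cluster`s.
#' @param order_processed integer order in which each was assembled
#'   (NA = skipped).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, order_processed, path) {
  df <- data.frame(
    cluster_id = vapply(clusters, function(x) x$cluster_id, numeric(1)),
    members = vapply(clusters, function(x)
      paste(x$genome_ids, collapse = ","), character(1)),
    longest_member = vapply(clusters, function(x) x$longest_genome_id,
                            character(1)),
    priority = vapply(clusters, function(x) x$priority, numeric(1)),
    order_processed = order_processed,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
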