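# Shared helpers: sequence coercion, seeded evaluation, FASTA/FASTQ I/O.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements (uppercased).
#' @export
revcomp <- function(x) .revcomp_cpp(as.character(x))

# Coerce DNAStringSet / list / character to a named character vector.
as_seq_vector <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.list(x)) x <- unlist(x)
  setNames(as.character(x), names(x))
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards (no hidden global randomness).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, staying < 2^31.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 13) %% 2147483629)
}

#' Read genome sequences from FASTA files
#'
#' Each FASTA record is one reference genome; ids are the first whitespace
#' token of the record header. Handles multi-record files, lowercase
#' sequence, and gzip-compressed input.
#'
#' @param paths character vector of FASTA file paths.
#' @return named character vector of uppercase sequences.
#' @export
read_genomes <- function(paths) {
  sets <- lapply(paths, Biostrings::readDNAStringSet)
  seqs <- do.call(c, sets)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out)))
    stop("duplicate genome ids across FASTA inputs: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read short reads from FASTQ
#'
#' Gzip-transparent. Read ids are truncated at the first whitespace.
#'
#' @param paths one or more FASTQ paths (e.g. R1 and R2 of a pair).
#' @return named character vector of read sequences, with per-read quality
#'   strings attached as the `"qualities"` attribute.
#' @export
read_fastq <- function(paths) {
  # readQualityScaledDNAStringSet warns about dropping its own fastq
  # metadata columns; that is expected and harmless here
  recs <- lapply(paths, function(p) withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(p),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  seqs <- setNames(character(0), character(0)); quals <- character(0)
  for (r in recs) {
    s <- toupper(as.character(r))
    names(s) <- sub("\\s.*$", "", names(r))
    seqs <- c(seqs, s)
    quals <- c(quals, as.character(Biostrings::quality(r)))
  }
  if (is.null(names(seqs))) names(seqs) <- character(0)
  if (anyDuplicated(names(seqs)))
    stop("duplicate read ids in FASTQ input")
  attr(seqs, "qualities") <- unname(quals)
  seqs
}

#' Write reads to FASTQ
#'
#' @param seqs named character vector of read sequences.
#' @param path output path.
#' @param qualities optional character vector of quality strings (defaults
#'   to constant Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, qualities = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs)) {
    if (is.null(qualities)) qualities <- strrep("I", nchar(seqs))
    writeLines(paste0("@", names(seqs), "\n", as.character(seqs), "\n+\n",
                      qualities), con)
  }
  invisible(path)
}

# Mate id under the "/1"-"/2" suffix convention; NA when unpaired.
mate_id <- function(ids) {
  out <- rep(NA_character_, length(ids))
  is1 <- endsWith(ids, "/1")
  is2 <- endsWith(ids, "/2")
  out[is1] <- paste0(substr(ids[is1], 1L, nchar(ids[is1]) - 2L), "/2")
  out[is2] <- paste0(substr(ids[is2], 1L, nchar(ids[is2]) - 2L), "/1")
  out
}

# Expand a set of used read ids with their mates (a pair counts as used
# when either mate is used).
expand_mates <- function(used_ids, all_ids) {
  mates <- mate_id(used_ids)
  union(used_ids, intersect(mates[!is.na(mates)], all_ids))
}
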