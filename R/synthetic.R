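# Seeded synthetic communities with full ground truth: species generated
# as independent random genomes (pairwise ANI undetectable), strains as
# substitution mutants, 40 single-copy marker genes per genome derived
# from fixed per-family ancestors (so homologous families cluster across
# genomes), log-varying abundances, and uniform-coverage reads with i.i.d.
# substitution errors. Everything is deterministic under the given seed.

FAMILY_ANCESTOR_SEED <- 700001L  # fixed: marker homology must hold across
                                 # independently generated genomes

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# The fixed ancestor sequence of marker family f.
family_ancestor <- function(family, marker_length) {
  with_seed(FAMILY_ANCESTOR_SEED + as.integer(family) * 131L +
              as.integer(marker_length),
            random_dna(marker_length, gc = 0.5))
}

#' Generate one reference genome with planted marker genes
#'
#' A random sequence of the requested length and GC content, with
#' `marker_count` non-overlapping marker intervals at deterministic seeded
#' positions (one per equal-width block, guaranteeing disjointness). The
#' family-f marker is the fixed per-family ancestor mutated at
#' `marker_divergence` substitutions, so homologous families cluster
#' across genomes while distinct genomes' copies differ.
#'
#' @param length genome length in bases.
#' @param gc GC fraction (default 0.5).
#' @param marker_count number of marker families planted (default 40).
#' @param marker_length marker gene length (default 1000 bp, realistic for
#'   universal single-copy genes).
#' @param marker_divergence per-genome substitution rate applied to each
#'   family ancestor (default 0.10: inter-species marker identity well
#'   below the 99% clustering threshold).
#' @param seed integer seed.
#' @param genome_id identifier for the genome.
#' @return list with `genome_id`, `sequence`, and `annotations`
#'   (data.frame `genome_id`, `family`, `start`, `end`, 0-based half-open).
#' @export
generate_genome <- function(length, gc = 0.5, marker_count = 40,
                            marker_length = 1000,
                            marker_divergence = 0.10, seed = 1,
                            genome_id = "genome") {
  if (marker_count * marker_length > length / 2)
    stop("infeasible marker placement: markers exceed half the genome")
  ancestors <- vapply(seq_len(marker_count), family_ancestor,
                      character(1), marker_length = marker_length)
  with_seed(seed, {
    seq0 <- random_dna(length, gc)
    block <- length %/% marker_count
    starts <- integer(marker_count)
    for (f in seq_len(marker_count)) {
      lo <- (f - 1L) * block
      hi <- f * block - marker_length
      starts[f] <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    }
    markers <- vapply(seq_len(marker_count), function(f)
      mutate_sequence(ancestors[f], marker_divergence, 0,
                      sample.int(2^31 - 1, 1))$sequence,
      character(1))
    chars <- strsplit(seq0, "")[[1]]
    for (f in seq_len(marker_count)) {
      chars[(starts[f] + 1L):(starts[f] + marker_length)] <-
        strsplit(markers[f], "")[[1]]
    }
    list(genome_id = genome_id,
         sequence = paste(chars, collapse = ""),
         annotations = data.frame(
           genome_id = genome_id, family = seq_len(marker_count),
           start = starts, end = starts + marker_length,
           stringsAsFactors = FALSE))
  })
}

# Core mutator used by both generate_genome (marker divergence) and
# mutate_genome; returns the mutated sequence plus the exact variant list.
mutate_sequence <- function(sequence, subst_rate, indel_rate, seed) {
  with_seed(seed, {
    chars <- strsplit(toupper(sequence), "")[[1]]
    n <- length(chars)
    bases <- c("A", "C", "G", "T")
    variants <- list()
    sub_pos <- which(runif(n) < subst_rate)
    if (length(sub_pos)) {
      old <- chars[sub_pos]
      shift <- sample.int(3, length(sub_pos), replace = TRUE)
      new <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
      chars[sub_pos] <- new
      variants[[1]] <- data.frame(
        position = sub_pos, type = "snp", ref = old, alt = new,
        stringsAsFactors = FALSE)
    }
    pieces <- chars
    if (indel_rate > 0) {
      ind_pos <- which(runif(n) < indel_rate)
      ind_pos <- ind_pos[ind_pos > 1 & ind_pos < n - 6]
      if (length(ind_pos)) {
        # drop overlapping events (min 10 bp apart) for unambiguous truth
        keep <- c(TRUE, diff(ind_pos) > 10)
        ind_pos <- ind_pos[keep]
        lens <- pmin(1L + stats::rgeom(length(ind_pos), 0.5), 5L)
        is_del <- runif(length(ind_pos)) < 0.5
        for (i in seq_along(ind_pos)) {
          p <- ind_pos[i]
          if (is_del[i]) {
            ref <- paste(chars[p:(p + lens[i] - 1L)], collapse = "")
            pieces[p:(p + lens[i] - 1L)] <- ""
            variants[[length(variants) + 1L]] <- data.frame(
              position = p, type = "del", ref = ref, alt = "",
              stringsAsFactors = FALSE)
          } else {
            insseq <- paste(sample(bases, lens[i], replace = TRUE),
                            collapse = "")
            pieces[p] <- paste0(insseq, pieces[p])
            variants[[length(variants) + 1L]] <- data.frame(
              position = p, type = "ins", ref = "", alt = insseq,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    vars <- if (length(variants)) do.call(rbind, variants)
            else data.frame(position = integer(0), type = character(0),
                            ref = character(0), alt = character(0))
    vars <- vars[order(vars$position), , drop = FALSE]
    rownames(vars) <- NULL
    list(sequence = paste(pieces, collapse = ""), variants = vars)
  })
}

#' Mutate a genome into a derived strain
#'
#' i.i.d. substitutions (always to a different base) at `subst_rate` and
#' short indels (1-5 bp, geometric lengths) at `indel_rate`; the returned
#' variant list is the exact ground truth (1-based positions on the input).
#'
#' @param base genome sequence (string) or a [generate_genome()] result.
#' @param subst_rate substitution probability per base (<= 0.2).
#' @param indel_rate indel initiation probability per base (<= 0.2).
#' @param seed integer seed.
#' @return list with `sequence` and `variants`.
#' @export
mutate_genome <- function(base, subst_rate, indel_rate = 0, seed = 1) {
  stopifnot(subst_rate >= 0, subst_rate <= 0.2,
            indel_rate >= 0, indel_rate <= 0.2)
  seqin <- if (is.list(base)) base$sequence else base
  mutate_sequence(seqin, subst_rate, indel_rate, seed)
}

#' Generate the default desk-scale community
#'
#' `n_species` independent random genomes (pairwise ANI undetectable at
#' k = 21), the first species carrying `n_strains` reference strains
#' (substitution mutants at rates spanning roughly 97-99% ANI), plus
#' `n_decoys` absent decoy genomes. The sampled organisms are mutants of
#' one reference per present species at `sample_divergence`. Abundances
#' follow a geometric (log-linear) series with ratio 0.7.
#'
#' @param seed integer community seed.
#' @param n_species number of distinct species present (default 4).
#' @param n_strains reference strains of species 1 (default 3).
#' @param n_decoys absent decoy reference genomes (default 2).
#' @param length_range genome length range in bases (default 100-300 kb).
#' @param strain_rates substitution rates deriving the extra species-1
#'   reference strains (default c(0.01, 0.02)).
#' @param sample_divergence substitution rate between each sample organism
#'   and its nearest reference (default 0.01).
#' @param marker_length,marker_divergence see [generate_genome()].
#' @return object of class `community_truth`: list with `genomes` (named
#'   vector: all references incl. strains and decoys), `annotations`,
#'   `sample_strains` (named by the guide reference id), `abundances`,
#'   `planted_variants` (named list), `present_ids`, `decoy_ids`, `seed`.
#' @export
make_community <- function(seed = 1, n_species = 4, n_strains = 3,
                           n_decoys = 2, length_range = c(100e3, 300e3),
                           strain_rates = c(0.01, 0.02),
                           sample_divergence = 0.01,
                           marker_length = 1000,
                           marker_divergence = 0.10) {
  stopifnot(n_strains >= 1, length(strain_rates) >= n_strains - 1)
  lens <- with_seed(child_seed(seed, "lengths"),
                    round(runif(n_species + n_decoys, length_range[1],
                                length_range[2])))
  genomes <- character(0)
  annotations <- list()
  add_genome <- function(g) {
    genomes[[g$genome_id]] <<- g$sequence
    annotations[[length(annotations) + 1L]] <<- g$annotations
  }
  for (i in seq_len(n_species)) {
    add_genome(generate_genome(
      lens[i], gc = 0.45 + 0.02 * i, marker_length = marker_length,
      marker_divergence = marker_divergence,
      seed = child_seed(seed, paste0("species", i)),
      genome_id = sprintf("sp%d_ref1", i)))
  }
  # extra strains of species 1: mutate the full genome (markers included,
  # so marker clusters can be shared within the species)
  base1 <- genomes[["sp1_ref1"]]
  ann1 <- annotations[[1]]
  for (j in seq_len(n_strains - 1)) {
    mid <- sprintf("sp1_ref%d", j + 1)
    mut <- mutate_genome(base1, strain_rates[j], 0,
                         child_seed(seed, paste0("strain", j)))
    genomes[[mid]] <- mut$sequence
    a <- ann1; a$genome_id <- mid
    annotations[[length(annotations) + 1L]] <- a
  }
  for (d in seq_len(n_decoys)) {
    add_genome(generate_genome(
      lens[n_species + d], gc = 0.5,
      marker_length = marker_length,
      marker_divergence = marker_divergence,
      seed = child_seed(seed, paste0("decoy", d)),
      genome_id = sprintf("decoy%d", d)))
  }
  present <- sprintf("sp%d_ref1", seq_len(n_species))
  sample_strains <- character(0)
  planted <- list()
  for (g in present) {
    mut <- mutate_genome(genomes[[g]], sample_divergence, 0,
                         child_seed(seed, paste0("sample", g)))
    sample_strains[[g]] <- mut$sequence
    planted[[g]] <- mut$variants
  }
  ab <- 0.7^(seq_len(n_species) - 1)
  structure(list(
    genomes = genomes,
    annotations = do.call(rbind, annotations),
    sample_strains = sample_strains,
    abundances = setNames(ab / sum(ab), present),
    planted_variants = planted,
    present_ids = present,
    decoy_ids = if (n_decoys) sprintf("decoy%d", seq_len(n_decoys))
                else character(0),
    seed = seed), class = "community_truth")
}

#' Simulate reads from a community
#'
#' Fragments are drawn from abundance-weighted sample strains at uniform
#' positions; paired mode emits the fragment's two ends (R2 reverse
#' complemented) with normally distributed insert sizes. Substitution
#' errors are i.i.d. Read names encode nothing about the truth; origins
#' live in the returned sidecar table.
#'
#' @param truth a [make_community()] result (or any list with
#'   `sample_strains` and `abundances`).
#' @param read_length read length (default 100).
#' @param total_pairs number of fragments (pairs, or single reads when
#'   `paired = FALSE`).
#' @param depth alternative to `total_pairs`: target mean depth over the
#'   present strains.
#' @param error_rate per-base substitution error rate (default 0.005).
#' @param paired emit pairs (default TRUE).
#' @param insert_mean,insert_sd fragment size distribution (default
#'   300 +/- 30).
#' @param seed integer seed.
#' @return list with `reads` (named character vector), `origins`
#'   (data.frame `read_id`, `genome_id`, `position` 0-based on the sample
#'   strain, `strand`).
#' @export
simulate_reads <- function(truth, read_length = 100, total_pairs = NULL,
                           depth = NULL, error_rate = 0.005,
                           paired = TRUE, insert_mean = 300,
                           insert_sd = 30, seed = 1) {
  strains <- truth$sample_strains
  ab <- truth$abundances[names(strains)]
  lens <- nchar(strains)
  stopifnot(read_length <= min(lens))
  if (is.null(total_pairs)) {
    stopifnot(!is.null(depth))
    bases_per_frag <- read_length * (if (paired) 2 else 1)
    total_pairs <- ceiling(depth * sum(lens) / bases_per_frag)
  }
  with_seed(seed, {
    gidx <- sample.int(length(strains), total_pairs, replace = TRUE,
                       prob = ab)
    frag <- if (paired)
      pmax(2 * read_length,
           pmin(round(rnorm(total_pairs, insert_mean, insert_sd)),
                lens[gidx]))
    else rep(read_length, total_pairs)
    start <- floor(runif(total_pairs) * (lens[gidx] - frag + 1))  # 0-based
    r1 <- substring(strains[gidx], start + 1, start + read_length)
    if (paired) {
      r2 <- revcomp(substring(strains[gidx], start + frag - read_length + 1,
                              start + frag))
      reads <- c(rbind(r1, r2))
      ids <- c(rbind(sprintf("r%d/1", seq_len(total_pairs)),
                     sprintf("r%d/2", seq_len(total_pairs))))
      origins <- data.frame(
        read_id = ids,
        genome_id = rep(names(strains)[gidx], each = 2),
        position = c(rbind(start, start + frag - read_length)),
        strand = rep(c("+", "-"), total_pairs),
        stringsAsFactors = FALSE)
    } else {
      reads <- r1
      ids <- sprintf("r%d", seq_len(total_pairs))
      origins <- data.frame(read_id = ids,
                            genome_id = names(strains)[gidx],
                            position = start, strand = "+",
                            stringsAsFactors = FALSE)
    }
    if (error_rate > 0) {
      nerr <- rbinom(length(reads), read_length, error_rate)
      pos_list <- lapply(seq_along(reads), function(i)
        if (nerr[i] > 0) sample.int(read_length, nerr[i]) else integer(0))
      alt_list <- lapply(nerr, function(k)
        if (k > 0) sample.int(3, k, replace = TRUE) - 1L else integer(0))
      reads <- .apply_substitutions_cpp(reads, pos_list, alt_list)
    }
    names(reads) <- ids
    list(reads = reads, origins = origins)
  })
}

#' Write a community to disk (FASTA + annotations + truth sidecar)
#'
#' @param truth a [make_community()] result.
#' @param sim optional [simulate_reads()] result (writes FASTQ + origins).
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_community <- function(truth, sim = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genomes = file.path(dir, "references.fasta"),
    annotations = file.path(dir, "markers.tsv"),
    strains = file.path(dir, "sample_strains.synthetic.fasta"))
  write_fasta(truth$genomes, paths[["genomes"]])
  write.table(truth$annotations, paths[["annotations"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(truth$sample_strains, paths[["strains"]])
  if (!is.null(sim)) {
    paths <- c(paths, reads = file.path(dir, "reads.fastq"),
               origins = file.path(dir, "read_origins.tsv"))
    write_fastq(sim$reads, paths[["reads"]])
    write.table(sim$origins, paths[["origins"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
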