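# MAG presence, transcript-count filtering, TPM normalization, per-capita
# expression, and aggregation of TPM by annotation keys.

#' Filter genomes on assembly quality
#'
#' @param qualities Data frame `(genome_id, completeness, contamination)`.
#' @param min_comp Inclusive completeness floor (default 50).
#' @param max_cont Inclusive contamination ceiling (default 5).
#' @return Character vector of retained genome ids (boundaries kept).
#' @export
filter_genome_quality <- function(qualities, min_comp = 50, max_cont = 5) {
  qualities$genome_id[qualities$completeness >= min_comp &
                        qualities$contamination <= max_cont]
}

#' Genome presence from contig coverage breadth
#'
#' Genome breadth per sample is the contig-length-weighted mean of contig
#' breadths; a genome is present when its breadth reaches `breadth_min`
#' (default 0.10, inclusive). Genome depth is summarised the same
#' length-weighted way.
#'
#' @param coverage Data frame `(contig_id, sample_id, depth, breadth,
#'   length)`; missing lengths are an error.
#' @param contig_genomes Data frame `(contig_id, genome_id)`; every contig
#'   in `coverage` must be mapped.
#' @param breadth_min Inclusive presence threshold on genome breadth.
#' @return Data frame `(genome_id, sample_id, breadth, depth, present)`.
#' @export
genome_presence <- function(coverage, contig_genomes, breadth_min = 0.10) {
  if (anyNA(coverage$length))
    fail("missing contig length in coverage table")
  gid <- contig_genomes$genome_id[match(coverage$contig_id,
                                        contig_genomes$contig_id)]
  if (anyNA(gid))
    fail("contigs without genome mapping: %s",
         paste(unique(coverage$contig_id[is.na(gid)]), collapse = ", "))
  key <- paste(gid, coverage$sample_id, sep = "\r")
  wb <- tapply(coverage$breadth * coverage$length, key, sum) /
    tapply(coverage$length, key, sum)
  wd <- tapply(coverage$depth * coverage$length, key, sum) /
    tapply(coverage$length, key, sum)
  parts <- strsplit(names(wb), "\r", fixed = TRUE)
  out <- data.frame(genome_id = vapply(parts, `[[`, character(1), 1L),
                    sample_id = vapply(parts, `[[`, character(1), 2L),
                    breadth = unname(wb), depth = unname(wd),
                    stringsAsFactors = FALSE)
  out$present <- out$breadth >= breadth_min
  out <- out[order(out$genome_id, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Zero out under-supported transcript counts
#'
#' Cells with fewer than `min_pairs` mapped read pairs are set to zero,
#' per gene per sample, before normalization. The threshold is applied
#' cell-wise (matching the per-sample TPM framing); the boundary is kept
#' (`counts == min_pairs` survives).
#'
#' @param counts Integer gene-by-sample matrix (non-integer values are an
#'   error).
#' @param min_pairs Exclusive lower bound (default 5).
#' @return The filtered matrix.
#' @export
filter_counts <- function(counts, min_pairs = 5L) {
  if (any(counts != round(counts)))
    fail("counts must be integers (read pairs)")
  counts[counts < min_pairs] <- 0
  counts
}

#' Normalize counts to transcripts per million
#'
#' Per sample: `rate_g = counts_g / (length_g / 1000)` and
#' `tpm_g = rate_g * 1e6 / sum(rate)`. The denominator runs over all genes
#' in the table (TPM is defined against the full transcriptome, and
#' filtering precedes subsetting); an all-zero sample column stays
#' all-zero.
#'
#' @param counts Gene-by-sample matrix, already filtered
#'   ([filter_counts()]).
#' @param gene_lengths Named vector of gene lengths in nt covering every
#'   row; zero or negative lengths are an error.
#' @return TPM matrix; every nonzero column sums to 1e6.
#' @export
tpm_normalize <- function(counts, gene_lengths) {
  len <- gene_lengths[rownames(counts)]
  if (anyNA(len))
    fail("missing gene lengths for: %s",
         paste(utils::head(rownames(counts)[is.na(len)]), collapse = ", "))
  if (any(len <= 0)) fail("gene lengths must be positive")
  rate <- counts / (len / 1000)
  cs <- colSums(rate)
  scale <- ifelse(cs > 0, 1e6 / cs, 0)
  sweep(rate, 2L, scale, `*`)
}

#' Per-capita (genome-coverage-normalized) expression
#'
#' Divides genome-summed TPM by the genome's mean fold coverage in the
#' same sample; a depth of zero leaves the value undefined (`NA`, not 0).
#'
#' @param tpm_by_genome Genome-by-sample matrix of summed TPM.
#' @param depth Genome-by-sample matrix of mean fold coverage covering the
#'   same genomes and samples.
#' @return Matrix of per-capita values with `NA` where depth is zero.
#' @export
per_capita <- function(tpm_by_genome, depth) {
  if (!all(rownames(tpm_by_genome) %in% rownames(depth)) ||
      !all(colnames(tpm_by_genome) %in% colnames(depth)))
    fail("depth table must cover every (genome, sample) pair")
  d <- depth[rownames(tpm_by_genome), colnames(tpm_by_genome), drop = FALSE]
  out <- tpm_by_genome / d
  out[d == 0] <- NA_real_
  out
}

#' Aggregate TPM by annotation key and genome
#'
#' Sums TPM within (key, genome, sample) where the key is the gene's EC
#' number, CAZy family, substrate, or the gene itself. A gene carrying
#' several keys (e.g. two ECs) contributes its full TPM to each of them.
#' Genes with no resolvable key (or no genome) are dropped with a message
#' giving the count.
#'
#' @param tpm Gene-by-sample TPM matrix.
#' @param annotations Annotation table.
#' @param genes Gene records (for genome membership).
#' @param by One of `"ec"`, `"family"`, `"substrate"`, `"gene"`.
#' @return Long data frame `(key, genome_id, sample_id, tpm)`.
#' @export
aggregate_tpm <- function(tpm, annotations, genes,
                          by = c("ec", "family", "substrate", "gene")) {
  by <- match.arg(by)
  ids <- rownames(tpm)
  keys <- switch(by,
    gene = as.list(ids),
    ec = split_sets(annotations$ec_numbers[match(ids, annotations$gene_id)]),
    family = split_sets(annotations$families[match(ids,
                                                   annotations$gene_id)]),
    substrate = split_sets(annotations$substrates[match(ids,
                                                        annotations$gene_id)]))
  genome <- genes$genome_id[match(ids, genes$gene_id)]
  nk <- lengths(keys)
  usable <- nk > 0 & !is.na(genome)
  dropped <- sum(!usable)
  if (dropped)
    message(sprintf("aggregate_tpm: dropped %d gene(s) without %s key",
                    dropped, by))
  empty <- data.frame(key = character(), genome_id = character(),
                      sample_id = character(), tpm = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(usable)) return(empty)
  idx <- rep(which(usable), nk[usable])
  grp <- paste(unlist(keys[usable]), genome[idx], sep = "\r")
  sums <- rowsum(tpm[idx, , drop = FALSE], group = grp)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  long <- data.frame(
    key = rep(vapply(parts, `[[`, character(1), 1L), ncol(sums)),
    genome_id = rep(vapply(parts, `[[`, character(1), 2L), ncol(sums)),
    sample_id = rep(colnames(sums), each = nrow(sums)),
    tpm = as.vector(sums), stringsAsFactors = FALSE)
  long <- long[order(long$key, long$genome_id, long$sample_id), ,
               drop = FALSE]
  rownames(long) <- NULL
  long
}
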