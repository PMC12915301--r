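# CAZy family assignment: significance filtering of HMM domain hits
# followed by deterministic resolution of overlapping domains.

#' Filter domain hits on E-value and profile coverage
#'
#' Retains hits with independent domain E-value strictly below `e_max` and
#' profile coverage `(hmm_to - hmm_from + 1) / hmm_length` of at least
#' `cov_min`. These are the significance thresholds used for CAZyme family
#' annotation (E < 1e-18, coverage >= 35%); coverage is measured on the HMM
#' profile, not the query, matching the meaning of "domain coverage" in
#' dbCAN-lineage tooling.
#'
#' @param hits Domain-hit `data.frame` (any number of genes).
#' @param e_max Exclusive upper bound on `i_evalue` (default `1e-18`).
#' @param cov_min Inclusive lower bound on profile coverage (default 0.35).
#' @return The retained rows, in input order.
#' @export
filter_hits <- function(hits, e_max = 1e-18, cov_min = 0.35) {
  hits <- as_domain_hits(hits)
  if (!nrow(hits)) return(hits)
  cov <- (hits$hmm_to - hits$hmm_from + 1) / hits$hmm_length
  out <- hits[hits$i_evalue < e_max & cov >= cov_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping domain hits on one gene
#'
#' Produces a non-overlapping set of domain matches: no retained pair may
#' overlap (on query coordinates) by more than 50% of the shorter
#' alignment's length. Candidates are taken in a fully deterministic
#' priority order -- ascending `i_evalue`, then descending alignment
#' length, then family, then `ali_from` -- and greedily accepted when
#' compatible with everything already kept. The boundary is strict: an
#' overlap of exactly half the shorter alignment keeps both hits.
#'
#' @param hits Domain hits sharing one `gene_id` (mixed genes are an
#'   error).
#' @return The retained hits sorted by `ali_from`.
#' @export
resolve_overlaps <- function(hits) {
  hits <- as_domain_hits(hits)
  if (nrow(hits) > 1L && length(unique(hits$gene_id)) != 1L)
    fail("resolve_overlaps() expects hits for a single gene, got: %s",
         paste(unique(hits$gene_id), collapse = ", "))
  if (nrow(hits) <= 1L) {
    rownames(hits) <- NULL
    return(hits)
  }
  alen <- hits$ali_to - hits$ali_from + 1L
  ord <- order(hits$i_evalue, -alen, hits$family, hits$ali_from)
  acc <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in acc) {
      ov <- min(hits$ali_to[i], hits$ali_to[j]) -
        max(hits$ali_from[i], hits$ali_from[j]) + 1L
      if (ov > 0.5 * min(alen[i], alen[j])) {
        ok <- FALSE
        break
      }
    }
    if (ok) acc <- c(acc, i)
  }
  out <- hits[acc, , drop = FALSE]
  out <- out[order(out$ali_from, out$ali_to, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate genes with CAZy families from domain hits
#'
#' For each gene: filter hits ([filter_hits()]) then resolve overlaps
#' ([resolve_overlaps()]); the gene's families are the families of the
#' surviving hits. Filtering precedes overlap resolution (order-stable and
#' conservative). Genes with no surviving hit are absent from the output;
#' more than one family can be assigned to a gene.
#'
#' @param hits Domain hits over any number of genes.
#' @param e_max,cov_min Thresholds passed to [filter_hits()].
#' @return A `data.frame` with one row per annotated gene: `gene_id`,
#'   `families` (comma-joined, sorted), `ec_numbers` (empty), `ec_source`
#'   (`"NONE"`), `substrates` (empty); the surviving per-hit detail table
#'   is attached as `attr(, "hits")`.
#' @export
annotate_genes <- function(hits, e_max = 1e-18, cov_min = 0.35) {
  kept <- filter_hits(hits, e_max = e_max, cov_min = cov_min)
  if (nrow(kept)) {
    pieces <- lapply(split(kept, kept$gene_id), resolve_overlaps)
    kept <- do.call(rbind, pieces)
    rownames(kept) <- NULL
  }
  if (nrow(kept)) {
    fams <- tapply(kept$family, kept$gene_id, join_set)
    ann <- data.frame(gene_id = names(fams),
                      families = unname(as.character(fams)),
                      ec_numbers = "", ec_source = "NONE", substrates = "",
                      stringsAsFactors = FALSE)
    ann <- ann[order(ann$gene_id), , drop = FALSE]
    rownames(ann) <- NULL
  } else {
    ann <- data.frame(gene_id = character(), families = character(),
                      ec_numbers = character(), ec_source = character(),
                      substrates = character(), stringsAsFactors = FALSE)
  }
  attr(ann, "hits") <- kept
  ann
}
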