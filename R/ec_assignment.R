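# EC-number assignment: an ordered four-rule evidence cascade over
# subfamily HMM hits, KO annotations, and protein-database alignments.

#' Filter subfamily (dbCAN-sub style) domain hits
#'
#' Applies the same criteria as CAZyme family annotation -- E-value
#' < `e_max`, profile coverage >= `cov_min`, and per-gene overlap
#' resolution -- to subfamily HMM hits. Extra columns (such as an `ec`
#' metadata column) are preserved.
#'
#' @param hits Domain hits over any number of genes.
#' @param e_max,cov_min Thresholds as in [filter_hits()].
#' @return Surviving hits, per gene sorted by `ali_from`.
#' @export
filter_dbcansub <- function(hits, e_max = 1e-18, cov_min = 0.35) {
  kept <- filter_hits(hits, e_max = e_max, cov_min = cov_min)
  if (!nrow(kept)) return(kept)
  out <- do.call(rbind, lapply(split(kept, kept$gene_id), resolve_overlaps))
  rownames(out) <- NULL
  out
}

#' Filter protein-database (CAZyDB style) alignment hits
#'
#' Retains hits with E-value strictly below `e_max` (default 1e-102),
#' percent identity of at least `pident_min` (default 35) and query
#' coverage of at least `qcov_min` (default 70); identity and coverage
#' boundaries are inclusive. Hits without a query-coverage value are
#' dropped.
#'
#' @param hits Alignment-hit `data.frame`.
#' @param e_max Exclusive E-value bound.
#' @param pident_min,qcov_min Inclusive percent bounds.
#' @return The retained rows.
#' @export
filter_cazydb <- function(hits, e_max = 1e-102, pident_min = 35,
                          qcov_min = 70) {
  hits <- as_alignment_hits(hits)
  if (!nrow(hits)) return(hits)
  keep <- hits$evalue < e_max & hits$pident >= pident_min &
    !is.na(hits$qcov) & hits$qcov >= qcov_min
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# union of ECs (comma-joined strings) over a character vector
ec_union <- function(x) {
  sort(unique(unlist(lapply(x, function(v) split_set(v)))))
}

#' Assign EC numbers by the ordered four-rule cascade
#'
#' Rules are evaluated strictly in order and the first rule yielding at
#' least one EC wins:
#' \enumerate{
#'   \item ECs carried by surviving subfamily (dbCAN-sub) hits;
#'   \item ECs of DRAM-sourced KO annotations that also appear in the
#'     curated EC list of at least one of the gene's CAZy families
#'     (annotations must agree);
#'   \item ECs of protein-database hits whose subject family is one of the
#'     gene's families;
#'   \item as rule 2 but with BLAST-derived KEGG KO annotations.
#' }
#' Genes satisfying no rule keep an empty EC set with source `"NONE"`.
#' When a rule yields several ECs all are kept; partial EC strings such as
#' `"3.2.1.-"` are compared literally.
#'
#' All hit/KO inputs are expected pre-filtered ([filter_dbcansub()],
#' [filter_cazydb()]); this function only applies the cascade.
#'
#' @param annotations Annotation table from [annotate_genes()] (non-empty
#'   `families` per row).
#' @param sub_hits Subfamily domain hits carrying an `ec` column
#'   (comma-joined, possibly empty).
#' @param dram_kos,kegg_kos KO tables (`gene_id, ko_id, ec, source`).
#' @param cazydb_hits Alignment hits with `subject_ec`/`subject_family`.
#' @param maps A [reference_maps()] object (for the family -> EC lists).
#' @return `annotations` with `ec_numbers` and `ec_source` filled in
#'   (`RULE1`..`RULE4` or `NONE`).
#' @export
assign_ec <- function(annotations, sub_hits = NULL, dram_kos = NULL,
                      cazydb_hits = NULL, kegg_kos = NULL, maps) {
  sub_hits <- sub_hits %||% empty_domain_hits()
  cazydb_hits <- as_alignment_hits(cazydb_hits %||% empty_alignment_hits())
  empty_ko <- data.frame(gene_id = character(), ko_id = character(),
                         ec = character(), source = character(),
                         stringsAsFactors = FALSE)
  dram_kos <- dram_kos %||% empty_ko
  kegg_kos <- kegg_kos %||% empty_ko
  fmap <- maps$family_ec_map
  sub_ec <- if ("ec" %in% names(sub_hits)) sub_hits$ec else
    rep("", nrow(sub_hits))

  n <- nrow(annotations)
  ecs <- character(n)
  src <- rep("NONE", n)
  for (i in seq_len(n)) {
    g <- annotations$gene_id[i]
    fams <- split_set(annotations$families[i])
    fam_ecs <- unique(fmap$ec[fmap$family %in% fams])
    ko_rule <- function(kos) {
      cand <- ec_union(kos$ec[kos$gene_id == g])
      intersect(cand, fam_ecs)
    }
    r <- ec_union(sub_ec[sub_hits$gene_id == g])                       # rule 1
    which_rule <- "RULE1"
    if (!length(r)) {                                                  # rule 2
      r <- ko_rule(dram_kos)
      which_rule <- "RULE2"
    }
    if (!length(r)) {                                                  # rule 3
      sel <- cazydb_hits$query_id == g &
        cazydb_hits$subject_family %in% fams &
        nzchar(cazydb_hits$subject_ec)
      r <- ec_union(cazydb_hits$subject_ec[sel])
      which_rule <- "RULE3"
    }
    if (!length(r)) {                                                  # rule 4
      r <- ko_rule(kegg_kos)
      which_rule <- "RULE4"
    }
    if (length(r)) {
      ecs[i] <- join_set(r)
      src[i] <- which_rule
    }
  }
  annotations$ec_numbers <- ecs
  annotations$ec_source <- src
  annotations
}
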