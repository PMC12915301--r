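# CAZyme gene clusters: signature-gene classification, cluster detection
# on contig gene order, and substrate prediction by PUL homology (method B)
# and by majority voting over member genes (method C).

SIGNATURE_ROLES <- c("CAZYME", "TF", "STP", "TRANSPORTER")

#' Classify signature genes
#'
#' Assigns the role used by cluster detection to every gene: `CAZYME`
#' (membership in `cazyme_ids`), `TRANSPORTER` (transporter-database
#' alignment or transporter-domain HMM hit), `TF` or `STP`
#' (transcription-factor / signal-transduction HMM hits), or `NULL`.
#' When several evidence types hit one gene the precedence is
#' `CAZYME > TRANSPORTER > TF > STP`: CAZyme membership is the
#' cluster-defining property. Hit thresholds follow dbCAN3-style defaults
#' (the source databases publish none): TF/STP HMM hits at E < 1e-4 with
#' coverage >= 0.35, transporter alignments at E <= 1e-10 with query
#' coverage >= 35%, transporter-domain HMM hits at E < 1e-4.
#'
#' @param genes Gene records (see [read_gene_table()]).
#' @param tf_hits,stp_hits,tcdoms_hits Domain-hit tables (may be `NULL`).
#' @param tcdb_hits Alignment-hit table (may be `NULL`).
#' @param cazyme_ids Character vector of CAZyme gene ids.
#' @param tf_e,tf_cov,stp_e,stp_cov,tcdb_e,tcdb_qcov,tcdoms_e Thresholds.
#' @return `genes` with the `role` column assigned.
#' @export
classify_signature <- function(genes, tf_hits = NULL, stp_hits = NULL,
                               tcdb_hits = NULL, tcdoms_hits = NULL,
                               cazyme_ids = character(),
                               tf_e = 1e-4, tf_cov = 0.35,
                               stp_e = 1e-4, stp_cov = 0.35,
                               tcdb_e = 1e-10, tcdb_qcov = 35,
                               tcdoms_e = 1e-4) {
  role <- rep("NULL", nrow(genes))
  dom_ids <- function(hits, e, cov) {
    if (is.null(hits) || !nrow(hits)) return(character(0))
    unique(filter_hits(hits, e_max = e, cov_min = cov)$gene_id)
  }
  # ascending precedence: later assignments override earlier ones
  role[genes$gene_id %in% dom_ids(stp_hits, stp_e, stp_cov)] <- "STP"
  role[genes$gene_id %in% dom_ids(tf_hits, tf_e, tf_cov)] <- "TF"
  tc <- character(0)
  if (!is.null(tcdb_hits) && nrow(tcdb_hits)) {
    h <- as_alignment_hits(tcdb_hits)
    tc <- unique(h$query_id[h$evalue <= tcdb_e &
                              !is.na(h$qcov) & h$qcov >= tcdb_qcov])
  }
  if (!is.null(tcdoms_hits) && nrow(tcdoms_hits)) {
    h <- as_domain_hits(tcdoms_hits)
    tc <- union(tc, unique(h$gene_id[h$i_evalue < tcdoms_e]))
  }
  role[genes$gene_id %in% tc] <- "TRANSPORTER"
  role[genes$gene_id %in% cazyme_ids] <- "CAZYME"
  genes$role <- role
  genes
}

#' Cluster spans from a contig role string
#'
#' Core of cluster detection, exposed for direct use on role vectors.
#' Signature genes (role other than `"NULL"`) are chained whenever at most
#' `max_gap` non-signature genes separate consecutive signature genes; a
#' maximal chain is a cluster iff it contains at least one `CAZYME` and at
#' least one other signature role. Spans run from the first to the last
#' signature member (leading/trailing non-signature genes excluded;
#' interior ones are part of the cluster).
#'
#' @param roles Character vector of roles along one contig, in gene order.
#' @param max_gap Maximum number of intervening non-signature genes
#'   (default 2).
#' @return Data frame `(first, last)` of 1-based positions in `roles`.
#' @export
cgc_spans <- function(roles, max_gap = 2L) {
  sig <- which(roles != "NULL")
  first <- integer(0)
  last <- integer(0)
  if (length(sig)) {
    brk <- which(diff(sig) - 1L > max_gap)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(sig))
    for (k in seq_along(starts)) {
      idx <- sig[starts[k]:ends[k]]
      r <- roles[idx]
      if (any(r == "CAZYME") && any(r %in% c("TF", "STP", "TRANSPORTER"))) {
        first <- c(first, idx[1L])
        last <- c(last, idx[length(idx)])
      }
    }
  }
  # list-based constructor: this function sits in tight loops over contigs
  structure(list(first = first, last = last), class = "data.frame",
            row.names = seq_along(first))
}

#' Detect CAZyme gene clusters on one contig
#'
#' @param contig_genes Gene records of a single contig with roles assigned,
#'   sorted by `index_on_contig` (unsorted input is an error).
#' @param max_gap Maximum intervening non-signature genes (default 2).
#' @return Long-format member table `(cgc_id, contig_id, gene_id,
#'   index_on_contig, role)`, one row per gene in a cluster span
#'   (including interior non-signature genes); zero rows when no cluster
#'   is found.
#' @export
find_cgcs <- function(contig_genes, max_gap = 2L) {
  empty <- data.frame(cgc_id = character(), contig_id = character(),
                      gene_id = character(), index_on_contig = integer(),
                      role = character(), stringsAsFactors = FALSE)
  if (!nrow(contig_genes)) return(empty)
  if (length(unique(contig_genes$contig_id)) != 1L)
    fail("find_cgcs() expects genes of a single contig")
  if (is.unsorted(contig_genes$index_on_contig, strictly = TRUE))
    fail("genes must be sorted by index_on_contig")
  spans <- cgc_spans(contig_genes$role, max_gap = max_gap)
  if (!nrow(spans)) return(empty)
  contig <- contig_genes$contig_id[1L]
  out <- lapply(seq_len(nrow(spans)), function(k) {
    rows <- spans$first[k]:spans$last[k]
    data.frame(cgc_id = sprintf("%s_CGC%03d", contig, k),
               contig_id = contig,
               gene_id = contig_genes$gene_id[rows],
               index_on_contig = contig_genes$index_on_contig[rows],
               role = contig_genes$role[rows],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect CAZyme gene clusters across all contigs
#'
#' @param genes Gene records with roles assigned (any number of contigs).
#' @param max_gap Maximum intervening non-signature genes.
#' @return Row-bound member tables from [find_cgcs()] per contig.
#' @export
find_all_cgcs <- function(genes, max_gap = 2L) {
  genes <- genes[order(genes$contig_id, genes$index_on_contig), , drop = FALSE]
  parts <- lapply(split(genes, genes$contig_id), find_cgcs,
                  max_gap = max_gap)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' CGC substrate by PUL homology (method B)
#'
#' Alignment hits from cluster members to a PUL database are filtered at
#' E-value < `e_max`; for each candidate PUL, bitscores of the retained
#' hits are summed, keeping only the best hit per (query gene, PUL) pair so
#' multiple HSPs are not double-counted. Eligible PULs are those whose
#' matched subject members include at least one CAZyme and at least one
#' other signature role; the eligible PUL with the highest summed bitscore
#' wins, ties broken by ascending PUL id.
#'
#' @param members Member table of one cluster (from [find_cgcs()]).
#' @param pul_hits Alignment hits with `subject_pul_id` and `subject_role`
#'   metadata; every query must be a cluster member (otherwise an error).
#' @param e_max Exclusive E-value bound (default 1e-102).
#' @param best_hit_per_pair Sum only the best hit per (query, PUL) pair
#'   (default `TRUE`).
#' @return One-row data frame `(substrate, pul_id, summed_bitscore)` with
#'   the substrate looked up from `maps$pul_db`, or a zero-row frame when
#'   no PUL is eligible.
#' @param maps A [reference_maps()] object carrying the PUL database.
#' @export
predict_cgc_substrate_homology <- function(members, pul_hits, maps,
                                           e_max = 1e-102,
                                           best_hit_per_pair = TRUE) {
  empty <- data.frame(substrate = character(), pul_id = character(),
                      summed_bitscore = numeric(), stringsAsFactors = FALSE)
  if (is.null(pul_hits) || !nrow(pul_hits)) return(empty)
  pul_hits <- as_alignment_hits(pul_hits)
  alien <- setdiff(pul_hits$query_id, members$gene_id)
  if (length(alien))
    fail("PUL hits from non-member genes: %s", paste(alien, collapse = ", "))
  h <- pul_hits[pul_hits$evalue < e_max & nzchar(pul_hits$subject_pul_id), ,
                drop = FALSE]
  if (!nrow(h)) return(empty)
  if (best_hit_per_pair) {
    h <- h[order(-h$bitscore, h$subject_id), , drop = FALSE]
    h <- h[!duplicated(paste(h$query_id, h$subject_pul_id, sep = "\r")), ,
           drop = FALSE]
  }
  sums <- tapply(h$bitscore, h$subject_pul_id, sum)
  eligible <- vapply(names(sums), function(p) {
    roles <- h$subject_role[h$subject_pul_id == p]
    any(roles == "CAZYME") && any(roles %in% c("TF", "STP", "TRANSPORTER"))
  }, logical(1))
  if (!any(eligible)) return(empty)
  sums <- sums[eligible]
  best <- names(sums)[order(-sums, names(sums))][1L]
  puls <- maps$pul_db$puls
  substrate <- if (!is.null(puls)) {
    s <- puls$substrate[match(best, puls$pul_id)]
    if (is.na(s)) "" else s
  } else ""
  data.frame(substrate = substrate, pul_id = best,
             summed_bitscore = unname(sums[best]), stringsAsFactors = FALSE)
}

#' CGC substrate by majority voting (method C)
#'
#' Every member gene with a non-empty substrate set casts one vote per
#' distinct substrate in its set; the winners are the substrates with the
#' maximal vote count, provided that count reaches `vote_min` (a one-vote
#' "majority" is uninformative). Ties return all co-winners, sorted.
#'
#' @param members Member table of one cluster.
#' @param annotations Annotation table with `substrates` filled.
#' @param vote_min Minimum winning vote count (default 2).
#' @return One-row data frame `(substrates, votes)` with comma-joined
#'   co-winners, or a zero-row frame below threshold.
#' @export
predict_cgc_substrate_voting <- function(members, annotations,
                                         vote_min = 2L) {
  empty <- data.frame(substrates = character(), votes = integer(),
                      stringsAsFactors = FALSE)
  idx <- match(members$gene_id, annotations$gene_id)
  subs <- ifelse(is.na(idx), "", annotations$substrates[idx])
  votes <- table(unlist(split_sets(subs)))
  if (!length(votes) || max(votes) < vote_min) return(empty)
  winners <- sort(names(votes)[votes == max(votes)])
  data.frame(substrates = paste(winners, collapse = ","),
             votes = as.integer(max(votes)), stringsAsFactors = FALSE)
}

#' Count adjacent tagged gene pairs inside clusters
#'
#' Generalizes tandem-gene tallies (such as susC/susD pairs in
#' Bacteroidota PULs): counts, over all clusters, adjacent member genes
#' (contig indices differing by exactly 1; an intervening gene breaks the
#' pair) whose tags match the requested pair in either order. Each
#' adjacent qualifying pair counts once.
#'
#' @param members Member table over any number of clusters.
#' @param tags Named character vector mapping `gene_id` to a tag (untagged
#'   genes may be absent).
#' @param tag_a,tag_b The two tags of the pair.
#' @return Integer count.
#' @export
count_gene_pairs <- function(members, tags, tag_a, tag_b) {
  if (!nrow(members)) return(0L)
  want <- sort(c(tag_a, tag_b))
  total <- 0L
  for (m in split(members, members$cgc_id)) {
    m <- m[order(m$index_on_contig), , drop = FALSE]
    t <- unname(tags[m$gene_id])
    adj <- which(diff(m$index_on_contig) == 1L)
    for (i in adj) {
      pair <- c(t[i], t[i + 1L])
      if (!anyNA(pair) && identical(sort(pair), want))
        total <- total + 1L
    }
  }
  total
}

#' Summarise a member table into one row per cluster
#'
#' @param members Member table from [find_all_cgcs()].
#' @return Data frame `(cgc_id, contig_id, first_index, last_index,
#'   n_genes, n_cazyme, n_other_signature, roles)`.
#' @export
cgc_summary <- function(members) {
  if (!nrow(members))
    return(data.frame(cgc_id = character(), contig_id = character(),
                      first_index = integer(), last_index = integer(),
                      n_genes = integer(), n_cazyme = integer(),
                      n_other_signature = integer(), roles = character(),
                      stringsAsFactors = FALSE))
  parts <- lapply(split(members, members$cgc_id), function(m) {
    data.frame(cgc_id = m$cgc_id[1L], contig_id = m$contig_id[1L],
               first_index = min(m$index_on_contig),
               last_index = max(m$index_on_contig),
               n_genes = nrow(m),
               n_cazyme = sum(m$role == "CAZYME"),
               n_other_signature = sum(m$role %in%
                                         c("TF", "STP", "TRANSPORTER")),
               roles = paste(m$role[order(m$index_on_contig)],
                             collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$contig_id, out$first_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
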