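# End-to-end pipeline wiring: annotate -> EC cascade -> substrates -> CGC
# detection -> quantification -> ecology summaries, plus comparison of a
# run against a simulation's truth ledger.

#' Default pipeline parameters
#'
#' Every threshold knob of the pipeline with its default, in one place:
#' domain-hit filtering (`e_max`, `cov_min`), protein-database filtering
#' (`cazydb_e`, `cazydb_pident`, `cazydb_qcov`), presence breadth,
#' read-pair floor, cluster gap and voting floor, and signature-hit
#' thresholds.
#'
#' @param ... Overrides of individual knobs; unknown names are rejected.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  defaults <- list(
    e_max = 1e-18, cov_min = 0.35,
    cazydb_e = 1e-102, cazydb_pident = 35, cazydb_qcov = 70,
    breadth_min = 0.10, min_pairs = 5L,
    min_completeness = 50, max_contamination = 5,
    cgc_max_gap = 2L, cgc_vote_min = 2L,
    tf_e = 1e-4, tf_cov = 0.35, stp_e = 1e-4, stp_cov = 0.35,
    tcdb_e = 1e-10, tcdb_qcov = 35, tcdoms_e = 1e-4,
    pul_e = 1e-102)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    fail("unknown pipeline parameter(s): %s", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, over)
}

#' Run the full annotation and quantification pipeline
#'
#' Executes, in order: CAZyme family annotation (filter + overlap
#' resolution), the four-rule EC cascade, substrate prediction, signature
#' classification and cluster detection with both substrate-prediction
#' methods, genome-quality filtering, presence from coverage breadth,
#' count filtering, TPM and per-capita expression, aggregation, and the
#' ecology summaries (expressing fractions, richness partition, per-sample
#' diversity). Deterministic: re-running on the same input yields
#' identical outputs.
#'
#' @param sim A `cazy_sim` object from [simulate_community()] or a fixture
#'   directory written by [write_simulation()].
#' @param params Parameter list from [pipeline_params()].
#' @return Named list with `annotations`, `cgc_members`, `cgc_table`,
#'   `presence`, `tpm`, `tpm_by_genome`, `per_capita`, `expressed`,
#'   `aggregated_ec`, `expressing`, `richness`, `diversity`,
#'   `genomes_kept`, and the `params` echo.
#' @export
run_pipeline <- function(sim, params = pipeline_params()) {
  if (is.character(sim)) sim <- read_simulation(sim)
  stopifnot(inherits(sim, "cazy_sim"))

  ## stage 1: CAZyme families
  ann <- annotate_genes(sim$dbcan_hits, e_max = params$e_max,
                        cov_min = params$cov_min)

  ## stage 2: EC cascade
  sub_f <- filter_dbcansub(sim$dbcansub_hits, e_max = params$e_max,
                           cov_min = params$cov_min)
  czy_f <- filter_cazydb(sim$cazydb_hits, e_max = params$cazydb_e,
                         pident_min = params$cazydb_pident,
                         qcov_min = params$cazydb_qcov)
  ann <- assign_ec(ann, sub_hits = sub_f, dram_kos = sim$dram_kos,
                   cazydb_hits = czy_f, kegg_kos = sim$kegg_kos,
                   maps = sim$maps)

  ## stage 3: substrates
  ann <- predict_gene_substrates(ann, sim$maps)

  ## stage 4: clusters
  genes <- classify_signature(sim$genes, tf_hits = sim$tf_hits,
                              stp_hits = sim$stp_hits,
                              tcdb_hits = sim$tcdb_hits,
                              tcdoms_hits = sim$tcdoms_hits,
                              cazyme_ids = ann$gene_id,
                              tf_e = params$tf_e, tf_cov = params$tf_cov,
                              stp_e = params$stp_e, stp_cov = params$stp_cov,
                              tcdb_e = params$tcdb_e,
                              tcdb_qcov = params$tcdb_qcov,
                              tcdoms_e = params$tcdoms_e)
  members <- find_all_cgcs(genes, max_gap = params$cgc_max_gap)
  cgc_tab <- cgc_summary(members)
  if (nrow(cgc_tab)) {
    preds <- lapply(cgc_tab$cgc_id, function(id) {
      m <- members[members$cgc_id == id, , drop = FALSE]
      ph <- sim$pul_hits[sim$pul_hits$query_id %in% m$gene_id, ,
                         drop = FALSE]
      b <- predict_cgc_substrate_homology(m, ph, sim$maps,
                                          e_max = params$pul_e)
      v <- predict_cgc_substrate_voting(m, ann,
                                        vote_min = params$cgc_vote_min)
      data.frame(substrate_B = if (nrow(b)) b$substrate else "",
                 pul_id = if (nrow(b)) b$pul_id else "",
                 summed_bitscore = if (nrow(b)) b$summed_bitscore else
                   NA_real_,
                 substrate_C = if (nrow(v)) v$substrates else "",
                 votes = if (nrow(v)) v$votes else NA_integer_,
                 stringsAsFactors = FALSE)
    })
    cgc_tab <- cbind(cgc_tab, do.call(rbind, preds))
  }

  ## stage 5: quantification
  kept <- filter_genome_quality(sim$genomes,
                                min_comp = params$min_completeness,
                                max_cont = params$max_contamination)
  contig_map <- unique(sim$genes[, c("contig_id", "genome_id")])
  presence <- genome_presence(sim$coverage, contig_map,
                              breadth_min = params$breadth_min)
  presence <- presence[presence$genome_id %in% kept, , drop = FALSE]
  keep_genes <- sim$genes$gene_id[sim$genes$genome_id %in% kept]
  counts <- sim$counts[intersect(rownames(sim$counts), keep_genes), ,
                       drop = FALSE]
  counts_f <- filter_counts(counts, min_pairs = params$min_pairs)
  lens <- stats::setNames(sim$genes$length_nt, sim$genes$gene_id)
  tpm <- tpm_normalize(counts_f, lens)
  expressed <- counts >= params$min_pairs
  genome_of <- sim$genes$genome_id[match(rownames(tpm), sim$genes$gene_id)]
  tpm_by_genome <- rowsum(tpm, group = genome_of)
  depth_m <- with(presence, tapply(depth, list(genome_id, sample_id), sum))
  percap <- per_capita(tpm_by_genome, depth_m)
  agg_ec <- aggregate_tpm(tpm, ann, sim$genes, by = "ec")

  ## stage 6: ecology summaries
  sample_hab <- stats::setNames(sim$samples$habitat, sim$samples$sample_id)
  expressing <- expressing_fraction(ann, sim$genes, presence, expressed,
                                    sample_hab)
  # family presence per (site, habitat): families of genomes present in
  # the site's sample of that habitat
  fam_rows <- list()
  gene_genome <- sim$genes$genome_id[match(ann$gene_id, sim$genes$gene_id)]
  for (i in seq_len(nrow(sim$samples))) {
    smp <- sim$samples$sample_id[i]
    pres_gen <- presence$genome_id[presence$sample_id == smp &
                                     presence$present]
    fams <- unique(unlist(split_sets(
      ann$families[gene_genome %in% pres_gen])))
    if (length(fams))
      fam_rows[[length(fam_rows) + 1L]] <- data.frame(
        site = sim$samples$site[i], habitat = sim$samples$habitat[i],
        family = fams, stringsAsFactors = FALSE)
  }
  fam_long <- do.call(rbind, fam_rows) %||%
    data.frame(site = character(), habitat = character(),
               family = character(), stringsAsFactors = FALSE)
  habs <- unique(sim$samples$habitat)
  richness <- if (length(habs) == 2L)
    richness_partition(fam_long, habitats = habs) else NULL
  diversity <- vapply(colnames(tpm), function(s) {
    v <- tpm[, s]
    if (sum(v) > 0) inverse_simpson(v) else NA_real_
  }, numeric(1))

  list(annotations = ann, genes = genes, cgc_members = members,
       cgc_table = cgc_tab, presence = presence, tpm = tpm,
       tpm_by_genome = tpm_by_genome, per_capita = percap,
       expressed = expressed, aggregated_ec = agg_ec,
       expressing = expressing, richness = richness,
       diversity = diversity, family_long = fam_long,
       genomes_kept = kept, params = params)
}

#' Compare a pipeline run against the simulation truth ledger
#'
#' Computes agreement fractions between a [run_pipeline()] result and the
#' generating truth: per-gene family sets, EC sets, EC source rules and
#' substrate sets (over all genes, counting an absent annotation as
#' agreement with an empty truth); cluster-span precision and recall with
#' substrate agreement for both prediction methods (over recovered
#' clusters); genome presence and per-cell expressed flags (restricted to
#' quality-passing genomes).
#'
#' @param res Result list from [run_pipeline()].
#' @param sim The generating `cazy_sim`.
#' @return Named list of agreement fractions in `[0, 1]`.
#' @export
compare_to_ledger <- function(res, sim) {
  lg <- sim$ledger$genes
  ann <- res$annotations
  idx <- match(lg$gene_id, ann$gene_id)
  got <- function(col) ifelse(is.na(idx), "", ann[[col]][idx])
  src_got <- ifelse(is.na(idx), "NONE", ann$ec_source[idx])
  agree <- list(
    families = mean(got("families") == lg$families),
    ec_numbers = mean(got("ec_numbers") == lg$ec_numbers),
    ec_source = mean(src_got == lg$ec_source),
    substrates = mean(got("substrates") == lg$substrates))

  truth_c <- sim$ledger$cgcs
  found <- res$cgc_table
  key <- function(d) paste(d$contig_id, d$first_index, d$last_index)
  tp <- sum(key(found) %in% key(truth_c))
  agree$cgc_precision <- if (nrow(found)) tp / nrow(found) else NA_real_
  agree$cgc_recall <- if (nrow(truth_c)) tp / nrow(truth_c) else NA_real_
  hit <- match(key(truth_c), key(found))
  ok <- !is.na(hit)
  agree$cgc_substrate_B <- if (any(ok))
    mean(found$substrate_B[hit[ok]] == truth_c$substrate[ok]) else NA_real_
  agree$cgc_substrate_C <- if (any(ok))
    mean(found$substrate_C[hit[ok]] == truth_c$substrate_C[ok]) else
      NA_real_

  kept <- res$genomes_kept
  lp <- sim$ledger$presence
  lp <- lp[lp$genome_id %in% kept, , drop = FALSE]
  pk <- paste(res$presence$genome_id, res$presence$sample_id)
  pi <- match(paste(lp$genome_id, lp$sample_id), pk)
  agree$presence <- mean(res$presence$present[pi] == lp$present)

  le <- sim$ledger$expression
  common <- intersect(rownames(res$expressed), rownames(le))
  agree$expressed <- mean(res$expressed[common, colnames(le)] ==
                            le[common, ])
  agree
}
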