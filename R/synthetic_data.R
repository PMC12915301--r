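# Seeded generator of a full mock study: genomes, gene tables, hit files,
# reference maps, coverage and count tables, plus a ground-truth ledger.
# No sequences are emitted, only identifiers, coordinates and hit tables.
#
# Construction guarantees used by the test suite:
#   * true CAZyme hits have E in [1e-40, 1e-19] and coverage in [0.4, 1];
#     decoys have E in [1e-17, 1e-5] or coverage <= 0.30, i.e. at least a
#     decade in E / 0.05 in coverage away from the filtering thresholds,
#     so decoys can never survive regardless of noise settings;
#   * every planted or decoy cluster sits on its own contig with at least
#     three non-signature genes on either side, so detected cluster spans
#     can be compared to the ledger exactly;
#   * expression states are drawn once per (genome, substrate, sample) and
#     inherited by the genome's genes for that substrate, making the
#     expressing fraction of encoding genomes a Bernoulli sample of the
#     configured probability.

# sample n values from lo:hi without sample()'s scalar surprise
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else
    sample(lo:hi, n, replace = TRUE)
}

# substrate-linked archetypes: one curated (family, EC, substrate) triple
# per substrate category
cazy_archetypes <- function(n) {
  a <- data.frame(
    substrate = c("starch", "beta-glucan", "cellulose", "xylan", "pectin",
                  "chitin", "alginate", "fucoidan", "agarose", "trehalose"),
    family = c("GH13", "GH16_3", "GH5", "GH10", "PL1",
               "GH18", "PL6", "GH29", "GH86", "GH15"),
    ec = c("3.2.1.1", "3.2.1.39", "3.2.1.4", "3.2.1.8", "4.2.2.2",
           "3.2.1.14", "4.2.2.3", "3.2.1.51", "3.2.1.81", "3.2.1.3"),
    stringsAsFactors = FALSE)
  if (n < 1L || n > nrow(a))
    fail("n_substrates must lie in [1, %d]", nrow(a))
  a[seq_len(n), , drop = FALSE]
}

#' Build a simulation configuration
#'
#' Defines the community the generator emits: genomes per habitat, contig
#' and gene-count ranges, the fraction of genes that are CAZymes, planted
#' and decoy gene clusters, habitat-by-substrate expression probabilities,
#' and the negative-binomial transcript count model. All values are
#' validated; an infeasible layout (e.g. a cluster that cannot fit on a
#' contig with its padding) is rejected before anything is emitted.
#'
#' @param seed Master seed; every fixture type draws from its own RNG
#'   stream derived from it.
#' @param n_genomes Quality-passing genomes per habitat.
#' @param habitats Habitat labels (one sampling site pairs one sample of
#'   each habitat).
#' @param n_samples Named integer vector of samples per habitat.
#' @param n_lowq Additional low-quality genomes per habitat (fail the
#'   completeness/contamination filter by a clear margin).
#' @param contigs_per_genome,genes_per_contig Integer ranges (min, max).
#' @param gene_length_nt Gene length range in nt, multiples of 3.
#' @param n_substrates Number of substrate categories (at most 10).
#' @param p_cazyme Named per-habitat fraction of eligible genes that are
#'   CAZymes.
#' @param n_planted_cgcs,n_decoy_cgcs Planted valid clusters and planted
#'   violations (gap of 3, or no second signature role).
#' @param decoy_rate Expected decoy domain hits per gene.
#' @param expression_prob Habitat-by-substrate matrix of expression
#'   probabilities; default 0.6 everywhere.
#' @param p_background_expr Expression probability for genes without a
#'   substrate (in present genomes).
#' @param p_present_home,p_present_away Probability a genome is present in
#'   a sample of its own / the other habitat.
#' @param count_model List `(mean_expressed, mean_silent, dispersion)` of
#'   the negative-binomial read-pair model (overdispersed counts emulate
#'   metatranscriptome libraries).
#' @param noise_free If `TRUE`, counts are deterministic: expressed cells
#'   get `max(5, round(mean_expressed))`, silent cells 0.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genomes = 30L,
                       habitats = c("water", "sediment"),
                       n_samples = c(water = 3L, sediment = 3L),
                       n_lowq = 2L,
                       contigs_per_genome = c(2L, 4L),
                       genes_per_contig = c(14L, 30L),
                       gene_length_nt = c(300L, 1500L),
                       n_substrates = 6L,
                       p_cazyme = c(water = 0.12, sediment = 0.25),
                       n_planted_cgcs = 12L,
                       n_decoy_cgcs = 12L,
                       decoy_rate = 0.5,
                       expression_prob = NULL,
                       p_background_expr = 0.5,
                       p_present_home = 0.9,
                       p_present_away = 0.1,
                       count_model = list(mean_expressed = 50,
                                          mean_silent = 1,
                                          dispersion = 5),
                       noise_free = FALSE) {
  arch <- cazy_archetypes(n_substrates)
  if (is.null(expression_prob))
    expression_prob <- matrix(0.6, length(habitats), n_substrates,
                              dimnames = list(habitats, arch$substrate))
  if (is.null(rownames(expression_prob)))
    rownames(expression_prob) <- habitats
  if (is.null(colnames(expression_prob)))
    colnames(expression_prob) <- arch$substrate
  cfg <- list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
              habitats = habitats, n_samples = n_samples,
              n_lowq = as.integer(n_lowq),
              contigs_per_genome = as.integer(contigs_per_genome),
              genes_per_contig = as.integer(genes_per_contig),
              gene_length_nt = as.integer(gene_length_nt),
              n_substrates = as.integer(n_substrates),
              p_cazyme = p_cazyme, n_planted_cgcs = as.integer(n_planted_cgcs),
              n_decoy_cgcs = as.integer(n_decoy_cgcs),
              decoy_rate = decoy_rate, expression_prob = expression_prob,
              p_background_expr = p_background_expr,
              p_present_home = p_present_home,
              p_present_away = p_present_away,
              count_model = count_model, noise_free = isTRUE(noise_free))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  rng_ok <- function(r) length(r) == 2L && r[1L] >= 1L && r[1L] <= r[2L]
  if (!rng_ok(cfg$contigs_per_genome) || !rng_ok(cfg$genes_per_contig) ||
      !rng_ok(cfg$gene_length_nt))
    fail("ranges must be non-empty (min <= max, min >= 1)")
  if (any(cfg$gene_length_nt %% 3L != 0L))
    fail("gene_length_nt bounds must be multiples of 3")
  if (cfg$gene_length_nt[1L] < 300L)
    fail("gene_length_nt minimum must be >= 300 nt")
  if (cfg$genes_per_contig[1L] < 12L)
    fail("infeasible config: genes_per_contig minimum must be >= 12 so a
planted cluster plus its padding fits on any contig")
  probs <- c(cfg$p_cazyme, cfg$expression_prob, cfg$p_background_expr,
             cfg$p_present_home, cfg$p_present_away)
  if (any(probs < 0 | probs > 1)) fail("all probabilities must lie in [0, 1]")
  if (!all(cfg$habitats %in% names(cfg$p_cazyme)) ||
      !all(cfg$habitats %in% names(cfg$n_samples)) ||
      !all(cfg$habitats %in% rownames(cfg$expression_prob)))
    fail("p_cazyme, n_samples and expression_prob must be keyed by habitat")
  if (ncol(cfg$expression_prob) != cfg$n_substrates)
    fail("expression_prob needs one column per substrate")
  cm <- cfg$count_model
  if (cm$mean_expressed < 5)
    fail("count_model$mean_expressed must be >= 5 so that noise-free
expressed cells pass the read-pair floor")
  if (cm$mean_silent < 0 || cm$dispersion <= 0)
    fail("count_model means must be >= 0 and dispersion > 0")
  invisible(cfg)
}

#' Estuary scenario configuration
#'
#' The documented study-shaped configuration: sediment communities carry a
#' higher CAZyme gene fraction than water (richer family repertoires),
#' while water populations express their substrate genes with higher
#' probability than sediment ones (0.9 vs 0.35 for every substrate), so
#' water substrates land above the 0.5 expressing-fraction line and
#' sediment substrates below it.
#'
#' @param seed Master seed.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
scenario_estuary <- function(seed = 1L, ...) {
  over <- list(...)
  defaults <- list(seed = seed,
                   p_cazyme = c(water = 0.12, sediment = 0.25))
  args <- utils::modifyList(defaults, over)
  if (is.null(args$expression_prob)) {
    n_sub <- args$n_substrates %||% 6L
    habitats <- args$habitats %||% c("water", "sediment")
    ep <- matrix(0.35, length(habitats), n_sub,
                 dimnames = list(habitats,
                                 cazy_archetypes(n_sub)$substrate))
    if ("water" %in% habitats) ep["water", ] <- 0.9
    args$expression_prob <- ep
  }
  do.call(sim_config, args)
}

#' Generate a synthetic community with ground truth
#'
#' Deterministically (given the seed) emits every table the pipeline
#' consumes -- gene records, CAZyme/subfamily/TF/STP/transporter-domain
#' domain hits, protein-database / transporter / PUL alignment hits, KO
#' tables, reference maps, contig coverage and gene-by-sample read-pair
#' counts -- together with a ledger of the planted truth (per-gene
#' families, ECs, substrates and roles; cluster spans and substrates;
#' per-sample presence and expression states). One RNG stream per fixture
#' type is derived from the master seed so adding a fixture type never
#' perturbs existing ones.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, all fixture files, the truth
#'   ledger TSVs and a checksum manifest are written there.
#' @return A list of class `cazy_sim` with the in-memory tables and the
#'   `ledger`.
#' @export
simulate_community <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  arch <- cazy_archetypes(config$n_substrates)
  set.seed(config$seed)
  streams <- sample.int(2147483646L, 8L)
  habitats <- config$habitats

  ## ---- stream 1: genomes, contigs, genes --------------------------------
  set.seed(streams[1L])
  per_hab <- config$n_genomes + config$n_lowq
  genome_id <- unlist(lapply(habitats, function(h)
    sprintf("MAG_%s_%03d", h, seq_len(per_hab))))
  genome_hab <- rep(habitats, each = per_hab)
  qc_pass <- rep(c(rep(TRUE, config$n_genomes), rep(FALSE, config$n_lowq)),
                 length(habitats))
  ng <- length(genome_id)
  completeness <- numeric(ng)
  contamination <- numeric(ng)
  completeness[qc_pass] <- stats::runif(sum(qc_pass), 55, 99)
  contamination[qc_pass] <- stats::runif(sum(qc_pass), 0, 4.5)
  lowq <- which(!qc_pass)
  lq_a <- lowq[seq_along(lowq) %% 2L == 1L]   # fail completeness
  lq_b <- setdiff(lowq, lq_a)                 # fail contamination
  completeness[lq_a] <- stats::runif(length(lq_a), 20, 49)
  contamination[lq_a] <- stats::runif(length(lq_a), 0, 4.5)
  completeness[lq_b] <- stats::runif(length(lq_b), 55, 99)
  contamination[lq_b] <- stats::runif(length(lq_b), 5.5, 20)

  ncontig <- sample_range(config$contigs_per_genome[1L],
                          config$contigs_per_genome[2L], ng)
  contig_genome <- rep(seq_len(ng), ncontig)
  contig_id <- paste0(genome_id[contig_genome], "_c",
                      unlist(lapply(ncontig, seq_len)))
  nc <- length(contig_id)
  ngene <- sample_range(config$genes_per_contig[1L],
                        config$genes_per_contig[2L], nc)
  gene_contig <- rep(seq_len(nc), ngene)
  ntot <- length(gene_contig)
  len <- 3L * sample_range(config$gene_length_nt[1L] %/% 3L,
                           config$gene_length_nt[2L] %/% 3L, ntot)
  gap <- sample(20:200, ntot, replace = TRUE)
  cum <- stats::ave(len + gap, gene_contig, FUN = cumsum)
  g_start <- cum - len + 1L
  g_end <- cum
  idx_on_contig <- sequence(ngene) - 1L
  gene_id <- sprintf("%s_g%03d", contig_id[gene_contig], idx_on_contig + 1L)
  strand <- sample(c("+", "-"), ntot, replace = TRUE)
  contig_first_row <- cumsum(ngene) - ngene + 1L
  aa <- len %/% 3L
  gene_genome <- contig_genome[gene_contig]

  ## ---- stream 2: planted clusters and decoys ----------------------------
  set.seed(streams[2L])
  roles <- rep("NULL", ntot)
  reserved <- logical(ntot)
  caz_arch <- rep(NA_integer_, ntot)
  planted_tpl <- list(c("CAZYME", "NULL", "TRANSPORTER"),
                      c("CAZYME", "CAZYME", "NULL", "NULL", "TF"),
                      c("TF", "CAZYME", "NULL", "STP"),
                      c("CAZYME", "NULL", "NULL", "TRANSPORTER", "CAZYME"))
  decoy_tpl <- list(gap3 = c("CAZYME", "NULL", "NULL", "NULL", "TRANSPORTER"),
                    no_other = c("CAZYME", "NULL", "CAZYME"))
  n_struct <- config$n_planted_cgcs + config$n_decoy_cgcs
  if (n_struct > nc)
    fail("infeasible config: %d planted structures but only %d contigs",
         n_struct, nc)
  struct_contig <- sample(nc, n_struct)
  place <- function(cix, tpl) {
    n <- ngene[cix]
    maxstart <- n - 3L - length(tpl) + 1L
    start_pos <- if (maxstart == 4L) 4L else sample(4:maxstart, 1L)
    rows <- contig_first_row[cix] + start_pos - 1L + seq_along(tpl) - 1L
    roles[rows] <<- tpl
    res <- (rows[1L] - 3L):(rows[length(rows)] + 3L)
    reserved[res] <<- TRUE
    list(rows = rows, start_pos = start_pos)
  }
  planted <- list()
  for (k in seq_len(config$n_planted_cgcs)) {
    cix <- struct_contig[k]
    tpl <- planted_tpl[[sample(length(planted_tpl), 1L)]]
    pl <- place(cix, tpl)
    ai <- sample(config$n_substrates, 1L)
    caz_rows <- pl$rows[tpl == "CAZYME"]
    caz_arch[caz_rows] <- ai
    planted[[k]] <- list(
      contig = cix, rows = pl$rows, tpl = tpl, arch = ai,
      first_index = pl$start_pos - 1L,
      last_index = pl$start_pos + length(tpl) - 2L,
      caz_rows = caz_rows,
      other_row = pl$rows[tpl %in% c("TF", "STP", "TRANSPORTER")][1L])
  }
  decoys <- list()
  for (k in seq_len(config$n_decoy_cgcs)) {
    cix <- struct_contig[config$n_planted_cgcs + k]
    kind <- names(decoy_tpl)[(k - 1L) %% 2L + 1L]
    tpl <- decoy_tpl[[kind]]
    pl <- place(cix, tpl)
    caz_arch[pl$rows[tpl == "CAZYME"]] <- sample(config$n_substrates, 1L)
    decoys[[k]] <- data.frame(
      contig_id = contig_id[cix], kind = kind,
      first_index = pl$start_pos - 1L,
      last_index = pl$start_pos + length(tpl) - 2L,
      stringsAsFactors = FALSE)
  }

  ## ---- stream 3: background CAZymes and evidence schedule ---------------
  set.seed(streams[3L])
  rare_pool <- paste0("GH", 101:250)
  eligible <- roles == "NULL" & !reserved
  p_caz <- config$p_cazyme[genome_hab[gene_genome]]
  bg <- eligible & stats::runif(ntot) < p_caz
  roles[bg] <- "CAZYME"
  bg_idx <- which(bg)
  bg_is_rare <- stats::runif(length(bg_idx)) < 0.5
  caz_arch[bg_idx[!bg_is_rare]] <- sample(config$n_substrates,
                                          sum(!bg_is_rare), replace = TRUE)
  rare_fam <- rep(NA_character_, ntot)
  rare_fam[bg_idx[bg_is_rare]] <- sample(rare_pool, sum(bg_is_rare),
                                         replace = TRUE)
  caz_idx <- which(roles == "CAZYME")
  caz_family <- ifelse(!is.na(caz_arch[caz_idx]),
                       arch$family[caz_arch[caz_idx]], rare_fam[caz_idx])
  multi <- rep(FALSE, ntot)
  bg_arch_idx <- bg_idx[!bg_is_rare]
  multi[bg_arch_idx] <- stats::runif(length(bg_arch_idx)) < 0.25

  # EC evidence rule schedule over substrate-linked CAZymes
  arch_genes <- which(!is.na(caz_arch))
  rule <- rep(NA_integer_, ntot)
  rule[arch_genes] <- (seq_along(arch_genes) - 1L) %% 4L + 1L

  # true CAZyme HMM hits: E in [1e-40, 1e-19], coverage in [0.4, 1]
  nhit <- length(caz_idx)
  hl <- sample(100:300, nhit, replace = TRUE)
  covv <- stats::runif(nhit, 0.4, 1)
  hmm_to <- pmin(hl, pmax(1L, as.integer(ceiling(covv * hl))))
  e_true <- 10^(-stats::runif(nhit, 19, 40))
  ali_to_main <- ifelse(multi[caz_idx],
                        pmax(1L, aa[caz_idx] * 45L %/% 100L),
                        pmax(1L, pmin(aa[caz_idx], hmm_to)))
  dbcan <- data.frame(
    gene_id = gene_id[caz_idx], family = caz_family,
    hmm_length = hl, hmm_from = 1L, hmm_to = hmm_to,
    ali_from = 1L, ali_to = as.integer(ali_to_main),
    i_evalue = e_true, score = stats::runif(nhit, 80, 600),
    stringsAsFactors = FALSE)
  m_idx <- which(multi)
  if (length(m_idx)) {
    cbm_from <- pmax(2L, aa[m_idx] * 55L %/% 100L)
    dbcan <- rbind(dbcan, data.frame(
      gene_id = gene_id[m_idx], family = "CBM48",
      hmm_length = 90L, hmm_from = 1L, hmm_to = 72L,
      ali_from = as.integer(cbm_from),
      ali_to = as.integer(pmin(aa[m_idx], cbm_from + 60L)),
      i_evalue = 1e-25, score = 110,
      stringsAsFactors = FALSE))
  }

  # evidence tables per rule
  r_genes <- function(k) arch_genes[rule[arch_genes] == k]
  r1 <- r_genes(1L); r2 <- r_genes(2L); r3 <- r_genes(3L); r4 <- r_genes(4L)
  arch_ec <- function(i) arch$ec[caz_arch[i]]
  arch_fam <- function(i) arch$family[caz_arch[i]]
  dbcansub <- if (length(r1)) data.frame(
    gene_id = gene_id[r1],
    family = sprintf("%s_e%02d", arch_fam(r1), caz_arch[r1]),
    hmm_length = 150L, hmm_from = 1L, hmm_to = 120L,
    ali_from = 1L, ali_to = pmin(aa[r1], 120L),
    i_evalue = 1e-30, score = 200, ec = arch_ec(r1),
    stringsAsFactors = FALSE) else
    cbind(empty_domain_hits(), ec = character(0))
  dram <- rbind(
    if (length(r2)) data.frame(gene_id = gene_id[r2], ko_id = "K00001",
                               ec = paste(arch_ec(r2), "9.9.9.9", sep = ","),
                               source = "DRAM", stringsAsFactors = FALSE),
    if (length(c(r3, r4))) data.frame(gene_id = gene_id[c(r3, r4)],
                                      ko_id = "K09999", ec = "9.9.9.9",
                                      source = "DRAM",
                                      stringsAsFactors = FALSE))
  dram <- dram %||% data.frame(gene_id = character(), ko_id = character(),
                               ec = character(), source = character(),
                               stringsAsFactors = FALSE)
  kegg <- if (length(r4)) data.frame(gene_id = gene_id[r4], ko_id = "K00002",
                                     ec = arch_ec(r4), source = "KEGG_BLAST",
                                     stringsAsFactors = FALSE) else
    data.frame(gene_id = character(), ko_id = character(), ec = character(),
               source = character(), stringsAsFactors = FALSE)
  caz_hit <- function(i, evalue) if (length(i)) data.frame(
    query_id = gene_id[i],
    subject_id = sprintf("CAZYDB|%s|%02d", arch_fam(i), caz_arch[i]),
    pident = 80, qcov = 90, evalue = evalue, bitscore = 400,
    subject_ec = arch_ec(i), subject_family = arch_fam(i),
    subject_pul_id = "", subject_role = "", stringsAsFactors = FALSE)
  cazydb <- rbind(caz_hit(r1, 1e-150), caz_hit(r3, 1e-150),
                  caz_hit(r2, 1e-50))           # r2 rows fail the E filter
  cazydb <- cazydb %||% empty_alignment_hits()

  ## signature-gene evidence
  sig_dom <- function(i, fam) if (length(i)) data.frame(
    gene_id = gene_id[i], family = fam, hmm_length = 120L, hmm_from = 1L,
    hmm_to = 96L, ali_from = 1L, ali_to = pmin(aa[i], 90L),
    i_evalue = 1e-10, score = 60, stringsAsFactors = FALSE) else
    empty_domain_hits()
  tf_hits <- sig_dom(which(roles == "TF"), "HTH_AraC")
  stp_hits <- sig_dom(which(roles == "STP"), "GHKL_STP")
  tc_idx <- which(roles == "TRANSPORTER")
  tc_even <- tc_idx[seq_along(tc_idx) %% 2L == 0L]
  tc_odd <- setdiff(tc_idx, tc_even)
  tcdb <- if (length(tc_odd)) data.frame(
    query_id = gene_id[tc_odd], subject_id = "TCDB|2.A.1.1.1",
    pident = 45, qcov = 80, evalue = 1e-20, bitscore = 250,
    subject_ec = "", subject_family = "", subject_pul_id = "",
    subject_role = "", stringsAsFactors = FALSE) else empty_alignment_hits()
  tcdoms <- sig_dom(tc_even, "tcdom_MFS")

  ## reference maps and PUL database
  maps <- reference_maps(
    family_ec_map = data.frame(family = arch$family, ec = arch$ec,
                               stringsAsFactors = FALSE),
    substrate_map = data.frame(family = arch$family, ec = arch$ec,
                               substrate = arch$substrate,
                               stringsAsFactors = FALSE),
    pul_db = list(
      puls = data.frame(pul_id = sprintf("PUL%03d",
                                         seq_len(config$n_substrates)),
                        substrate = arch$substrate, stringsAsFactors = FALSE),
      members = data.frame(
        pul_id = rep(sprintf("PUL%03d", seq_len(config$n_substrates)), 2L),
        subject_id = c(sprintf("PUL%03d_caz", seq_len(config$n_substrates)),
                       sprintf("PUL%03d_tc", seq_len(config$n_substrates))),
        role = rep(c("CAZYME", "TRANSPORTER"),
                   each = config$n_substrates),
        stringsAsFactors = FALSE)))

  pul_hits <- empty_alignment_hits()
  if (length(planted)) {
    rows <- lapply(planted, function(p) {
      pul <- sprintf("PUL%03d", p$arch)
      wrong <- sprintf("PUL%03d", p$arch %% config$n_substrates + 1L)
      data.frame(
        query_id = c(gene_id[p$caz_rows[1L]], gene_id[p$other_row],
                     gene_id[p$caz_rows[1L]]),
        subject_id = c(paste0(pul, "_caz"), paste0(pul, "_tc"),
                       paste0(wrong, "_caz")),
        pident = 80, qcov = 90,
        evalue = c(1e-150, 1e-140, 1e-50),     # the last fails the filter
        bitscore = c(500, 300, 450),
        subject_ec = "", subject_family = "",
        subject_pul_id = c(pul, pul, wrong),
        subject_role = c("CAZYME", "TRANSPORTER", "CAZYME"),
        stringsAsFactors = FALSE)
    })
    pul_hits <- do.call(rbind, rows)
  }

  ## ---- stream 4: decoy domain hits --------------------------------------
  set.seed(streams[4L])
  ndec <- stats::rpois(1L, config$decoy_rate * ntot)
  if (ndec > 0L) {
    tgt <- sample(ntot, ndec, replace = TRUE)
    d_hl <- sample(100:300, ndec, replace = TRUE)
    e_type <- stats::runif(ndec) < 0.5
    d_e <- ifelse(e_type, 10^(-stats::runif(ndec, 5, 17)),
                  10^(-stats::runif(ndec, 19, 40)))
    d_to <- ifelse(e_type,
                   pmin(d_hl, pmax(1L, as.integer(
                     ceiling(stats::runif(ndec, 0.4, 1) * d_hl)))),
                   pmax(1L, d_hl * 30L %/% 100L))
    dbcan <- rbind(dbcan, data.frame(
      gene_id = gene_id[tgt],
      family = sample(c(arch$family, rare_pool), ndec, replace = TRUE),
      hmm_length = d_hl, hmm_from = 1L, hmm_to = as.integer(d_to),
      ali_from = 1L, ali_to = pmax(1L, aa[tgt] %/% 2L),
      i_evalue = d_e, score = stats::runif(ndec, 20, 60),
      stringsAsFactors = FALSE))
  }

  ## ---- stream 5: samples and coverage -----------------------------------
  set.seed(streams[5L])
  samples <- do.call(rbind, lapply(habitats, function(h)
    data.frame(sample_id = sprintf("%s_s%d", h,
                                   seq_len(config$n_samples[[h]])),
               habitat = h, site = paste0("site",
                                          seq_len(config$n_samples[[h]])),
               stringsAsFactors = FALSE)))
  ns <- nrow(samples)
  home <- outer(genome_hab, samples$habitat, "==")
  p_pres <- ifelse(home, config$p_present_home, config$p_present_away)
  present <- matrix(stats::runif(ng * ns), ng, ns) < p_pres
  breadth_g <- matrix(stats::runif(ng * ns, 0.15, 0.9), ng, ns)
  n_abs <- sum(!present)
  breadth_g[!present] <- stats::runif(n_abs, 0, 0.05)
  zero_mask <- !present & matrix(stats::runif(ng * ns), ng, ns) < 0.3
  breadth_g[zero_mask] <- 0
  depth_g <- matrix(stats::runif(ng * ns, 3, 40), ng, ns)
  depth_g[!present] <- stats::runif(n_abs, 0.01, 0.2)
  depth_g[breadth_g == 0] <- 0
  dimnames(present) <- dimnames(breadth_g) <- dimnames(depth_g) <-
    list(genome_id, samples$sample_id)
  contig_len <- as.integer(tapply(g_end, gene_contig, max)) + 100L
  coverage <- data.frame(
    contig_id = rep(contig_id, ns),
    sample_id = rep(samples$sample_id, each = nc),
    depth = as.vector(depth_g[contig_genome, ]),
    breadth = as.vector(breadth_g[contig_genome, ]),
    length = rep(contig_len, ns), stringsAsFactors = FALSE)

  ## ---- stream 6: expression states --------------------------------------
  set.seed(streams[6L])
  gene_present <- present[gene_genome, , drop = FALSE]
  expr <- (matrix(stats::runif(ntot * ns), ntot, ns) <
             config$p_background_expr) & gene_present
  sub_gene <- arch_genes
  if (length(sub_gene)) {
    key <- paste(gene_genome[sub_gene], caz_arch[sub_gene])
    for (uk in unique(key)) {
      rows <- sub_gene[key == uk]
      g <- gene_genome[rows[1L]]
      a <- caz_arch[rows[1L]]
      pr <- config$expression_prob[samples$habitat, arch$substrate[a]]
      state <- (stats::runif(ns) < pr) & present[g, ]
      expr[rows, ] <- matrix(state, length(rows), ns, byrow = TRUE)
    }
  }
  dimnames(expr) <- list(gene_id, samples$sample_id)

  ## ---- stream 7: read-pair counts ----------------------------------------
  set.seed(streams[7L])
  cm <- config$count_model
  if (config$noise_free) {
    counts <- ifelse(expr, max(5L, as.integer(round(cm$mean_expressed))), 0L)
  } else {
    mu <- ifelse(expr, cm$mean_expressed,
                 ifelse(gene_present, cm$mean_silent, 0))
    counts <- matrix(stats::rnbinom(ntot * ns, size = cm$dispersion,
                                    mu = as.vector(mu)), ntot, ns)
  }
  dimnames(counts) <- list(gene_id, samples$sample_id)

  ## ---- stream 8: signal peptides -----------------------------------------
  set.seed(streams[8L])
  has_sp <- roles == "CAZYME" & stats::runif(ntot) < 0.3

  ## ---- assemble tables and ledger ----------------------------------------
  genes <- data.frame(
    gene_id = gene_id, contig_id = contig_id[gene_contig],
    genome_id = genome_id[gene_genome], index_on_contig = idx_on_contig,
    start = g_start, end = g_end, strand = strand, length_nt = len,
    has_signal_peptide = has_sp, role = "NULL", stringsAsFactors = FALSE)

  fam_truth <- rep("", ntot)
  fam_truth[caz_idx] <- caz_family
  fam_truth[multi] <- vapply(which(multi), function(i)
    join_set(c(fam_truth[i], "CBM48")), character(1))
  ec_truth <- rep("", ntot)
  ec_truth[arch_genes] <- arch$ec[caz_arch[arch_genes]]
  src_truth <- rep("NONE", ntot)
  src_truth[caz_idx] <- "NONE"
  src_truth[arch_genes] <- paste0("RULE", rule[arch_genes])
  sub_truth <- rep("", ntot)
  sub_truth[arch_genes] <- arch$substrate[caz_arch[arch_genes]]

  ledger_genes <- data.frame(
    gene_id = gene_id, contig_id = contig_id[gene_contig],
    genome_id = genome_id[gene_genome],
    habitat = genome_hab[gene_genome], role = roles,
    families = fam_truth, ec_numbers = ec_truth, ec_source = src_truth,
    substrates = sub_truth, stringsAsFactors = FALSE)
  ledger_cgcs <- if (length(planted)) do.call(rbind, lapply(
    seq_along(planted), function(k) {
      p <- planted[[k]]
      n_caz <- sum(p$tpl == "CAZYME")
      data.frame(contig_id = contig_id[p$contig],
                 first_index = p$first_index, last_index = p$last_index,
                 substrate = arch$substrate[p$arch],
                 pul_id = sprintf("PUL%03d", p$arch),
                 substrate_C = if (n_caz >= 2L) arch$substrate[p$arch]
                               else "",
                 n_caz = n_caz, stringsAsFactors = FALSE)
    })) else data.frame(contig_id = character(), first_index = integer(),
                        last_index = integer(), substrate = character(),
                        pul_id = character(), substrate_C = character(),
                        n_caz = integer(), stringsAsFactors = FALSE)
  ledger_decoys <- do.call(rbind, decoys) %||%
    data.frame(contig_id = character(), kind = character(),
               first_index = integer(), last_index = integer(),
               stringsAsFactors = FALSE)
  ledger_presence <- data.frame(
    genome_id = rep(genome_id, ns),
    sample_id = rep(samples$sample_id, each = ng),
    present = as.vector(present), stringsAsFactors = FALSE)

  sim <- structure(list(
    config = config, archetypes = arch,
    genomes = data.frame(genome_id = genome_id, habitat = genome_hab,
                         completeness = completeness,
                         contamination = contamination, qc_pass = qc_pass,
                         stringsAsFactors = FALSE),
    samples = samples, genes = genes,
    dbcan_hits = as_domain_hits(dbcan),
    dbcansub_hits = dbcansub,
    tf_hits = tf_hits, stp_hits = stp_hits, tcdoms_hits = tcdoms,
    cazydb_hits = as_alignment_hits(cazydb), tcdb_hits = tcdb,
    pul_hits = pul_hits,
    dram_kos = dram, kegg_kos = kegg,
    maps = maps, coverage = coverage, counts = counts,
    ledger = list(genes = ledger_genes, cgcs = ledger_cgcs,
                  decoys = ledger_decoys, presence = ledger_presence,
                  expression = expr)), class = "cazy_sim")
  if (!is.null(dir)) write_simulation(sim, dir)
  sim
}

#' Write a simulated community to fixture files
#'
#' Serializes every table through the package's own writers (domtblout,
#' outfmt-6 tabular, 7-column gene TSV, plain TSV matrices), the truth
#' ledger under `truth/`, and a `manifest.json` listing every file with
#' its MD5 checksum and the configuration echo.
#'
#' @param sim A `cazy_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_gene_table(sim$genes, p("genes.tsv"))
  write_tsv(sim$genomes[, c("genome_id", "completeness", "contamination")],
            p("genome_quality.tsv"))
  write_tsv(sim$samples, p("samples.tsv"))
  write_domtblout(sim$dbcan_hits, p("dbcan.domtblout"))
  write_domtblout(sim$dbcansub_hits[, domain_hit_cols], p("dbcansub.domtblout"))
  write_tsv(unique(data.frame(profile = sim$dbcansub_hits$family,
                              ec = sim$dbcansub_hits$ec,
                              stringsAsFactors = FALSE)),
            p("dbcansub_meta.tsv"))
  write_domtblout(sim$tf_hits, p("tf.domtblout"))
  write_domtblout(sim$stp_hits, p("stp.domtblout"))
  write_domtblout(sim$tcdoms_hits, p("tcdoms.domtblout"))
  write_blast_tab(sim$tcdb_hits, p("tcdb.tsv"))
  write_blast_tab(sim$cazydb_hits, p("cazydb.tsv"))
  write_tsv(unique(data.frame(subject_id = sim$cazydb_hits$subject_id,
                              ec = sim$cazydb_hits$subject_ec,
                              family = sim$cazydb_hits$subject_family,
                              stringsAsFactors = FALSE)),
            p("cazydb_meta.tsv"))
  write_blast_tab(sim$pul_hits, p("pul_hits.tsv"))
  write_tsv(unique(data.frame(subject_id = sim$pul_hits$subject_id,
                              pul_id = sim$pul_hits$subject_pul_id,
                              role = sim$pul_hits$subject_role,
                              stringsAsFactors = FALSE)),
            p("pul_meta.tsv"))
  write_tsv(sim$dram_kos, p("dram_ko.tsv"))
  write_tsv(sim$kegg_kos, p("kegg_ko.tsv"))
  write_tsv(sim$maps$family_ec_map, p("family_ec_map.tsv"))
  write_tsv(sim$maps$substrate_map, p("substrate_map.tsv"))
  write_tsv(sim$maps$pul_db$puls, p("pul_db.tsv"))
  write_tsv(sim$maps$pul_db$members, p("pul_members.tsv"))
  write_tsv(sim$coverage, p("coverage.tsv"))
  write_matrix(sim$counts, p("counts.tsv"), id_col = "gene_id")
  write_tsv(sim$ledger$genes, p("truth", "genes.tsv"))
  write_tsv(sim$ledger$cgcs, p("truth", "cgcs.tsv"))
  write_tsv(sim$ledger$decoys, p("truth", "decoys.tsv"))
  write_tsv(sim$ledger$presence, p("truth", "presence.tsv"))
  write_matrix(sim$ledger$expression + 0, p("truth", "expression.tsv"),
               id_col = "gene_id")
  files <- sort(c(list.files(dir, pattern = "\\.(tsv|domtblout)$"),
                  file.path("truth",
                            list.files(file.path(dir, "truth")))))
  manifest <- list(
    files = data.frame(name = files,
                       md5 = unname(tools::md5sum(file.path(dir, files))),
                       bytes = file.size(file.path(dir, files)),
                       stringsAsFactors = FALSE),
    seed = sim$config$seed,
    n_genes = nrow(sim$genes))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a simulated community back from fixture files
#'
#' Reconstructs the input tables (not the ledger draws) from a directory
#' written by [write_simulation()], using the package's parsers; the truth
#' ledger is loaded from `truth/`.
#'
#' @param dir Directory written by [write_simulation()].
#' @return A list of class `cazy_sim` (config slot carries only the seed
#'   echo from the manifest).
#' @export
read_simulation <- function(dir) {
  p <- function(...) file.path(dir, ...)
  submeta <- read_tsv(p("dbcansub_meta.tsv"))
  dbcansub <- read_domtblout(p("dbcansub.domtblout"))
  dbcansub$ec <- submeta$ec[match(dbcansub$family, submeta$profile)]
  dbcansub$ec[is.na(dbcansub$ec)] <- ""
  expr <- read_matrix(p("truth", "expression.tsv")) > 0
  structure(list(
    config = NULL, archetypes = NULL,
    genomes = read_genome_quality(p("genome_quality.tsv")),
    samples = read_tsv(p("samples.tsv")),
    genes = read_gene_table(p("genes.tsv")),
    dbcan_hits = read_domtblout(p("dbcan.domtblout")),
    dbcansub_hits = dbcansub,
    tf_hits = read_domtblout(p("tf.domtblout")),
    stp_hits = read_domtblout(p("stp.domtblout")),
    tcdoms_hits = read_domtblout(p("tcdoms.domtblout")),
    cazydb_hits = read_blast_tab(p("cazydb.tsv"),
                                 metadata = read_tsv(p("cazydb_meta.tsv"))),
    tcdb_hits = read_blast_tab(p("tcdb.tsv")),
    pul_hits = read_blast_tab(p("pul_hits.tsv"),
                              metadata = read_tsv(p("pul_meta.tsv"))),
    dram_kos = read_ko_table(p("dram_ko.tsv")),
    kegg_kos = read_ko_table(p("kegg_ko.tsv")),
    maps = read_reference_maps(p("family_ec_map.tsv"),
                               p("substrate_map.tsv"),
                               p("pul_db.tsv"), p("pul_members.tsv")),
    coverage = read_coverage(p("coverage.tsv")),
    counts = read_matrix(p("counts.tsv")),
    ledger = list(genes = read_tsv(p("truth", "genes.tsv")),
                  cgcs = read_tsv(p("truth", "cgcs.tsv")),
                  decoys = read_tsv(p("truth", "decoys.tsv")),
                  presence = read_tsv(p("truth", "presence.tsv")),
                  expression = expr)), class = "cazy_sim")
}
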