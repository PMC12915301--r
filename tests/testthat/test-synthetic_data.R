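small_cfg <- function(seed = 5, ...) {
  scenario_estuary(seed = seed, n_genomes = 8L, n_lowq = 1L,
                   n_planted_cgcs = 5L, n_decoy_cgcs = 5L,
                   n_samples = c(water = 2L, sediment = 2L),
                   noise_free = TRUE, ...)
}

test_that("the generator is deterministic given the seed", {
  s1 <- simulate_community(small_cfg())
  s2 <- simulate_community(small_cfg())
  expect_identical(s1$ledger, s2$ledger)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$dbcan_hits, s2$dbcan_hits)
  s3 <- simulate_community(small_cfg(seed = 6))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("written fixture sets are byte-identical across runs and parse back", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_community(small_cfg(), dir = d1)
  simulate_community(small_cfg(), dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  m1 <- unname(tools::md5sum(file.path(d1, f1)))
  m2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(m1, m2)
  back <- read_simulation(d1)
  expect_identical(nrow(back$genes),
                   nrow(simulate_community(small_cfg())$genes))
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_true(length(manifest$files) > 10)
})

test_that("decoy hits never survive the published thresholds", {
  sim <- simulate_community(small_cfg(decoy_rate = 2))
  kept <- filter_hits(sim$dbcan_hits)
  truth <- sim$ledger$genes
  # every surviving (gene, family) pair is part of the planted truth
  fams <- strsplit(truth$families[match(kept$gene_id, truth$gene_id)], ",")
  ok <- mapply(function(f, tf) f %in% tf, kept$family, fams)
  expect_true(all(ok))
  # and margins are constructed: decoys are a decade/0.05 away
  cov <- (sim$dbcan_hits$hmm_to - sim$dbcan_hits$hmm_from + 1) /
    sim$dbcan_hits$hmm_length
  fails <- !(sim$dbcan_hits$i_evalue < 1e-18 & cov >= 0.35)
  expect_true(all(sim$dbcan_hits$i_evalue[fails] >= 1e-17 |
                    cov[fails] <= 0.30))
})

test_that("noise-free counts encode the planted expression states exactly", {
  sim <- simulate_community(small_cfg())
  expect_identical(unname(sim$counts >= 5), unname(sim$ledger$expression))
  silent <- simulate_community(small_cfg(
    expression_prob = matrix(0, 2, 6,
                             dimnames = list(c("water", "sediment"), NULL)),
    p_background_expr = 0, decoy_rate = 0))
  expect_true(all(silent$counts == 0))
  expect_false(any(silent$ledger$expression))
})

test_that("noisy count marginals match the negative-binomial model", {
  cfg <- scenario_estuary(seed = 19, n_genomes = 30L,
                          n_samples = c(water = 2L, sediment = 2L),
                          noise_free = FALSE)
  sim <- simulate_community(cfg)
  expr <- sim$ledger$expression
  x <- sim$counts[expr]
  expect_gte(length(x), 1000)
  mu <- cfg$count_model$mean_expressed
  sizev <- cfg$count_model$dispersion
  se <- sqrt((mu + mu^2 / sizev) / length(x))
  expect_lt(abs(mean(x) - mu), 3 * se)
})

test_that("infeasible or invalid configurations are rejected up front", {
  expect_error(sim_config(genes_per_contig = c(11L, 15L)), "infeasible")
  expect_error(sim_config(p_cazyme = c(water = 1.2, sediment = 0.2)),
               "probabilities")
  expect_error(sim_config(gene_length_nt = c(301L, 1500L)), "multiples")
  expect_error(sim_config(count_model = list(mean_expressed = 2,
                                             mean_silent = 1,
                                             dispersion = 5)),
               "mean_expressed")
  expect_error(
    simulate_community(sim_config(n_genomes = 1L, n_lowq = 0L,
                                  contigs_per_genome = c(1L, 1L),
                                  n_planted_cgcs = 5L, n_decoy_cgcs = 0L)),
    "infeasible")
})

test_that("the estuary scenario plants its habitat contrasts", {
  cfg <- scenario_estuary(seed = 23, n_genomes = 50L,
                          n_samples = c(water = 1L, sediment = 1L),
                          noise_free = TRUE)
  expect_gt(cfg$p_cazyme[["sediment"]], cfg$p_cazyme[["water"]])
  expect_true(all(cfg$expression_prob["water", ] >
                    cfg$expression_prob["sediment", ]))
  sim <- simulate_community(cfg)
  res <- suppressMessages(run_pipeline(sim))
  fam <- res$family_long
  gh_per_sample <- tapply(fam$family, fam$habitat, function(f)
    length(unique(grep("^GH", f, value = TRUE))))
  expect_gt(gh_per_sample[["sediment"]], gh_per_sample[["water"]])
})
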