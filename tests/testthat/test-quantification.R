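test_that("genome quality boundaries are inclusive", {
  q <- data.frame(genome_id = c("m1", "m2", "m3"),
                  completeness = c(50.0, 49.9, 90),
                  contamination = c(5.0, 1.0, 5.1))
  expect_identical(filter_genome_quality(q), "m1")
  expect_identical(length(filter_genome_quality(q[0, ])), 0L)
})

test_that("genome breadth is the contig-length-weighted mean", {
  cov <- data.frame(contig_id = c("c1", "c2"), sample_id = "s1",
                    depth = c(2, 1), breadth = c(0.2, 0.05),
                    length = c(10000, 90000))
  map <- data.frame(contig_id = c("c1", "c2"), genome_id = "m1")
  got <- genome_presence(cov, map)
  expect_equal(got$breadth, 0.065)
  expect_false(got$present)

  cov$breadth <- c(0.10, 0.10)               # exactly at the threshold
  expect_true(genome_presence(cov, map)$present)

  cov$breadth <- c(0, 0)
  cov$depth <- c(0, 0)
  expect_false(genome_presence(cov, map)$present)

  expect_error(genome_presence(cov, map[1, , drop = FALSE]),
               "without genome")
})

test_that("read-pair floor zeroes cells below five and keeps the boundary", {
  m <- matrix(c(4, 5, 0, 12), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  got <- filter_counts(m)
  expect_identical(as.vector(got), c(0, 5, 0, 12))
  zeros <- matrix(0, 2, 2, dimnames = dimnames(m))
  expect_identical(filter_counts(zeros), zeros)
  frac <- m
  frac[1, 1] <- 1.5
  expect_error(filter_counts(frac), "integers")
})

test_that("TPM matches the worked example and always sums to one million", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  lens <- c(g1 = 1000, g2 = 2000)
  tpm <- tpm_normalize(counts, lens)
  expect_equal(tpm["g1", 1], 2 / 3 * 1e6, tolerance = 1e-9)
  expect_equal(tpm["g2", 1], 1 / 3 * 1e6, tolerance = 1e-9)

  single <- matrix(c(7, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(tpm_normalize(single, lens)["g1", 1], 1e6)

  set.seed(5)
  for (i in 1:20) {
    m <- matrix(rpois(30, 20), 10, 3,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
    l <- stats::setNames(sample(300:3000, 10), rownames(m))
    cs <- colSums(tpm_normalize(m, l))
    nz <- colSums(m) > 0
    expect_equal(unname(cs[nz]), rep(1e6, sum(nz)), tolerance = 1e-6)
  }
  expect_error(tpm_normalize(counts, c(g1 = 0, g2 = 100)), "positive")
})

test_that("count filtering must precede normalization", {
  counts <- matrix(c(4, 996), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  lens <- c(g1 = 1000, g2 = 1000)
  pipeline <- tpm_normalize(filter_counts(counts), lens)
  reversed <- tpm_normalize(counts, lens)
  expect_identical(pipeline["g1", 1], 0)
  expect_gt(reversed["g1", 1], 0)
  expect_false(identical(pipeline, reversed))
})

test_that("per-capita expression divides by depth and is scale-equivariant", {
  tpm <- matrix(100, 1, 1, dimnames = list("m1", "s1"))
  depth <- matrix(20, 1, 1, dimnames = list("m1", "s1"))
  expect_equal(per_capita(tpm, depth)["m1", "s1"], 5)
  zero <- matrix(0, 1, 1, dimnames = list("m1", "s1"))
  expect_true(is.na(per_capita(tpm, zero)["m1", "s1"]))

  set.seed(6)
  t2 <- matrix(runif(12, 1, 100), 4, 3,
               dimnames = list(paste0("m", 1:4), paste0("s", 1:3)))
  d2 <- matrix(runif(12, 0.5, 30), 4, 3, dimnames = dimnames(t2))
  for (cc in runif(5, 0.1, 10)) {
    expect_equal(per_capita(t2, d2 * cc), per_capita(t2, d2) / cc,
                 tolerance = 1e-12)
    expect_equal(per_capita(t2 * cc, d2 * cc), per_capita(t2, d2),
                 tolerance = 1e-12)
  }
})

test_that("TPM aggregation duplicates multi-EC genes into every key", {
  tpm <- matrix(c(10, 5, 10, 0), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ann <- data.frame(gene_id = c("g1", "g2"),
                    families = "GH13",
                    ec_numbers = c("3.2.1.1,3.2.1.4", "3.2.1.1"),
                    ec_source = "RULE1", substrates = "",
                    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("g1", "g2"), genome_id = "m1",
                      stringsAsFactors = FALSE)
  got <- aggregate_tpm(tpm, ann, genes, by = "ec")
  s1 <- got[got$sample_id == "s1", ]
  expect_equal(s1$tpm[s1$key == "3.2.1.1"], 15)    # summed within the key
  expect_equal(s1$tpm[s1$key == "3.2.1.4"], 10)    # full TPM duplicated

  ann_none <- ann
  ann_none$ec_numbers <- ""
  expect_message(got2 <- aggregate_tpm(tpm, ann_none, genes, by = "ec"),
                 "dropped 2")
  expect_identical(nrow(got2), 0L)
})
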