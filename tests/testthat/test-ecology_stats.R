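test_that("richness partition splits families into habitat-unique and shared", {
  x <- data.frame(site = "site1",
                  habitat = c("water", "water", "sediment", "sediment"),
                  family = c("GH13", "GH16", "GH13", "GH5"))
  got <- richness_partition(x)
  expect_identical(got$water_only, 1L)
  expect_identical(got$sediment_only, 1L)
  expect_identical(got$shared, 1L)

  same <- data.frame(site = "s", habitat = rep(c("water", "sediment"), 3),
                     family = rep(c("a", "b", "c"), each = 2))
  got2 <- richness_partition(same)
  expect_identical(c(got2$water_only, got2$sediment_only, got2$shared),
                   c(0L, 0L, 3L))

  one <- data.frame(site = "s", habitat = "sediment",
                    family = c("a", "b"))
  got3 <- richness_partition(one)
  expect_identical(c(got3$water_only, got3$sediment_only, got3$shared),
                   c(0L, 2L, 0L))
})

test_that("inverse Simpson matches hand values and the vegan reference", {
  expect_equal(inverse_simpson(c(1, 1, 1, 1)), 4)
  expect_equal(inverse_simpson(7), 1)
  expect_equal(inverse_simpson(c(9, 1)), 1 / 0.82)
  expect_error(inverse_simpson(c(0, 0)), "all-zero")
  set.seed(31)
  for (i in 1:20) {
    v <- rpois(8, 10) + 1
    expect_equal(inverse_simpson(v),
                 unname(vegan::diversity(v, index = "invsimpson")),
                 tolerance = 1e-12)
    expect_equal(inverse_simpson(sample(v)), inverse_simpson(v))
    expect_lte(inverse_simpson(v), length(v) + 1e-12)
  }
})

test_that("Bray-Curtis matches hand values, bounds and the vegan reference", {
  expect_equal(bray_curtis(c(1, 2), c(2, 1)), 1 / 3)
  expect_equal(bray_curtis(c(3, 4), c(3, 4)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 5)), 1)
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")
  set.seed(32)
  for (i in 1:20) {
    x <- runif(6, 0, 10)
    y <- runif(6, 0, 10)
    d <- bray_curtis(x, y)
    expect_equal(d, bray_curtis(y, x))
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(d, as.numeric(vegan::vegdist(rbind(x, y))),
                 tolerance = 1e-12)
  }
})

test_that("Spearman correlation matches the worked example and cor.test", {
  got <- spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(got$rho, 0.8)
  expect_equal(spearman_cor(1:5, 1:5)$rho, 1)
  expect_equal(spearman_cor(1:5, 5:1)$rho, -1)
  expect_error(spearman_cor(c(1, 1, 1), 1:3), "constant")
  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(12)
    y <- x + rnorm(12, sd = 2)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                            exact = FALSE))
    got <- spearman_cor(x, y)
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("rank-sum comparison is exact for small groups", {
  same <- rank_sum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  sep <- rank_sum_compare(1:5, 6:10)
  expect_true(sep$U %in% c(0, 25))
  expect_equal(sep$p, 2 / choose(10, 5))
  expect_equal(round(sep$p, 4), 0.0079)
  single <- rank_sum_compare(3, 8)
  expect_equal(single$p, 1)
  expect_error(rank_sum_compare(numeric(0), 1), "non-empty")
})

test_that("exact rank-sum p equals the permutation oracle, ties included", {
  set.seed(34)
  for (i in 1:30) {
    a <- sample(1:6, sample(2:6, 1), replace = TRUE)
    b <- sample(1:6, sample(2:6, 1), replace = TRUE)
    expect_equal(rank_sum_compare(a, b)$p, oracle_ranksum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("large-sample rank-sum agrees with the normal-approximation reference", {
  set.seed(35)
  a <- rnorm(30)
  b <- rnorm(40, mean = 0.5)
  got <- rank_sum_compare(a, b)
  ref <- stats::wilcox.test(a, b, correct = FALSE, exact = FALSE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
})

test_that("expressing fractions count encoding, present, expressing genomes", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    families = "GH13", ec_numbers = "x", ec_source = "RULE1",
                    substrates = c("xylan", "xylan", "pectin"),
                    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      genome_id = c("m1", "m2", "m3"),
                      stringsAsFactors = FALSE)
  presence <- data.frame(genome_id = c("m1", "m2", "m3"),
                         sample_id = "s1", breadth = c(0.5, 0.5, 0.05),
                         depth = 1, present = c(TRUE, TRUE, FALSE))
  expressed <- matrix(c(TRUE, FALSE, TRUE), 3, 1,
                      dimnames = list(c("g1", "g2", "g3"), "s1"))
  got <- expressing_fraction(ann, genes, presence, expressed,
                             c(s1 = "water"))
  xy <- got[got$substrate == "xylan", ]
  expect_identical(xy$n_present, 2L)
  expect_identical(xy$n_expressing, 1L)
  expect_equal(xy$fraction, 0.5)
  expect_false(xy$above_half)
  pe <- got[got$substrate == "pectin", ]
  expect_identical(pe$n_present, 0L)          # encoding genome not present
  expect_true(is.na(pe$fraction))             # excluded from classification
  expect_true(is.na(pe$above_half))
})
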