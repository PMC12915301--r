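ann1 <- function(gene = "g1", fams = "GH13") {
  data.frame(gene_id = gene, families = fams, ec_numbers = "",
             ec_source = "NONE", substrates = "", stringsAsFactors = FALSE)
}

test_that("protein-database filter bounds are strict on E, inclusive on id/coverage", {
  hits <- rbind(ah("g1", e = 1e-103, pident = 35.0, qcov = 70.0),
                ah("g2", e = 1e-102, pident = 99, qcov = 99),
                ah("g3", e = 1e-110, pident = 34.9, qcov = 99),
                ah("g4", e = 1e-110, pident = 99, qcov = 69.9))
  expect_identical(filter_cazydb(hits)$query_id, "g1")
  expect_identical(nrow(filter_cazydb(empty_alignment_hits())), 0L)
})

test_that("subfamily hits are filtered under the same criteria as family hits", {
  hits <- rbind(dh("g1", "GH13_e01", e = 1e-17),
                dh("g2", "GH13_e01", e = 1e-19, hf = 1L, ht = 40L))
  got <- filter_dbcansub(hits)
  expect_identical(got$gene_id, "g2")
  expect_identical(nrow(filter_dbcansub(empty_domain_hits())), 0L)
})

test_that("the cascade stops at the first rule that yields an EC", {
  maps <- toy_maps()
  sub_hits <- cbind(dh("g1", "GH13_e01"), ec = "3.2.1.39")
  caz_conflict <- ah("g1", family = "GH13", ec = "3.2.1.133")
  got <- assign_ec(ann1(), sub_hits = sub_hits, cazydb_hits = caz_conflict,
                   maps = maps)
  expect_identical(got$ec_numbers, "3.2.1.39")   # rule 1 wins over rule 3
  expect_identical(got$ec_source, "RULE1")

  dram <- data.frame(gene_id = "g1", ko_id = "K1", ec = "3.2.1.1",
                     source = "DRAM")
  got2 <- assign_ec(ann1(), dram_kos = dram, maps = maps)
  expect_identical(got2$ec_numbers, "3.2.1.1")
  expect_identical(got2$ec_source, "RULE2")

  dram_bad <- data.frame(gene_id = "g1", ko_id = "K1", ec = "1.1.1.1",
                         source = "DRAM")
  caz <- ah("g1", family = "GH13", ec = "3.2.1.133")
  got3 <- assign_ec(ann1(), dram_kos = dram_bad, cazydb_hits = caz,
                    maps = maps)
  expect_identical(got3$ec_numbers, "3.2.1.133")
  expect_identical(got3$ec_source, "RULE3")

  got4 <- assign_ec(ann1(), maps = maps)
  expect_identical(got4$ec_numbers, "")
  expect_identical(got4$ec_source, "NONE")
})

test_that("KO agreement means membership in a family's curated EC list", {
  maps <- toy_maps()
  # gene annotated GH5: the DRAM EC is curated for GH13 only, so no match
  dram <- data.frame(gene_id = "g1", ko_id = "K1", ec = "3.2.1.1",
                     source = "DRAM")
  got <- assign_ec(ann1(fams = "GH5"), dram_kos = dram, maps = maps)
  expect_identical(got$ec_source, "NONE")
  # two families: agreement through either one suffices
  got2 <- assign_ec(ann1(fams = "GH13,GH5"), dram_kos = dram, maps = maps)
  expect_identical(got2$ec_numbers, "3.2.1.1")
  expect_identical(got2$ec_source, "RULE2")
})

test_that("assigned ECs always come from the evidence and ignore input order", {
  maps <- toy_maps()
  set.seed(77)
  for (i in 1:25) {
    caz <- rbind(ah("g1", subject = "s1", family = "GH13", ec = "3.2.1.1"),
                 ah("g1", subject = "s2", family = "GH13", ec = "3.2.1.133"),
                 ah("g1", subject = "s3", family = "GH99", ec = "5.5.5.5"))
    shuffled <- caz[sample(nrow(caz)), , drop = FALSE]
    got <- assign_ec(ann1(), cazydb_hits = shuffled, maps = maps)
    expect_identical(got$ec_numbers, "3.2.1.1,3.2.1.133")
    evidence <- c("3.2.1.1", "3.2.1.133", "5.5.5.5")
    expect_true(all(strsplit(got$ec_numbers, ",")[[1]] %in% evidence))
  }
})
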