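mk_genes <- function(roles, contig = "c1") {
  n <- length(roles)
  data.frame(gene_id = paste0(contig, "_g", seq_len(n)), contig_id = contig,
             genome_id = "m1", index_on_contig = seq_len(n) - 1L,
             start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
             strand = "+", length_nt = 501L, has_signal_peptide = FALSE,
             role = roles, stringsAsFactors = FALSE)
}

mk_members <- function(roles, cgc = "c1_CGC001") {
  data.frame(cgc_id = cgc, contig_id = "c1",
             gene_id = paste0("g", seq_along(roles)),
             index_on_contig = seq_along(roles) - 1L, role = roles,
             stringsAsFactors = FALSE)
}

test_that("cluster detection follows the two-gene gap rule", {
  g1 <- find_cgcs(mk_genes(c("CAZYME", "NULL", "NULL", "TRANSPORTER")))
  expect_identical(nrow(g1), 4L)              # one cluster spanning all 4
  expect_identical(length(unique(g1$cgc_id)), 1L)

  g2 <- find_cgcs(mk_genes(c("CAZYME", "NULL", "NULL", "NULL",
                             "TRANSPORTER")))
  expect_identical(nrow(g2), 0L)              # three intervening genes

  g3 <- find_cgcs(mk_genes(c("CAZYME", "CAZYME")))
  expect_identical(nrow(g3), 0L)              # no other signature role

  g4 <- find_cgcs(mk_genes(c("TF", "CAZYME", "NULL", "STP")))
  expect_identical(nrow(g4), 4L)

  unsorted <- mk_genes(c("CAZYME", "TF"))[2:1, ]
  expect_error(find_cgcs(unsorted), "sorted")
})

test_that("cluster spans equal the segment-construction oracle on random contigs", {
  set.seed(99)
  roles_pool <- c("CAZYME", "TRANSPORTER", "TF", "STP", "NULL")
  for (i in 1:500) {
    roles <- sample(roles_pool, sample(1:12, 1), replace = TRUE,
                    prob = c(0.25, 0.15, 0.1, 0.1, 0.4))
    got <- cgc_spans(roles)
    ora <- oracle_spans(roles)
    expect_identical(unname(got$first), ora$first)
    expect_identical(unname(got$last), ora$last)
  }
})

test_that("detected clusters are disjoint and cover all reachable signature genes", {
  set.seed(100)
  for (i in 1:100) {
    roles <- sample(c("CAZYME", "TRANSPORTER", "NULL"), 12, replace = TRUE)
    spans <- cgc_spans(roles)
    if (nrow(spans) > 1) {
      expect_true(all(spans$first[-1] > spans$last[-nrow(spans)]))
    }
  }
})

test_that("signature classification applies role precedence", {
  genes <- mk_genes(rep("NULL", 4))
  tf <- dh(genes$gene_id[1], "HTH", e = 1e-10, hf = 1L, ht = 50L)
  tcdb <- ah(genes$gene_id[2], "TCDB|1", e = 1e-20, qcov = 80)
  got <- classify_signature(genes, tf_hits = tf, tcdb_hits = tcdb,
                            cazyme_ids = genes$gene_id[1])
  expect_identical(got$role, c("CAZYME", "TRANSPORTER", "NULL", "NULL"))
  # sub-threshold evidence never assigns a role
  weak <- classify_signature(genes,
                             tf_hits = dh(genes$gene_id[3], "HTH", e = 1e-3),
                             tcdb_hits = ah(genes$gene_id[4], "TCDB|1",
                                            e = 1e-5, qcov = 80))
  expect_true(all(weak$role == "NULL"))
})

test_that("PUL homology ranks by summed bitscore among eligible PULs only", {
  maps <- toy_maps()
  members <- mk_members(c("CAZYME", "TRANSPORTER"))
  hits <- rbind(
    ah("g1", "PUL001_caz", e = 1e-150, bits = 200, pul = "PUL001",
       role = "CAZYME"),
    ah("g2", "PUL001_tc", e = 1e-140, bits = 100, pul = "PUL001",
       role = "TRANSPORTER"),
    ah("g1", "PUL002_caz", e = 1e-150, bits = 350, pul = "PUL002",
       role = "CAZYME"))                      # higher sum but CAZyme-only
  got <- predict_cgc_substrate_homology(members, hits, maps)
  expect_identical(got$pul_id, "PUL001")
  expect_identical(got$substrate, "xylan")
  expect_equal(got$summed_bitscore, 300)

  none <- predict_cgc_substrate_homology(
    members, ah("g1", "PUL001_caz", e = 1e-50, pul = "PUL001",
                role = "CAZYME"), maps)
  expect_identical(nrow(none), 0L)            # nothing below threshold

  expect_error(predict_cgc_substrate_homology(
    members, ah("alien", "PUL001_caz", e = 1e-150, pul = "PUL001",
                role = "CAZYME"), maps), "non-member")
})

test_that("PUL homology breaks ties lexicographically and dedups HSPs", {
  maps <- toy_maps()
  members <- mk_members(c("CAZYME", "TRANSPORTER"))
  mk <- function(pul, bits1, bits2) rbind(
    ah("g1", paste0(pul, "_caz"), e = 1e-150, bits = bits1, pul = pul,
       role = "CAZYME"),
    ah("g2", paste0(pul, "_tc"), e = 1e-140, bits = bits2, pul = pul,
       role = "TRANSPORTER"))
  got <- predict_cgc_substrate_homology(members,
                                        rbind(mk("PUL002", 150, 150),
                                              mk("PUL001", 100, 200)), maps)
  expect_identical(got$pul_id, "PUL001")      # equal sums: smaller id wins
  # a second HSP from the same gene to the same PUL must not inflate sums
  extra <- rbind(mk("PUL001", 100, 200),
                 ah("g1", "PUL001_caz", e = 1e-120, bits = 90,
                    pul = "PUL001", role = "CAZYME"))
  got2 <- predict_cgc_substrate_homology(members, extra, maps)
  expect_equal(got2$summed_bitscore, 300)
})

test_that("majority voting requires support and reports co-winners", {
  ann <- data.frame(gene_id = paste0("g", 1:4),
                    families = "GH13", ec_numbers = "x", ec_source = "RULE1",
                    substrates = c("xylan", "xylan", "pectin", ""),
                    stringsAsFactors = FALSE)
  members <- mk_members(rep("CAZYME", 4))
  got <- predict_cgc_substrate_voting(members, ann)
  expect_identical(got$substrates, "xylan")
  expect_identical(got$votes, 2L)

  ann2 <- ann
  ann2$substrates <- c("xylan", "pectin", "", "")
  expect_identical(nrow(predict_cgc_substrate_voting(members, ann2)), 0L)

  ann3 <- ann
  ann3$substrates <- c("xylan", "xylan", "pectin", "pectin")
  got3 <- predict_cgc_substrate_voting(members, ann3)
  expect_identical(got3$substrates, "pectin,xylan")
  expect_identical(got3$votes, 2L)
})

test_that("voting equals the brute-force tally on random member sets", {
  set.seed(202)
  subs <- c("xylan", "pectin", "starch", "chitin")
  for (i in 1:200) {
    n <- sample(1:8, 1)
    sets <- lapply(seq_len(n), function(j)
      sample(subs, sample(0:4, 1)))
    ann <- data.frame(gene_id = paste0("g", seq_len(n)), families = "GH13",
                      ec_numbers = "x", ec_source = "RULE1",
                      substrates = vapply(sets, paste, character(1),
                                          collapse = ","),
                      stringsAsFactors = FALSE)
    got <- predict_cgc_substrate_voting(mk_members(rep("CAZYME", n)), ann)
    ora <- oracle_vote(sets)
    if (is.null(ora)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(strsplit(got$substrates, ",")[[1]], ora$substrates)
      expect_identical(got$votes, as.integer(ora$votes))
    }
  }
})

test_that("adjacent tagged pairs are counted only when truly adjacent", {
  members <- mk_members(c("TRANSPORTER", "TRANSPORTER", "NULL", "CAZYME"))
  tags <- c(g1 = "susC", g2 = "susD", g4 = "susC")
  expect_identical(count_gene_pairs(members, tags, "susC", "susD"), 1L)
  apart <- mk_members(c("TRANSPORTER", "NULL", "TRANSPORTER"))
  tags2 <- c(g1 = "susC", g3 = "susD")
  expect_identical(count_gene_pairs(apart, tags2, "susC", "susD"), 0L)
  expect_identical(count_gene_pairs(members[0, ], tags, "susC", "susD"), 0L)
})
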