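# Shared fixture builders and independent oracles.

dh <- function(gene = "g1", family = "GH13", hf = 1L, ht = 100L, hl = 100L,
               af = 1L, at = 100L, e = 1e-30, score = 100) {
  data.frame(gene_id = gene, family = family, hmm_length = as.integer(hl),
             hmm_from = as.integer(hf), hmm_to = as.integer(ht),
             ali_from = as.integer(af), ali_to = as.integer(at),
             i_evalue = e, score = score, stringsAsFactors = FALSE)
}

ah <- function(query = "g1", subject = "s1", pident = 80, qcov = 90,
               e = 1e-150, bits = 400, ec = "", family = "", pul = "",
               role = "") {
  data.frame(query_id = query, subject_id = subject, pident = pident,
             qcov = qcov, evalue = e, bitscore = bits, subject_ec = ec,
             subject_family = family, subject_pul_id = pul,
             subject_role = role, stringsAsFactors = FALSE)
}

toy_maps <- function() {
  reference_maps(
    family_ec_map = data.frame(
      family = c("GH13", "GH13", "GH16_3", "GH5"),
      ec = c("3.2.1.1", "3.2.1.133", "3.2.1.39", "3.2.1.4"),
      stringsAsFactors = FALSE),
    substrate_map = data.frame(
      family = c("GH16_3", "GH13", "GH5"),
      ec = c("3.2.1.39", "3.2.1.1", "3.2.1.1"),
      substrate = c("beta-glucan", "starch", "glycogen"),
      stringsAsFactors = FALSE),
    pul_db = list(
      puls = data.frame(pul_id = c("PUL001", "PUL002"),
                        substrate = c("xylan", "pectin"),
                        stringsAsFactors = FALSE),
      members = data.frame(pul_id = c("PUL001", "PUL001", "PUL002"),
                           subject_id = c("PUL001_caz", "PUL001_tc",
                                          "PUL002_caz"),
                           role = c("CAZYME", "TRANSPORTER", "CAZYME"),
                           stringsAsFactors = FALSE)))
}

random_hits <- function(n, gene = "g1") {
  af <- sample(1:150, n, replace = TRUE)
  at <- af + sample(5:80, n, replace = TRUE)
  do.call(rbind, lapply(seq_len(n), function(i)
    dh(gene = gene, family = sample(c("GH13", "GH16_3", "CBM48", "PL1"), 1),
       hf = 1L, ht = 80L, hl = 100L, af = af[i], at = at[i],
       e = 10^(-sample(19:40, 1)), score = runif(1, 50, 300))))
}

# Exhaustive-enumeration oracle for overlap resolution: among all subsets
# satisfying the pairwise <= 50%-of-shorter overlap constraint, pick the
# one that maximises hit inclusion lexicographically by the deterministic
# priority order.
oracle_resolve <- function(hits) {
  n <- nrow(hits)
  alen <- hits$ali_to - hits$ali_from + 1L
  pri <- order(hits$i_evalue, -alen, hits$family, hits$ali_from)
  ok_pair <- function(i, j) {
    ov <- min(hits$ali_to[i], hits$ali_to[j]) -
      max(hits$ali_from[i], hits$ali_from[j]) + 1L
    ov <= 0.5 * min(alen[i], alen[j])
  }
  bits <- 2^(seq_len(n) - 1L)
  best_vec <- NULL
  best_rows <- integer(0)
  for (mask in 0:(2^n - 1)) {
    rows <- which(bitwAnd(mask, bits) > 0)
    valid <- TRUE
    if (length(rows) > 1L) {
      for (a in 1:(length(rows) - 1L)) {
        for (b in (a + 1L):length(rows)) {
          if (!ok_pair(rows[a], rows[b])) {
            valid <- FALSE
            break
          }
        }
        if (!valid) break
      }
    }
    if (!valid) next
    vec <- pri %in% rows
    if (is.null(best_vec)) {
      best_vec <- vec
      best_rows <- rows
    } else {
      d <- which(vec != best_vec)
      if (length(d) && vec[d[1L]]) {
        best_vec <- vec
        best_rows <- rows
      }
    }
  }
  sort(best_rows)
}

# Independent cluster-span oracle: split the contig at maximal runs of
# more than max_gap consecutive non-signature genes, then keep segments
# holding a CAZyme plus another signature role.
oracle_spans <- function(roles, max_gap = 2L) {
  r <- rle(roles == "NULL")
  cut <- r$values & r$lengths > max_gap
  seg_id <- rep.int(cumsum(cut), r$lengths)
  keep <- !rep.int(cut, r$lengths)
  pos <- seq_along(roles)
  first <- integer(0)
  last <- integer(0)
  for (s in unique(seg_id[keep])) {
    p <- pos[keep & seg_id == s]
    sig <- p[roles[p] != "NULL"]
    if (!length(sig)) next
    rr <- roles[sig]
    if (any(rr == "CAZYME") && any(rr %in% c("TF", "STP", "TRANSPORTER"))) {
      first <- c(first, sig[1L])
      last <- c(last, sig[length(sig)])
    }
  }
  list(first = first, last = last)
}

# Brute-force majority-vote tally, iterating substrates rather than
# tabulating votes.
oracle_vote <- function(member_sets, vote_min = 2L) {
  subs <- sort(unique(unlist(member_sets)))
  if (!length(subs)) return(NULL)
  counts <- vapply(subs, function(s)
    sum(vapply(member_sets, function(m) s %in% m, logical(1))), integer(1))
  m <- max(counts)
  if (m < vote_min) return(NULL)
  list(substrates = sort(subs[counts == m]), votes = m)
}

# Exhaustive rank-sum p-value by bitmask enumeration of group assignments,
# with U computed by direct pair counting (independent of rank arithmetic).
oracle_ranksum_p <- function(a, b) {
  v <- c(a, b)
  n <- length(v)
  n1 <- length(a)
  bits <- 2^(seq_len(n) - 1L)
  ufun <- function(rows) {
    x <- v[rows]
    y <- v[-rows]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  mu <- n1 * (n - n1) / 2
  obs <- abs(ufun(seq_len(n1)) - mu)
  devs <- numeric(0)
  for (mask in 0:(2^n - 1)) {
    rows <- which(bitwAnd(mask, bits) > 0)
    if (length(rows) != n1) next
    devs <- c(devs, abs(ufun(rows) - mu))
  }
  mean(devs >= obs - 1e-9)
}
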