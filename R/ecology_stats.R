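# Community-level summaries: richness partitions, diversity,
# dissimilarity, correlation, rank-sum comparison, expressing fractions.

#' Partition family richness between two habitats per site
#'
#' For each site, counts the CAZyme families unique to the first habitat,
#' unique to the second, and shared (a standard set partition). A site
#' missing one habitat is compared against the empty set.
#'
#' @param x Data frame `(site, habitat, family)`.
#' @param habitats Length-2 character vector naming the habitats (default
#'   `c("water", "sediment")`).
#' @return Data frame with columns `site`, `<habitat1>_only`,
#'   `<habitat2>_only`, `shared`.
#' @export
richness_partition <- function(x, habitats = c("water", "sediment")) {
  stopifnot(length(habitats) == 2L)
  sites <- sort(unique(x$site))
  out <- data.frame(site = sites, a = NA_integer_, b = NA_integer_,
                    shared = NA_integer_, stringsAsFactors = FALSE)
  for (k in seq_along(sites)) {
    a <- unique(x$family[x$site == sites[k] & x$habitat == habitats[1L]])
    b <- unique(x$family[x$site == sites[k] & x$habitat == habitats[2L]])
    out$a[k] <- length(setdiff(a, b))
    out$b[k] <- length(setdiff(b, a))
    out$shared[k] <- length(intersect(a, b))
  }
  names(out)[2:3] <- paste0(habitats, "_only")
  out
}

#' Inverse Simpson diversity
#'
#' `1 / sum(p_i^2)` with `p_i = x_i / sum(x)`; an effective-number
#' diversity measure, equal to `k` for a uniform vector of `k` positive
#' entries.
#'
#' @param x Non-negative abundance vector with positive sum.
#' @return Real value `>= 1`.
#' @export
inverse_simpson <- function(x) {
  if (any(x < 0)) fail("abundances must be non-negative")
  s <- sum(x)
  if (s <= 0) fail("inverse Simpson is undefined for an all-zero vector")
  # S^2 / sum(x^2) == 1 / sum(p^2), exact for integer-valued input
  s^2 / sum(x^2)
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|x - y|) / sum(x + y)` between two non-negative abundance
#' vectors; 0 for identical vectors, 1 for disjoint supports.
#'
#' @param x,y Equal-length non-negative vectors, not both all-zero.
#' @return Real value in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) fail("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) fail("abundances must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot <= 0) fail("Bray-Curtis is undefined for two all-zero vectors")
  sum(abs(x - y)) / tot
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using average ranks for ties; the two-sided p-value
#' comes from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (p = 0 at |rho| = 1).
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; constant vectors
#'   are an error (rho undefined).
#' @return List `(rho, p)`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n != length(y)) fail("vectors must have equal length")
  if (n < 3L) fail("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    fail("rank correlation is undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Two-sided rank-sum (Mann-Whitney) comparison
#'
#' Computes the Mann-Whitney U statistic for the first group. When both
#' groups have at most `exact_max` observations the two-sided p-value is
#' obtained by exhaustive enumeration of all group assignments of the
#' pooled values (ties handled through average ranks); otherwise the
#' normal approximation with tie correction is used, without continuity
#' correction.
#'
#' @param a,b Non-empty numeric vectors (e.g. summed TPM per sample).
#' @param exact_max Largest group size for the exact path (default 8).
#' @return List `(U, p)`.
#' @export
rank_sum_compare <- function(a, b, exact_max = 8L) {
  if (!length(a) || !length(b)) fail("both groups must be non-empty")
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    picks <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[picks], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
  } else {
    N <- n1 + n2
    ties <- table(c(a, b))
    corr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * (N + 1 - corr))
    p <- min(1, 2 * stats::pnorm(-abs((U - mu) / sigma)))
  }
  list(U = U, p = p)
}

#' Expressing fraction of substrate-encoding populations
#'
#' For every (substrate, habitat): `n_present` counts genomes that are
#' present in at least one sample of the habitat and encode at least one
#' gene for the substrate; `n_expressing` counts how many of those have at
#' least one such gene expressed in a habitat sample. The fraction
#' `n_expressing / n_present` is classified against the 0.5 line
#' (`above_half`); it is undefined (`NA`) when `n_present` is zero.
#'
#' @param annotations Annotation table with `substrates` filled.
#' @param genes Gene records (genome membership).
#' @param presence Data frame from [genome_presence()].
#' @param expressed Logical gene-by-sample matrix (counts >= threshold).
#' @param sample_habitats Named character vector `sample_id -> habitat`.
#' @return Data frame `(substrate, habitat, n_present, n_expressing,
#'   fraction, above_half)`.
#' @export
expressing_fraction <- function(annotations, genes, presence, expressed,
                                sample_habitats) {
  subs <- split_sets(annotations$substrates)
  long <- data.frame(
    gene_id = rep(annotations$gene_id, lengths(subs)),
    substrate = unlist(subs), stringsAsFactors = FALSE)
  long$genome_id <- genes$genome_id[match(long$gene_id, genes$gene_id)]
  habitats <- sort(unique(sample_habitats))
  substrates <- sort(unique(long$substrate))
  rows <- list()
  for (h in habitats) {
    smp <- names(sample_habitats)[sample_habitats == h]
    present_gen <- unique(presence$genome_id[
      presence$sample_id %in% smp & presence$present])
    for (s in substrates) {
      enc <- unique(long$genome_id[long$substrate == s])
      pres <- intersect(enc, present_gen)
      n_expr <- 0L
      for (g in pres) {
        gg <- long$gene_id[long$substrate == s & long$genome_id == g]
        gg <- intersect(gg, rownames(expressed))
        cols <- intersect(smp, colnames(expressed))
        if (length(gg) && length(cols) &&
            any(expressed[gg, cols, drop = FALSE]))
          n_expr <- n_expr + 1L
      }
      frac <- if (length(pres)) n_expr / length(pres) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        substrate = s, habitat = h, n_present = length(pres),
        n_expressing = n_expr, fraction = frac,
        above_half = if (is.na(frac)) NA else frac > 0.5,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(substrate = character(), habitat = character(),
               n_present = integer(), n_expressing = integer(),
               fraction = numeric(), above_half = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
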