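# Readers and writers for every external table the pipeline touches.
# All coordinates are 1-based inclusive (HMMER / GFF convention).

domain_hit_cols <- c("gene_id", "family", "hmm_length", "hmm_from", "hmm_to",
                     "ali_from", "ali_to", "i_evalue", "score")

alignment_hit_cols <- c("query_id", "subject_id", "pident", "qcov", "evalue",
                        "bitscore", "subject_ec", "subject_family",
                        "subject_pul_id", "subject_role")

#' Empty domain-hit table
#'
#' A zero-row table with the canonical domain-hit columns: one row per HMM
#' profile match on a protein, with profile (`hmm_*`) and query (`ali_*`)
#' coordinates, the independent domain E-value and the bit score.
#'
#' @return A zero-row `data.frame` with the domain-hit columns.
#' @export
empty_domain_hits <- function() {
  data.frame(gene_id = character(), family = character(),
             hmm_length = integer(), hmm_from = integer(), hmm_to = integer(),
             ali_from = integer(), ali_to = integer(),
             i_evalue = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Validate a domain-hit table
#'
#' Checks the invariants every domain hit must satisfy:
#' `1 <= hmm_from <= hmm_to <= hmm_length`, `1 <= ali_from <= ali_to`, and
#' `i_evalue >= 0`. Extra columns are allowed and preserved.
#'
#' @param x A data frame with at least the domain-hit columns.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
as_domain_hits <- function(x) {
  if (!is.data.frame(x)) fail("domain hits must be a data.frame")
  miss <- setdiff(domain_hit_cols, names(x))
  if (length(miss))
    fail("missing domain-hit columns: %s", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(x$hmm_length < 1)) fail("hmm_length must be a positive integer")
    if (any(x$hmm_from < 1 | x$hmm_from > x$hmm_to | x$hmm_to > x$hmm_length))
      fail("domain hits must satisfy 1 <= hmm_from <= hmm_to <= hmm_length")
    if (any(x$ali_from < 1 | x$ali_from > x$ali_to))
      fail("domain hits must satisfy 1 <= ali_from <= ali_to")
    if (any(x$i_evalue < 0)) fail("i_evalue must be non-negative")
  }
  x
}

#' Empty alignment-hit table
#'
#' Zero-row table for DIAMOND/BLAST protein alignments with optional
#' subject-side metadata (EC numbers, CAZy family, PUL membership, role).
#'
#' @return A zero-row `data.frame` with the alignment-hit columns.
#' @export
empty_alignment_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pident = numeric(), qcov = numeric(), evalue = numeric(),
             bitscore = numeric(), subject_ec = character(),
             subject_family = character(), subject_pul_id = character(),
             subject_role = character(), stringsAsFactors = FALSE)
}

#' Validate an alignment-hit table
#'
#' @param x A data frame with at least the alignment-hit columns.
#' @return `x` unchanged, or an error describing the violated bound
#'   (`0 <= pident, qcov <= 100`; `evalue >= 0`).
#' @export
as_alignment_hits <- function(x) {
  if (!is.data.frame(x)) fail("alignment hits must be a data.frame")
  miss <- setdiff(alignment_hit_cols, names(x))
  if (length(miss))
    fail("missing alignment-hit columns: %s", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(x$pident < 0 | x$pident > 100)) fail("pident must lie in [0, 100]")
    qc <- x$qcov[!is.na(x$qcov)]
    if (any(qc < 0 | qc > 100)) fail("qcov must lie in [0, 100]")
    if (any(x$evalue < 0)) fail("evalue must be non-negative")
  }
  x
}

#' Read a HMMER per-domain table (domtblout)
#'
#' Parses the whitespace-delimited per-domain output of `hmmsearch
#' --domtblout` where the target is a protein sequence and the query is an
#' HMM profile. The profile name becomes the CAZy family label after
#' stripping any trailing `".hmm"`; subfamily labels such as `"GH16_3"` are
#' kept distinct from their parent family.
#'
#' @param path Path to a domtblout file. Lines beginning with `#` are
#'   comments.
#' @return A domain-hit `data.frame` (see [empty_domain_hits()]), one row
#'   per non-comment line, in file order.
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) fail("no such file: %s", path)
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) return(empty_domain_hits())
  rows <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  nf <- lengths(rows)
  if (any(nf < 22L))
    fail("malformed domtblout line %d: expected >= 22 fields, found %d",
         keep[which(nf < 22L)[1L]], nf[which(nf < 22L)[1L]])
  col <- function(i) vapply(rows, `[[`, character(1), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v))
      fail("malformed domtblout line %d: non-numeric %s",
           keep[which(is.na(v))[1L]], what)
    v
  }
  hits <- data.frame(
    gene_id    = col(1L),
    family     = sub("\\.hmm$", "", col(4L)),
    hmm_length = as.integer(num(6L, "profile length")),
    hmm_from   = as.integer(num(16L, "hmm_from")),
    hmm_to     = as.integer(num(17L, "hmm_to")),
    ali_from   = as.integer(num(18L, "ali_from")),
    ali_to     = as.integer(num(19L, "ali_to")),
    i_evalue   = num(13L, "i-Evalue"),
    score      = num(14L, "domain score"),
    stringsAsFactors = FALSE)
  as_domain_hits(hits)
}

#' Write a domain-hit table in domtblout column order
#'
#' Emits the documented HMMER per-domain column order (23 columns) with
#' neutral placeholders for fields the hit table does not carry, so that
#' [read_domtblout()] round-trips the values.
#'
#' @param hits A domain-hit `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  hits <- as_domain_hits(hits)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
               "#------------------- ----------"), con)
  if (nrow(hits)) {
    e <- sprintf("%.10g", hits$i_evalue)
    s <- sprintf("%.10g", hits$score)
    writeLines(paste(hits$gene_id, "-", hits$ali_to, hits$family, "-",
                     hits$hmm_length, e, s, "0.0", "1", "1", e, e, s, "0.0",
                     hits$hmm_from, hits$hmm_to, hits$ali_from, hits$ali_to,
                     hits$ali_from, hits$ali_to, "0.90", "-"), con)
  }
  invisible(path)
}

#' Read a BLAST/DIAMOND tabular file (outfmt 6)
#'
#' Expects the standard 12-column layout `qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`, with an
#' optional 13th `qcovhsp` column read as query coverage. A side table keyed
#' by subject can supply EC numbers, CAZy family, PUL id and signature role
#' for each subject sequence.
#'
#' @param path Path to the tabular file.
#' @param metadata Optional `data.frame` with a `subject_id` column and any
#'   of `ec`, `family`, `pul_id`, `role`; joined onto hits by subject.
#' @param strict If `TRUE`, a hit whose subject is absent from `metadata`
#'   is an error listing the missing ids; the default lenient mode leaves
#'   the optional fields empty (public database dumps are incomplete).
#' @return An alignment-hit `data.frame` (see [empty_alignment_hits()]).
#' @export
read_blast_tab <- function(path, metadata = NULL, strict = FALSE) {
  if (!file.exists(path)) fail("no such file: %s", path)
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) return(empty_alignment_hits())
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf < 12L))
    fail("malformed tabular line %d: expected >= 12 fields, found %d",
         keep[which(nf < 12L)[1L]], nf[which(nf < 12L)[1L]])
  col <- function(i) vapply(rows, `[[`, character(1), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v))
      fail("malformed tabular line %d: non-numeric %s",
           keep[which(is.na(v))[1L]], what)
    v
  }
  qcov <- rep(NA_real_, length(rows))
  has13 <- nf >= 13L
  if (any(has13))
    qcov[has13] <- suppressWarnings(as.numeric(
      vapply(rows[has13], `[[`, character(1), 13L)))
  hits <- data.frame(
    query_id = col(1L), subject_id = col(2L),
    pident = num(3L, "pident"), qcov = qcov,
    evalue = num(11L, "evalue"), bitscore = num(12L, "bitscore"),
    subject_ec = "", subject_family = "", subject_pul_id = "",
    subject_role = "", stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    if (!"subject_id" %in% names(metadata))
      fail("metadata must have a subject_id column")
    idx <- match(hits$subject_id, metadata$subject_id)
    if (strict && anyNA(idx))
      fail("subjects absent from metadata: %s",
           paste(unique(hits$subject_id[is.na(idx)]), collapse = ", "))
    pull <- function(colname) {
      if (!colname %in% names(metadata)) return(rep("", nrow(hits)))
      v <- metadata[[colname]][idx]
      ifelse(is.na(v), "", v)
    }
    hits$subject_ec     <- pull("ec")
    hits$subject_family <- pull("family")
    hits$subject_pul_id <- pull("pul_id")
    hits$subject_role   <- pull("role")
  }
  as_alignment_hits(hits)
}

#' Write alignment hits as a 13-column tabular file
#'
#' @param hits An alignment-hit `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  hits <- as_alignment_hits(hits)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(hits)) {
    qc <- ifelse(is.na(hits$qcov), "0", sprintf("%.10g", hits$qcov))
    writeLines(paste(hits$query_id, hits$subject_id,
                     sprintf("%.10g", hits$pident), "100", "0", "0", "1",
                     "100", "1", "100", sprintf("%.10g", hits$evalue),
                     sprintf("%.10g", hits$bitscore), qc, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a gene table (GFF3 or 7-column TSV)
#'
#' Accepts either GFF3 (gene id from the `ID=` attribute, genome membership
#' from a `genome=` attribute, signal peptide from `signal_peptide=`) or a
#' headered 7-column TSV (`gene_id, contig_id, genome_id, start, end,
#' strand, signal_peptide`). Within each contig, `index_on_contig` is
#' assigned 0-based by ascending start, ties broken by end then gene id.
#'
#' @param path Path to the gene table.
#' @return A `data.frame` with columns `gene_id, contig_id, genome_id,
#'   index_on_contig, start, end, strand, length_nt, has_signal_peptide,
#'   role` (role initialised to `"NULL"`), ordered by contig then index.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) fail("no such file: %s", path)
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  is_gff <- length(body) > 0 &&
    length(strsplit(body[1L], "\t", fixed = TRUE)[[1L]]) == 9L
  if (is_gff) {
    rows <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(rows) != 9L)) fail("malformed GFF3 row")
    attr_get <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
      vapply(m, function(x) if (length(x) == 2L) x[2L] else "", character(1))
    }
    attrs <- vapply(rows, `[[`, character(1), 9L)
    genes <- data.frame(
      gene_id   = attr_get(attrs, "ID"),
      contig_id = vapply(rows, `[[`, character(1), 1L),
      genome_id = attr_get(attrs, "genome"),
      start     = as.integer(vapply(rows, `[[`, character(1), 4L)),
      end       = as.integer(vapply(rows, `[[`, character(1), 5L)),
      strand    = vapply(rows, `[[`, character(1), 7L),
      signal_peptide = tolower(attr_get(attrs, "signal_peptide")) %in%
        c("true", "1", "yes"),
      stringsAsFactors = FALSE)
    if (any(!nzchar(genes$gene_id))) fail("GFF3 row without an ID attribute")
  } else {
    genes <- read_tsv(path)
    need <- c("gene_id", "contig_id", "genome_id", "start", "end", "strand",
              "signal_peptide")
    miss <- setdiff(need, names(genes))
    if (length(miss))
      fail("gene table missing columns: %s", paste(miss, collapse = ", "))
    genes$signal_peptide <- as.logical(genes$signal_peptide) |
      genes$signal_peptide %in% c(1, "1", "true", "TRUE", "yes")
  }
  build_gene_records(genes)
}

#' Assemble validated gene records from a raw gene table
#'
#' @param genes Data frame with `gene_id, contig_id, genome_id, start, end,
#'   strand, signal_peptide`.
#' @return Gene records with `index_on_contig`, `length_nt` and a `role`
#'   column (initially `"NULL"`); see [read_gene_table()].
#' @export
build_gene_records <- function(genes) {
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    fail("duplicate gene_id: %s", paste(unique(dup), collapse = ", "))
  bad <- genes$start > genes$end
  if (any(bad))
    fail("start > end for gene %s", genes$gene_id[which(bad)[1L]])
  ord <- order(genes$contig_id, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$index_on_contig <- stats::ave(
    seq_len(nrow(genes)), genes$contig_id,
    FUN = function(i) seq_along(i) - 1L)
  genes$length_nt <- genes$end - genes$start + 1L
  genes$has_signal_peptide <- as.logical(genes$signal_peptide)
  genes$role <- "NULL"
  rownames(genes) <- NULL
  genes[, c("gene_id", "contig_id", "genome_id", "index_on_contig", "start",
            "end", "strand", "length_nt", "has_signal_peptide", "role")]
}

#' Write a gene table as 7-column TSV
#'
#' @param genes Gene records as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, contig_id = genes$contig_id,
                    genome_id = genes$genome_id, start = genes$start,
                    end = genes$end, strand = genes$strand,
                    signal_peptide = tolower(as.character(
                      genes$has_signal_peptide)),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Read a numeric matrix from TSV
#'
#' First row holds sample ids, first column row ids. Missing cells and
#' ragged rows are errors (no silent zero-fill); negative values are
#' rejected.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix with row and column names. A header-only file
#'   yields a zero-row matrix that preserves the sample ids.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) fail("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) fail("matrix file is empty (no header): %s", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  samples <- header[-1L]
  if (length(lines) == 1L)
    return(matrix(numeric(0), nrow = 0, ncol = length(samples),
                  dimnames = list(character(0), samples)))
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf != length(header)))
    fail("ragged matrix row %d: expected %d fields, found %d",
         which(nf != length(header))[1L] + 1L, length(header),
         nf[which(nf != length(header))[1L]])
  ids <- vapply(rows, `[[`, character(1), 1L)
  vals <- suppressWarnings(vapply(rows, function(r)
    as.numeric(r[-1L]), numeric(length(samples))))
  m <- if (length(samples) == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(m)) fail("missing or non-numeric cell in matrix %s", path)
  if (any(m < 0)) fail("negative value in matrix %s", path)
  dimnames(m) <- list(ids, samples)
  m
}

#' Write a numeric matrix as TSV
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the row-id header cell.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_col = "id") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  if (nrow(m)) {
    body <- apply(m, 1L, function(r) paste(sprintf("%.10g", r),
                                           collapse = "\t"))
    writeLines(paste(rownames(m), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a genome-quality table
#'
#' @param path TSV with columns `genome_id, completeness, contamination`
#'   (percent, contamination after accounting for strain heterogeneity).
#' @return The validated data frame.
#' @export
read_genome_quality <- function(path) {
  q <- read_tsv(path)
  miss <- setdiff(c("genome_id", "completeness", "contamination"), names(q))
  if (length(miss))
    fail("quality table missing columns: %s", paste(miss, collapse = ", "))
  if (any(q$completeness < 0 | q$completeness > 100) ||
      any(q$contamination < 0 | q$contamination > 100))
    fail("completeness/contamination must lie in [0, 100]")
  q
}

#' Read a contig coverage table
#'
#' @param path TSV with columns `contig_id, sample_id, depth, breadth,
#'   length` (depth: mean fold coverage; breadth: fraction of positions
#'   covered in `[0, 1]`; length in nt).
#' @return The validated data frame.
#' @export
read_coverage <- function(path) {
  cv <- read_tsv(path)
  miss <- setdiff(c("contig_id", "sample_id", "depth", "breadth", "length"),
                  names(cv))
  if (length(miss))
    fail("coverage table missing columns: %s", paste(miss, collapse = ", "))
  if (any(cv$depth < 0)) fail("depth must be non-negative")
  if (any(cv$breadth < 0 | cv$breadth > 1)) fail("breadth must lie in [0, 1]")
  if (any(cv$depth == 0 & cv$breadth > 0))
    fail("depth = 0 implies breadth = 0")
  cv
}

#' Read a KO annotation table
#'
#' @param path TSV with columns `gene_id, ko_id, ec, source` where `ec` is a
#'   comma-joined (possibly empty) EC set and `source` is `DRAM` or
#'   `KEGG_BLAST`.
#' @return The data frame with `ec` coerced to character ("" for none).
#' @export
read_ko_table <- function(path) {
  k <- read_tsv(path, colClasses = "character")
  miss <- setdiff(c("gene_id", "ko_id", "ec", "source"), names(k))
  if (length(miss))
    fail("KO table missing columns: %s", paste(miss, collapse = ", "))
  k$ec <- ifelse(is.na(k$ec), "", k$ec)
  k
}

#' Assemble reference maps for EC and substrate assignment
#'
#' @param family_ec_map Data frame `(family, ec)`: the curated EC numbers
#'   associated with each CAZy family.
#' @param substrate_map Data frame `(family, ec, substrate)`: one row per
#'   curated (family, EC) to substrate-category triple. Every family used
#'   here must appear in `family_ec_map`.
#' @param pul_db List with `puls` (`pul_id, substrate`) and `members`
#'   (`pul_id, subject_id, role`); every PUL must have at least one member.
#' @return A list of class `reference_maps`.
#' @export
reference_maps <- function(family_ec_map, substrate_map,
                           pul_db = list(puls = NULL, members = NULL)) {
  stopifnot(all(c("family", "ec") %in% names(family_ec_map)),
            all(c("family", "ec", "substrate") %in% names(substrate_map)))
  orphan <- setdiff(substrate_map$family, family_ec_map$family)
  if (length(orphan))
    fail("substrate_map families absent from family_ec_map: %s",
         paste(orphan, collapse = ", "))
  if (!is.null(pul_db$puls) && nrow(pul_db$puls)) {
    empty <- setdiff(pul_db$puls$pul_id, pul_db$members$pul_id)
    if (length(empty))
      fail("PUL without members: %s", paste(empty, collapse = ", "))
  }
  structure(list(family_ec_map = family_ec_map, substrate_map = substrate_map,
                 pul_db = pul_db), class = "reference_maps")
}

#' Read reference maps from TSV files
#'
#' @param family_ec_path TSV `(family, ec)`.
#' @param substrate_path TSV `(family, ec, substrate)`.
#' @param pul_path,pul_members_path Optional TSVs `(pul_id, substrate)` and
#'   `(pul_id, subject_id, role)`.
#' @return A `reference_maps` object.
#' @export
read_reference_maps <- function(family_ec_path, substrate_path,
                                pul_path = NULL, pul_members_path = NULL) {
  pul_db <- list(puls = NULL, members = NULL)
  if (!is.null(pul_path)) {
    pul_db$puls <- read_tsv(pul_path)
    pul_db$members <- read_tsv(pul_members_path)
  }
  reference_maps(read_tsv(family_ec_path), read_tsv(substrate_path), pul_db)
}
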