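# Substrate prediction: joint (family, EC) lookup against a curated map.

#' Default curated reference maps shipped with the package
#'
#' A minimal substrate map of well-characterized (family, EC, substrate)
#' triples (amylases on starch, xylanases on xylan, pectate and alginate
#' lyases, and so on) with the matching family-to-EC list; intended as a
#' documented starting point, not a complete ontology. The full map used
#' in a real study is an input file the analyst curates.
#'
#' @return A [reference_maps()] object with an empty PUL database.
#' @export
default_reference_maps <- function() {
  ext <- function(f) system.file("extdata", f, package = "cazyscape",
                                 mustWork = TRUE)
  read_reference_maps(ext("family_ec_map.tsv"), ext("substrate_map.tsv"))
}

#' Predict substrates for EC-bearing CAZyme genes
#'
#' Genes without EC numbers get no substrates. Otherwise the substrate set
#' is the union, over all pairs of the gene's families and ECs, of the
#' curated substrate categories keyed by that `(family, ec)` pair; a
#' missing key contributes nothing. Matching requires the family and the
#' EC to co-occur as a curated key (the stricter, joint reading of
#' matching both against the map).
#'
#' @param annotations Annotation table with `families` and `ec_numbers`.
#' @param maps A [reference_maps()] object (uses `substrate_map`).
#' @return `annotations` with the `substrates` column filled (comma-joined,
#'   sorted).
#' @export
predict_gene_substrates <- function(annotations, maps) {
  sm <- maps$substrate_map
  key <- paste(sm$family, sm$ec, sep = "\r")
  annotations$substrates <- vapply(seq_len(nrow(annotations)), function(i) {
    ecs <- split_set(annotations$ec_numbers[i])
    if (!length(ecs)) return("")
    fams <- split_set(annotations$families[i])
    want <- as.vector(outer(fams, ecs, paste, sep = "\r"))
    join_set(sm$substrate[key %in% want])
  }, character(1))
  annotations
}

#' Census of substrate-encoding genomes and genes per habitat
#'
#' Counts, for every (substrate, habitat) pair, how many distinct genomes
#' harbor at least one gene predicted to target the substrate, and the
#' total number of such genes. A genome is counted once per substrate
#' regardless of gene count.
#'
#' @param annotations Annotation table with `substrates` filled.
#' @param genes Gene records mapping `gene_id` to `genome_id`.
#' @param genome_habitats Data frame `(genome_id, habitat)`.
#' @return Data frame `(substrate, habitat, n_encoding_mags, n_genes)`;
#'   empty when no gene carries a substrate.
#' @export
substrate_census <- function(annotations, genes, genome_habitats) {
  has <- annotations[nzchar(annotations$substrates), , drop = FALSE]
  empty <- data.frame(substrate = character(), habitat = character(),
                      n_encoding_mags = integer(), n_genes = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(has)) return(empty)
  gidx <- match(has$gene_id, genes$gene_id)
  if (anyNA(gidx))
    fail("genes with unknown genome: %s",
         paste(has$gene_id[is.na(gidx)], collapse = ", "))
  genome <- genes$genome_id[gidx]
  habitat <- genome_habitats$habitat[match(genome, genome_habitats$genome_id)]
  if (anyNA(habitat))
    fail("genomes without habitat label: %s",
         paste(unique(genome[is.na(habitat)]), collapse = ", "))
  subs <- split_sets(has$substrates)
  long <- data.frame(
    substrate = unlist(subs),
    genome = rep(genome, lengths(subs)),
    habitat = rep(habitat, lengths(subs)),
    stringsAsFactors = FALSE)
  keys <- unique(long[, c("substrate", "habitat")])
  keys <- keys[order(keys$substrate, keys$habitat), , drop = FALSE]
  keys$n_encoding_mags <- mapply(function(s, h)
    length(unique(long$genome[long$substrate == s & long$habitat == h])),
    keys$substrate, keys$habitat)
  keys$n_genes <- mapply(function(s, h)
    sum(long$substrate == s & long$habitat == h),
    keys$substrate, keys$habitat)
  rownames(keys) <- NULL
  keys
}
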