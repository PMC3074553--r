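# fixture builders shared across test files; everything is generated in code

make_tx <- function(exons, chrom = "chr1", strand = "+", id = "tx1",
                    sym = "G1", start = NULL, end = NULL) {
  exons <- matrix(exons, ncol = 2, byrow = TRUE)
  if (is.null(start)) start <- min(exons[, 1])
  if (is.null(end)) end <- max(exons[, 2])
  transcript_model(id, sym, chrom, strand, start, end, exons)
}

make_gene <- function(..., sym = "G1") gene_model(sym, list(...))

reps_df <- function(start, end, chrom = "chr1", family = "AluY") {
  repeat_intervals(rep(chrom, length(start)), start, end,
                   rep(family, length(start)))
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  close(con)
  path
}

# a small genome spec for machinery tests (gene sizes shrunk for speed; the
# statistical-fidelity tests use the package defaults instead)
tiny_spec <- function(n_genes = 40L, chroms = c("chrA", "chrB"),
                      r = 0.3, shape = 0.8, scale = 1.2, ...) {
  synthetic_genome_spec(
    chromosomes = data.frame(chrom = chroms, n_genes = n_genes,
                             r = r, shape = shape, scale = scale,
                             stringsAsFactors = FALSE),
    gene_length_log10_mean = 3.7, gene_length_log10_sd = 0.3,
    exon_geom_p = 0.3, ...)
}

# cancer-gene class table derived from a feature table, written as TSV
write_classes_file <- function(features, seed = 1,
                               path = tempfile(fileext = ".tsv")) {
  set.seed(seed)
  n <- nrow(features)
  dominance <- sample(c("dominant", "recessive", "Rec?"), n, TRUE,
                      prob = c(0.65, 0.3, 0.05))
  cell_type <- sample(c("somatic", "germline", "somatic/germline"), n, TRUE,
                      prob = c(0.7, 0.2, 0.1))
  translocation <- sample(c("yes", "no"), n, TRUE)
  utils::write.table(
    data.frame(gene_symbol = features$gene, dominance = dominance,
               cell_type = cell_type, translocation = translocation),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
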