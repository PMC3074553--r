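test_that("BED12 blocks become exons with the intron in between", {
  line <- paste("chr1", 1000, 1600, "tx1|GENE1", 0, "+", 1000, 1600, 0, 2,
                "100,200,", "0,400,", sep = "\t")
  path <- tempfile(); writeLines(line, path)
  out <- read_gene_models(path, "bed12")
  expect_length(out$genes, 1L)
  tx <- out$genes[[1]]$transcripts[[1]]
  expect_equal(unname(tx$exons),
               matrix(c(1000, 1100, 1400, 1600), ncol = 2, byrow = TRUE))
  expect_equal(unname(transcript_introns(tx)),
               matrix(c(1100, 1400), ncol = 2))
  expect_equal(tx$gene_symbol, "GENE1")
})

test_that("GTF 1-based closed coordinates convert to half-open", {
  lines <- c(
    'chr2\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "G2"; transcript_id "T2";',
    'chr2\tsrc\texon\t300\t400\t.\t+\t.\tgene_id "G2"; transcript_id "T2";')
  path <- tempfile(); writeLines(lines, path)
  out <- read_gene_models(path, "gtf")
  tx <- out$genes[[1]]$transcripts[[1]]
  expect_equal(unname(tx$exons[1, ]), c(99, 200))
  expect_equal(unname(tx$exons[1, 2] - tx$exons[1, 1]), 101)
})

test_that("single-exon genes are excluded and reported; bookkeeping conserves totals", {
  lines <- c(
    paste("chr1", 0, 500, "t1|SINGLE", 0, "+", 0, 500, 0, 1, "500,", "0,",
          sep = "\t"),
    paste("chr1", 1000, 2000, "t2|MULTI", 0, "+", 1000, 2000, 0, 2,
          "100,100,", "0,900,", sep = "\t"),
    # a single-exon transcript of a gene that also has a multi-exon one
    paste("chr1", 1000, 1100, "t3|MULTI", 0, "+", 1000, 1100, 0, 1, "100,",
          "0,", sep = "\t"))
  path <- tempfile(); writeLines(lines, path)
  out <- read_gene_models(path, "bed12")
  expect_equal(out$excluded_single_exon, "SINGLE")
  expect_equal(names(out$genes), "MULTI")
  expect_length(out$genes[["MULTI"]]$transcripts, 1L)
  # |genes in| = |gene models out| + |excluded|
  expect_equal(2L, length(out$genes) + length(out$excluded_single_exon))
})

test_that("malformed annotation lines raise errors naming the line", {
  path <- tempfile()
  writeLines(c(paste("chr1", 0, 500, "a|A", 0, "+", 0, 500, 0, 1, "500,",
                     "0,", sep = "\t"),
               "chr1\tnot\tenough"), path)
  expect_error(read_gene_models(path, "bed12"), "line 2")
  writeLines('chr1\tsrc\texon\tX\t200\t.\t+\t.\tgene_id "g"; transcript_id "t";',
             path)
  expect_error(read_gene_models(path, "gtf"), "line 1")
  # overlapping exon blocks within one transcript
  writeLines(paste("chr1", 0, 500, "a|A", 0, "+", 0, 500, 0, 2, "300,300,",
                   "0,200,", sep = "\t"), path)
  expect_error(read_gene_models(path, "bed12"), "overlap")
})

test_that("coordinates round-trip exactly between formats and internal form", {
  line <- paste("chr3", 12345, 99999, "t|G", 0, "-", 12345, 99999, 0, 3,
                "100,250,400,", "0,20000,87254,", sep = "\t")
  path <- tempfile(); writeLines(line, path)
  tx <- read_gene_models(path, "bed12")$genes[[1]]$transcripts[[1]]
  sizes <- tx$exons[, 2] - tx$exons[, 1]
  starts <- tx$exons[, 1] - tx$start
  regen <- paste(tx$chrom, tx$start, tx$end, paste0(tx$transcript_id, "|",
                 tx$gene_symbol), 0, tx$strand, tx$start, tx$end, 0,
                 nrow(tx$exons),
                 paste0(paste(sizes, collapse = ","), ","),
                 paste0(paste(starts, collapse = ","), ","), sep = "\t")
  expect_identical(regen, line)
  # GTF round-trip on the same exons
  gtf <- sprintf('chr3\tsrc\texon\t%d\t%d\t.\t-\t.\tgene_id "G"; transcript_id "t";',
                 tx$exons[, 1] + 1, tx$exons[, 2])
  path2 <- tempfile(); writeLines(gtf, path2)
  tx2 <- read_gene_models(path2, "gtf")$genes[[1]]$transcripts[[1]]
  expect_equal(unname(tx2$exons), unname(tx$exons))
})

test_that("repeat readers normalize coordinates and filter by family", {
  out_lines <- c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin  end (left)    repeat class/family",
    "",
    " 1500  10.0  0.1  0.2  chr1     5001  5300 (100) +  AluSx  SINE/Alu  1 300 (0) 1",
    " 1200  12.0  0.1  0.2  chr1     9001  9400 (100) C  L1PA3  LINE/L1   1 400 (0) 2")
  path <- tempfile(); writeLines(out_lines, path)
  reps <- read_repeat_intervals(path, "rmsk_out")
  expect_equal(nrow(reps), 1L)
  expect_equal(reps$start, 5000)
  expect_equal(reps$end, 5300)
  expect_equal(reps$family, "AluSx")
  # empty filter keeps the L1 record too
  expect_equal(nrow(read_repeat_intervals(path, "rmsk_out",
                                          family_filter = "")), 2L)

  bed <- "chr1\t5000\t5300\tAluY\t0\t+"
  path2 <- tempfile(); writeLines(bed, path2)
  reps2 <- read_repeat_intervals(path2, "bed6")
  expect_equal(reps2$start, 5000)
  expect_equal(reps2$end, 5300)
  expect_equal(reps2$family, "AluY")
  writeLines("chr1\tfive\t5300\tAluY\t0\t+", path2)
  expect_error(read_repeat_intervals(path2, "bed6"), "line 1")
})

test_that("cancer gene table parses ambiguity and both-compartment records", {
  tab <- data.frame(gene_symbol = c("TP53", "AMBIG", "BOTH"),
                    dominance = c("recessive", "Rec?", "dominant"),
                    cell_type = c("somatic", "somatic", "somatic/germline"),
                    translocation = c("no", "yes", "no"))
  path <- tempfile()
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- read_cancer_gene_table(path)
  expect_equal(out$records$dominance, c("recessive", "ambiguous", "dominant"))
  expect_equal(out$records$cell_type, c("somatic", "somatic", "both"))
  expect_equal(out$exclusions$dominant_recessive, 1L)
  expect_equal(out$exclusions$somatic_germline, 1L)
  # missing column errors by name
  write.table(tab[, -2], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cancer_gene_table(path), "dominance")
})

test_that("sequence accessor fetches half-open intervals case-insensitively", {
  path <- write_fasta(c(chr1 = "ACGT", chr2 = "acgt"))
  genome <- read_sequences(path)
  expect_equal(seq_fetch(genome, "chr1", 1, 3), "CG")
  expect_equal(seq_fetch(genome, "chr2", 0, 4), "ACGT")
  expect_error(seq_fetch(genome, "chrZ", 0, 1), "chrZ")
  expect_error(seq_fetch(genome, "chr1", 0, 5), "out of bounds")
})

test_that("feature table round-trips losslessly", {
  feats <- data.frame(gene = c("A", "B", "C"), chrom = "chr1", strand = "+",
                      Di = c(0.42253521126760563, 0, 2.5),
                      De = c(0.58823529411764708, 0, 0),
                      Mi = c(0.4, 1.25, 0), Me = c(0, 0, 0),
                      pair_density = c(0, 0, 1.2), triplet_count = c(0, 0.5, 2),
                      gc_adjusted = c(0.5, 0.667, 1),
                      Si = c(7.1, 10, 1.5), Se = c(1.7, 0.4, 1.1),
                      log10_size = c(3.94, 4.02, 3.41),
                      stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_feature_table(feats, path)
  back <- read_feature_table(path)
  expect_equal(nrow(back), 3L)
  for (col in names(feats)) expect_equal(back[[col]], feats[[col]])
  # zero intron-Alu density serializes as plain 0
  raw <- read.delim(path, colClasses = "character")
  expect_equal(raw$Di[2], "0")
})
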