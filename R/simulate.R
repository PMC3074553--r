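#' Draw gene-level densities from the zero-inflated Gamma mixture
#'
#' Each value is exactly zero with probability \code{r} and otherwise a
#' Gamma(shape, scale) draw — the generative counterpart of
#' \code{\link{fit_mixture}}.
#'
#' @param r Zero-inflation fraction in \code{[0, 1]}.
#' @param shape,scale Positive Gamma parameters of the positive component.
#' @param n Number of genes.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of length \code{n}.
#' @export
simulate_density_sample <- function(r, shape, scale, n, seed = NULL) {
  if (r < 0 || r > 1) stop("r must lie in [0, 1]")
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  zero <- stats::rbinom(n, 1L, r) == 1L
  x <- stats::rgamma(n, shape = shape, scale = scale)
  x[zero] <- 0
  x
}

#' Specification of a synthetic genome
#'
#' Collects every knob of the simulator: per-chromosome gene counts and
#' mixture parameters of the target intron Alu density, the log10-normal
#' gene-length law, exon-structure distributions, the Alu element length,
#' the insertion-motif background rate and its coupling to Alu presence
#' (logit scale) and intensity (linear scale), and the class-label model.
#' Defaults use four published chromosome parameter sets spanning the
#' observed range (chr1, chr7, chr19, chrY) at 200 genes each, with gene
#' sizes scaled down (median ~5 Knt) so a full genome stays desk-sized.
#'
#' @param chromosomes data.frame with columns \code{chrom}, \code{n_genes},
#'   \code{r}, \code{shape}, \code{scale}.
#' @param gene_length_log10_mean,gene_length_log10_sd Gene span length is
#'   \code{10^N(mean, sd)} nt.
#' @param exon_geom_p Exon count is \code{2 + rgeom(p)} (multi-exon by
#'   construction).
#' @param exon_length_meanlog,exon_length_sdlog Exon lengths are log-normal
#'   (floored at 30 nt).
#' @param alu_length Length of each inserted Alu element (nt).
#' @param alu_gc GC fraction of the synthetic Alu tag sequence.
#' @param motif Motif string planted in introns.
#' @param motif_rate Mean planted intron motif density (occurrences per
#'   Knt); per-gene rates vary around it with coefficient of variation
#'   \code{motif_rate_cv}.
#' @param motif_rate_cv Relative spread of per-gene motif rates.
#' @param beta_presence Logit-scale coupling of the (centred) motif density
#'   to Alu presence.
#' @param beta_intensity Linear-scale coupling of the (centred) motif
#'   density to positive Alu density.
#' @param intergenic_alu_rate Intergenic Alu placements per Knt of gap.
#' @param intergenic_gap Range (nt) of the uniform gap between adjacent
#'   genes.
#' @param class_intercept,class_beta_di,class_beta_size Class-label model:
#'   logit P(label = 1) = intercept + beta_di * Di + beta_size * log10_size.
#' @return An object of class \code{"synthetic_genome_spec"}.
#' @export
synthetic_genome_spec <- function(chromosomes = NULL,
                                  gene_length_log10_mean = 4.4,
                                  gene_length_log10_sd = 0.5,
                                  exon_geom_p = 0.12,
                                  exon_length_meanlog = log(140),
                                  exon_length_sdlog = 0.35,
                                  alu_length = 300,
                                  alu_gc = 0.55,
                                  motif = "TTAAAA",
                                  motif_rate = 1.0,
                                  motif_rate_cv = 0.5,
                                  beta_presence = 0,
                                  beta_intensity = 0,
                                  intergenic_alu_rate = 0.2,
                                  intergenic_gap = c(1000, 5000),
                                  class_intercept = -1,
                                  class_beta_di = 1,
                                  class_beta_size = 0.5) {
  if (is.null(chromosomes)) {
    ref <- hg18_intron_alu_params()
    ref <- ref[ref$chrom %in% c("chr1", "chr7", "chr19", "chrY"), ]
    chromosomes <- data.frame(chrom = ref$chrom, n_genes = 200L,
                              r = ref$r, shape = ref$shape,
                              scale = ref$scale, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "n_genes", "r", "shape", "scale") %in%
                  names(chromosomes)))
  if (any(chromosomes$r < 0 | chromosomes$r > 1))
    stop("r must lie in [0, 1]")
  if (any(chromosomes$shape <= 0 | chromosomes$scale <= 0))
    stop("shape and scale must be positive")
  if (any(chromosomes$n_genes < 1)) stop("n_genes must be positive")
  if (alu_length < 1 || alu_gc < 0 || alu_gc > 1 || motif_rate < 0 ||
      intergenic_alu_rate < 0)
    stop("invalid simulator parameter")
  structure(list(chromosomes = chromosomes,
                 gene_length_log10_mean = gene_length_log10_mean,
                 gene_length_log10_sd = gene_length_log10_sd,
                 exon_geom_p = exon_geom_p,
                 exon_length_meanlog = exon_length_meanlog,
                 exon_length_sdlog = exon_length_sdlog,
                 alu_length = alu_length, alu_gc = alu_gc,
                 motif = motif, motif_rate = motif_rate,
                 motif_rate_cv = motif_rate_cv,
                 beta_presence = beta_presence,
                 beta_intensity = beta_intensity,
                 intergenic_alu_rate = intergenic_alu_rate,
                 intergenic_gap = intergenic_gap,
                 class_intercept = class_intercept,
                 class_beta_di = class_beta_di,
                 class_beta_size = class_beta_size),
            class = "synthetic_genome_spec")
}

# fixed synthetic Alu tag: a GC block then an AT block, dinucleotide
# alternation, so the tag never contains the TTAAAA motif
alu_tag_sequence <- function(len, gc) {
  n_gc <- round(gc * len)
  paste0(paste(rep_len(c("G", "C"), n_gc), collapse = ""),
         paste(rep_len(c("A", "T"), len - n_gc), collapse = ""))
}

# one gene structure draw: exon lengths and intron lengths (nt), redrawn
# until the introns leave room for at least one Alu per intron plus margin
draw_gene_structure <- function(spec) {
  repeat {
    n_ex <- 2L + stats::rgeom(1L, spec$exon_geom_p)
    ex_len <- pmax(30L, round(stats::rlnorm(n_ex, spec$exon_length_meanlog,
                                            spec$exon_length_sdlog)))
    L <- round(10^stats::rnorm(1, spec$gene_length_log10_mean,
                               spec$gene_length_log10_sd))
    intron_total <- L - sum(ex_len)
    n_in <- n_ex - 1L
    if (intron_total >= max(1500, n_in * (spec$alu_length + 50))) break
  }
  w <- stats::rexp(n_in) + 0.05
  in_len <- floor(intron_total * w / sum(w))
  in_len[1L] <- in_len[1L] + (intron_total - sum(in_len))
  list(ex_len = ex_len, in_len = in_len)
}

# target Alu count for density d over introns totalling intron_total nt:
# the self-consistent count solving n = d * (intron_total - n * alu_w) / 1000,
# so the realized (Alu-adjusted) density equals d up to integer rounding
target_alu_count <- function(d, intron_total, alu_w) {
  max(1L, as.integer(round(d * intron_total / (1000 + alu_w * d))))
}

# the discretized density law, sampled without any coordinate placement or
# sequence emission: used as the granularity-matched oracle for full-loop
# fidelity checks (realized densities are integer counts over finite introns,
# so values below ~1/Si are not representable)
simulate_realized_densities <- function(spec, r, shape, scale, n) {
  vapply(seq_len(n), function(i) {
    if (stats::rbinom(1, 1, r) == 1L) return(0)
    st <- draw_gene_structure(spec)
    intron_total <- sum(st$in_len)
    max_alu <- sum(floor(st$in_len / spec$alu_length))
    repeat {
      d <- stats::rgamma(1, shape = shape, scale = scale)
      n_alu <- target_alu_count(d, intron_total, spec$alu_length)
      if (n_alu <= max_alu) break
    }
    n_alu / ((intron_total - n_alu * spec$alu_length) / 1000)
  }, numeric(1))
}

# non-overlapping placement of k intervals of width w inside [lo, hi):
# sorted-uniform trick over the free slack
place_nonoverlapping <- function(k, w, lo, hi) {
  slack <- (hi - lo) - k * w
  if (k == 0L) return(numeric(0))
  if (slack < 0) stop("no room to place intervals")
  offs <- sort(floor(stats::runif(k, 0, slack + 1)))
  lo + offs + w * (seq_len(k) - 1L)
}

#' Simulate a synthetic genome with known Alu ground truth
#'
#' For every gene: draws a span length and exon/intron structure, draws a
#' target intron Alu density from the chromosome's zero-inflated Gamma
#' mixture (with optional motif coupling on the presence logit and on the
#' positive intensity), places \code{round(d * Si_planned)} non-overlapping
#' Alu elements uniformly in the introns, and plants insertion-motif copies
#' in the Alu-free intron sequence at the gene's motif rate. Background
#' sequence is i.i.d. uniform A/C/G/T (which itself contains the motif at
#' about 0.24 copies per Knt; planted copies come on top). An infeasible
#' density draw (more Alu nucleotides than intron room) is resampled and
#' counted. All outputs are mutually consistent and parse with the package
#' readers.
#'
#' @param spec A \code{\link{synthetic_genome_spec}}.
#' @param seed Integer seed; every output is a pure function of
#'   \code{(spec, seed)}.
#' @param dir Output directory (created if needed).
#' @return List with \code{paths} (\code{fasta}, \code{genes} BED12,
#'   \code{repeats} BED6, \code{truth} TSV), the \code{truth} data.frame
#'   (per gene: intended and realized intron Alu density, Alu count, planted
#'   motif count and rate, presence flag), \code{chrom_lengths}, and
#'   \code{n_resampled} infeasible-density redraws.
#' @export
simulate_genome <- function(spec, seed, dir = tempfile("syngenome")) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  alu_w <- spec$alu_length
  mlen <- nchar(spec$motif)
  motif_chars <- strsplit(spec$motif, "", fixed = TRUE)[[1]]
  tag_chars <- strsplit(alu_tag_sequence(alu_w, spec$alu_gc), "",
                        fixed = TRUE)[[1]]
  # per-gene motif rate spread around the mean with the requested CV
  m_shape <- 1 / spec$motif_rate_cv^2
  n_resampled <- 0L
  bed12 <- character(0)
  bed6 <- character(0)
  truth <- list()
  seqs <- list()
  chrom_lengths <- numeric(0)

  for (ci in seq_len(nrow(spec$chromosomes))) {
    cr <- spec$chromosomes[ci, ]
    cursor <- 0
    chars_chunks <- list()
    gap0 <- floor(stats::runif(1, spec$intergenic_gap[1],
                               spec$intergenic_gap[2]))
    chars_chunks[[1]] <- sample(c("A", "C", "G", "T"), gap0, replace = TRUE)
    intergenic_gaps <- list(c(0, gap0))
    cursor <- gap0

    for (gi in seq_len(cr$n_genes)) {
      # --- gene structure ---
      st <- draw_gene_structure(spec)
      ex_len <- st$ex_len
      in_len <- st$in_len
      n_ex <- length(ex_len)
      n_in <- n_ex - 1L
      # absolute layout: e1 i1 e2 i2 ... en
      gstart <- cursor
      exon_starts <- numeric(n_ex)
      intron_iv <- matrix(0, nrow = n_in, ncol = 2)
      pos <- gstart
      for (k in seq_len(n_ex)) {
        exon_starts[k] <- pos
        pos <- pos + ex_len[k]
        if (k <= n_in) {
          intron_iv[k, ] <- c(pos, pos + in_len[k])
          pos <- pos + in_len[k]
        }
      }
      gend <- pos

      # --- motif rate and coupled target density ---
      x_g <- stats::rgamma(1, shape = m_shape,
                           scale = spec$motif_rate / m_shape)
      dx <- x_g - spec$motif_rate
      p_present <- stats::plogis(stats::qlogis(1 - cr$r) +
                                   spec$beta_presence * dx)
      z <- stats::rbinom(1, 1, p_present) == 1L
      max_alu <- sum(floor(in_len / alu_w))
      d <- 0; n_alu <- 0L
      if (z) {
        repeat {
          d <- stats::rgamma(1, shape = cr$shape, scale = cr$scale) +
            spec$beta_intensity * dx
          if (d <= 0) next
          n_alu <- target_alu_count(d, sum(in_len), alu_w)
          if (n_alu <= max_alu) break
          n_resampled <- n_resampled + 1L
        }
      }

      # --- allocate Alus to introns by capacity, place within introns ---
      alu_starts <- numeric(0)
      if (n_alu > 0L) {
        cap <- floor(in_len / alu_w)
        alloc <- integer(n_in)
        want <- n_alu
        ord <- order(in_len, decreasing = TRUE)
        share <- floor(n_alu * in_len / sum(in_len))
        alloc <- pmin(share, cap)
        want <- n_alu - sum(alloc)
        for (k in ord) {
          if (want == 0L) break
          add <- min(want, cap[k] - alloc[k])
          alloc[k] <- alloc[k] + add
          want <- want - add
        }
        for (k in seq_len(n_in)) {
          if (alloc[k] == 0L) next
          alu_starts <- c(alu_starts,
                          place_nonoverlapping(alloc[k], alu_w,
                                               intron_iv[k, 1],
                                               intron_iv[k, 2]))
        }
      }
      si_real <- (sum(in_len) - length(alu_starts) * alu_w) / 1000
      d_real <- length(alu_starts) / si_real

      # --- gene sequence with Alu tags and planted motifs ---
      gene_chars <- sample(c("A", "C", "G", "T"), gend - gstart,
                           replace = TRUE)
      for (a in alu_starts) {
        off <- a - gstart
        gene_chars[(off + 1):(off + alu_w)] <- tag_chars
      }
      n_motif <- round(x_g * si_real)
      placed <- matrix(numeric(0), ncol = 2)
      alu_iv <- if (length(alu_starts))
        cbind(alu_starts, alu_starts + alu_w) else matrix(numeric(0), ncol = 2)
      if (n_motif > 0L) {
        free_w <- pmax(0, in_len - mlen)
        tries <- 0L
        placed_n <- 0L
        while (placed_n < n_motif && tries < 200L * n_motif) {
          tries <- tries + 1L
          k <- sample.int(n_in, 1L, prob = free_w + 1e-9)
          p <- floor(stats::runif(1, intron_iv[k, 1],
                                  intron_iv[k, 2] - mlen + 1))
          if (overlaps_any(p, p + mlen, alu_iv)) next
          if (overlaps_any(p, p + mlen, placed)) next
          off <- p - gstart
          gene_chars[(off + 1):(off + mlen)] <- motif_chars
          placed <- rbind(placed, c(p, p + mlen))
          placed_n <- placed_n + 1L
        }
        n_motif <- placed_n
      }
      chars_chunks[[length(chars_chunks) + 1L]] <- gene_chars

      # --- intergenic gap after the gene, with background Alus ---
      gap <- floor(stats::runif(1, spec$intergenic_gap[1],
                                spec$intergenic_gap[2]))
      gap_chars <- sample(c("A", "C", "G", "T"), gap, replace = TRUE)
      n_ig <- stats::rpois(1, spec$intergenic_alu_rate * gap / 1000)
      n_ig <- min(n_ig, floor((gap - 2) / alu_w))
      ig_starts <- if (n_ig > 0L)
        place_nonoverlapping(n_ig, alu_w, gend + 1, gend + gap - 1)
        else numeric(0)
      for (a in ig_starts) {
        off <- a - gend
        gap_chars[(off + 1):(off + alu_w)] <- tag_chars
      }
      chars_chunks[[length(chars_chunks) + 1L]] <- gap_chars
      intergenic_gaps[[length(intergenic_gaps) + 1L]] <- c(gend, gend + gap)
      cursor <- gend + gap

      # --- records ---
      sym <- sprintf("G%s_%04d", sub("^chr", "", cr$chrom), gi)
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      sizes <- paste0(paste(ex_len, collapse = ","), ",")
      starts <- paste0(paste(exon_starts - gstart, collapse = ","), ",")
      bed12 <- c(bed12, paste(cr$chrom, gstart, gend,
                              paste0("tx_", sym, "|", sym), 0, strand,
                              gstart, gend, 0, n_ex, sizes, starts,
                              sep = "\t"))
      all_alus <- c(alu_starts, ig_starts)
      if (length(all_alus))
        bed6 <- c(bed6, paste(cr$chrom, all_alus, all_alus + alu_w,
                              "AluSyn", 0, "+", sep = "\t"))
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = cr$chrom, gene = sym,
        intended_density = d, realized_density = d_real,
        n_alu = length(alu_starts),
        motif_rate = x_g, motif_count = n_motif,
        alu_present = as.integer(z), stringsAsFactors = FALSE)
    }
    seqs[[cr$chrom]] <- paste(unlist(chars_chunks), collapse = "")
    chrom_lengths[cr$chrom] <- cursor
  }

  paths <- list(fasta = file.path(dir, "genome.fa"),
                genes = file.path(dir, "genes.bed"),
                repeats = file.path(dir, "alus.bed"),
                truth = file.path(dir, "truth.tsv"))
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(ss, paths$fasta, width = 80L)
  writeLines(bed12, paths$genes)
  writeLines(bed6, paths$repeats)
  truth_df <- do.call(rbind, truth)
  utils::write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(paths = paths, truth = truth_df, chrom_lengths = chrom_lengths,
       n_resampled = n_resampled, spec = spec)
}

#' Simulate binary class labels from gene features
#'
#' Labels follow logit P(label = 1) = intercept + beta_di * Di +
#' beta_size * log10_size — the generative counterpart of
#' \code{\link{class_association}}.
#'
#' @param features data.frame with columns \code{Di} and \code{log10_size}.
#' @param intercept,beta_di,beta_size Model coefficients.
#' @param seed Optional integer seed.
#' @return Integer 0/1 vector, one label per feature row.
#' @export
simulate_class_labels <- function(features, intercept, beta_di, beta_size,
                                  seed = NULL) {
  if (nrow(features) == 0L) stop("features is empty")
  if (!is.null(seed)) set.seed(seed)
  eta <- intercept + beta_di * features$Di + beta_size * features$log10_size
  stats::rbinom(nrow(features), 1L, stats::plogis(eta))
}
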