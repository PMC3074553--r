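# Interval helpers. All intervals are 0-based half-open; an overlap of >= 1 nt
# means max(starts) < min(ends).

ov_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

# total overlap of one interval with a set of disjoint intervals (2-col matrix)
ov_len_set <- function(s, e, ivs) {
  if (nrow(ivs) == 0L) return(0)
  sum(ov_len(s, e, ivs[, 1], ivs[, 2]))
}

overlaps_any <- function(s, e, ivs) {
  nrow(ivs) > 0L && any(ivs[, 1] < e & s < ivs[, 2])
}

merge_intervals <- function(ivs) {
  if (nrow(ivs) <= 1L) return(ivs)
  ivs <- ivs[order(ivs[, 1], ivs[, 2]), , drop = FALSE]
  out <- ivs[1L, , drop = FALSE]
  for (i in 2:nrow(ivs)) {
    if (ivs[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], ivs[i, 2])
    } else {
      out <- rbind(out, ivs[i, , drop = FALSE])
    }
  }
  out
}

complement_intervals <- function(ivs, lo, hi) {
  ivs <- merge_intervals(ivs)
  edges <- c(lo, t(ivs), hi)
  m <- matrix(edges, ncol = 2, byrow = TRUE)
  m[m[, 2] > m[, 1], , drop = FALSE]
}

#' Partition the Alus overlapping a transcript into exon and intron Alus
#'
#' An Alu overlapping the transcript span by at least one nucleotide counts
#' toward the transcript total Nt. It is an exon Alu (covering both exonic
#' and exonized insertions) when it overlaps any exon by at least one
#' nucleotide; otherwise it is an intron Alu, so Ni = Nt - Ne by
#' construction. Alu lengths are clipped to the region each Alu is assigned
#' to (and to the span), which keeps the adjusted region lengths local and
#' non-negative.
#'
#' @param tx A \code{\link{transcript_model}}.
#' @param repeats A \code{\link{repeat_intervals}} data.frame (any
#'   chromosome; rows on other chromosomes are ignored).
#' @return A list with counts \code{n_total}, \code{n_exon}, \code{n_intron};
#'   interval matrices \code{exon_alu}, \code{intron_alu} (original
#'   coordinates); and clipped totals \code{exon_alu_len},
#'   \code{intron_alu_len} in nucleotides.
#' @export
partition_repeats <- function(tx, repeats) {
  r <- repeats[repeats$chrom == tx$chrom, , drop = FALSE]
  hit <- r$start < tx$end & tx$start < r$end
  r <- r[hit, , drop = FALSE]
  empty <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(r) == 0L)
    return(list(n_total = 0L, n_exon = 0L, n_intron = 0L,
                exon_alu = empty, intron_alu = empty,
                exon_alu_len = 0, intron_alu_len = 0))
  ex <- tx$exons
  is_exonic <- vapply(seq_len(nrow(r)), function(i)
    overlaps_any(r$start[i], r$end[i], ex), TRUE)
  introns <- transcript_introns(tx)
  exon_alu   <- cbind(start = r$start[is_exonic],  end = r$end[is_exonic])
  intron_alu <- cbind(start = r$start[!is_exonic], end = r$end[!is_exonic])
  exon_alu_len <- sum(vapply(seq_len(nrow(exon_alu)), function(i)
    ov_len_set(exon_alu[i, 1], exon_alu[i, 2], ex), numeric(1)))
  intron_alu_len <- sum(vapply(seq_len(nrow(intron_alu)), function(i)
    ov_len_set(intron_alu[i, 1], intron_alu[i, 2], introns), numeric(1)))
  list(n_total = nrow(r), n_exon = nrow(exon_alu), n_intron = nrow(intron_alu),
       exon_alu = exon_alu, intron_alu = intron_alu,
       exon_alu_len = exon_alu_len, intron_alu_len = intron_alu_len)
}

# per-transcript adjusted lengths in Knt and densities; NULL when both
# denominators are non-positive
transcript_alu_densities <- function(tx, part) {
  span_len <- tx$end - tx$start
  exon_len <- sum(tx$exons[, 2] - tx$exons[, 1])
  Si <- (span_len - exon_len - part$intron_alu_len) / 1000
  Se <- (exon_len - part$exon_alu_len) / 1000
  list(Si = Si, Se = Se,
       Di = if (Si > 0) part$n_intron / Si else NA_real_,
       De = if (Se > 0) part$n_exon / Se else NA_real_)
}

#' Gene-level intron and exon Alu densities
#'
#' For each multi-exon transcript the adjusted intron length is
#' Si = (span length - exon length - clipped intron-Alu length) / 1000 Knt
#' and the adjusted exon length is Se = (exon length - clipped exon-Alu
#' length) / 1000 Knt; the densities are Di = Ni / Si and De = Ne / Se. The
#' gene value is the arithmetic mean over the gene's multi-exon transcripts.
#'
#' @param gene A \code{\link{gene_model}}.
#' @param repeats A \code{\link{repeat_intervals}} data.frame.
#' @return A list with gene means \code{Di}, \code{De}, \code{Si}, \code{Se}
#'   (Knt), counts \code{Ni}, \code{Ne} (transcript means), and
#'   \code{n_transcripts} used.
#' @export
gene_alu_densities <- function(gene, repeats) {
  txs <- multi_exon_transcripts(gene)
  if (length(txs) == 0L)
    stop("gene ", gene$gene_symbol, " has no multi-exon transcript")
  rows <- list()
  for (tx in txs) {
    part <- partition_repeats(tx, repeats)
    d <- transcript_alu_densities(tx, part)
    if (d$Si <= 0 || d$Se <= 0) next
    rows[[length(rows) + 1L]] <-
      c(Di = d$Di, De = d$De, Si = d$Si, Se = d$Se,
        Ni = part$n_intron, Ne = part$n_exon)
  }
  if (length(rows) == 0L)
    stop("gene ", gene$gene_symbol,
         " rejected: adjusted intron/exon length non-positive in every transcript")
  m <- colMeans(do.call(rbind, rows))
  list(Di = m[["Di"]], De = m[["De"]], Si = m[["Si"]], Se = m[["Se"]],
       Ni = m[["Ni"]], Ne = m[["Ne"]], n_transcripts = length(rows))
}

#' Scan a sequence for exact motif matches
#'
#' Finds every exact, possibly overlapping, forward-strand occurrence of the
#' motif whose full extent lies inside \code{region}. Matching is
#' case-insensitive (soft-masked lowercase is treated as sequence).
#'
#' @param sequence Nucleotide string; its first character sits at coordinate
#'   0.
#' @param motif Motif over A/C/G/T, e.g. the L1-endonuclease cleavage signal
#'   \code{"TTAAAA"}.
#' @param region Half-open interval \code{c(start, end)} restricting matches;
#'   default the whole sequence.
#' @return Ascending integer vector of 0-based match start positions.
#' @export
scan_motif <- function(sequence, motif, region = c(0, nchar(sequence))) {
  if (!nzchar(motif) || grepl("[^ACGT]", toupper(motif)))
    stop("motif must be a nonempty string over A/C/G/T")
  sequence <- toupper(sequence)
  if (nchar(sequence) < nchar(motif)) return(integer(0))
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(sequence))
  pos <- Biostrings::start(hits) - 1L
  keep <- pos >= region[1] & (pos + nchar(motif)) <= region[2]
  sort(pos[keep])
}

# per-transcript intron/exon motif counts under the partition geometry
transcript_motif_counts <- function(tx, part, genome, motif,
                                    count_motifs_in_alus = FALSE) {
  seq <- seq_fetch(genome, tx$chrom, tx$start, tx$end)
  pos <- scan_motif(seq, motif) + tx$start
  if (length(pos) == 0L) return(c(intron = 0L, exon = 0L))
  mlen <- nchar(motif)
  alus <- rbind(part$exon_alu, part$intron_alu)
  n_ex <- 0L; n_in <- 0L
  for (p in pos) {
    if (!count_motifs_in_alus && overlaps_any(p, p + mlen, alus)) next
    if (overlaps_any(p, p + mlen, tx$exons)) n_ex <- n_ex + 1L
    else n_in <- n_in + 1L
  }
  c(intron = n_in, exon = n_ex)
}

#' Gene-level motif densities in introns and exons
#'
#' Motif occurrences are classified with the same geometry as
#' \code{\link{partition_repeats}} (>= 1 nt exon overlap makes an exon
#' motif); occurrences overlapping any Alu assigned to the transcript are by
#' default not counted, mirroring the exclusion of Alu nucleotides from the
#' denominators. Densities use the same adjusted lengths Si and Se as the
#' Alu densities; the gene value is the mean over multi-exon transcripts.
#'
#' @inheritParams gene_alu_densities
#' @param genome A \code{"genome_seq"} accessor from
#'   \code{\link{read_sequences}}.
#' @param motif Motif string, default \code{"TTAAAA"}.
#' @param count_motifs_in_alus If \code{TRUE}, occurrences inside Alu
#'   intervals are counted in the numerator (the denominator always excludes
#'   Alu nucleotides).
#' @return List with gene means \code{Mi} and \code{Me} (occurrences per
#'   Knt).
#' @export
gene_motif_densities <- function(gene, repeats, genome, motif = "TTAAAA",
                                 count_motifs_in_alus = FALSE) {
  txs <- multi_exon_transcripts(gene)
  if (length(txs) == 0L)
    stop("gene ", gene$gene_symbol, " has no multi-exon transcript")
  rows <- list()
  for (tx in txs) {
    part <- partition_repeats(tx, repeats)
    d <- transcript_alu_densities(tx, part)
    if (d$Si <= 0 || d$Se <= 0) next
    cnt <- transcript_motif_counts(tx, part, genome, motif,
                                   count_motifs_in_alus)
    rows[[length(rows) + 1L]] <- c(Mi = cnt[["intron"]] / d$Si,
                                   Me = cnt[["exon"]] / d$Se)
  }
  if (length(rows) == 0L)
    stop("gene ", gene$gene_symbol,
         " rejected: adjusted intron/exon length non-positive in every transcript")
  m <- colMeans(do.call(rbind, rows))
  list(Mi = m[["Mi"]], Me = m[["Me"]])
}

#' Count adjacent intron Alu pairs
#'
#' Two intron Alus adjacent in coordinate order form a pair when the gap
#' between them (next start - previous end) is strictly less than
#' \code{gap} nucleotides — a proxy for Alu/Alu recombination potential.
#'
#' @param intron_alu Two-column matrix of intron Alu intervals.
#' @param gap Gap threshold in nt (default 300, roughly one Alu length).
#' @return Integer pair count.
#' @export
alu_pair_count <- function(intron_alu, gap = 300) {
  n <- nrow(intron_alu)
  if (n < 2L) return(0L)
  iv <- intron_alu[order(intron_alu[, 1]), , drop = FALSE]
  gaps <- iv[-1L, 1] - iv[-n, 2]
  sum(gaps < gap)
}

#' Intron Alu-pair density of a transcript
#'
#' @param tx A \code{\link{transcript_model}}.
#' @param repeats A \code{\link{repeat_intervals}} data.frame.
#' @param gap Gap threshold in nt.
#' @return Pairs per Knt of adjusted intron length.
#' @export
alu_pair_density <- function(tx, repeats, gap = 300) {
  part <- partition_repeats(tx, repeats)
  d <- transcript_alu_densities(tx, part)
  if (d$Si <= 0) stop("adjusted intron length non-positive")
  alu_pair_count(part$intron_alu, gap) / d$Si
}

#' Count Alu-exon-Alu triplets of a transcript
#'
#' An exon forms a triplet when some Alu ends before it within a gap of
#' \code{gap} nt and some Alu starts after it within \code{gap} nt (a proxy
#' for exon-deleting recombination risk). Each exon contributes at most one
#' triplet, so one Alu may serve two consecutive exons.
#'
#' @inheritParams alu_pair_density
#' @return Integer triplet count (sum over exons).
#' @export
alu_exon_alu_triplets <- function(tx, repeats, gap = 300) {
  r <- repeats[repeats$chrom == tx$chrom, , drop = FALSE]
  if (nrow(r) == 0L) return(0L)
  n <- 0L
  for (i in seq_len(nrow(tx$exons))) {
    es <- tx$exons[i, 1]; ee <- tx$exons[i, 2]
    left  <- any(r$end <= es & (es - r$end) < gap)
    right <- any(r$start >= ee & (r$start - ee) < gap)
    if (left && right) n <- n + 1L
  }
  n
}

#' Alu-masked GC content of a gene
#'
#' GC fraction of the gene's union-hull span after masking every nucleotide
#' covered by an overlapping Alu; ambiguous bases (anything not A/C/G/T) are
#' excluded from both numerator and denominator. Masking removes the Alus'
#' own strong base composition so the value reflects the genomic environment
#' the Alus integrated into.
#'
#' @inheritParams gene_motif_densities
#' @return GC fraction in \code{[0, 1]}.
#' @export
adjusted_gc_content <- function(gene, repeats, genome) {
  sp <- gene_span(gene)
  seq <- seq_fetch(genome, gene$chrom, sp[1], sp[2])
  r <- repeats[repeats$chrom == gene$chrom &
                 repeats$start < sp[2] & repeats$end > sp[1], , drop = FALSE]
  keep <- rep(TRUE, nchar(seq))
  if (nrow(r) > 0L) {
    for (i in seq_len(nrow(r))) {
      a <- max(r$start[i], sp[1]) - sp[1] + 1L
      b <- min(r$end[i], sp[2]) - sp[1]
      keep[a:b] <- FALSE
    }
  }
  bases <- strsplit(seq, "", fixed = TRUE)[[1]][keep]
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  if (length(bases) == 0L)
    stop("GC content undefined for gene ", gene$gene_symbol,
         ": no unambiguous non-Alu nucleotides in span")
  sum(bases %in% c("G", "C")) / length(bases)
}

#' Distance from a gene to its nearest genomic site
#'
#' @param gene A \code{\link{gene_model}}.
#' @param sites data.frame with columns \code{chrom} and \code{position}
#'   (e.g. fragile-site midpoints).
#' @return Minimum absolute distance in nt between the gene's span midpoint
#'   and a same-chromosome site.
#' @export
nearest_site_distance <- function(gene, sites) {
  s <- sites[sites$chrom == gene$chrom, , drop = FALSE]
  if (nrow(s) == 0L)
    stop("no site on chromosome ", gene$chrom)
  sp <- gene_span(gene)
  min(abs((sp[1] + sp[2]) / 2 - s$position))
}

#' Compute the full per-gene Alu feature table
#'
#' One row per gene: intron/exon Alu densities (Di, De), motif densities
#' (Mi, Me), adjacent Alu-pair density, Alu-exon-Alu triplet count
#' (transcript mean, possibly fractional), Alu-masked GC content, adjusted
#' lengths Si and Se (Knt) and log10 of the adjusted gene length in nt.
#' Motif and GC columns are \code{NA} when \code{genome} is \code{NULL}.
#'
#' @param genes List of \code{\link{gene_model}} objects.
#' @param repeats A \code{\link{repeat_intervals}} data.frame.
#' @param genome Optional \code{"genome_seq"} accessor.
#' @param motif Motif string for Mi/Me.
#' @param gap Gap threshold (nt) for pairs and triplets.
#' @param count_motifs_in_alus Passed to \code{\link{gene_motif_densities}}.
#' @return data.frame with the columns of \code{\link{write_feature_table}}.
#' @export
gene_alu_features <- function(genes, repeats, genome = NULL,
                              motif = "TTAAAA", gap = 300,
                              count_motifs_in_alus = FALSE) {
  rows <- lapply(genes, function(gene) {
    dens <- gene_alu_densities(gene, repeats)
    txs <- multi_exon_transcripts(gene)
    pd <- tc <- adj_len <- numeric(0)
    for (tx in txs) {
      part <- partition_repeats(tx, repeats)
      d <- transcript_alu_densities(tx, part)
      if (d$Si <= 0 || d$Se <= 0) next
      pd <- c(pd, alu_pair_count(part$intron_alu, gap) / d$Si)
      tc <- c(tc, alu_exon_alu_triplets(tx, repeats, gap))
      adj_len <- c(adj_len, (d$Si + d$Se) * 1000)
    }
    if (!is.null(genome)) {
      mo <- gene_motif_densities(gene, repeats, genome, motif,
                                 count_motifs_in_alus)
      gc <- adjusted_gc_content(gene, repeats, genome)
    } else {
      mo <- list(Mi = NA_real_, Me = NA_real_)
      gc <- NA_real_
    }
    data.frame(gene = gene$gene_symbol, chrom = gene$chrom,
               strand = gene$strand,
               Di = dens$Di, De = dens$De, Mi = mo$Mi, Me = mo$Me,
               pair_density = mean(pd), triplet_count = mean(tc),
               gc_adjusted = gc, Si = dens$Si, Se = dens$Se,
               log10_size = log10(mean(adj_len)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chromosome-level region densities
#'
#' Pooled densities: total counts divided by total adjusted lengths (never a
#' mean of gene densities). Intergenic regions are the complement of the
#' merged transcript spans within \code{[0, chrom_length)}; an Alu counts as
#' intergenic when it overlaps no transcript span, and the intergenic length
#' is adjusted by the intergenic-Alu nucleotides it contains.
#'
#' @param genes List of \code{\link{gene_model}} objects on one chromosome.
#' @param repeats A \code{\link{repeat_intervals}} data.frame.
#' @param chrom_length Chromosome length in nt.
#' @param motifs Optional two-column matrix of motif intervals (0-based
#'   half-open) on the chromosome; enables the motif densities.
#' @return One-row data.frame: \code{chrom}, \code{intron_alu},
#'   \code{exon_alu}, \code{intergenic_alu}, \code{intron_motif},
#'   \code{chrom_motif} (all per Knt; motif columns \code{NA} without
#'   \code{motifs}).
#' @export
chromosome_region_densities <- function(genes, repeats, chrom_length,
                                        motifs = NULL) {
  chrom <- if (length(genes)) genes[[1L]]$chrom
           else unique(repeats$chrom)[1L]
  spans <- do.call(rbind, lapply(genes, function(g)
    do.call(rbind, lapply(g$transcripts, function(tx) c(tx$start, tx$end)))))
  if (is.null(spans))
    spans <- matrix(numeric(0), ncol = 2)
  max_coord <- max(c(spans[, 2], repeats$end[repeats$chrom == chrom], 0))
  if (chrom_length < max_coord)
    stop("chrom_length ", chrom_length,
         " smaller than max annotated coordinate ", max_coord)

  tot <- c(Ni = 0, Ne = 0, Si = 0, Se = 0, Mi_count = 0)
  for (g in genes) {
    if (!identical(g$chrom, chrom)) stop("genes span multiple chromosomes")
    d <- gene_alu_densities(g, repeats)
    tot["Ni"] <- tot["Ni"] + d$Ni; tot["Ne"] <- tot["Ne"] + d$Ne
    tot["Si"] <- tot["Si"] + d$Si; tot["Se"] <- tot["Se"] + d$Se
    if (!is.null(motifs))
      tot["Mi_count"] <- tot["Mi_count"] +
        gene_motif_interval_count(g, repeats, motifs)
  }

  r <- repeats[repeats$chrom == chrom, , drop = FALSE]
  inter <- complement_intervals(spans, 0, chrom_length)
  in_gene <- vapply(seq_len(nrow(r)), function(i)
    overlaps_any(r$start[i], r$end[i], spans), TRUE)
  rg <- r[!in_gene, , drop = FALSE]
  inter_len <- sum(inter[, 2] - inter[, 1])
  inter_alu_len <- sum(vapply(seq_len(nrow(rg)), function(i)
    ov_len_set(rg$start[i], rg$end[i], inter), numeric(1)))
  inter_adj <- (inter_len - inter_alu_len) / 1000

  chrom_motif <- NA_real_
  intron_motif <- NA_real_
  if (!is.null(motifs)) {
    alu_cov <- if (nrow(r)) merge_intervals(cbind(r$start, r$end))
               else matrix(numeric(0), ncol = 2)
    alu_nt <- sum(alu_cov[, 2] - alu_cov[, 1])
    free <- vapply(seq_len(nrow(motifs)), function(i)
      !overlaps_any(motifs[i, 1], motifs[i, 2], alu_cov), TRUE)
    chrom_motif <- sum(free) / ((chrom_length - alu_nt) / 1000)
    intron_motif <- if (tot["Si"] > 0) tot[["Mi_count"]] / tot[["Si"]]
                    else NA_real_
  }

  data.frame(chrom = chrom,
             intron_alu = if (tot["Si"] > 0) tot[["Ni"]] / tot[["Si"]] else NA_real_,
             exon_alu = if (tot["Se"] > 0) tot[["Ne"]] / tot[["Se"]] else NA_real_,
             intergenic_alu = if (inter_adj > 0) nrow(rg) / inter_adj else NA_real_,
             intron_motif = intron_motif, chrom_motif = chrom_motif,
             stringsAsFactors = FALSE)
}

# transcript-mean count of motif intervals assigned to introns of a gene,
# excluding motifs overlapping the transcript's Alus
gene_motif_interval_count <- function(gene, repeats, motifs) {
  txs <- multi_exon_transcripts(gene)
  cnts <- numeric(0)
  for (tx in txs) {
    part <- partition_repeats(tx, repeats)
    d <- transcript_alu_densities(tx, part)
    if (d$Si <= 0 || d$Se <= 0) next
    alus <- rbind(part$exon_alu, part$intron_alu)
    n <- 0L
    for (i in seq_len(nrow(motifs))) {
      ms <- motifs[i, 1]; me <- motifs[i, 2]
      if (ms < tx$start || me > tx$end) next
      if (overlaps_any(ms, me, alus)) next
      if (!overlaps_any(ms, me, tx$exons)) n <- n + 1L
    }
    cnts <- c(cnts, n)
  }
  if (length(cnts) == 0L) 0 else mean(cnts)
}
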