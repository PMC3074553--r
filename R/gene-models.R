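#' Construct a transcript model
#'
#' A transcript is the measurement unit for all gene-level densities: an
#' ordered set of exons within a chromosomal span. All coordinates are
#' 0-based, half-open \code{[start, end)}; introns are the gaps between
#' consecutive exons, so a single-exon transcript has no introns and carries
#' no information about intron Alu integration.
#'
#' @param transcript_id Transcript identifier (e.g. a RefSeq accession).
#' @param gene_symbol Official gene symbol the transcript belongs to.
#' @param chrom Chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param start,end Transcript span, 0-based half-open.
#' @param exons Two-column integer matrix of exon \code{(start, end)}
#'   intervals, 0-based half-open, sorted ascending, pairwise disjoint and
#'   contained in \code{[start, end)}.
#' @return An object of class \code{"transcript_model"}.
#' @export
transcript_model <- function(transcript_id, gene_symbol, chrom, strand,
                             start, end, exons) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'")
  if (end <= start)
    stop("transcript span is empty: [", start, ",", end, ")")
  if (nrow(exons) < 1L) stop("transcript must have at least one exon")
  if (any(exons[, 2] <= exons[, 1]))
    stop("empty exon in transcript ", transcript_id)
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exon blocks in transcript ", transcript_id)
  if (exons[1L, 1] < start || exons[nrow(exons), 2] > end)
    stop("exons extend beyond the span of transcript ", transcript_id)
  structure(list(transcript_id = as.character(transcript_id),
                 gene_symbol   = as.character(gene_symbol),
                 chrom = as.character(chrom), strand = strand,
                 start = as.numeric(start), end = as.numeric(end),
                 exons = exons),
            class = "transcript_model")
}

#' Construct a gene model
#'
#' Groups transcripts sharing a (symbol, chromosome, strand) identity. The
#' same symbol annotated on a different chromosome or strand is a distinct
#' gene model and is analysed independently, mirroring the convention of
#' averaging densities over the reference sequences of a gene on one
#' chromosome and strand.
#'
#' @param gene_symbol Gene symbol.
#' @param transcripts Nonempty list of \code{\link{transcript_model}} objects
#'   with identical \code{chrom} and \code{strand}.
#' @return An object of class \code{"gene_model"}.
#' @export
gene_model <- function(gene_symbol, transcripts) {
  if (length(transcripts) == 0L)
    stop("gene model needs at least one transcript")
  chrom  <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strand <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chrom) != 1L || length(strand) != 1L)
    stop("transcripts of gene ", gene_symbol,
         " disagree on chromosome or strand")
  structure(list(gene_symbol = as.character(gene_symbol),
                 chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%s-%s [%s], %d exon(s)>\n",
              x$transcript_id, x$gene_symbol, x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              x$strand, nrow(x$exons)))
  invisible(x)
}

#' @export
print.gene_model <- function(x, ...) {
  sp <- gene_span(x)
  cat(sprintf("<gene %s %s:%s-%s [%s], %d transcript(s)>\n",
              x$gene_symbol, x$chrom,
              format(sp[1], scientific = FALSE),
              format(sp[2], scientific = FALSE),
              x$strand, length(x$transcripts)))
  invisible(x)
}

#' Intron intervals of a transcript
#'
#' @param tx A \code{\link{transcript_model}}.
#' @return Two-column matrix of intron \code{(start, end)} intervals (0-based
#'   half-open); zero rows for a single-exon transcript.
#' @export
transcript_introns <- function(tx) {
  e <- tx$exons
  n <- nrow(e)
  if (n < 2L)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  m <- cbind(start = e[-n, 2], end = e[-1L, 1])
  m[m[, 2] > m[, 1], , drop = FALSE]
}

#' Union hull span of a gene model
#'
#' @param gene A \code{\link{gene_model}}.
#' @return Numeric \code{c(start, end)} of the union hull of transcript spans.
#' @export
gene_span <- function(gene) {
  s <- vapply(gene$transcripts, `[[`, numeric(1), "start")
  e <- vapply(gene$transcripts, `[[`, numeric(1), "end")
  c(min(s), max(e))
}

# transcripts with >= 2 exons; densities are undefined on single-exon ones
multi_exon_transcripts <- function(gene) {
  Filter(function(tx) nrow(tx$exons) >= 2L, gene$transcripts)
}

#' Construct a repeat interval table
#'
#' @param chrom,start,end,family,strand Parallel vectors describing repeat
#'   occurrences; coordinates 0-based half-open. \code{strand} may be
#'   \code{"+"}, \code{"-"} or \code{"*"} (unknown); it is retained for
#'   provenance but ignored by all overlap logic.
#' @return A data.frame of class \code{"repeat_intervals"}.
#' @export
repeat_intervals <- function(chrom, start, end, family,
                             strand = rep("*", length(chrom))) {
  if (any(end <= start)) stop("repeat interval with end <= start")
  if (any(!nzchar(family))) stop("repeat with empty family label")
  structure(data.frame(chrom = as.character(chrom),
                       start = as.numeric(start), end = as.numeric(end),
                       family = as.character(family),
                       strand = as.character(strand),
                       stringsAsFactors = FALSE),
            class = c("repeat_intervals", "data.frame"))
}
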