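#' Read gene models from BED12 or GTF
#'
#' Parses transcript structures and groups them into gene models keyed by
#' (gene symbol, chromosome, strand). Internal coordinates are uniformly
#' 0-based half-open: BED is taken as-is, GTF's 1-based closed exon
#' coordinates are shifted at this boundary and nowhere else.
#'
#' Single-exon transcripts carry no intron sequence and are dropped; a gene
#' is excluded (and its symbol reported) only when all of its transcripts are
#' single-exon.
#'
#' For BED12 the \code{name} field is either \code{"transcriptId|geneSymbol"}
#' or a bare symbol (used as both identifiers). For GTF the attribute keys
#' \code{transcript_id} and \code{gene_id} are required on \code{exon}
#' records; other feature types are ignored.
#'
#' @param path Path to the annotation file.
#' @param format \code{"bed12"} or \code{"gtf"}; declared by the caller,
#'   never sniffed.
#' @return A list with elements \code{genes} (list of
#'   \code{\link{gene_model}}) and \code{excluded_single_exon} (character
#'   vector of gene symbols dropped because every transcript was single-exon).
#' @export
read_gene_models <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  txs <- switch(format,
                bed12 = parse_bed12(path),
                gtf   = parse_gtf(path))
  group_transcripts(txs)
}

parse_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  txs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L)
      stop("malformed BED12 record at line ", i, ": expected 12 fields, got ",
           length(f))
    start <- suppressWarnings(as.numeric(f[2]))
    end   <- suppressWarnings(as.numeric(f[3]))
    nblk  <- suppressWarnings(as.integer(f[10]))
    if (anyNA(c(start, end, nblk)))
      stop("malformed BED12 record at line ", i, ": non-numeric coordinates")
    sizes  <- suppressWarnings(as.numeric(split_csv(f[11])))
    starts <- suppressWarnings(as.numeric(split_csv(f[12])))
    if (anyNA(sizes) || anyNA(starts) ||
        length(sizes) != nblk || length(starts) != nblk)
      stop("malformed BED12 block fields at line ", i)
    ids <- strsplit(f[4], "|", fixed = TRUE)[[1]]
    tx_id <- ids[1L]
    sym   <- ids[length(ids)]
    exons <- cbind(start + starts, start + starts + sizes)
    txs[[i]] <- transcript_model(tx_id, sym, f[1], f[6], start, end, exons)
  }
  txs
}

split_csv <- function(x) {
  out <- strsplit(x, ",", fixed = TRUE)[[1]]
  out[nzchar(out)]
}

parse_gtf <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  recs <- list()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("malformed GTF record at line ", lineno[k],
           ": expected 9 fields, got ", length(f))
    if (f[3] != "exon") next
    start <- suppressWarnings(as.numeric(f[4]))
    end   <- suppressWarnings(as.numeric(f[5]))
    if (anyNA(c(start, end)))
      stop("malformed GTF coordinates at line ", lineno[k])
    gid <- gtf_attribute(f[9], "gene_id")
    tid <- gtf_attribute(f[9], "transcript_id")
    if (is.na(gid) || is.na(tid))
      stop("missing gene_id/transcript_id attribute at line ", lineno[k])
    recs[[length(recs) + 1L]] <-
      # GTF is 1-based closed: [start, end] -> [start-1, end)
      list(chrom = f[1], strand = f[7], start = start - 1, end = end,
           gene = gid, tx = tid)
  }
  if (length(recs) == 0L) return(list())
  key <- vapply(recs, function(r)
    paste(r$tx, r$gene, r$chrom, r$strand, sep = "\r"), "")
  lapply(split(recs, key), function(rs) {
    ex <- cbind(vapply(rs, `[[`, numeric(1), "start"),
                vapply(rs, `[[`, numeric(1), "end"))
    r1 <- rs[[1L]]
    transcript_model(r1$tx, r1$gene, r1$chrom, r1$strand,
                     min(ex[, 1]), max(ex[, 2]), ex)
  })
}

gtf_attribute <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))[[1]]
  if (length(m) < 2L) NA_character_ else m[2]
}

group_transcripts <- function(txs) {
  if (length(txs) == 0L)
    return(list(genes = list(), excluded_single_exon = character(0)))
  key <- vapply(txs, function(tx)
    paste(tx$gene_symbol, tx$chrom, tx$strand, sep = "\r"), "")
  genes <- list()
  excluded <- character(0)
  for (grp in split(txs, factor(key, levels = unique(key)))) {
    multi <- Filter(function(tx) nrow(tx$exons) >= 2L, grp)
    if (length(multi) == 0L) {
      excluded <- c(excluded, grp[[1L]]$gene_symbol)
    } else {
      genes[[length(genes) + 1L]] <- gene_model(multi[[1L]]$gene_symbol, multi)
    }
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_symbol")
  list(genes = genes, excluded_single_exon = excluded)
}

#' Read repeat coordinates from BED6 or RepeatMasker output
#'
#' @param path Path to the file.
#' @param format \code{"bed6"} or \code{"rmsk_out"} (RepeatMasker \code{.out}
#'   whitespace table with its two header lines).
#' @param family_filter Keep only repeats whose family name starts with this
#'   prefix; default \code{"Alu"}. Use \code{""} to keep everything.
#' @return A \code{\link{repeat_intervals}} data.frame, coordinates 0-based
#'   half-open.
#' @export
read_repeat_intervals <- function(path, format = c("bed6", "rmsk_out"),
                                  family_filter = "Alu") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  reps <- switch(format,
                 bed6 = parse_bed6(path),
                 rmsk_out = parse_rmsk_out(path))
  if (nzchar(family_filter))
    reps <- reps[startsWith(reps$family, family_filter), , drop = FALSE]
  rownames(reps) <- NULL
  structure(reps, class = c("repeat_intervals", "data.frame"))
}

parse_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  n <- length(lines)
  out <- data.frame(chrom = character(n), start = numeric(n),
                    end = numeric(n), family = character(n),
                    strand = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L)
      stop("malformed BED record at line ", i)
    start <- suppressWarnings(as.numeric(f[2]))
    end   <- suppressWarnings(as.numeric(f[3]))
    if (anyNA(c(start, end)))
      stop("non-numeric coordinates in BED record at line ", i)
    out$chrom[i] <- f[1]; out$start[i] <- start; out$end[i] <- end
    out$family[i] <- f[4]
    out$strand[i] <- if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "*"
  }
  out
}

parse_rmsk_out <- function(path) {
  lines <- readLines(path)
  # .out files begin with two banner lines and a blank line
  body <- grep("^\\s*[0-9]", lines)
  recs <- lapply(body, function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 11L)
      stop("malformed RepeatMasker record at line ", i)
    begin <- suppressWarnings(as.numeric(f[6]))
    end   <- suppressWarnings(as.numeric(f[7]))
    if (anyNA(c(begin, end)))
      stop("non-numeric coordinates in RepeatMasker record at line ", i)
    # .out coordinates are 1-based closed
    list(chrom = f[5], start = begin - 1, end = end, family = f[10],
         strand = if (f[9] == "+") "+" else "-")
  })
  data.frame(chrom  = vapply(recs, `[[`, "", "chrom"),
             start  = vapply(recs, `[[`, numeric(1), "start"),
             end    = vapply(recs, `[[`, numeric(1), "end"),
             family = vapply(recs, `[[`, "", "family"),
             strand = vapply(recs, `[[`, "", "strand"),
             stringsAsFactors = FALSE)
}

#' Read a cancer-gene classification table
#'
#' Expects a TSV with header columns \code{gene_symbol}, \code{dominance},
#' \code{cell_type} and \code{translocation}. A dominance of \code{"Rec?"}
#' is parsed as \code{"ambiguous"} (excluded from the dominant/recessive
#' comparison only); a cell type naming both compartments (e.g.
#' \code{"somatic/germline"} or \code{"both"}) is parsed as \code{"both"}
#' (excluded from the somatic/germline comparison only).
#'
#' @param path Path to the TSV file.
#' @return A list with \code{records} (data.frame with columns
#'   \code{gene_symbol}, \code{dominance}, \code{cell_type},
#'   \code{translocation}) and \code{exclusions}, a named list of
#'   per-comparison exclusion counts.
#' @export
read_cancer_gene_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_symbol", "dominance", "cell_type", "translocation")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  dom <- tolower(trimws(tab$dominance))
  dominance <- ifelse(dom %in% c("rec?", "ambiguous"), "ambiguous",
                ifelse(dom %in% c("rec", "recessive"), "recessive",
                ifelse(dom %in% c("dom", "dominant"), "dominant",
                       NA_character_)))
  if (anyNA(dominance))
    stop("unrecognized dominance value(s): ",
         paste(unique(tab$dominance[is.na(dominance)]), collapse = ", "))
  ct <- tolower(trimws(tab$cell_type))
  cell_type <- ifelse(grepl("/", ct, fixed = TRUE) | ct == "both", "both",
                ifelse(ct == "somatic", "somatic",
                ifelse(ct %in% c("germline", "germ"), "germline",
                       NA_character_)))
  if (anyNA(cell_type))
    stop("unrecognized cell_type value(s): ",
         paste(unique(tab$cell_type[is.na(cell_type)]), collapse = ", "))
  tl <- tolower(trimws(tab$translocation))
  translocation <- ifelse(tl %in% c("yes", "y", "t", "true", "1"), "yes",
                    ifelse(tl %in% c("no", "n", "f", "false", "0"), "no",
                           NA_character_))
  if (anyNA(translocation))
    stop("unrecognized translocation value(s): ",
         paste(unique(tab$translocation[is.na(translocation)]), collapse = ", "))
  records <- data.frame(gene_symbol = as.character(tab$gene_symbol),
                        dominance = dominance, cell_type = cell_type,
                        translocation = translocation,
                        stringsAsFactors = FALSE)
  list(records = records,
       exclusions = list(
         dominant_recessive = sum(dominance == "ambiguous"),
         somatic_germline   = sum(cell_type == "both"),
         translocation      = 0L))
}

#' Read fragile-site (or other point) coordinates
#'
#' @param path TSV with header columns \code{chrom}, \code{position} (0-based
#'   midpoint) and optionally \code{label}.
#' @return data.frame with columns \code{chrom}, \code{position},
#'   \code{label}.
#' @export
read_genomic_sites <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "position") %in% names(tab)))
    stop("missing required column(s): chrom, position")
  if (any(tab$position < 0)) stop("negative site position")
  data.frame(chrom = as.character(tab$chrom),
             position = as.numeric(tab$position),
             label = if ("label" %in% names(tab)) as.character(tab$label)
                     else paste0("site", seq_len(nrow(tab))),
             stringsAsFactors = FALSE)
}

#' Load a genome FASTA as a sequence accessor
#'
#' @param path FASTA file with records named by chromosome (description after
#'   the first whitespace is ignored).
#' @return An object of class \code{"genome_seq"}; query it with
#'   \code{\link{seq_fetch}}.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  structure(list(seqs = ss), class = "genome_seq")
}

#' Fetch a subsequence by half-open interval
#'
#' @param genome A \code{"genome_seq"} from \code{\link{read_sequences}}.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Uppercase character string of length \code{end - start}
#'   (soft-masking case is normalized away).
#' @export
seq_fetch <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_seq"))
  if (!chrom %in% names(genome$seqs))
    stop("chromosome not in FASTA: ", chrom)
  len <- Biostrings::width(genome$seqs[chrom])
  if (start < 0 || end > len || end < start)
    stop("interval [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", len, ")")
  toupper(as.character(Biostrings::subseq(genome$seqs[[chrom]],
                                          start + 1L, end)))
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq:", length(x$seqs), "sequence(s),",
      format(sum(as.numeric(Biostrings::width(x$seqs))), big.mark = ","),
      "nt>\n")
  invisible(x)
}

feature_table_columns <- c("gene", "chrom", "strand", "Di", "De", "Mi", "Me",
                           "pair_density", "triplet_count", "gc_adjusted",
                           "Si", "Se", "log10_size")

#' Write / read the per-gene feature table
#'
#' One row per gene, fixed column order (\code{gene, chrom, strand, Di, De,
#' Mi, Me, pair_density, triplet_count, gc_adjusted, Si, Se, log10_size});
#' numeric values round-trip losslessly.
#'
#' @param features data.frame of per-gene features (as produced by
#'   \code{\link{gene_alu_features}}).
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (nrow(features) == 0L) stop("empty feature table")
  missing <- setdiff(feature_table_columns, names(features))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  out <- features[, feature_table_columns]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x)
    vapply(x, format, "", digits = 17, scientific = FALSE, trim = TRUE,
           drop0trailing = TRUE))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write feature table to ", path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(feature_table_columns, names(tab))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  tab
}
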