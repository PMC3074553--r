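#' Pipeline configuration
#'
#' Bundles input paths, formats and analysis parameters for
#' \code{\link{run_pipeline}}.
#'
#' @param genes Path to the gene-model file.
#' @param repeats Path to the repeat-coordinate file.
#' @param outdir Output directory for all result files.
#' @param genes_format \code{"bed12"} or \code{"gtf"}.
#' @param repeats_format \code{"bed6"} or \code{"rmsk_out"}.
#' @param fasta Optional genome FASTA (enables motif densities and GC).
#' @param classes Optional cancer-gene class TSV
#'   (see \code{\link{read_cancer_gene_table}}).
#' @param sites Optional fragile-site TSV (see
#'   \code{\link{read_genomic_sites}}).
#' @param motif Motif string (default \code{"TTAAAA"}).
#' @param gap Pair/triplet gap threshold in nt (default 300).
#' @param cut_height Dendrogram cut height (default 4.5).
#' @param count_motifs_in_alus Count motif copies inside Alus (default
#'   \code{FALSE}).
#' @param log_response Model-2 on log density (default \code{FALSE}).
#' @param scale Feature scaling for clustering, \code{"none"} or
#'   \code{"zscore"}.
#' @param min_genes Per-chromosome gene floor for the two-step regression.
#' @param include_fs_distance Add nearest fragile-site distance to the
#'   class-association covariates (needs \code{sites}).
#' @param family_filter Repeat family prefix to keep (default
#'   \code{"Alu"}).
#' @param seed Integer seed recorded in the report.
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(genes, repeats, outdir,
                            genes_format = "bed12",
                            repeats_format = "bed6",
                            fasta = NULL, classes = NULL, sites = NULL,
                            motif = "TTAAAA", gap = 300, cut_height = 4.5,
                            count_motifs_in_alus = FALSE,
                            log_response = FALSE,
                            scale = "none", min_genes = 10,
                            include_fs_distance = FALSE,
                            family_filter = "Alu", seed = 1L) {
  if (gap <= 0 || cut_height < 0) stop("thresholds must be positive")
  if (grepl("[^ACGT]", toupper(motif)))
    stop("motif must be over A/C/G/T")
  structure(list(genes = genes, genes_format = genes_format,
                 repeats = repeats, repeats_format = repeats_format,
                 fasta = fasta, classes = classes, sites = sites,
                 motif = toupper(motif), gap = gap,
                 cut_height = cut_height,
                 count_motifs_in_alus = count_motifs_in_alus,
                 log_response = log_response, scale = scale,
                 min_genes = min_genes,
                 include_fs_distance = include_fs_distance,
                 family_filter = family_filter,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full Alu-distribution analysis
#'
#' Stages, in order: read inputs; per-gene feature extraction;
#' chromosome-level region densities; per-chromosome zero-inflated Gamma
#' mixture fits; two-step motif regression across chromosomes; class
#' associations (dominant/recessive, somatic/germline,
#' translocation) when a class table is given; clustering of the classified
#' genes with Fisher enrichment of the recessive class in the smaller
#' clusters. Intermediate tables are written under \code{config$outdir};
#' progress and filter counts go to stderr, results never do.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return An object of class \code{"alu_report"} (also serialized as JSON
#'   in the output directory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[aludist] ", ...)

  gm <- run_stage("read_gene_models",
                  read_gene_models(config$genes, config$genes_format))
  log_msg(length(gm$genes), " gene model(s); ",
          length(gm$excluded_single_exon), " single-exon gene(s) excluded")
  reps <- run_stage("read_repeats",
                    read_repeat_intervals(config$repeats,
                                          config$repeats_format,
                                          config$family_filter))
  genome <- NULL
  if (!is.null(config$fasta))
    genome <- run_stage("read_sequences", read_sequences(config$fasta))
  classes <- NULL
  if (!is.null(config$classes)) {
    classes <- run_stage("read_classes",
                         read_cancer_gene_table(config$classes))
    log_msg(nrow(classes$records), " classified gene(s); exclusions: ",
            "dominant/recessive ", classes$exclusions$dominant_recessive,
            ", somatic/germline ", classes$exclusions$somatic_germline)
  }
  sites <- NULL
  if (!is.null(config$sites))
    sites <- run_stage("read_sites", read_genomic_sites(config$sites))

  features <- run_stage("feature_extraction",
                        gene_alu_features(gm$genes, reps, genome,
                                          config$motif, config$gap,
                                          config$count_motifs_in_alus))
  if (!is.null(sites))
    features$fs_distance <- vapply(gm$genes, function(g)
      nearest_site_distance(g, sites), numeric(1))
  write_feature_table(features, file.path(config$outdir, "features.tsv"))

  chroms <- unique(features$chrom)
  chrom_dens <- run_stage("chromosome_densities", {
    rows <- lapply(chroms, function(ch) {
      gch <- Filter(function(g) g$chrom == ch, gm$genes)
      len <- if (!is.null(genome) && ch %in% names(genome$seqs))
        Biostrings::width(genome$seqs[ch])
      else max(c(vapply(gch, function(g) gene_span(g)[2], numeric(1)),
                 reps$end[reps$chrom == ch]))
      motifs <- NULL
      if (!is.null(genome) && ch %in% names(genome$seqs)) {
        pos <- scan_motif(seq_fetch(genome, ch, 0, len), config$motif)
        motifs <- cbind(pos, pos + nchar(config$motif))
      }
      chromosome_region_densities(gch, reps, len, motifs)
    })
    do.call(rbind, rows)
  })
  utils::write.table(chrom_dens,
                     file.path(config$outdir, "chromosome_densities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  fits <- run_stage("mixture_fits", {
    out <- lapply(chroms, function(ch)
      fit_mixture(features$Di[features$chrom == ch], group = ch))
    names(out) <- chroms
    out
  })
  fit_tab <- data.frame(group = chroms,
                        n = vapply(fits, `[[`, numeric(1), "n"),
                        r = vapply(fits, `[[`, numeric(1), "r"),
                        shape = vapply(fits, `[[`, numeric(1), "shape"),
                        scale = vapply(fits, `[[`, numeric(1), "scale"),
                        loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                        stringsAsFactors = FALSE)
  jsonlite::write_json(fit_tab, file.path(config$outdir, "mixture_fits.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  two_step <- NULL
  if (!is.null(genome) && length(chroms) >= 2L) {
    two_step <- run_stage("two_step_regression",
                          two_step_motif_analysis(features,
                                                  config$min_genes,
                                                  config$log_response))
    utils::write.table(two_step,
                       file.path(config$outdir, "two_step_regression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  associations <- list()
  clustering <- NULL
  if (!is.null(classes)) {
    cls <- classes$records[classes$records$gene_symbol %in% features$gene, ,
                           drop = FALSE]
    log_msg(nrow(classes$records) - nrow(cls),
            " classified gene(s) absent from the feature table")
    idx <- match(cls$gene_symbol, features$gene)
    fcls <- features[idx, , drop = FALSE]
    covars <- c("Di", "log10_size")
    if (config$include_fs_distance && "fs_distance" %in% names(features))
      covars <- c(covars, "fs_distance")
    comparisons <- list(
      dominant_recessive = list(keep = cls$dominance != "ambiguous",
                                label = as.numeric(cls$dominance == "recessive")),
      somatic_germline = list(keep = cls$cell_type != "both",
                              label = as.numeric(cls$cell_type == "germline")),
      translocation = list(keep = rep(TRUE, nrow(cls)),
                           label = as.numeric(cls$translocation == "no")))
    associations <- run_stage("class_associations", {
      out <- list()
      for (nm in names(comparisons)) {
        cc <- comparisons[[nm]]
        if (length(unique(cc$label[cc$keep])) < 2L) next
        out[[nm]] <- class_association(fcls[cc$keep, , drop = FALSE],
                                       cc$label[cc$keep], covars, name = nm)
      }
      out
    })

    if (nrow(fcls) >= 3L) {
      clustering <- run_stage("clustering", {
        mat <- fcls[, c("Di", "De", "pair_density", "triplet_count",
                        "gc_adjusted")]
        mat$gene <- fcls$gene
        tree <- cluster_genes(mat, config$scale)
        assign <- cut_dendrogram(tree, config$cut_height)
        sizes <- assign$sizes
        nonsing <- as.integer(names(sizes)[sizes > 1L])
        enrich <- NULL
        if (length(nonsing) >= 2L &&
            length(unique(cls$dominance[cls$dominance != "ambiguous"])) == 2L) {
          focus <- setdiff(nonsing, nonsing[which.max(sizes[as.character(nonsing)])])
          lab <- as.numeric(cls$dominance == "recessive")
          enrich <- tryCatch(cluster_class_enrichment(assign, lab, focus),
                             error = function(e) NULL)
        }
        dendrogram_newick(tree, file.path(config$outdir, "dendrogram.nwk"))
        utils::write.table(
          data.frame(gene = names(assign$cluster),
                     cluster = as.integer(assign$cluster)),
          file.path(config$outdir, "cluster_assignment.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
        list(tree = tree, assignment = assign, enrichment = enrich)
      })
    }
  }

  report <- structure(list(config = config,
                           n_genes = length(gm$genes),
                           excluded_single_exon = gm$excluded_single_exon,
                           class_exclusions = if (!is.null(classes))
                             classes$exclusions else NULL,
                           features = features,
                           chrom_densities = chrom_dens,
                           mixture_fits = fits,
                           mixture_table = fit_tab,
                           two_step = two_step,
                           associations = associations,
                           clustering = clustering),
                      class = "alu_report")
  report_json <- list(
    provenance = list(package_version = as.character(
      utils::packageVersion("aludist")), seed = config$seed),
    n_genes = report$n_genes,
    excluded_single_exon = report$excluded_single_exon,
    mixture_fits = fit_tab,
    two_step = two_step,
    enrichment = if (!is.null(clustering) && !is.null(clustering$enrichment))
      list(table = clustering$enrichment$table,
           p_value = clustering$enrichment$p_value,
           odds_ratio = clustering$enrichment$odds_ratio) else NULL)
  jsonlite::write_json(report_json, file.path(config$outdir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  report
}

#' @export
print.alu_report <- function(x, ...) {
  cat("Alu distribution analysis report\n")
  cat("  genes analysed:", x$n_genes, " (", length(x$excluded_single_exon),
      "single-exon excluded)\n")
  cat("  chromosomes:", paste(x$mixture_table$group, collapse = ", "), "\n")
  if (!is.null(x$two_step))
    cat("  two-step regression rows:", nrow(x$two_step), "\n")
  if (length(x$associations))
    cat("  class associations:", paste(names(x$associations),
                                       collapse = ", "), "\n")
  if (!is.null(x$clustering) && !is.null(x$clustering$enrichment))
    cat(sprintf("  cluster enrichment p = %.3g\n",
                x$clustering$enrichment$p_value))
  invisible(x)
}

#' Render a human-readable summary and plot-ready tables
#'
#' Writes a markdown summary plus machine-readable TSVs behind each figure
#' of the analysis: per-chromosome Q-Q pairs, adjusted mixture density
#' curves, and the two-model -log10 adjusted-p scatter of the motif
#' regression.
#'
#' @param report An \code{"alu_report"} from \code{\link{run_pipeline}}.
#' @param dir Output directory (defaults to the report's outdir).
#' @return Path of the markdown file, invisibly.
#' @export
render_report <- function(report, dir = report$config$outdir) {
  stopifnot(inherits(report, "alu_report"))
  required <- c("features", "chrom_densities", "mixture_fits",
                "mixture_table")
  missing <- required[vapply(required, function(f) is.null(report[[f]]), TRUE)]
  if (length(missing))
    stop("incomplete report; missing section(s): ",
         paste(missing, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  qq_rows <- list()
  curve_rows <- list()
  for (ch in names(report$mixture_fits)) {
    fit <- report$mixture_fits[[ch]]
    if (!fit$has_gamma || fit$r >= 1) next
    qq <- qq_points(fit)
    qq_rows[[ch]] <- data.frame(group = ch, qq)
    grid <- seq(1e-3, max(fit$positive_values), length.out = 200)
    md <- mixture_density(fit, grid)
    curve_rows[[ch]] <- data.frame(group = ch, x = md$x,
                                   adjusted_density = md$density)
  }
  utils::write.table(do.call(rbind, qq_rows),
                     file.path(dir, "qq_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, curve_rows),
                     file.path(dir, "mixture_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$two_step)) {
    ts <- report$two_step
    ts$neg_log10_padj <- -log10(ts$padj)
    utils::write.table(ts, file.path(dir, "motif_effect_scatter.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  md <- c("# Alu distribution analysis", "",
          "## Inputs and exclusions", "",
          paste0("- genes analysed: ", report$n_genes),
          paste0("- single-exon genes excluded: ",
                 length(report$excluded_single_exon)), "",
          "## Chromosome-level densities", "",
          df_to_md(report$chrom_densities), "",
          "## Mixture model fits", "",
          df_to_md(report$mixture_table), "")
  if (!is.null(report$two_step))
    md <- c(md, "## Two-step motif regression", "",
            df_to_md(report$two_step), "")
  if (length(report$associations)) {
    md <- c(md, "## Class associations", "")
    for (nm in names(report$associations)) {
      a <- report$associations[[nm]]
      md <- c(md, paste0("### ", nm), "",
              vapply(a$covariates, function(term)
                sprintf("- %s: coefficient %.4g, p = %.3g (%s)", term,
                        a$fit$coefficients[[term]], a$fit$p[[term]],
                        a$verdicts[[term]]), ""), "")
    }
  }
  if (!is.null(report$clustering)) {
    md <- c(md, "## Clustering", "",
            paste0("- cut height: ", report$clustering$assignment$height),
            paste0("- cluster sizes: ",
                   paste(report$clustering$assignment$sizes, collapse = ", ")))
    if (!is.null(report$clustering$enrichment)) {
      e <- report$clustering$enrichment
      md <- c(md, sprintf("- enrichment: %.1f%% vs %.1f%% (Fisher p = %.3g, OR = %.3g)",
                          100 * e$focus_proportion, 100 * e$other_proportion,
                          e$p_value, e$odds_ratio))
    }
    md <- c(md, "")
  }
  path <- file.path(dir, "report.md")
  writeLines(md, path)
  invisible(path)
}

df_to_md <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
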