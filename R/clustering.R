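#' Agglomerative clustering of genes on Alu-related features
#'
#' Complete-linkage hierarchical clustering with Euclidean distance on the
#' per-gene feature matrix (intron Alu density, exon Alu density, Alu-pair
#' density, Alu-exon-Alu triplet count, Alu-masked GC content). Features
#' enter unscaled by default: the absolute cut height and the isolation of
#' extreme triplet-count genes are only meaningful on raw features;
#' \code{scale = "zscore"} standardizes each column first.
#'
#' @param features Numeric matrix or data.frame (rows = genes; row names or
#'   a \code{gene} column give the leaf labels).
#' @param scale \code{"none"} (default) or \code{"zscore"}.
#' @return An \code{\link[stats]{hclust}} dendrogram (merge heights
#'   non-decreasing under complete linkage).
#' @export
cluster_genes <- function(features, scale = c("none", "zscore")) {
  scale <- match.arg(scale)
  if (is.data.frame(features)) {
    labels <- if ("gene" %in% names(features)) features$gene
              else rownames(features)
    num <- vapply(features, is.numeric, TRUE)
    mat <- as.matrix(features[, num, drop = FALSE])
  } else {
    mat <- as.matrix(features)
    labels <- rownames(mat)
  }
  if (nrow(mat) < 2L) stop("need at least 2 genes")
  if (any(is.na(mat))) {
    bad <- which(apply(is.na(mat), 1, any))
    stop("NA feature value for gene(s): ",
         paste(utils::head(if (is.null(labels)) bad else labels[bad], 5),
               collapse = ", "))
  }
  if (scale == "zscore") mat <- base::scale(mat)
  rownames(mat) <- labels
  stats::hclust(stats::dist(mat, method = "euclidean"), method = "complete")
}

#' Cut a dendrogram at a height
#'
#' Clusters are the connected components left after removing all merges
#' higher than the cut.
#'
#' @param tree An \code{\link[stats]{hclust}} object.
#' @param height Non-negative cut height (default 4.5, a heuristic choice on
#'   raw features).
#' @return An object of class \code{"cluster_assignment"}: named integer
#'   vector \code{cluster}, the \code{height} used, and \code{sizes} per
#'   cluster (singletons permitted).
#' @export
cut_dendrogram <- function(tree, height = 4.5) {
  if (height < 0) stop("height must be non-negative")
  cl <- stats::cutree(tree, h = height)
  structure(list(cluster = cl, height = height,
                 sizes = table(cl)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Dendrogram cut at height", x$height, "->", length(x$sizes),
      "cluster(s)\n")
  print(x$sizes)
  invisible(x)
}

#' Enrichment of a binary class in focus clusters
#'
#' Pools the focus clusters against the remaining non-singleton clusters
#' (singleton clusters sit in neither pool) and tests the 2x2 table of class
#' membership with \code{\link{fisher_exact_2x2}}.
#'
#' @param assignment A \code{"cluster_assignment"} from
#'   \code{\link{cut_dendrogram}}.
#' @param labels Named or positionally aligned binary labels (1 = class of
#'   interest) for the clustered genes.
#' @param focus Integer ids of the focus clusters.
#' @return List with the 2x2 \code{table} (rows: focus pool, other pool;
#'   columns: label 1, label 0), \code{p_value}, \code{odds_ratio}, and the
#'   two pools' class proportions.
#' @export
cluster_class_enrichment <- function(assignment, labels, focus) {
  cl <- assignment$cluster
  if (length(labels) != length(cl))
    stop("labels and assignment differ in length")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  singleton_ids <- as.integer(names(assignment$sizes)[assignment$sizes == 1L])
  in_focus <- cl %in% focus
  in_other <- !in_focus & !(cl %in% singleton_ids)
  if (!any(in_focus) || !any(in_other))
    stop("focus pool or complement pool is empty")
  tab <- matrix(c(sum(labels[in_focus] == 1), sum(labels[in_focus] == 0),
                  sum(labels[in_other] == 1), sum(labels[in_other] == 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("focus", "other"),
                                c("class1", "class0")))
  ft <- fisher_exact_2x2(tab)
  list(table = tab, p_value = ft$p_value, odds_ratio = ft$odds_ratio,
       focus_proportion = tab[1, 1] / sum(tab[1, ]),
       other_proportion = tab[2, 1] / sum(tab[2, ]))
}

#' Export a dendrogram as a newick string
#'
#' @param tree An \code{\link[stats]{hclust}} object.
#' @param path Optional file to write to.
#' @return The newick string, invisibly if written to a file.
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
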