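#' Logistic regression fit with Wald tests
#'
#' Maximum-likelihood logit fit (iteratively reweighted least squares via
#' \code{stats::glm}, log-likelihood convergence tolerance 1e-10) with
#' per-term Wald p-values. Possible perfect separation (fitted probabilities
#' numerically 0 or 1) is surfaced as a warning; the estimates returned are
#' the finite values at the iteration cap.
#'
#' @param y Binary response vector (0/1, both classes present).
#' @param X Covariate matrix or data.frame (an intercept is always added).
#' @return An object of class \code{"alu_glm"}: \code{coefficients},
#'   \code{se}, \code{p} (Wald), \code{loglik}, \code{n}, \code{model}.
#' @export
fit_logistic <- function(y, X) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("y is single-class")
  X <- as.data.frame(X)
  if (ncol(X) > 0 && nrow(X) != length(y)) stop("X and y lengths differ")
  fml <- if (ncol(X) == 0L) .y ~ 1 else .y ~ .
  if (ncol(X) > 0L) {
    mm <- stats::model.matrix(~ ., data = X)
    if (qr(mm)$rank < ncol(mm)) stop("covariate matrix is rank deficient")
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated)
    warning("possible perfect separation: estimates capped at iteration limit")
  sm <- summary(fit)$coefficients
  structure(list(coefficients = sm[, 1], se = sm[, 2],
                 p = sm[, 4], loglik = as.numeric(stats::logLik(fit)),
                 n = length(y), model = "logistic",
                 separated = separated),
            class = "alu_glm")
}

#' Ordinary least squares fit with t tests and R-squared
#'
#' @param y Numeric response.
#' @param X Covariate matrix or data.frame (an intercept is always added).
#' @return An object of class \code{"alu_glm"} with \code{coefficients},
#'   \code{se}, \code{p} (t tests), \code{r_squared}, \code{loglik},
#'   \code{n}.
#' @export
fit_linear <- function(y, X) {
  y <- as.numeric(y)
  X <- as.data.frame(X)
  if (ncol(X) > 0 && nrow(X) != length(y)) stop("X and y lengths differ")
  fml <- if (ncol(X) == 0L) .y ~ 1 else .y ~ .
  if (ncol(X) > 0L) {
    mm <- stats::model.matrix(~ ., data = X)
    if (qr(mm)$rank < ncol(mm)) stop("covariate matrix is rank deficient")
    if (length(y) <= ncol(mm)) stop("more terms than observations")
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  structure(list(coefficients = sm$coefficients[, 1],
                 se = sm$coefficients[, 2],
                 p = sm$coefficients[, 4],
                 r_squared = sm$r.squared,
                 loglik = as.numeric(stats::logLik(fit)),
                 n = length(y), model = "linear"),
            class = "alu_glm")
}

#' @export
print.alu_glm <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit, n = %d, logLik = %.*g\n",
              if (x$model == "logistic") "Logistic" else "Linear",
              x$n, digits, x$loglik))
  tab <- cbind(estimate = x$coefficients, se = x$se, p = x$p)
  print(signif(tab, digits))
  if (!is.null(x$r_squared))
    cat(sprintf("R-squared: %.*g\n", digits, x$r_squared))
  invisible(x)
}

#' Nagelkerke pseudo-R-squared
#'
#' @param loglik Model log-likelihood.
#' @param loglik_null Intercept-only log-likelihood on the same
#'   observations.
#' @param n Number of observations.
#' @return Nagelkerke R^2 in \code{[0, 1]}:
#'   \code{(1 - exp((2/n) (ll0 - ll))) / (1 - exp((2/n) ll0))}.
#' @export
nagelkerke_r2 <- function(loglik, loglik_null, n) {
  cox_snell <- 1 - exp((2 / n) * (loglik_null - loglik))
  max_r2 <- 1 - exp((2 / n) * loglik_null)
  cox_snell / max_r2
}

#' Pseudo-R-squared contribution of the terms added by a full model
#'
#' The increase of the Nagelkerke index when moving from the reduced to the
#' full (nesting) model, clipped at zero if numerically negative.
#'
#' @param full,reduced,null \code{"alu_glm"} logistic fits on identical
#'   observations; \code{null} is intercept-only.
#' @return Non-negative pseudo-R^2 increase.
#' @export
nagelkerke_contribution <- function(full, reduced, null) {
  ns <- c(full$n, reduced$n, null$n)
  if (length(unique(ns)) != 1L)
    stop("models fitted on different numbers of observations")
  max(0, nagelkerke_r2(full$loglik, null$loglik, full$n) -
        nagelkerke_r2(reduced$loglik, null$loglik, full$n))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement; the input
#' order is preserved in the output.
#'
#' @param pvalues Numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-step regression of motif density on intron Alu density
#'
#' Per chromosome: Model-1 is a logistic regression of Alu presence
#' (z = [Di > 0]) on intron motif density Mi and log10 adjusted gene size,
#' over all multi-exon genes; Model-2 is an ordinary linear regression of
#' the intron Alu density Di on the same covariates over the genes with at
#' least one intron Alu. The motif-term p-values are Benjamini-Hochberg
#' adjusted across chromosomes separately within each model. Contribution
#' columns give the increase in Nagelkerke pseudo-R^2 (Model-1) or R^2
#' (Model-2) from adding the motif term to the size-only reduced model.
#'
#' @param features Per-gene feature data.frame with columns \code{chrom},
#'   \code{Di}, \code{Mi}, \code{log10_size}.
#' @param min_genes Minimum genes per chromosome for it to enter the
#'   analysis (default 10).
#' @param log_response If \code{TRUE}, Model-2 regresses \code{log(Di)}
#'   instead of the raw density.
#' @return data.frame with one row per chromosome and model:
#'   \code{chrom}, \code{model} (1 or 2), \code{n}, \code{beta} (motif
#'   coefficient), \code{se}, \code{p}, \code{padj}, \code{contribution};
#'   plus an attribute \code{"skipped"} naming chromosome/model pairs that
#'   could not be fitted and why.
#' @export
two_step_motif_analysis <- function(features, min_genes = 10,
                                    log_response = FALSE) {
  need <- c("chrom", "Di", "Mi", "log10_size")
  missing <- setdiff(need, names(features))
  if (length(missing))
    stop("features lack column(s): ", paste(missing, collapse = ", "))
  chroms <- unique(features$chrom)
  rows <- list()
  skipped <- character(0)
  for (ch in chroms) {
    f <- features[features$chrom == ch, , drop = FALSE]
    if (nrow(f) < min_genes) {
      skipped <- c(skipped, paste0(ch, ": fewer than ", min_genes, " genes"))
      next
    }
    z <- as.numeric(f$Di > 0)
    if (length(unique(z)) < 2L) {
      skipped <- c(skipped,
                   paste0(ch, "/model1: Alu presence is constant"))
    } else {
      full <- fit_logistic(z, f[, c("Mi", "log10_size")])
      red  <- fit_logistic(z, f[, "log10_size", drop = FALSE])
      nul  <- fit_logistic(z, data.frame(row.names = seq_along(z))[, 0,
                                                                   drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, model = 1L, n = full$n,
        beta = full$coefficients[["Mi"]], se = full$se[["Mi"]],
        p = full$p[["Mi"]],
        contribution = nagelkerke_contribution(full, red, nul),
        stringsAsFactors = FALSE)
    }
    fp <- f[f$Di > 0, , drop = FALSE]
    if (nrow(fp) < 4L) {
      skipped <- c(skipped,
                   paste0(ch, "/model2: fewer than 4 Alu-containing genes"))
    } else {
      yy <- if (log_response) log(fp$Di) else fp$Di
      full2 <- fit_linear(yy, fp[, c("Mi", "log10_size")])
      red2  <- fit_linear(yy, fp[, "log10_size", drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, model = 2L, n = full2$n,
        beta = full2$coefficients[["Mi"]], se = full2$se[["Mi"]],
        p = full2$p[["Mi"]],
        contribution = max(0, full2$r_squared - red2$r_squared),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no chromosome could be analysed")
  out <- do.call(rbind, rows)
  out$padj <- NA_real_
  for (mdl in unique(out$model))
    out$padj[out$model == mdl] <- bh_adjust(out$p[out$model == mdl])
  out <- out[, c("chrom", "model", "n", "beta", "se", "p", "padj",
                 "contribution")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Association between a binary gene class and Alu features
#'
#' Logistic regression of the class label on the chosen covariates (default:
#' intron Alu density and log10 gene size; exon Alu density or the nearest
#' fragile-site distance can be added by name).
#'
#' @param features Per-gene feature data.frame.
#' @param labels Binary class label per row of \code{features}.
#' @param covariates Character vector of feature columns to use.
#' @param name Label for the classification (e.g.
#'   \code{"dominant_recessive"}).
#' @return An object of class \code{"association_result"} wrapping the
#'   \code{"alu_glm"} fit and per-term significance verdicts ("extremely
#'   significant" p < 0.001, "marginally significant" p < 0.05, otherwise
#'   "not significant").
#' @export
class_association <- function(features, labels,
                              covariates = c("Di", "log10_size"),
                              name = "classification") {
  missing <- setdiff(covariates, names(features))
  if (length(missing))
    stop("features lack covariate(s): ", paste(missing, collapse = ", "))
  fit <- fit_logistic(labels, features[, covariates, drop = FALSE])
  verdict <- ifelse(fit$p < 0.001, "extremely significant",
             ifelse(fit$p < 0.05, "marginally significant",
                    "not significant"))
  names(verdict) <- names(fit$p)
  structure(list(name = name, fit = fit, covariates = covariates,
                 verdicts = verdict),
            class = "association_result")
}

#' @export
print.association_result <- function(x, digits = 4, ...) {
  cat("Class association:", x$name, "\n")
  print(x$fit, digits = digits)
  for (term in x$covariates)
    cat(sprintf("  %s: %s (p = %.*g)\n", term, x$verdicts[[term]],
                digits, x$fit$p[[term]]))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table. The odds
#' ratio reported is the sample odds ratio ad/(bc).
#'
#' @param table 2x2 matrix of non-negative integer counts with all margins
#'   positive.
#' @return List with \code{p_value} and \code{odds_ratio}.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-8))
    stop("counts must be non-negative integers")
  tab <- round(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c          # column-1 total
  n <- b + d          # column-2 total
  k <- a + b          # row-1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c == 0) Inf else (a * d) / (b * c)
  list(p_value = min(1, p), odds_ratio = or)
}
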