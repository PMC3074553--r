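test_that("logistic fit matches a hand-rolled IRLS oracle", {
  set.seed(31)
  n <- 200
  x1 <- rnorm(n); x2 <- runif(n)
  y <- rbinom(n, 1, plogis(-0.5 + 1.2 * x1 - 0.8 * x2))
  fit <- fit_logistic(y, data.frame(x1 = x1, x2 = x2))
  oracle <- irls_logistic(cbind(1, x1, x2), y)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-8)
  expect_error(fit_logistic(rep(1, 10), data.frame(x = rnorm(10))),
               "single-class")
  expect_error(fit_logistic(y, data.frame(x1 = x1, x1b = x1)),
               "rank deficient")
})

test_that("logistic simulation recovery and null behaviour", {
  set.seed(32)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  fit <- fit_logistic(y, data.frame(x = x))
  expect_lt(abs(fit$coefficients[["x"]] - 1), 3 * fit$se[["x"]])
  # separation is flagged, not fatal
  ys <- as.numeric(x > 0)
  expect_warning(fit_logistic(ys, data.frame(x = x)), "separation")
})

test_that("linear fit is exact on noiseless data and rejects collinearity", {
  x <- 1:20
  fit <- suppressWarnings(fit_linear(2 * x, data.frame(x = x)))
  expect_equal(fit$coefficients[["x"]], 2)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_linear(rnorm(20), data.frame(a = x, b = 2 * x)),
               "rank deficient")
})

test_that("Nagelkerke contribution obeys its algebraic identities", {
  set.seed(33)
  n <- 500
  x <- rnorm(n); l <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * x))
  full <- fit_logistic(y, data.frame(x = x, l = l))
  red <- fit_logistic(y, data.frame(l = l))
  nul <- fit_logistic(y, data.frame(row.names = 1:n)[, 0, drop = FALSE])
  expect_equal(nagelkerke_contribution(full, full, nul), 0)
  contrib <- nagelkerke_contribution(full, red, nul)
  # likelihood-ratio reconstruction of the same quantity
  denom <- 1 - exp((2 / n) * nul$loglik)
  alt <- (exp((2 / n) * (nul$loglik - red$loglik)) -
            exp((2 / n) * (nul$loglik - full$loglik))) / denom
  expect_equal(contrib, alt, tolerance = 1e-10)
  expect_gte(contrib, 0)
  red_small <- fit_logistic(y[-1], data.frame(l = l[-1]))
  expect_error(nagelkerke_contribution(full, red_small, nul), "different")
})

test_that("a strong presence coupling yields a pseudo-contribution near one third", {
  # small-sample setting: 93 genes, coupling calibrated to ~0.33
  set.seed(34)
  contribs <- replicate(50, {
    n <- 93
    x <- rgamma(n, 2, scale = 0.5)
    l <- rnorm(n, 4.4, 0.4)
    z <- rbinom(n, 1, plogis(-1.2 + 1.8 * (x - 1)))
    if (length(unique(z)) < 2) return(NA_real_)
    full <- fit_logistic(z, data.frame(Mi = x, log10_size = l))
    red <- fit_logistic(z, data.frame(log10_size = l))
    nul <- fit_logistic(z, data.frame(row.names = 1:n)[, 0, drop = FALSE])
    nagelkerke_contribution(full, red, nul)
  })
  expect_lt(abs(mean(contribs, na.rm = TRUE) - 0.33), 0.05)
})

test_that("BH adjustment follows the step-up rule and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- c(0.04, 0.001, 0.8, 0.2)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("two-step analysis separates presence and intensity coupling", {
  set.seed(35)
  make_chrom <- function(ch, n, b_presence, b_intensity) {
    Mi <- rgamma(n, 2, scale = 0.5)
    size <- rnorm(n, 4.4, 0.4)
    z <- rbinom(n, 1, plogis(0.5 + b_presence * (Mi - 1)))
    Di <- ifelse(z == 1,
                 pmax(rgamma(n, 0.8, scale = 1.2) +
                        b_intensity * (Mi - 1), 0.01), 0)
    data.frame(chrom = ch, Di = Di, Mi = Mi, log10_size = size)
  }
  feats <- rbind(make_chrom("c_both", 600, 2.0, 1.0),
                 make_chrom("c_presence", 600, 2.0, 0),
                 make_chrom("c_null", 600, 0, 0))
  res <- two_step_motif_analysis(feats)
  expect_equal(nrow(res), 6L)
  get <- function(ch, m) res[res$chrom == ch & res$model == m, ]
  expect_lt(get("c_both", 1)$padj, 0.05)
  expect_lt(get("c_both", 2)$padj, 0.05)
  expect_gt(get("c_both", 1)$beta, 0)
  # presence-only coupling: Model-1 significant, Model-2 not
  expect_lt(get("c_presence", 1)$padj, 0.05)
  expect_gt(get("c_presence", 2)$padj, 0.05)
  expect_gt(get("c_null", 1)$padj, 0.05)
  expect_true(all(res$padj >= res$p))
  expect_true(all(res$contribution >= 0))
})

test_that("two-step analysis handles degenerate chromosomes", {
  set.seed(36)
  feats <- data.frame(chrom = "only", Di = rgamma(100, 1, 1),
                      Mi = rgamma(100, 2, 2), log10_size = rnorm(100, 4))
  feats$Di[1:30] <- 0
  res <- two_step_motif_analysis(feats)
  expect_equal(res$padj, res$p)   # single group: BH is the identity
  # a chromosome with all zero densities skips Model-2 with a diagnostic
  feats2 <- rbind(feats,
                  data.frame(chrom = "allzero", Di = 0,
                             Mi = rgamma(50, 2, 2), log10_size = rnorm(50, 4)))
  res2 <- two_step_motif_analysis(feats2)
  expect_false(any(res2$chrom == "allzero" & res2$model == 2))
  expect_match(paste(attr(res2, "skipped"), collapse = "; "), "allzero")
})

test_that("class association recovers a simulated density effect", {
  set.seed(37)
  n <- 2000
  feats <- data.frame(Di = rgamma(n, 0.8, scale = 1.3),
                      log10_size = rnorm(n, 4.4, 0.4))
  labels <- simulate_class_labels(feats, -2, 1.5, 0, seed = 1)
  res <- class_association(feats, labels, name = "toy")
  expect_gt(res$fit$coefficients[["Di"]], 0)
  expect_lt(res$fit$p[["Di"]], 0.001)
  expect_equal(res$verdicts[["Di"]], "extremely significant")
  expect_error(class_association(feats, rep(0, n)), "single-class")
})

test_that("Fisher exact test matches closed forms and printed example", {
  res <- fisher_exact_2x2(matrix(c(22, 26, 53, 249), 2, 2, byrow = TRUE))
  expect_equal(res$p_value,
               fisher.test(matrix(c(22, 26, 53, 249), 2, 2,
                                  byrow = TRUE))$p.value, tolerance = 1e-10)
  expect_equal(res$odds_ratio, (22 * 249) / (26 * 53))
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2))$p_value,
               2 / choose(10, 5))
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2, 2)), "integer")
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 1), 2, 2)), "margins")
})

test_that("Fisher agrees with full enumeration on random small tables", {
  set.seed(38)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 4) + c(1, 0, 0, 1), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    if (sum(tab) > 40) next
    expect_equal(fisher_exact_2x2(tab)$p_value, fisher_enum(tab),
                 tolerance = 1e-12)
  }
})
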