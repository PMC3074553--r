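# independent brute-force oracles; deliberately naive implementations kept
# separate from the package code paths they check

# O(n*m) classification of repeats against a transcript
brute_partition <- function(tx, reps) {
  reps <- reps[reps$chrom == tx$chrom, , drop = FALSE]
  nt <- ne <- ni <- 0L
  for (i in seq_len(nrow(reps))) {
    s <- reps$start[i]; e <- reps$end[i]
    if (!(s < tx$end && tx$start < e)) next
    nt <- nt + 1L
    hit_exon <- FALSE
    for (j in seq_len(nrow(tx$exons)))
      if (s < tx$exons[j, 2] && tx$exons[j, 1] < e) hit_exon <- TRUE
    if (hit_exon) ne <- ne + 1L else ni <- ni + 1L
  }
  c(n_total = nt, n_exon = ne, n_intron = ni)
}

# character-by-character motif scan
brute_scan <- function(sequence, motif, region = c(0, nchar(sequence))) {
  sequence <- toupper(sequence); motif <- toupper(motif)
  m <- nchar(motif)
  out <- integer(0)
  for (p in 0:(nchar(sequence) - m)) {
    if (p < region[1] || p + m > region[2]) next
    if (substr(sequence, p + 1, p + m) == motif) out <- c(out, p)
  }
  out
}

# hand-rolled IRLS for the logistic model (X includes the intercept column)
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) return(drop(beta_new))
    beta <- drop(beta_new)
  }
  drop(beta)
}

# full hypergeometric enumeration for a 2x2 table, two-sided by the
# point-probability rule
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  lo <- max(0, r1 - (N - c1)); hi <- min(r1, c1)
  logp <- function(x)
    lchoose(c1, x) + lchoose(N - c1, r1 - x) - lchoose(N, r1)
  ps <- exp(vapply(lo:hi, logp, numeric(1)))
  pobs <- exp(logp(a))
  sum(ps[ps <= pobs * (1 + 1e-7)])
}

# naive complete-linkage agglomeration: returns the sorted merge heights
brute_complete_heights <- function(mat) {
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- 0L
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}
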