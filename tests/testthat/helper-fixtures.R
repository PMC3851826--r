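## Shared fixtures and independent oracles, built in code.

## A contig from a list of M per-accession N x 4 count matrices.
make_contig <- function(mats, ref = NULL, id = "c1",
                        acc = sprintf("a%d", seq_along(mats))) {
  m <- length(mats)
  n <- nrow(mats[[1]])
  counts <- array(0L, dim = c(m, n, 4L))
  for (a in seq_len(m)) counts[a, , ] <- as.integer(mats[[a]])
  if (is.null(ref)) ref <- strrep("A", n)
  contig_counts(id, acc, ref, counts)
}

## A questionable_sites object by fiat (bypassing the screen).
make_qset <- function(contig, sites) {
  cov <- homeosplitr:::coverage_matrix(contig)
  structure(list(contig_id = contig$contig_id,
                 sites = as.integer(sites),
                 n_het = rep(NA_integer_, length(sites)),
                 n_genotyped = rep(NA_integer_, length(sites)),
                 mean_coverage = sum(cov) / nchar(contig$ref_seq)),
            class = "questionable_sites")
}

## Brute-force split log-likelihood: plain loops and raw probability
## products (no log-space arithmetic), independent of the package's
## vectorised scorer. Valid for small counts only (no underflow).
bf_split_loglik <- function(contig, qset, ck1, p1_min_cov = 10) {
  qs <- qset$sites
  m <- length(contig$accession_ids)
  ck2 <- integer(length(qs))
  for (j in seq_along(qs)) {
    g <- colSums(matrix(contig$counts[, qs[j], ], m, 4L))
    mf1 <- min(which(g == max(g)))
    g2 <- g; g2[mf1] <- -1
    mf2 <- min(which(g2 == max(g2)))
    ck2[j] <- if (mf1 != ck1[j]) mf1 else mf2
  }
  ## factor-by-factor product with rescaling: clamped proportions make a
  ## whole binomial term (e.g. (1e-6)^55) unrepresentable in doubles, so
  ## the product is rebalanced whenever it drifts too low; every single
  ## factor is >= 1e-6, keeping the accumulator in normal range
  prob <- 1
  scale_log <- 0
  mul <- function(x) {
    prob <<- prob * x
    if (prob < 1e-100) {
      scale_log <<- scale_log + log(prob)
      prob <<- 1
    }
  }
  for (a in seq_len(m)) {
    props <- numeric(0)
    for (j in seq_along(qs)) {
      v <- contig$counts[a, qs[j], ]
      n <- sum(v)
      if (n >= p1_min_cov) props <- c(props, v[ck1[j]] / n)
    }
    if (length(props) == 0) next
    p1 <- min(max(mean(props), 1e-6), 1 - 1e-6)
    p2 <- 1 - p1
    for (j in seq_along(qs)) {
      v <- contig$counts[a, qs[j], ]
      n <- sum(v)
      k1 <- v[ck1[j]]; k2 <- v[ck2[j]]
      mul(choose(n, k1))
      for (i in seq_len(k1)) mul(p1)
      for (i in seq_len(n - k1)) mul(1 - p1)
      mul(choose(n, k2))
      for (i in seq_len(k2)) mul(p2)
      for (i in seq_len(n - k2)) mul(1 - p2)
    }
  }
  scale_log + log(prob)
}

## Random small instance: every site is declared questionable; two
## nucleotides per site with 5..30 reads each, so per-accession coverage
## is always >= 10 and each single binomial factor stays representable
## for the raw-product oracle.
random_small_instance <- function(m = 3, nq = 2, max_count = 30) {
  mats <- lapply(seq_len(m), function(a) {
    mat <- matrix(0L, nq, 4L)
    for (s in seq_len(nq)) {
      nuc <- sample.int(4L, 2L)
      mat[s, nuc] <- sample(5:max_count, 2L, replace = TRUE)
    }
    mat
  })
  contig <- make_contig(mats)
  list(contig = contig, qset = make_qset(contig, seq_len(nq)))
}
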