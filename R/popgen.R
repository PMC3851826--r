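## Genotype calling, per-site Fis and SNP classification.
##
## The genotype caller is a deliberately simple count-threshold rule (an
## accession's alleles at a site are the nucleotides with enough reads),
## NOT a probabilistic genotyper: it stands in for model-based callers
## only so the downstream Fis machinery has genotypes to work on. The Fis
## of a bi-allelic SNP is 1 - Hobs / (2 p (1 - p)). In a selfing panel a
## genuine homologous SNP sits near Fis = 1; a site whose apparent
## polymorphism is fixed divergence between merged homeologs shows every
## accession heterozygous and Fis = -1; mixtures fall in between.

#' Call simple count-threshold genotypes
#'
#' A site is callable for an accession when its coverage exceeds
#' `min_call_coverage` (strictly). Alleles are the nucleotides reaching
#' both `min_allele_count` reads and `min_allele_fraction` of the site's
#' coverage: one passing nucleotide gives a homozygote, two a
#' heterozygote, zero or three or more leave the call missing.
#'
#' @param contig A [contig_counts()].
#' @param sites Sites to call (default all).
#' @param min_call_coverage Coverage that must be exceeded (default 10).
#' @param min_allele_count Minimum reads per allele (default 5).
#' @param min_allele_fraction Minimum fraction of site coverage per
#'   allele (default 0.1).
#' @return Data frame with one row per accession x site: `accession`,
#'   `site`, allele indices `a1 <= a2` (NA when missing) and `status`
#'   (`"called"`/`"missing"`).
#' @export
call_genotypes <- function(contig, sites = NULL, min_call_coverage = 10L,
                           min_allele_count = 5L,
                           min_allele_fraction = 0.1) {
  stopifnot(inherits(contig, "contig_counts"))
  n <- nchar(contig$ref_seq)
  if (is.null(sites)) sites <- seq_len(n)
  m <- length(contig$accession_ids)
  rows <- vector("list", length(sites))
  for (j in seq_along(sites)) {
    s <- sites[j]
    cnt <- matrix(contig$counts[, s, ], m, 4L)
    cov <- rowSums(cnt)
    pass <- cnt >= min_allele_count & cnt >= min_allele_fraction * cov
    npass <- rowSums(pass)
    called <- cov > min_call_coverage & npass >= 1L & npass <= 2L
    a1 <- rep(NA_integer_, m); a2 <- rep(NA_integer_, m)
    for (a in which(called)) {
      al <- which(pass[a, ])
      a1[a] <- al[1]
      a2[a] <- al[length(al)]   # == al[1] for homozygotes
    }
    rows[[j]] <- data.frame(accession = contig$accession_ids,
                            site = s, a1 = a1, a2 = a2,
                            status = ifelse(called, "called", "missing"),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Fis of one bi-allelic site
#'
#' From the called genotypes at one site: `p` is the frequency of the
#' first (smaller-index) allele, `hobs` the heterozygote fraction, and
#' `Fis = 1 - hobs / (2 p (1 - p))`.
#'
#' @param calls Data frame as returned by [call_genotypes()], restricted
#'   to one site; missing calls are dropped.
#' @param contig_id Optional contig id stored in the record.
#' @param homologous_threshold Passed to [classify_snp()].
#' @return One-row data frame (`SnpRecord`): `contig_id`, `site`,
#'   `allele1`, `allele2`, `n_called`, `p`, `hobs`, `fis`,
#'   `class`. `fis` is `NA` when `p` is 0 or 1.
#' @export
fis_per_site <- function(calls, contig_id = NA_character_,
                         homologous_threshold = 0.6) {
  calls <- calls[calls$status == "called", , drop = FALSE]
  if (nrow(calls) == 0L) stop("no called genotypes at this site")
  if (length(unique(calls$site)) != 1L)
    stop("'calls' must cover exactly one site")
  alleles <- sort(unique(c(calls$a1, calls$a2)))
  if (length(alleles) > 2L)
    stop("site is not bi-allelic (", length(alleles), " alleles)")
  n <- nrow(calls)
  het <- calls$a1 != calls$a2
  first <- alleles[1]
  p <- (sum(calls$a1 == first) + sum(calls$a2 == first)) / (2 * n)
  hobs <- mean(het)
  fis <- if (p <= 0 || p >= 1) NA_real_ else 1 - hobs / (2 * p * (1 - p))
  data.frame(contig_id = contig_id,
             site = calls$site[1],
             allele1 = first,
             allele2 = alleles[length(alleles)],
             n_called = n, p = p, hobs = hobs, fis = fis,
             class = classify_snp(fis, homologous_threshold),
             stringsAsFactors = FALSE)
}

#' Classify a SNP by its Fis value
#'
#' `fis > homologous_threshold` (strict) marks a homologous SNP — genuine
#' within-genome polymorphism in a selfing panel; `fis <= -0.5` marks a
#' homeologous SNP — fixed divergence between merged gene copies read as
#' heterozygosity; anything in between is intermediate (e.g. a homologous
#' polymorphism sitting on one copy of a merged pair). The 0.6 bound is
#' the empirical acceptance threshold for homologous SNPs; the -0.5 bound
#' merely bins the lower mode.
#'
#' @param fis Numeric vector of Fis values (NA allowed).
#' @param homologous_threshold Default 0.6.
#' @param homeologous_bound Default -0.5.
#' @return Character vector over `"homologous"`, `"intermediate"`,
#'   `"homeologous"`, `"undefined"`.
#' @export
classify_snp <- function(fis, homologous_threshold = 0.6,
                         homeologous_bound = -0.5) {
  out <- ifelse(is.na(fis), "undefined",
                ifelse(fis > homologous_threshold, "homologous",
                       ifelse(fis <= homeologous_bound, "homeologous",
                              "intermediate")))
  as.character(out)
}

#' Pearson chi-square on a 2x2 table
#'
#' Without continuity correction, df = 1. Used to compare the homologous
#' SNP yield of two splitting strategies.
#'
#' @param a,b First row (e.g. homologous / non-homologous counts of one
#'   method); `c`, `d` the second row.
#' @return List with `chi2`, `df` (always 1) and `p_value`.
#' @export
chi2_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(vapply(cells, is_count_scalar, logical(1))))
  tab <- matrix(cells, nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("both margins of the 2x2 table must be positive")
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ht$statistic), df = 1L, p_value = unname(ht$p.value))
}

#' Fis spectrum of a dataset
#'
#' Calls genotypes on every contig, keeps bi-allelic polymorphic sites,
#' computes each site's Fis and bins the defined values (width 0.1 over
#' \[-1, 1\]).
#'
#' @param dataset An [alr_dataset()].
#' @param min_call_coverage,min_allele_count,min_allele_fraction Passed
#'   to [call_genotypes()].
#' @param homologous_threshold Passed to [classify_snp()].
#' @return An object of class `fis_spectrum`: list with `snps` (one
#'   `SnpRecord` row per bi-allelic SNP) and `histogram` (`bin_lo`,
#'   `bin_hi`, `count`).
#' @export
fis_spectrum <- function(dataset, min_call_coverage = 10L,
                         min_allele_count = 5L, min_allele_fraction = 0.1,
                         homologous_threshold = 0.6) {
  stopifnot(inherits(dataset, "alr_dataset"))
  recs <- list()
  for (cc in dataset$contigs) {
    n <- nchar(cc$ref_seq)
    if (n == 0L) next
    m <- length(cc$accession_ids)
    cov <- coverage_matrix(cc)
    pass <- cc$counts >= min_allele_count &
      cc$counts >= min_allele_fraction * array(cov, dim = dim(cc$counts))
    npass <- pass[, , 1L] + pass[, , 2L] + pass[, , 3L] + pass[, , 4L]
    called <- matrix(cov > min_call_coverage & npass >= 1L & npass <= 2L,
                     m, n)
    ## candidate SNP sites: >= 2 distinct alleles among called accessions
    present <- vapply(1:4, function(nu)
      colSums(matrix(pass[, , nu], m, n) & called) > 0L, logical(n))
    present <- matrix(present, n, 4L)
    cand <- which(rowSums(present) >= 2L & colSums(called) > 0L)
    for (s in cand) {
      if (sum(present[s, ]) != 2L) next   # reject non-bi-allelic
      calls <- call_genotypes(cc, sites = s, min_call_coverage,
                              min_allele_count, min_allele_fraction)
      recs[[length(recs) + 1L]] <-
        fis_per_site(calls, cc$contig_id, homologous_threshold)
    }
  }
  snps <- if (length(recs)) do.call(rbind, recs)
  else data.frame(contig_id = character(0), site = integer(0),
                  allele1 = integer(0), allele2 = integer(0),
                  n_called = integer(0), p = numeric(0),
                  hobs = numeric(0), fis = numeric(0),
                  class = character(0), stringsAsFactors = FALSE)
  breaks <- seq(-1, 1, by = 0.1)
  fis <- snps$fis[!is.na(snps$fis)]
  cnt <- if (length(fis))
    as.integer(table(cut(fis, breaks, include.lowest = TRUE)))
  else integer(length(breaks) - 1L)
  structure(list(snps = snps,
                 histogram = data.frame(bin_lo = breaks[-length(breaks)],
                                        bin_hi = breaks[-1L],
                                        count = cnt)),
            class = "fis_spectrum")
}

#' @export
print.fis_spectrum <- function(x, ...) {
  def <- sum(!is.na(x$snps$fis))
  cat(sprintf("<fis_spectrum> %d bi-allelic SNP(s), %d with defined Fis\n",
              nrow(x$snps), def))
  if (def) {
    tab <- table(factor(x$snps$class,
                        levels = c("homologous", "intermediate",
                                   "homeologous", "undefined")))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
plot.fis_spectrum <- function(x, ...) {
  h <- x$histogram
  barplot(h$count, names.arg = sprintf("%.1f", h$bin_lo), las = 2,
          xlab = "Fis (bin lower edge)", ylab = "SNPs",
          main = "Fis spectrum", ...)
  invisible(x)
}
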