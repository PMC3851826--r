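## Screening for heterozygous sites, questionable sites and questionable
## contigs.
##
## A site is heterozygous for an accession when at least two nucleotides
## are each backed by >= 5 reads; a site is questionable when at least 1/8
## of the accessions genotyped there are heterozygous; a contig is
## questionable when it holds >= 1 questionable site at >= 5X mean
## coverage. All thresholds are tunable.

#' Most and second-most frequent nucleotide of a count vector
#'
#' Nucleotides are indexed A = 1, C = 2, G = 3, T = 4; ties are broken
#' towards the smaller index so results are deterministic.
#'
#' @param count_vector Four non-negative counts in A/C/G/T order.
#' @return Integer vector `c(mf1, mf2)`; `c(NA, NA)` for an all-zero
#'   vector (no nucleotide observed).
#' @examples
#' most_frequent_indices(c(0, 29, 1, 10))  # C then T: c(2, 4)
#' @export
most_frequent_indices <- function(count_vector) {
  stopifnot(length(count_vector) == 4L, all(count_vector >= 0))
  if (all(count_vector == 0)) return(c(NA_integer_, NA_integer_))
  o <- order(-count_vector, seq_len(4L))
  as.integer(o[1:2])
}

#' Is a site heterozygous for one accession?
#'
#' @param count_vector Four counts in A/C/G/T order.
#' @param min_allele_count Minimum reads per nucleotide for it to count as
#'   an observed allele (default 5).
#' @return `TRUE` iff at least two nucleotides each reach
#'   `min_allele_count`.
#' @export
is_heterozygous <- function(count_vector, min_allele_count = 5L) {
  stopifnot(length(count_vector) == 4L)
  sum(count_vector >= min_allele_count) >= 2L
}

#' Find the questionable sites of a contig
#'
#' A site is questionable when the number of accessions heterozygous there
#' is at least `max(1, het_fraction * n_genotyped)`, where an accession is
#' "genotyped" at a site when its coverage reaches
#' `min_genotyped_coverage`. With `denominator = "all"` the fraction is
#' instead taken over all M accessions regardless of coverage.
#'
#' @param contig A [contig_counts()].
#' @param min_allele_count Per-nucleotide read threshold of the
#'   heterozygosity rule (default 5).
#' @param het_fraction Fraction of genotyped accessions that must be
#'   heterozygous (default 1/8).
#' @param min_genotyped_coverage Coverage at which an accession counts as
#'   genotyped at a site (default 10).
#' @param denominator `"genotyped"` (default) or `"all"`.
#' @return An object of class `questionable_sites`: list with `contig_id`,
#'   `sites` (increasing 1-based indices), per-site `n_het` and
#'   `n_genotyped`, and the contig `mean_coverage`.
#' @export
find_questionable_sites <- function(contig, min_allele_count = 5L,
                                    het_fraction = 1 / 8,
                                    min_genotyped_coverage = 10L,
                                    denominator = c("genotyped", "all")) {
  stopifnot(inherits(contig, "contig_counts"))
  denominator <- match.arg(denominator)
  cn <- contig$counts
  m <- dim(cn)[1]
  n <- dim(cn)[2]
  if (n == 0L)
    return(structure(list(contig_id = contig$contig_id,
                          sites = integer(0), n_het = integer(0),
                          n_genotyped = integer(0), mean_coverage = NaN),
                     class = "questionable_sites"))
  cov <- coverage_matrix(contig)                    # M x N
  ge <- cn >= min_allele_count
  n_alleles <- ge[, , 1L] + ge[, , 2L] + ge[, , 3L] + ge[, , 4L]
  het <- matrix(n_alleles >= 2L, m, n)
  gen <- matrix(cov >= min_genotyped_coverage, m, n)
  n_het <- colSums(het)
  n_gen <- colSums(gen)
  denom <- if (denominator == "genotyped") n_gen else rep(m, n)
  q <- n_het >= pmax(1, het_fraction * denom)
  sites <- which(q)
  structure(list(contig_id = contig$contig_id,
                 sites = as.integer(sites),
                 n_het = as.integer(n_het[sites]),
                 n_genotyped = as.integer(n_gen[sites]),
                 mean_coverage = sum(cov) / n),
            class = "questionable_sites")
}

#' @export
print.questionable_sites <- function(x, ...) {
  cat(sprintf(
    "<questionable_sites> %s: %d questionable site(s), mean coverage %.2fX\n",
    x$contig_id, length(x$sites), x$mean_coverage))
  invisible(x)
}

#' Does a contig qualify for splitting?
#'
#' @param qset A `questionable_sites` object from
#'   [find_questionable_sites()].
#' @param min_mean_coverage Mean-coverage floor (default 5).
#' @return `TRUE` iff the contig has at least one questionable site and a
#'   mean coverage of at least `min_mean_coverage`.
#' @export
is_questionable_contig <- function(qset, min_mean_coverage = 5) {
  stopifnot(inherits(qset, "questionable_sites"))
  length(qset$sites) >= 1L &&
    !is.nan(qset$mean_coverage) &&
    qset$mean_coverage >= min_mean_coverage
}

#' Per-site global summaries of a contig
#'
#' @param contig A [contig_counts()].
#' @param sites Sites to summarise (default all).
#' @return Data frame with `site`, global `mf1` and `mf2` nucleotide
#'   indices (NA where nothing is observed) and `coverage`
#'   (total reads over all accessions).
#' @export
site_summaries <- function(contig, sites = NULL) {
  stopifnot(inherits(contig, "contig_counts"))
  g <- global_count_matrix(contig)
  if (is.null(sites)) sites <- seq_len(nrow(g))
  mf <- t(vapply(sites, function(s) most_frequent_indices(g[s, ]),
                 integer(2)))
  data.frame(site = as.integer(sites),
             mf1 = mf[, 1L], mf2 = mf[, 2L],
             coverage = as.integer(rowSums(g[sites, , drop = FALSE])))
}
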