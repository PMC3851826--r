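## Evaluating splits against diploid reference consensus sequences.
##
## The two diploid consensus sequences Uk and Sk aligned to a contig act
## as a gold standard of the disentangled homeologs. diffSym measures how
## much closer (in summed percent similarity) the two split sequences get
## to that standard than the original contig was, allowing for either
## assignment of split to reference. All sequences must be pre-aligned on
## common coordinates (gaps as "-"); any external aligner can produce
## them.

#' Percent similarity of two aligned sequences
#'
#' @param x,y Equal-length aligned sequences (gaps `"-"`).
#' @return List with `sim` (percent identical columns over the non-gap
#'   overlap; `NA` when the overlap is empty) and `overlap` (number of
#'   columns where both are non-gap).
#' @export
pairwise_similarity <- function(x, y) {
  stopifnot(is.character(x), is.character(y),
            length(x) == 1L, length(y) == 1L)
  if (nchar(x) != nchar(y))
    stop("sequences must be pre-aligned to equal length")
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  both <- cx != "-" & cy != "-"
  overlap <- sum(both)
  sim <- if (overlap == 0L) NA_real_
  else 100 * sum(cx[both] == cy[both]) / overlap
  list(sim = sim, overlap = overlap)
}

#' diffSym: similarity gain of a split over the original contig
#'
#' `diffSym = max(sim(ck1,uk) + sim(ck2,sk), sim(ck2,uk) + sim(ck1,sk))
#'  - (sim(ck,uk) + sim(ck,sk))`: positive when the two split sequences
#' are jointly closer to the two diploid references than the unsplit
#' contig, under the better of the two split-to-reference assignments.
#'
#' @param ck Original contig sequence.
#' @param ck1,ck2 The two split sequences.
#' @param uk,sk Diploid reference consensus sequences (first and second
#'   progenitor genome).
#' @param min_overlap Minimum non-gap overlap of `ck` with each reference
#'   (default 100); below it the contig is excluded and `NA` returned.
#' @return The diffSym value, or `NA` when overlap is insufficient.
#' @export
diff_sym <- function(ck, ck1, ck2, uk, sk, min_overlap = 100L) {
  ov_u <- pairwise_similarity(ck, uk)
  ov_s <- pairwise_similarity(ck, sk)
  if (ov_u$overlap < min_overlap || ov_s$overlap < min_overlap)
    return(NA_real_)
  s11 <- pairwise_similarity(ck1, uk)$sim
  s22 <- pairwise_similarity(ck2, sk)$sim
  s21 <- pairwise_similarity(ck2, uk)$sim
  s12 <- pairwise_similarity(ck1, sk)$sim
  max(s11 + s22, s21 + s12) - (ov_u$sim + ov_s$sim)
}

#' Random split flipping a fixed number of sites
#'
#' Baseline control for the `max` bias of [diff_sym()]: starting from the
#' consensus (global-majority) pattern, picks `n_changed` questionable
#' sites uniformly without replacement and flips each to a uniformly
#' chosen different nucleotide observed at that site. Scored with the
#' standard likelihood and complement rule.
#'
#' @inheritParams complement_pattern
#' @param n_changed Number of sites to flip (`<=` number of questionable
#'   sites).
#' @param seed Optional integer; when given, the draw is reproducible and
#'   the caller's RNG stream is untouched.
#' @param p1_min_cov Passed to the likelihood scoring.
#' @return A `homeo_split` object with `method = "random_same_count"`.
#' @export
random_split_same_count <- function(contig, qset, n_changed, seed = NULL,
                                    p1_min_cov = 10L) {
  ctx <- split_context(contig, qset)
  stopifnot(n_changed >= 0L, n_changed <= ctx$nq)
  with_seed(seed, {
    ck1 <- ctx$gmf1
    flip <- if (n_changed > 0L) sample.int(ctx$nq, n_changed) else integer(0)
    choices <- lapply(flip, function(s)
      setdiff(which(ctx$g[s, ] > 0L), ck1[s]))
    if (any(lengths(choices) == 0L))
      stop("a selected site has a single observed nucleotide; cannot flip")
    ck1[flip] <- vapply(choices, function(ch)
      ch[sample.int(length(ch), 1L)], integer(1))
    make_homeo_split(ctx, ck1, score_pattern(ctx, ck1, p1_min_cov),
                     "random_same_count")
  })
}

#' Random split redrawing every questionable site
#'
#' Second baseline: at every questionable site, draws uniformly among the
#' nucleotides observed there (global count > 0).
#'
#' @inheritParams random_split_same_count
#' @return A `homeo_split` object with `method = "random_per_site"`.
#' @export
random_split_per_site <- function(contig, qset, seed = NULL,
                                  p1_min_cov = 10L) {
  ctx <- split_context(contig, qset)
  with_seed(seed, {
    ck1 <- vapply(seq_len(ctx$nq), function(s) {
      obs <- which(ctx$g[s, ] > 0L)
      obs[sample.int(length(obs), 1L)]
    }, integer(1))
    make_homeo_split(ctx, ck1, score_pattern(ctx, ck1, p1_min_cov),
                     "random_per_site")
  })
}
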