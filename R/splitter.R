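## Maximum-likelihood splitting of a questionable contig into two
## homeolog sequences.
##
## A split is defined by a pattern Ck1: one nucleotide per questionable
## site. Its complement Ck2 takes the globally most frequent nucleotide at
## each site unless Ck1 already chose it, in which case the second most
## frequent. Each accession is assumed to express the two homeologs in a
## roughly constant ratio along the contig, so given the per-accession
## proportion p1[a] of Ck1 reads, the counts of the Ck1 and Ck2
## nucleotides at a site are each modelled as Binomial(total coverage,
## p1[a]) and Binomial(total, 1 - p1[a]); the split likelihood is the
## product of both binomial masses over sites and accessions.

## Precomputed questionable-site slices of one contig; every scoring path
## goes through this context so candidates are evaluated identically.
split_context <- function(contig, qset) {
  stopifnot(inherits(contig, "contig_counts"),
            inherits(qset, "questionable_sites"))
  qs <- qset$sites
  nq <- length(qs)
  if (nq == 0L)
    stop("contig '", contig$contig_id, "' has no questionable sites")
  m <- dim(contig$counts)[1]
  counts_q <- contig$counts[, qs, , drop = FALSE]        # M x Nq x 4
  cov <- counts_q[, , 1L] + counts_q[, , 2L] +
    counts_q[, , 3L] + counts_q[, , 4L]
  cov <- matrix(cov, m, nq)
  g <- matrix(0L, nq, 4L)                                # global counts
  for (n in 1:4) g[, n] <- colSums(matrix(counts_q[, , n], m, nq))
  gmf <- t(vapply(seq_len(nq), function(s) most_frequent_indices(g[s, ]),
                  integer(2)))
  list(contig = contig, sites = qs, nq = nq, m = m,
       counts_mat = matrix(counts_q, m, nq * 4L),  # col (n-1)*Nq + s
       cov = cov, g = g, gmf1 = gmf[, 1L], gmf2 = gmf[, 2L])
}

## Counts of one nucleotide-per-site pattern, as an M x Nq matrix.
pattern_counts <- function(ctx, pattern) {
  ctx$counts_mat[, (pattern - 1L) * ctx$nq + seq_len(ctx$nq), drop = FALSE]
}

#' Complement pattern of a split
#'
#' Given the pattern `ck1` chosen for the first homeolog, the second
#' receives at each questionable site the globally most frequent
#' nucleotide — unless `ck1` already took it, in which case the second
#' most frequent.
#'
#' @param contig A [contig_counts()].
#' @param qset Its `questionable_sites`.
#' @param ck1 Integer vector of nucleotide indices (one per questionable
#'   site).
#' @return Integer vector `ck2` with `ck2[s] != ck1[s]` everywhere.
#' @export
complement_pattern <- function(contig, qset, ck1) {
  ctx <- split_context(contig, qset)
  check_pattern(ctx, ck1)
  complement_of(ctx, ck1)
}

check_pattern <- function(ctx, ck1) {
  if (length(ck1) != ctx$nq)
    stop("pattern length ", length(ck1), " != number of questionable sites ",
         ctx$nq)
  if (!all(ck1 %in% 1:4))
    stop("pattern entries must be nucleotide indices 1..4")
  invisible(TRUE)
}

complement_of <- function(ctx, ck1) {
  two <- rowSums(ctx$g > 0) >= 2L
  if (!all(two))
    stop("site ", ctx$sites[which(!two)[1]],
         " has fewer than two observed nucleotides; cannot complement")
  ifelse(ctx$gmf1 != ck1, ctx$gmf1, ctx$gmf2)
}

#' Per-accession proportion of the first homeolog
#'
#' For each accession, the mean over questionable sites with coverage at
#' least `min_site_coverage` of the fraction of reads carrying the `ck1`
#' nucleotide. Accessions with no sufficiently covered site get `NA`.
#'
#' @inheritParams complement_pattern
#' @param min_site_coverage Per-accession coverage a site needs to enter
#'   the average (default 10).
#' @return Numeric vector of length M named by accession, values in
#'   \[0, 1\] or `NA`.
#' @export
estimate_p1 <- function(contig, qset, ck1, min_site_coverage = 10L) {
  ctx <- split_context(contig, qset)
  check_pattern(ctx, ck1)
  p1 <- p1_of(ctx, ck1, min_site_coverage)
  setNames(p1, contig$accession_ids)
}

p1_of <- function(ctx, ck1, min_site_coverage) {
  k1 <- pattern_counts(ctx, ck1)
  valid <- ctx$cov >= min_site_coverage
  prop <- matrix(0, ctx$m, ctx$nq)
  prop[valid] <- k1[valid] / ctx$cov[valid]
  denom <- rowSums(valid)
  out <- rowSums(prop) / denom
  out[denom == 0L] <- NA_real_
  out
}

#' Log-probability of one site's counts under a split
#'
#' The product of two binomial masses: among the `n` reads at the site,
#' the count of the `ck1` nucleotide ~ Binomial(n, p1) and the count of
#' the `ck2` nucleotide ~ Binomial(n, p2). Computed in log space, always
#' finite for p1, p2 in (0, 1).
#'
#' @param count_vector Four counts in A/C/G/T order.
#' @param ck1_nuc,ck2_nuc Distinct nucleotide indices assigned to the two
#'   homeologs at this site.
#' @param p1a,p2a Expression proportions of the two homeologs for this
#'   accession, both strictly inside (0, 1).
#' @return The natural-log probability (0 for an all-zero count vector).
#' @export
site_log_prob <- function(count_vector, ck1_nuc, ck2_nuc, p1a, p2a) {
  stopifnot(length(count_vector) == 4L)
  if (any(count_vector < 0)) stop("negative counts")
  if (ck1_nuc == ck2_nuc) stop("ck1_nuc and ck2_nuc must differ")
  if (p1a <= 0 || p1a >= 1 || p2a <= 0 || p2a >= 1)
    stop("p1a and p2a must lie strictly inside (0, 1)")
  n <- sum(count_vector)
  dbinom(count_vector[ck1_nuc], n, p1a, log = TRUE) +
    dbinom(count_vector[ck2_nuc], n, p2a, log = TRUE)
}

## Vectorised log-likelihood of one pattern over all sites x accessions.
## Returns list(log_likelihood, p1, ck2).
score_pattern <- function(ctx, ck1, p1_min_cov = 10L, clamp_eps = 1e-6) {
  ck2 <- complement_of(ctx, ck1)
  p1 <- p1_of(ctx, ck1, p1_min_cov)
  active <- !is.na(p1)
  ll <- 0
  if (any(active)) {
    p1c <- clamp_prop(p1[active], clamp_eps)
    k1 <- pattern_counts(ctx, ck1)[active, , drop = FALSE]
    k2 <- pattern_counts(ctx, ck2)[active, , drop = FALSE]
    cov <- ctx$cov[active, , drop = FALSE]
    P1 <- matrix(p1c, nrow = sum(active), ncol = ctx$nq)
    ll <- sum(dbinom(k1, cov, P1, log = TRUE) +
                dbinom(k2, cov, 1 - P1, log = TRUE))
  }
  list(log_likelihood = ll, p1 = p1, ck2 = ck2)
}

## Assemble the exported split object.
make_homeo_split <- function(ctx, ck1, scored, method, n_candidates = NA_integer_,
                             ll_gap = NA_real_) {
  chars <- strsplit(ctx$contig$ref_seq, "")[[1]]
  s1 <- chars; s2 <- chars
  s1[ctx$sites] <- NUCS[ck1]
  s2[ctx$sites] <- NUCS[scored$ck2]
  structure(list(contig_id = ctx$contig$contig_id,
                 sites = ctx$sites,
                 ck1 = as.integer(ck1),
                 ck2 = as.integer(scored$ck2),
                 p1 = setNames(scored$p1, ctx$contig$accession_ids),
                 log_likelihood = scored$log_likelihood,
                 seq1 = paste(s1, collapse = ""),
                 seq2 = paste(s2, collapse = ""),
                 method = method,
                 n_candidates = as.integer(n_candidates),
                 ll_gap = ll_gap),
            class = "homeo_split")
}

#' Score one split pattern
#'
#' Estimates the per-accession proportions, derives the complement and
#' sums the two-binomial site log-probabilities over all questionable
#' sites and all accessions with a defined proportion (accessions without
#' one contribute nothing). Assumes independence between sites.
#'
#' @inheritParams complement_pattern
#' @param p1_min_cov Coverage a site needs to enter the proportion
#'   estimate (default 10).
#' @return A `homeo_split` object: the scored pair of patterns, the
#'   per-accession proportions, the total log-likelihood and the two
#'   rebuilt contig sequences.
#' @export
split_log_likelihood <- function(contig, qset, ck1, p1_min_cov = 10L) {
  ctx <- split_context(contig, qset)
  check_pattern(ctx, ck1)
  make_homeo_split(ctx, ck1, score_pattern(ctx, ck1, p1_min_cov), "pattern")
}

#' Heuristic candidate patterns
#'
#' One pattern per accession — its own most frequent nucleotide at each
#' questionable site, falling back to the global majority where it has no
#' coverage — plus the global-majority pattern itself; duplicates removed,
#' so at most M + 1 candidates.
#'
#' @inheritParams complement_pattern
#' @return Integer matrix, one candidate pattern per row.
#' @export
heuristic_candidates <- function(contig, qset) {
  ctx <- split_context(contig, qset)
  heuristic_cand(ctx)
}

heuristic_cand <- function(ctx) {
  pat <- matrix(NA_integer_, ctx$m, ctx$nq)
  for (s in seq_len(ctx$nq)) {
    sub <- matrix(ctx$counts_mat[, (0:3) * ctx$nq + s], ctx$m, 4L)
    mf <- max.col(sub, ties.method = "first")
    mf[ctx$cov[, s] == 0L] <- ctx$gmf1[s]
    pat[, s] <- mf
  }
  unique(rbind(pat, ctx$gmf1))
}

#' Exhaustive candidate patterns
#'
#' The cartesian product of per-site candidate alphabets; a nucleotide is
#' a candidate at a site iff some accession holds at least
#' `min_allele_count` copies of it there.
#'
#' @inheritParams complement_pattern
#' @param min_allele_count Per-accession threshold for a nucleotide to
#'   enter a site's alphabet (default 5).
#' @param max_combinations Cap on the candidate count (default 2^20);
#'   beyond it the search is refused as intractable and the heuristic
#'   should be used.
#' @return Integer matrix, one candidate pattern per row.
#' @export
exhaustive_candidates <- function(contig, qset, min_allele_count = 5L,
                                  max_combinations = 2^20) {
  ctx <- split_context(contig, qset)
  exhaustive_cand(ctx, min_allele_count, max_combinations)
}

site_alphabets <- function(ctx, min_allele_count) {
  lapply(seq_len(ctx$nq), function(s) {
    sub <- matrix(ctx$counts_mat[, (0:3) * ctx$nq + s], ctx$m, 4L)
    which(apply(sub, 2L, max) >= min_allele_count)
  })
}

exhaustive_cand <- function(ctx, min_allele_count, max_combinations) {
  alpha <- site_alphabets(ctx, min_allele_count)
  sizes <- lengths(alpha)
  if (any(sizes == 0L))
    stop("site ", ctx$sites[which(sizes == 0L)[1]],
         " has no nucleotide reaching min_allele_count in any accession")
  if (prod(sizes) > max_combinations)
    stop("exhaustive search not tractable: ", prod(sizes),
         " combinations exceed the cap of ", max_combinations,
         "; use the heuristic search")
  out <- as.matrix(do.call(expand.grid, c(alpha, KEEP.OUT.ATTRS = FALSE)))
  dimnames(out) <- NULL
  out
}

## Pick the best-scoring pattern among candidate rows. Exact likelihood
## ties are broken by preferring the global-majority pattern, then the
## lexicographically smallest pattern.
select_best <- function(ctx, cand, method, p1_min_cov) {
  scored <- vector("list", nrow(cand))
  ll <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    scored[[i]] <- score_pattern(ctx, cand[i, ], p1_min_cov)
    ll[i] <- scored[[i]]$log_likelihood
  }
  best <- max(ll)
  tied <- which(ll == best)
  if (length(tied) > 1L) {
    is_gm <- vapply(tied, function(i) all(cand[i, ] == ctx$gmf1), logical(1))
    if (any(is_gm)) {
      pick <- tied[which(is_gm)[1]]
    } else {
      ord <- do.call(order, as.data.frame(cand[tied, , drop = FALSE]))
      pick <- tied[ord[1]]
    }
  } else pick <- tied
  others <- ll[-pick]
  gap <- if (length(others)) best - max(others) else Inf
  make_homeo_split(ctx, cand[pick, ], scored[[pick]], method,
                   n_candidates = nrow(cand), ll_gap = gap)
}

#' Maximum-likelihood split of a questionable contig
#'
#' Enumerates candidate splits (exhaustively, or via the at-most-(M+1)
#' accession-majority heuristic), scores each with
#' [split_log_likelihood()]'s model and returns the maximum-likelihood
#' one. Mode `"auto"` runs the exhaustive search when its candidate count
#' fits under `max_combinations` and the heuristic otherwise. Exact
#' likelihood ties are resolved towards the global-majority pattern, then
#' the lexicographically smallest pattern.
#'
#' @inheritParams exhaustive_candidates
#' @param mode `"auto"`, `"heuristic"` or `"exhaustive"`.
#' @param p1_min_cov Coverage a site needs to enter the proportion
#'   estimate (default 10).
#' @return A `homeo_split` object; its `ll_gap` element holds the
#'   log-likelihood margin over the best alternative candidate (near-zero
#'   margins flag balanced expression, where the split is poorly
#'   determined).
#' @examples
#' sim <- simulate_contig(length = 60, n_divergent = 3, n_accessions = 8,
#'                        seed = 1)
#' q <- find_questionable_sites(sim$contig)
#' best_split(sim$contig, q)
#' @export
best_split <- function(contig, qset, mode = c("auto", "heuristic",
                                              "exhaustive"),
                       min_allele_count = 5L, p1_min_cov = 10L,
                       max_combinations = 2^20) {
  mode <- match.arg(mode)
  ctx <- split_context(contig, qset)   # errors when no questionable sites
  if (mode == "auto") {
    sizes <- lengths(site_alphabets(ctx, min_allele_count))
    mode <- if (all(sizes > 0L) && prod(sizes) <= max_combinations)
      "exhaustive" else "heuristic"
  }
  cand <- if (mode == "exhaustive")
    exhaustive_cand(ctx, min_allele_count, max_combinations)
  else heuristic_cand(ctx)
  select_best(ctx, cand, mode, p1_min_cov)
}

#' Global-majority split
#'
#' The baseline splitter: the first homeolog takes the globally most
#' frequent nucleotide at every questionable site (i.e. it reproduces the
#' de novo consensus), the second the second most frequent. Scored with
#' the same likelihood as [best_split()] for comparability.
#'
#' @inheritParams complement_pattern
#' @param p1_min_cov Coverage a site needs to enter the proportion
#'   estimate (default 10).
#' @return A `homeo_split` object with `method = "majority"`.
#' @export
majority_split <- function(contig, qset, p1_min_cov = 10L) {
  ctx <- split_context(contig, qset)
  make_homeo_split(ctx, ctx$gmf1, score_pattern(ctx, ctx$gmf1, p1_min_cov),
                   "majority", n_candidates = 1L)
}

#' Screen and split every contig of a dataset
#'
#' Runs the questionable-site screen on each contig; questionable contigs
#' are split with [best_split()] and emitted as two records suffixed
#' `_1` and `_2`, all other contigs pass through unchanged. A per-contig
#' failure is logged in the report and the contig passed through.
#'
#' @param dataset An [alr_dataset()].
#' @param mode Search mode handed to [best_split()].
#' @param min_allele_count,het_fraction,min_genotyped_coverage Screening
#'   thresholds, see [find_questionable_sites()].
#' @param min_mean_coverage Contig-level coverage floor, see
#'   [is_questionable_contig()].
#' @param p1_min_cov,max_combinations Passed to [best_split()].
#' @param sites Optional externally supplied questionable sites: a data
#'   frame with columns `contig_id` and `site` (1-based), bypassing the
#'   screen for the listed contigs.
#' @param near_tie_gap Log-likelihood margin under which a split is
#'   flagged as a near tie (balanced expression; default 0.01).
#' @return List with `records` (data frame `id`, `seq`, ready for
#'   [write_fasta()]) and `report` (one row per contig: `n_questionable`,
#'   `method`, `log_likelihood`, `ll_gap`, `near_tie`, `p1_mean`, `note`).
#' @export
split_all_contigs <- function(dataset, mode = "auto",
                              min_allele_count = 5L, het_fraction = 1 / 8,
                              min_genotyped_coverage = 10L,
                              min_mean_coverage = 5,
                              p1_min_cov = 10L, max_combinations = 2^20,
                              sites = NULL, near_tie_gap = 0.01) {
  stopifnot(inherits(dataset, "alr_dataset"))
  ids <- character(0); seqs <- character(0)
  rep_rows <- vector("list", length(dataset$contigs))
  for (k in seq_along(dataset$contigs)) {
    cc <- dataset$contigs[[k]]
    row <- list(contig_id = cc$contig_id, n_questionable = 0L,
                questionable = FALSE, method = "none",
                log_likelihood = NA_real_, ll_gap = NA_real_,
                near_tie = FALSE, p1_mean = NA_real_, note = "")
    res <- tryCatch({
      if (!is.null(sites) && cc$contig_id %in% sites$contig_id) {
        qs <- sort(unique(as.integer(
          sites$site[sites$contig_id == cc$contig_id])))
        if (any(qs < 1L | qs > nchar(cc$ref_seq)))
          stop("supplied site outside contig ", cc$contig_id)
        cov <- coverage_matrix(cc)
        qset <- structure(list(contig_id = cc$contig_id, sites = qs,
                               n_het = rep(NA_integer_, length(qs)),
                               n_genotyped = rep(NA_integer_, length(qs)),
                               mean_coverage = sum(cov) / nchar(cc$ref_seq)),
                          class = "questionable_sites")
      } else {
        qset <- find_questionable_sites(cc, min_allele_count, het_fraction,
                                        min_genotyped_coverage)
      }
      row$n_questionable <- length(qset$sites)
      if (is_questionable_contig(qset, min_mean_coverage)) {
        row$questionable <- TRUE
        best_split(cc, qset, mode, min_allele_count, p1_min_cov,
                   max_combinations)
      } else NULL
    }, error = function(e) {
      row$note <<- conditionMessage(e)
      NULL
    })
    if (is.null(res)) {
      ids <- c(ids, cc$contig_id); seqs <- c(seqs, cc$ref_seq)
    } else {
      ids <- c(ids, paste0(cc$contig_id, "_1"), paste0(cc$contig_id, "_2"))
      seqs <- c(seqs, res$seq1, res$seq2)
      row$method <- res$method
      row$log_likelihood <- res$log_likelihood
      row$ll_gap <- res$ll_gap
      row$near_tie <- is.finite(res$ll_gap) && res$ll_gap <= near_tie_gap
      row$p1_mean <- mean(res$p1, na.rm = TRUE)
    }
    rep_rows[[k]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  list(records = data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
       report = do.call(rbind, rep_rows))
}
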