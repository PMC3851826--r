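## Seeded simulator of allo-tetraploid RNA-seq nucleotide counts with
## known homeolog truth.
##
## A mixed contig carries two homeolog sequences diverging at a chosen
## set of sites (default 2.5% of the length, the typical divergence of
## the two progenitor genomes). Each accession expresses homeolog A in a
## fixed proportion (its bias, default Beta(6, 2) with a random
## orientation flip, i.e. clearly unbalanced either way). Per site and
## accession, total coverage is Poisson, reads are allocated to the two
## copies binomially by the bias, and each read is misread with a uniform
## error to one of the other three nucleotides. Homologous SNPs (true
## within-copy polymorphism) are planted as alleles fixed within an
## accession — the selfing regime of a near-inbred panel.

## Counts emitted by `k[s]` reads of nucleotide `idx[s]` at each site,
## with per-read error `e` spread uniformly over the other nucleotides.
emit_counts <- function(k, idx, e) {
  n <- length(k)
  err <- rbinom(n, k, e)
  e1 <- rbinom(n, err, 1 / 3)
  e2 <- rbinom(n, err - e1, 1 / 2)
  e3 <- err - e1 - e2
  o1 <- ifelse(idx == 1L, 2L, 1L)
  o2 <- ifelse(idx <= 2L, 3L, 2L)
  o3 <- ifelse(idx == 4L, 3L, 4L)
  mat <- matrix(0L, n, 4L)
  mat[cbind(seq_len(n), idx)] <- k - err
  mat[cbind(seq_len(n), o1)] <- e1
  mat[cbind(seq_len(n), o2)] <- e2
  mat[cbind(seq_len(n), o3)] <- e3
  mat
}

#' Simulate one contig of allo-tetraploid counts
#'
#' @param length Contig length in bp.
#' @param n_divergent Number of sites where the two homeologs differ
#'   (default 2.5% of the length).
#' @param n_accessions Size of the accession panel (default 30).
#' @param coverage_lambda Mean per-accession, per-site coverage of the
#'   pooled pair (Poisson; default 30).
#' @param error_rate Per-read sequencing error probability (default
#'   0.005).
#' @param bias_shape Beta shape parameters of the expression bias
#'   (default `c(6, 2)`, mean 0.75).
#' @param flip_bias Randomly mirror each accession's bias to `1 - bias`
#'   (default `TRUE`), so the favoured copy varies among accessions.
#' @param biases Optional explicit vector of per-accession biases,
#'   overriding the Beta draw.
#' @param n_homologous_snps Number of true within-copy SNPs planted on
#'   non-divergent sites (default ~1 per kb, the order of magnitude of
#'   homologous SNP density observed in inbred wheat transcriptomes).
#' @param hom_freq_range Range of the derived-allele frequency of
#'   homologous SNPs (default 0.1 to 0.9); each accession carries the
#'   derived allele fixed (homozygous) with that probability.
#' @param mixed If `FALSE`, simulate a clean single-copy contig: no
#'   divergent sites, all reads from homeolog A.
#' @param contig_id,accession_ids Identifiers.
#' @param seed Optional integer seed; the caller's RNG stream is
#'   untouched when it is given.
#' @return List with `contig` (a [contig_counts()] whose `ref_seq` is the
#'   global majority consensus, as a de novo assembler would produce) and
#'   `truth` (class `sim_truth`): the two homeolog sequences, the
#'   divergent sites with their nucleotide pairs, the per-accession
#'   biases, the planted homologous SNPs, the per-copy count arrays
#'   `counts_a`/`counts_b` and the full parameter record.
#' @export
simulate_contig <- function(length = 1000L,
                            n_divergent = round(0.025 * length),
                            n_accessions = 30L,
                            coverage_lambda = 30,
                            error_rate = 0.005,
                            bias_shape = c(6, 2),
                            flip_bias = TRUE,
                            biases = NULL,
                            n_homologous_snps = round(0.001 * length),
                            hom_freq_range = c(0.1, 0.9),
                            mixed = TRUE,
                            contig_id = "contig1",
                            accession_ids = sprintf("acc%02d",
                                                    seq_len(n_accessions)),
                            seed = NULL) {
  stopifnot(length >= 1L, n_divergent >= 0L, n_divergent <= length,
            n_accessions >= 1L, coverage_lambda >= 0,
            error_rate >= 0, error_rate < 1,
            n_homologous_snps >= 0L,
            n_homologous_snps + n_divergent <= length,
            length(accession_ids) == n_accessions)
  if (!mixed) n_divergent <- 0L
  m <- n_accessions
  with_seed(seed, {
    ia <- sample.int(4L, length, replace = TRUE)
    ib <- ia
    div <- sort(sample.int(length, n_divergent))
    ib[div] <- vapply(div, function(s)
      sample(setdiff(1:4, ia[s]), 1L), integer(1))
    b <- if (!mixed) rep(1, m)
    else if (!is.null(biases)) {
      stopifnot(length(biases) == m, all(biases >= 0), all(biases <= 1))
      biases
    } else {
      x <- rbeta(m, bias_shape[1], bias_shape[2])
      if (flip_bias) {
        fl <- runif(m) < 0.5
        x[fl] <- 1 - x[fl]
      }
      x
    }
    ## homologous SNPs on non-divergent sites, fixed within accession
    hs <- if (n_homologous_snps > 0L)
      sort(sample(setdiff(seq_len(length), div), n_homologous_snps))
    else integer(0)
    hom <- data.frame(site = hs,
                      copy = if (length(hs))
                        if (mixed) sample(c("a", "b"), length(hs),
                                          replace = TRUE)
                        else rep("a", length(hs))
                      else character(0),
                      derived = integer(length(hs)),
                      freq = if (length(hs))
                        runif(length(hs), hom_freq_range[1],
                              hom_freq_range[2])
                      else numeric(0),
                      stringsAsFactors = FALSE)
    carriers <- matrix(FALSE, m, length(hs))
    for (j in seq_along(hs)) {
      base <- if (hom$copy[j] == "a") ia[hs[j]] else ib[hs[j]]
      hom$derived[j] <- sample(setdiff(1:4, base), 1L)
      carriers[, j] <- runif(m) < hom$freq[j]
    }
    counts_a <- array(0L, dim = c(m, length, 4L))
    counts_b <- array(0L, dim = c(m, length, 4L))
    for (a in seq_len(m)) {
      ia_acc <- ia; ib_acc <- ib
      for (j in seq_along(hs)) {
        if (!carriers[a, j]) next
        if (hom$copy[j] == "a") ia_acc[hs[j]] <- hom$derived[j]
        else ib_acc[hs[j]] <- hom$derived[j]
      }
      ntot <- rpois(length, coverage_lambda)
      ka <- rbinom(length, ntot, b[a])
      counts_a[a, , ] <- emit_counts(ka, ia_acc, error_rate)
      counts_b[a, , ] <- emit_counts(ntot - ka, ib_acc, error_rate)
    }
    counts <- counts_a + counts_b
    ## de novo consensus: global majority, homeolog A where uncovered
    gl <- matrix(0L, length, 4L)
    for (n in 1:4) gl[, n] <- colSums(matrix(counts[, , n], m, length))
    cons <- max.col(gl, ties.method = "first")
    cons[rowSums(gl) == 0L] <- ia[rowSums(gl) == 0L]
    contig <- contig_counts(contig_id, accession_ids,
                            paste(NUCS[cons], collapse = ""), counts)
    truth <- structure(list(
      contig_id = contig_id,
      homeolog_a = paste(NUCS[ia], collapse = ""),
      homeolog_b = paste(NUCS[ib], collapse = ""),
      divergent_sites = data.frame(site = div, nuc_a = ia[div],
                                   nuc_b = ib[div]),
      biases = setNames(b, accession_ids),
      hom_snps = hom,
      carriers = carriers,
      mixed = mixed,
      counts_a = counts_a,
      counts_b = counts_b,
      params = list(length = length, n_divergent = n_divergent,
                    n_accessions = m, coverage_lambda = coverage_lambda,
                    error_rate = error_rate, bias_shape = bias_shape,
                    n_homologous_snps = n_homologous_snps,
                    hom_freq_range = hom_freq_range, seed = seed)),
      class = "sim_truth")
    list(contig = contig, truth = truth)
  })
}

#' Simulate a multi-contig dataset
#'
#' A mixture of mixed-homeolog contigs and clean single-copy contigs over
#' one shared accession panel, deterministic under `seed`.
#'
#' @param n_contigs Number of contigs.
#' @param fraction_mixed Fraction of contigs that merge two homeologs
#'   (default 0.4); `round(fraction_mixed * n_contigs)` contigs, listed
#'   first, are mixed.
#' @inheritParams simulate_contig
#' @param seed Optional integer seed.
#' @return List with `dataset` (an [alr_dataset()]) and `truths` (list of
#'   `sim_truth`, one per contig, in dataset order).
#' @export
simulate_dataset <- function(n_contigs = 50L, fraction_mixed = 0.4,
                             length = 1000L,
                             n_divergent = round(0.025 * length),
                             n_accessions = 30L, coverage_lambda = 30,
                             error_rate = 0.005, bias_shape = c(6, 2),
                             n_homologous_snps = round(0.001 * length),
                             hom_freq_range = c(0.1, 0.9),
                             seed = NULL) {
  stopifnot(n_contigs >= 1L, fraction_mixed >= 0, fraction_mixed <= 1)
  n_mixed <- round(fraction_mixed * n_contigs)
  acc <- sprintf("acc%02d", seq_len(n_accessions))
  with_seed(seed, {
    sims <- lapply(seq_len(n_contigs), function(k)
      simulate_contig(length = length, n_divergent = n_divergent,
                      n_accessions = n_accessions,
                      coverage_lambda = coverage_lambda,
                      error_rate = error_rate, bias_shape = bias_shape,
                      n_homologous_snps = n_homologous_snps,
                      hom_freq_range = hom_freq_range,
                      mixed = k <= n_mixed,
                      contig_id = sprintf("contig%03d", k),
                      accession_ids = acc))
    list(dataset = alr_dataset(lapply(sims, `[[`, "contig")),
         truths = lapply(sims, `[[`, "truth"))
  })
}

#' Compare splits with the simulated truth
#'
#' For each split, the fraction of planted divergent sites whose
#' nucleotide pair `{ck1, ck2}` equals the planted pair (orientation
#' free: either assignment counts), and the mean absolute error of the
#' estimated per-accession proportions against the true biases, taking
#' the better of the two orientations.
#'
#' @param results List of `homeo_split` objects.
#' @param truths List of `sim_truth` objects covering the same contig
#'   ids.
#' @return Data frame with one row per split: `contig_id`,
#'   `n_divergent`, `n_detected` (planted sites among the questionable
#'   set), `site_accuracy`, `bias_mae`, `method`.
#' @export
recovery_report <- function(results, truths) {
  tid <- vapply(truths, `[[`, character(1), "contig_id")
  rows <- lapply(results, function(res) {
    stopifnot(inherits(res, "homeo_split"))
    k <- match(res$contig_id, tid)
    if (is.na(k)) stop("no simulated truth for contig ", res$contig_id)
    tr <- truths[[k]]
    div <- tr$divergent_sites
    hits <- 0L; detected <- 0L
    for (i in seq_len(nrow(div))) {
      j <- match(div$site[i], res$sites)
      if (is.na(j)) next
      detected <- detected + 1L
      pair <- sort(c(res$ck1[j], res$ck2[j]))
      if (identical(pair, sort(c(div$nuc_a[i], div$nuc_b[i]))))
        hits <- hits + 1L
    }
    mae1 <- mean(abs(res$p1 - tr$biases), na.rm = TRUE)
    mae2 <- mean(abs(res$p1 - (1 - tr$biases)), na.rm = TRUE)
    data.frame(contig_id = res$contig_id,
               n_divergent = nrow(div),
               n_detected = detected,
               site_accuracy = if (nrow(div)) hits / nrow(div) else NA_real_,
               bias_mae = min(mae1, mae2),
               method = res$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Idealised re-mapping of simulated reads onto a split
#'
#' Emulates re-mapping the simulated reads onto the two split sequences:
#' each copy's reads (known to the simulator) are routed to the split
#' sequence that matches that copy better at the planted divergent sites;
#' on a tie (a chimeric, uninformative split) every read is assigned to
#' either side with probability 1/2. This is a simulator instrument — it
#' uses the simulation truth, which a real mapper approximates through
#' read-level sequence similarity.
#'
#' @param truth A `sim_truth` for a mixed contig.
#' @param split The `homeo_split` of the same contig.
#' @param seed Optional integer seed (used only for tie randomisation).
#' @return List of two [contig_counts()] named `<id>_1` and `<id>_2`,
#'   with the split sequences as references.
#' @export
remap_to_split <- function(truth, split, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(split, "homeo_split"),
            identical(truth$contig_id, split$contig_id))
  div <- truth$divergent_sites
  s1 <- strsplit(split$seq1, "")[[1]]
  s2 <- strsplit(split$seq2, "")[[1]]
  a_chr <- NUCS[div$nuc_a]; b_chr <- NUCS[div$nuc_b]
  m1 <- sum(s1[div$site] == a_chr) + sum(s2[div$site] == b_chr)
  m2 <- sum(s2[div$site] == a_chr) + sum(s1[div$site] == b_chr)
  with_seed(seed, {
    if (m1 > m2) {
      c1 <- truth$counts_a; c2 <- truth$counts_b
    } else if (m2 > m1) {
      c1 <- truth$counts_b; c2 <- truth$counts_a
    } else {
      ha <- array(rbinom(length(truth$counts_a), truth$counts_a, 0.5),
                  dim = dim(truth$counts_a))
      hb <- array(rbinom(length(truth$counts_b), truth$counts_b, 0.5),
                  dim = dim(truth$counts_b))
      c1 <- ha + hb
      c2 <- (truth$counts_a - ha) + (truth$counts_b - hb)
    }
    acc <- names(truth$biases)
    list(contig_counts(paste0(truth$contig_id, "_1"), acc, split$seq1, c1),
         contig_counts(paste0(truth$contig_id, "_2"), acc, split$seq2, c2))
  })
}

## Minimal SAM text emitter for exercising sam_to_alr: ungapped
## forward-strand reads with uniform base quality. Internal test helper.
write_sim_sam <- function(path, ref_name, ref_len, pos, seqs,
                          mapq = 60L, qual_char = "I") {
  stopifnot(length(pos) == length(seqs))
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste(sprintf("read%04d", i), 0L, ref_name, pos[i],
                            mapq, paste0(nchar(seqs[i]), "M"), "*", 0L, 0L,
                            seqs[i],
                            strrep(qual_char, nchar(seqs[i])),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
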