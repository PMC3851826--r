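test_that("the complement takes the global majority unless already used", {
  ## global counts: site 1 A:20 C:5 G:15 (mf1 A, mf2 G);
  ##                site 2 A:48 G:61 (mf1 G, mf2 A) - near-tie blur case
  mats <- list(rbind(c(15, 5, 0, 0), c(10, 0, 32, 0)),
               rbind(c(5, 0, 15, 0), c(38, 0, 29, 0)))
  cc <- make_contig(mats, ref = "AG")
  q <- make_qset(cc, 1:2)
  ## ck1 avoiding the majorities -> complement is the global majority
  expect_equal(complement_pattern(cc, q, c(2L, 1L)), c(1L, 3L))
  ## ck1 = global majority everywhere -> complement = second most frequent
  expect_equal(complement_pattern(cc, q, c(1L, 3L)), c(3L, 1L))
  ## ck1 = global second -> complement = global majority (first branch)
  expect_equal(complement_pattern(cc, q, c(3L, 1L)), c(1L, 3L))
  ## a monomorphic site cannot be complemented
  mono <- make_contig(list(rbind(c(12, 0, 0, 0))), ref = "A")
  expect_error(complement_pattern(mono, make_qset(mono, 1L), 1L),
               "fewer than two")
})

test_that("p1 reproduces the worked two-site average and the coverage rule", {
  ## accession 1: 5 C of 20 at site 1, 10 A of 42 at site 2 (pattern "CA")
  mats <- list(rbind(c(15, 5, 0, 0), c(10, 0, 32, 0)),
               rbind(c(5, 0, 15, 0), c(38, 0, 29, 0)))
  cc <- make_contig(mats, ref = "AG")
  q <- make_qset(cc, 1:2)
  p1 <- estimate_p1(cc, q, c(2L, 1L))
  expect_equal(unname(p1[1]), mean(c(5 / 20, 10 / 42)))
  expect_equal(unname(p1[1]), 0.244, tolerance = 0.01)
  ## balanced counts give exactly 1/2
  bal <- make_contig(list(rbind(c(25, 25, 0, 0), c(0, 30, 0, 30))),
                     ref = "AC")
  expect_equal(unname(estimate_p1(bal, make_qset(bal, 1:2), c(1L, 2L))),
               0.5)
  ## an accession with every site below 10X has no defined p1
  low <- make_contig(list(rbind(c(5, 4, 0, 0))), ref = "A")
  expect_true(is.na(estimate_p1(low, make_qset(low, 1L), 1L)))
})

test_that("site log-probability matches the closed form and sanity cases", {
  ## [3,3,0,0] at p1 = p2 = 1/2: (C(6,3) 0.5^6)^2 = 0.3125^2
  lp <- site_log_prob(c(3, 3, 0, 0), 1L, 2L, 0.5, 0.5)
  expect_equal(exp(lp), 0.09765625, tolerance = 1e-12)
  expect_equal(lp, 2 * log(choose(6, 3) * 0.5^6), tolerance = 1e-12)
  ## an all-zero site contributes nothing
  expect_equal(site_log_prob(c(0, 0, 0, 0), 1L, 2L, 0.3, 0.7), 0)
  ## errors
  expect_error(site_log_prob(c(-1, 0, 0, 0), 1L, 2L, 0.5, 0.5), "negative")
  expect_error(site_log_prob(c(1, 1, 0, 0), 2L, 2L, 0.5, 0.5), "differ")
  expect_error(site_log_prob(c(1, 1, 0, 0), 1L, 2L, 0, 1), "strictly")
})

test_that("an error-born nucleotide loses to the majority split", {
  ## single accession, single site: 49 A, 50 C, 1 T observed
  cc <- make_contig(list(rbind(c(49, 50, 0, 1))), ref = "C")
  q <- make_qset(cc, 1L)
  ll_T <- split_log_likelihood(cc, q, 4L)$log_likelihood
  ll_A <- split_log_likelihood(cc, q, 1L)$log_likelihood
  ll_C <- split_log_likelihood(cc, q, 2L)$log_likelihood
  expect_lt(ll_T, ll_A)
  expect_lt(ll_T, ll_C)
})

test_that("the split likelihood has the symmetric closed form", {
  cc <- make_contig(list(rbind(c(10, 10, 0, 0))), ref = "A")
  q <- make_qset(cc, 1L)
  res <- split_log_likelihood(cc, q, 1L)
  expect_equal(res$log_likelihood, 2 * log(choose(20, 10) * 0.5^20),
               tolerance = 1e-9)
  expect_equal(res$ck2, 2L)
  expect_equal(unname(res$p1), 0.5)
})

test_that("the vectorised likelihood agrees with the raw-product oracle", {
  set.seed(17)
  for (rep in 1:50) {
    inst <- random_small_instance(m = sample(1:4, 1), nq = sample(1:3, 1))
    nq <- length(inst$qset$sites)
    ck1 <- sample.int(4L, nq, replace = TRUE)
    got <- split_log_likelihood(inst$contig, inst$qset, ck1)$log_likelihood
    want <- bf_split_loglik(inst$contig, inst$qset, ck1)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("heuristic candidates are the accession majorities plus global", {
  ## opposite per-accession majorities; the pooled majority is chimeric
  ## (site 1 follows accession 1, site 2 follows accession 2)
  mats <- list(rbind(c(30, 0, 5, 0), c(5, 0, 20, 0)),
               rbind(c(5, 0, 20, 0), c(30, 0, 6, 0)))
  cc <- make_contig(mats, ref = "AA")
  q <- make_qset(cc, 1:2)
  cand <- heuristic_candidates(cc, q)
  expect_equal(nrow(cand), 3L)   # acc1, acc2 and the global majority
  expect_true(any(apply(cand, 1, identical, c(1L, 3L))))  # acc1: A,G
  expect_true(any(apply(cand, 1, identical, c(3L, 1L))))  # acc2: G,A
  expect_true(any(apply(cand, 1, identical, c(1L, 1L))))  # global: A,A
  ## identical majorities collapse to one candidate
  same <- make_contig(list(rbind(c(20, 5, 0, 0)), rbind(c(30, 6, 0, 0))),
                      ref = "A")
  expect_equal(nrow(heuristic_candidates(same, make_qset(same, 1L))), 1L)
  ## candidate count never exceeds M + 1 on simulated contigs
  set.seed(31)
  for (rep in 1:5) {
    sim <- simulate_contig(length = 60, n_divergent = 5, n_accessions = 7,
                           coverage_lambda = 25)
    qs <- find_questionable_sites(sim$contig)
    if (length(qs$sites) == 0) next
    expect_lte(nrow(heuristic_candidates(sim$contig, qs)), 8L)
  }
})

test_that("exhaustive candidates are the product of per-site alphabets", {
  ## two qualifying nucleotides at each of two sites -> 2 x 2 patterns
  mats <- list(rbind(c(15, 0, 0, 0), c(10, 0, 32, 0)),
               rbind(c(0, 0, 15, 0), c(38, 0, 29, 0)))
  cc <- make_contig(mats, ref = "AG")
  cand <- exhaustive_candidates(cc, make_qset(cc, 1:2))
  expect_equal(nrow(cand), 4L)
  ## one site with three qualifying nucleotides -> 3 patterns
  cc3 <- make_contig(list(rbind(c(15, 5, 5, 0))), ref = "A")
  expect_equal(nrow(exhaustive_candidates(cc3, make_qset(cc3, 1L))), 3L)
  ## alphabets never include a nucleotide absent everywhere
  set.seed(13)
  for (rep in 1:5) {
    inst <- random_small_instance(m = 3, nq = 2)
    cand <- exhaustive_candidates(inst$contig, inst$qset,
                                  min_allele_count = 1)
    g <- t(sapply(inst$qset$sites, function(s)
      colSums(matrix(inst$contig$counts[, s, ], 3, 4))))
    for (s in 1:2)
      expect_true(all(g[s, unique(cand[, s])] > 0))
  }
  ## the combination cap raises an explicit intractability error
  big <- make_contig(list(matrix(10L, 12, 4)), ref = strrep("A", 12))
  expect_error(exhaustive_candidates(big, make_qset(big, 1:12),
                                     max_combinations = 2^10),
               "not tractable")
})

test_that("best_split breaks exact symmetric ties towards the consensus", {
  cc <- make_contig(list(rbind(c(10, 10, 0, 0))), ref = "A")
  q <- make_qset(cc, 1L)
  res <- best_split(cc, q, mode = "exhaustive")
  expect_equal(res$ck1, 1L)       # global majority (A before C on ties)
  expect_equal(res$ck2, 2L)
  expect_equal(res$method, "exhaustive")
  expect_error(best_split(cc, make_qset(cc, integer(0))),
               "no questionable sites")
})

test_that("best_split recovers planted homeolog pairs under strong bias", {
  set.seed(41)
  for (rep in 1:3) {
    sim <- simulate_contig(length = 100, n_divergent = 6, n_accessions = 12,
                           coverage_lambda = 30, error_rate = 0,
                           biases = runif(12, 0.7, 0.95),
                           n_homologous_snps = 0)
    q <- find_questionable_sites(sim$contig)
    res <- best_split(sim$contig, q)
    rec <- recovery_report(list(res), list(sim$truth))
    expect_equal(rec$site_accuracy, 1)
  }
})

test_that("the exhaustive search never scores below the heuristic", {
  set.seed(59)
  for (rep in 1:10) {
    sim <- simulate_contig(length = 50, n_divergent = 4, n_accessions = 8,
                           coverage_lambda = 25, n_homologous_snps = 0)
    q <- find_questionable_sites(sim$contig)
    if (length(q$sites) == 0) next
    ll_ex <- best_split(sim$contig, q, mode = "exhaustive")$log_likelihood
    ll_he <- best_split(sim$contig, q, mode = "heuristic")$log_likelihood
    expect_gte(ll_ex, ll_he - 1e-9)
  }
})

test_that("the majority split reproduces the consensus pattern", {
  sim <- simulate_contig(length = 80, n_divergent = 5, n_accessions = 10,
                         coverage_lambda = 30, seed = 77,
                         n_homologous_snps = 0)
  q <- find_questionable_sites(sim$contig)
  maj <- majority_split(sim$contig, q)
  cons <- strsplit(sim$contig$ref_seq, "")[[1]][q$sites]
  expect_equal(homeosplitr:::NUCS[maj$ck1], cons)
  expect_equal(maj$method, "majority")
  ## with one shared bias direction the ML split agrees with the majority
  uni <- simulate_contig(length = 80, n_divergent = 5, n_accessions = 10,
                         coverage_lambda = 30, error_rate = 0,
                         biases = rep(0.8, 10), n_homologous_snps = 0,
                         seed = 78)
  qu <- find_questionable_sites(uni$contig)
  expect_equal(best_split(uni$contig, qu)$ck1,
               majority_split(uni$contig, qu)$ck1)
})

test_that("split_all_contigs emits two records per questionable contig", {
  sim <- simulate_dataset(n_contigs = 3, fraction_mixed = 1 / 3,
                          length = 60, n_divergent = 4, n_accessions = 8,
                          coverage_lambda = 25, n_homologous_snps = 0,
                          seed = 91)
  out <- split_all_contigs(sim$dataset)
  expect_equal(sum(out$report$questionable), 1L)
  expect_equal(nrow(out$records), 4L)   # one split pair + two pass-through
  expect_setequal(out$records$id,
                  c("contig001_1", "contig001_2", "contig002", "contig003"))
  split_seqs <- out$records$seq[out$records$id == "contig001_1"]
  expect_equal(nchar(split_seqs), 60L)
  ## externally supplied questionable sites are honoured
  out2 <- split_all_contigs(sim$dataset,
                            sites = data.frame(contig_id = "contig002",
                                               site = c(5L, 9L)))
  expect_equal(out2$report$n_questionable[2], 2L)
})

test_that("fitted split objects expose model-style accessors", {
  sim <- simulate_contig(length = 60, n_divergent = 4, n_accessions = 8,
                         coverage_lambda = 30, seed = 8,
                         n_homologous_snps = 0)
  q <- find_questionable_sites(sim$contig)
  res <- best_split(sim$contig, q)
  expect_s3_class(res, "homeo_split")
  expect_named(coef(res), sim$contig$accession_ids)
  expect_equal(as.numeric(logLik(res)), res$log_likelihood)
  expect_output(print(res), "homeo_split")
  expect_output(print(summary(res)), "per-site assignment")
  ## seq1/seq2 differ from the consensus only at questionable sites
  cons <- strsplit(sim$contig$ref_seq, "")[[1]]
  s1 <- strsplit(res$seq1, "")[[1]]
  s2 <- strsplit(res$seq2, "")[[1]]
  expect_true(all(which(s1 != cons) %in% q$sites))
  expect_true(all(which(s2 != cons) %in% q$sites))
  expect_true(all(s1[q$sites] != s2[q$sites]))
})
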