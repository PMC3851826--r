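test_that("ALR parsing recovers the counts written in the file", {
  f <- withr::local_tempfile(fileext = ".alr")
  writeLines(c(">ctg1",
               "#accessions\tacc1,acc2",
               "1\tA\t0/29/1/10\t5/0/0/15",
               "2\tC\t1/2/3/4\t0/0/0/0"), f)
  d <- read_alr(f)
  expect_s3_class(d, "alr_dataset")
  expect_equal(d$accession_ids, c("acc1", "acc2"))
  cc <- d$contigs[["ctg1"]]
  expect_equal(cc$ref_seq, "AC")
  expect_equal(cc$counts[1, 1, ], c(0L, 29L, 1L, 10L))
  expect_equal(cc$counts[2, 1, ], c(5L, 0L, 0L, 15L))
  expect_equal(cc$counts[1, 2, ], c(1L, 2L, 3L, 4L))
})

test_that("a header-only block yields an empty contig", {
  f <- withr::local_tempfile(fileext = ".alr")
  writeLines(c(">empty", "#accessions\ta1"), f)
  d <- read_alr(f)
  expect_equal(nchar(d$contigs[["empty"]]$ref_seq), 0L)
  expect_equal(dim(d$contigs[["empty"]]$counts), c(1L, 0L, 4L))
})

test_that("malformed ALR input raises errors naming the line", {
  write_tmp <- function(lines) {
    f <- tempfile(fileext = ".alr")
    writeLines(lines, f)
    f
  }
  expect_error(read_alr(write_tmp(c("garbage"))), "line 1")
  expect_error(read_alr(write_tmp(c(">c1", "#accessions\ta1,a2",
                                    "1\tA\t0/0/0/0"))),
               "line 3.*fields")
  expect_error(read_alr(write_tmp(c(">c1", "#accessions\ta1",
                                    "1\tA\t0/-1/0/0"))),
               "line 3.*malformed count")
  expect_error(read_alr(write_tmp(c(">c1", "#accessions\ta1", "1\tA\t1/0/0/0",
                                    ">c1", "#accessions\ta1"))),
               "duplicate contig id")
  expect_error(read_alr(write_tmp(c(">c1", "#accessions\ta1",
                                    "2\tA\t1/0/0/0"))),
               "expected position 1")
  expect_error(read_alr(write_tmp(c(">c1", "#accessions\ta1", "1\tA\t1/0/0/0",
                                    ">c2", "#accessions\tb1"))),
               "panel differs")
})

test_that("write_alr / read_alr round-trip a simulated dataset exactly", {
  sim <- simulate_dataset(n_contigs = 4, fraction_mixed = 0.5, length = 40,
                          n_divergent = 3, n_accessions = 5,
                          coverage_lambda = 12, n_homologous_snps = 1,
                          seed = 11)
  f <- withr::local_tempfile(fileext = ".alr")
  write_alr(sim$dataset, f)
  back <- read_alr(f)
  expect_identical(back, sim$dataset)
  ## an empty dataset writes a valid, empty file
  f2 <- withr::local_tempfile(fileext = ".alr")
  write_alr(alr_dataset(list()), f2)
  expect_equal(length(read_alr(f2)$contigs), 0L)
})

test_that("write_fasta wraps at 80 columns and round-trips sequences", {
  f <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(c1_1 = paste(rep("ACGT", 250), collapse = ""),  # 1000 bases
            c1_2 = "ACGT")
  write_fasta(seqs, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, ">")), 2L)
  body1 <- lines[2:(which(lines == ">c1_2") - 1)]
  expect_length(body1, 13L)                      # ceiling(1000 / 80)
  expect_true(all(nchar(body1[-13]) == 80L))
  back <- Biostrings::readDNAStringSet(f)
  expect_equal(as.character(back), seqs)
  expect_error(write_fasta(c(x = "A", x = "C"), f), "duplicate")
  expect_error(write_fasta(c(x = ""), f), "empty")
})

test_that("sam_to_alr pileup-counts a single clean read base by base", {
  ref_fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ctg", "ACGTACGT"), ref_fa)
  sam <- withr::local_tempfile(fileext = ".sam")
  homeosplitr:::write_sim_sam(sam, "ctg", 8L, pos = 1L, seqs = "ACGT")
  d <- sam_to_alr(sam, ref_fa, accession_ids = "s1")
  cc <- d$contigs[["ctg"]]
  expect_equal(cc$counts[1, 1, ], c(1L, 0L, 0L, 0L))
  expect_equal(cc$counts[1, 2, ], c(0L, 1L, 0L, 0L))
  expect_equal(cc$counts[1, 3, ], c(0L, 0L, 1L, 0L))
  expect_equal(cc$counts[1, 4, ], c(0L, 0L, 0L, 1L))
  expect_equal(sum(cc$counts), 4L)
  ## a base-quality threshold above every base removes everything
  expect_warning(d0 <- sam_to_alr(sam, ref_fa, min_base_quality = 41L,
                                  accession_ids = "s1"),
                 "no aligned bases")
  expect_equal(sum(d0$contigs[["ctg"]]$counts), 0L)
})

test_that("sam_to_alr matches direct bookkeeping on many simulated reads", {
  set.seed(5)
  ref <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  ref_fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ctg", ref), ref_fa)
  pos <- sample.int(41L, 10L, replace = TRUE)
  seqs <- vapply(pos, function(p) {
    s <- strsplit(substr(ref, p, p + 19L), "")[[1]]
    i <- sample.int(20L, 2L)                      # two mismatches
    s[i] <- vapply(s[i], function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                    b), 1L), character(1))
    paste(s, collapse = "")
  }, character(1))
  expected <- matrix(0L, 60L, 4L)
  for (i in seq_along(pos)) {
    b <- strsplit(seqs[i], "")[[1]]
    for (j in seq_along(b)) {
      n <- match(b[j], c("A", "C", "G", "T"))
      expected[pos[i] + j - 1L, n] <- expected[pos[i] + j - 1L, n] + 1L
    }
  }
  sam <- withr::local_tempfile(fileext = ".sam")
  homeosplitr:::write_sim_sam(sam, "ctg", 60L, pos = pos, seqs = seqs)
  d <- sam_to_alr(sam, ref_fa, accession_ids = "s1")
  got <- matrix(d$contigs[["ctg"]]$counts[1, , ], ncol = 4L)
  expect_equal(got, expected)
})

test_that("sam_to_alr rejects a reference absent from the FASTA", {
  ref_fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">other", "ACGT"), ref_fa)
  sam <- withr::local_tempfile(fileext = ".sam")
  homeosplitr:::write_sim_sam(sam, "ctg", 8L, pos = 1L, seqs = "ACGT")
  expect_error(sam_to_alr(sam, ref_fa, accession_ids = "s1"),
               "absent from")
})
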