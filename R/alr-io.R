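## ALR input/output and SAM -> count conversion.
##
## ALR dialect (text, UTF-8, tab-separated), one block per contig:
##   >contig_id
##   #accessions<TAB>id1,id2,...,idM          (identical in every block)
##   <pos><TAB><ref base><TAB><A/C/G/T counts acc1><TAB>...<TAB><acc M>
## Positions are 1-based and sequential from 1; a count field is four
## non-negative integers joined by "/" in A/C/G/T order.

alr_stop <- function(line, fmt, ...) {
  stop(sprintf("ALR parse error at line %d: %s", line, sprintf(fmt, ...)),
       call. = FALSE)
}

#' Read a per-accession nucleotide-count (ALR) file
#'
#' Parses the tab-separated ALR dialect documented above into an
#' [alr_dataset()]. The parser is strict: malformed headers, inconsistent
#' field counts, non-sequential positions, negative counts and duplicate
#' contig ids all raise an error naming the offending line.
#'
#' @param path Path to an ALR file.
#' @return An [alr_dataset()].
#' @seealso [write_alr()], [sam_to_alr()]
#' @export
read_alr <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  contigs <- list()
  panel <- NULL
  i <- 1L
  while (i <= length(nonblank)) {
    ln <- nonblank[i]
    hdr <- lines[ln]
    if (!startsWith(hdr, ">"))
      alr_stop(ln, "expected contig header starting with '>', got %s",
               deparse(substr(hdr, 1, 30)))
    contig_id <- trimws(substring(hdr, 2L))
    if (!nzchar(contig_id)) alr_stop(ln, "empty contig id")
    if (contig_id %in% names(contigs))
      alr_stop(ln, "duplicate contig id '%s'", contig_id)
    i <- i + 1L
    if (i > length(nonblank))
      alr_stop(ln, "contig '%s' has no accession line", contig_id)
    ln <- nonblank[i]
    acc_line <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(acc_line) != 2L || acc_line[1] != "#accessions")
      alr_stop(ln, "expected '#accessions<TAB>id1,id2,...'")
    acc <- strsplit(acc_line[2], ",", fixed = TRUE)[[1]]
    if (length(acc) == 0L || any(!nzchar(acc)))
      alr_stop(ln, "empty accession id")
    if (anyDuplicated(acc)) alr_stop(ln, "duplicate accession id")
    if (is.null(panel)) panel <- acc
    else if (!identical(panel, acc))
      alr_stop(ln, "accession panel differs from first block")
    m <- length(acc)
    i <- i + 1L
    ## site lines until next ">" or end of file
    ref <- character(0)
    rows <- list()
    pos_expect <- 1L
    while (i <= length(nonblank) && !startsWith(lines[nonblank[i]], ">")) {
      ln <- nonblank[i]
      fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
      if (length(fields) != 2L + m)
        alr_stop(ln, "expected %d tab-separated fields, got %d",
                 2L + m, length(fields))
      pos <- suppressWarnings(as.integer(fields[1]))
      if (is.na(pos) || pos != pos_expect)
        alr_stop(ln, "expected position %d, got '%s'", pos_expect, fields[1])
      base <- fields[2]
      if (!base %in% c(NUCS, "N"))
        alr_stop(ln, "invalid reference base '%s'", base)
      cnt <- matrix(NA_integer_, m, 4L)
      for (a in seq_len(m)) {
        f <- fields[2L + a]
        if (!grepl("^[0-9]+/[0-9]+/[0-9]+/[0-9]+$", f))
          alr_stop(ln, "malformed count field '%s' (want a/c/g/t)", f)
        cnt[a, ] <- as.integer(strsplit(f, "/", fixed = TRUE)[[1]])
      }
      ref[pos_expect] <- base
      rows[[pos_expect]] <- cnt
      pos_expect <- pos_expect + 1L
      i <- i + 1L
    }
    n <- length(rows)
    counts <- array(0L, dim = c(m, n, 4L))
    for (s in seq_len(n)) counts[, s, ] <- rows[[s]]
    contigs[[contig_id]] <- contig_counts(
      contig_id, panel, paste(ref, collapse = ""), counts)
  }
  alr_dataset(unname(contigs))
}

#' Write an [alr_dataset()] to an ALR file
#'
#' Deterministic inverse of [read_alr()]: contigs and accessions are
#' written in stored order, so `read_alr(write_alr(d))` reproduces `d`
#' field by field.
#'
#' @param dataset An [alr_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alr <- function(dataset, path) {
  stopifnot(inherits(dataset, "alr_dataset"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  acc_line <- paste0("#accessions\t",
                     paste(dataset$accession_ids, collapse = ","))
  for (cc in dataset$contigs) {
    writeLines(paste0(">", cc$contig_id), con)
    writeLines(acc_line, con)
    n <- nchar(cc$ref_seq)
    if (n == 0L) next
    bases <- strsplit(cc$ref_seq, "")[[1]]
    m <- length(cc$accession_ids)
    ## build "a/c/g/t" fields for all cells at once
    flat <- matrix(aperm(cc$counts, c(3L, 1L, 2L)), nrow = 4L)  # 4 x (M*N)
    fields <- matrix(paste(flat[1L, ], flat[2L, ], flat[3L, ], flat[4L, ],
                           sep = "/"), nrow = m)
    body <- vapply(seq_len(n), function(s)
      paste(c(s, bases[s], fields[, s]), collapse = "\t"), character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Convert per-accession SAM/BAM mappings to nucleotide counts
#'
#' Pileup-counts aligned bases by reference position, one SAM/BAM file per
#' accession (accession identity is file identity; read groups are
#' ignored). Bases below `min_base_quality`, reads below
#' `min_mapping_quality`, deletions, Ns and clipped bases contribute
#' nothing; insertions are ignored. Bases opposite a reference N are
#' counted normally.
#'
#' @param sam_paths Character vector of SAM or BAM files, one per
#'   accession.
#' @param ref_fasta FASTA of the contigs the reads were mapped to; every
#'   target named in a SAM header must be present with a matching length.
#' @param min_base_quality,min_mapping_quality Phred thresholds; bases or
#'   reads below them are skipped.
#' @param accession_ids Accession names; defaults to the file base names
#'   without extension.
#' @return An [alr_dataset()] with one contig per FASTA record.
#' @export
sam_to_alr <- function(sam_paths, ref_fasta,
                       min_base_quality = 20L, min_mapping_quality = 10L,
                       accession_ids = NULL) {
  stopifnot(length(sam_paths) >= 1L, file.exists(ref_fasta))
  if (is.null(accession_ids))
    accession_ids <- sub("\\.(sam|bam)$", "", basename(sam_paths),
                         ignore.case = TRUE)
  if (anyDuplicated(accession_ids))
    stop("accession ids derived from file names are not unique; ",
         "pass 'accession_ids'")
  ref <- Biostrings::readDNAStringSet(ref_fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  m <- length(sam_paths)
  lens <- Biostrings::width(ref)
  counts <- lapply(seq_along(ref), function(k)
    array(0L, dim = c(m, lens[k], 4L)))
  names(counts) <- names(ref)
  pparam <- Rsamtools::PileupParam(
    max_depth = 100000L,
    min_base_quality = as.integer(min_base_quality),
    min_mapq = as.integer(min_mapping_quality),
    min_nucleotide_depth = 1L,
    distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE,
    include_deletions = FALSE,
    include_insertions = FALSE)
  for (a in seq_len(m)) {
    path <- sam_paths[a]
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      dest <- tempfile(fileext = "")
      bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                              indexDestination = TRUE)
    } else {
      bam <- path
      if (!file.exists(paste0(bam, ".bai")))
        Rsamtools::indexBam(bam)
    }
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    bad <- setdiff(names(hdr), names(ref))
    if (length(bad))
      stop(sprintf("SAM reference '%s' in %s is absent from %s",
                   bad[1], basename(path), basename(ref_fasta)))
    mism <- names(hdr)[hdr != lens[match(names(hdr), names(ref))]]
    if (length(mism))
      stop(sprintf("length of reference '%s' differs between %s and %s",
                   mism[1], basename(path), basename(ref_fasta)))
    pu <- Rsamtools::pileup(bam, pileupParam = pparam)
    if (nrow(pu) == 0L) {
      warning(sprintf("no aligned bases pass filters in %s; ",
                      basename(path)), "counts are all zero")
      next
    }
    pu <- pu[pu$nucleotide %in% NUCS, , drop = FALSE]
    nuc <- match(as.character(pu$nucleotide), NUCS)
    ctg <- as.character(pu$seqnames)
    for (id in unique(ctg)) {
      sel <- ctg == id
      counts[[id]][cbind(a, pu$pos[sel], nuc[sel])] <-
        counts[[id]][cbind(a, pu$pos[sel], nuc[sel])] + pu$count[sel]
    }
  }
  contigs <- lapply(names(ref), function(id)
    contig_counts(id, accession_ids, as.character(ref[[id]]), counts[[id]]))
  alr_dataset(contigs)
}

#' Write sequences as 80-column wrapped FASTA
#'
#' @param seqs Named character vector of nucleotide sequences; names are
#'   the record ids and must be unique, sequences must be non-empty.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must be named")
  if (anyDuplicated(ids)) stop("duplicate record id: ",
                               ids[duplicated(ids)][1])
  if (any(nchar(seqs) == 0L)) stop("empty sequence for id ",
                                   ids[nchar(seqs) == 0L][1])
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}
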