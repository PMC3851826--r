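## Small internal helpers shared across modules.

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Clamp proportions away from {0, 1} so binomial log-masses stay finite.
clamp_prop <- function(p, eps = 1e-6) {
  pmin(pmax(p, eps), 1 - eps)
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}

#' Per-contig nucleotide count matrix
#'
#' Bundles the M x N x 4 array of nucleotide counts observed for one contig
#' (M accessions, N reference sites, nucleotides indexed A = 1, C = 2,
#' G = 3, T = 4) together with the contig id, the accession panel and the
#' contig consensus sequence. Site indices are 1-based both in files and in
#' memory.
#'
#' @param contig_id Single contig identifier.
#' @param accession_ids Character vector of M unique accession identifiers.
#' @param ref_seq Consensus/reference sequence of the contig, an uppercase
#'   string over A/C/G/T/N of length N.
#' @param counts Integer array of dimension `c(M, N, 4)`; `counts[a, s, n]`
#'   is the number of reads of accession `a` showing nucleotide `n` at
#'   site `s`.
#' @return An object of class `contig_counts`.
#' @examples
#' cc <- contig_counts("c1", c("acc1", "acc2"), "AC",
#'                     array(0L, dim = c(2, 2, 4)))
#' cc
#' @export
contig_counts <- function(contig_id, accession_ids, ref_seq, counts) {
  stopifnot(is.character(contig_id), length(contig_id) == 1L,
            is.character(accession_ids), length(accession_ids) >= 1L,
            is.character(ref_seq), length(ref_seq) == 1L)
  if (anyDuplicated(accession_ids))
    stop("accession ids must be unique")
  m <- length(accession_ids)
  n <- nchar(ref_seq)
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("'counts' must be an M x N x 4 array")
  if (!all(dim(counts) == c(m, n, 4L)))
    stop(sprintf("'counts' has dimension %s; expected %d x %d x 4",
                 paste(dim(counts), collapse = " x "), m, n))
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (n > 0 && !grepl("^[ACGTN]*$", ref_seq))
    stop("ref_seq must contain only A, C, G, T or N")
  storage.mode(counts) <- "integer"
  structure(list(contig_id = contig_id,
                 accession_ids = accession_ids,
                 ref_seq = ref_seq,
                 counts = counts),
            class = "contig_counts")
}

#' @export
print.contig_counts <- function(x, ...) {
  cat(sprintf("<contig_counts> %s: %d sites, %d accessions, total depth %d\n",
              x$contig_id, nchar(x$ref_seq), length(x$accession_ids),
              sum(x$counts)))
  invisible(x)
}

#' Multi-contig count dataset
#'
#' An ordered collection of [contig_counts()] objects sharing one accession
#' panel — the in-memory form of an ALR file.
#'
#' @param contigs List of `contig_counts` objects with identical
#'   `accession_ids` in identical order.
#' @return An object of class `alr_dataset` with elements `contigs` (named
#'   list) and `accession_ids`.
#' @export
alr_dataset <- function(contigs) {
  stopifnot(is.list(contigs))
  if (length(contigs) == 0L)
    return(structure(list(contigs = list(), accession_ids = character(0)),
                     class = "alr_dataset"))
  ok <- vapply(contigs, inherits, logical(1), "contig_counts")
  if (!all(ok)) stop("all elements must be contig_counts objects")
  ids <- vapply(contigs, `[[`, character(1), "contig_id")
  if (anyDuplicated(ids)) stop("duplicate contig id: ",
                               ids[duplicated(ids)][1])
  acc <- contigs[[1]]$accession_ids
  same <- vapply(contigs, function(cc) identical(cc$accession_ids, acc),
                 logical(1))
  if (!all(same)) stop("all contigs must share one accession panel")
  names(contigs) <- ids
  structure(list(contigs = contigs, accession_ids = acc),
            class = "alr_dataset")
}

#' @export
print.alr_dataset <- function(x, ...) {
  cat(sprintf("<alr_dataset> %d contigs, %d accessions\n",
              length(x$contigs), length(x$accession_ids)))
  invisible(x)
}

## Per-accession coverage matrix (M x N) of a contig.
coverage_matrix <- function(contig) {
  cn <- contig$counts
  cn[, , 1L] + cn[, , 2L] + cn[, , 3L] + cn[, , 4L]
}

## Global (summed over accessions) N x 4 count matrix.
global_count_matrix <- function(contig) {
  cn <- contig$counts
  if (dim(cn)[1] == 1L) {
    matrix(cn[1L, , ], ncol = 4L)
  } else {
    apply(cn, c(2L, 3L), sum)
  }
}
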