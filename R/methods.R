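## S3 methods for the fitted split object.

#' @export
print.homeo_split <- function(x, ...) {
  cat(sprintf("<homeo_split> %s (%s search)\n", x$contig_id, x$method))
  cat(sprintf("  %d questionable site(s), log-likelihood %.3f",
              length(x$sites), x$log_likelihood))
  if (is.finite(x$ll_gap))
    cat(sprintf(" (margin %.3f over next candidate)", x$ll_gap))
  cat("\n")
  p1 <- x$p1[!is.na(x$p1)]
  if (length(p1))
    cat(sprintf("  p1 over %d accession(s): min %.3f / median %.3f / max %.3f\n",
                length(p1), min(p1), stats::median(p1), max(p1)))
  cat(sprintf("  pattern   %s\n", paste(NUCS[x$ck1], collapse = "")))
  cat(sprintf("  complement %s\n", paste(NUCS[x$ck2], collapse = "")))
  invisible(x)
}

#' @export
summary.homeo_split <- function(object, ...) {
  out <- list(split = object,
              sites = data.frame(site = object$sites,
                                 ck1 = NUCS[object$ck1],
                                 ck2 = NUCS[object$ck2]),
              p1 = object$p1,
              n_missing_p1 = sum(is.na(object$p1)))
  class(out) <- "summary.homeo_split"
  out
}

#' @export
print.summary.homeo_split <- function(x, ...) {
  print(x$split)
  cat("  per-site assignment:\n")
  print(x$sites, row.names = FALSE)
  if (x$n_missing_p1 > 0)
    cat(sprintf("  %d accession(s) without a defined p1 (no site at >=10X)\n",
                x$n_missing_p1))
  invisible(x)
}

#' @export
coef.homeo_split <- function(object, ...) object$p1

#' @export
logLik.homeo_split <- function(object, ...) {
  structure(object$log_likelihood,
            df = sum(!is.na(object$p1)),
            nobs = sum(!is.na(object$p1)) * length(object$sites),
            class = "logLik")
}
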