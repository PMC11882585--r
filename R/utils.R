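#' @importFrom rlang abort warn inform .data
#' @importFrom dplyr %>%
NULL

# Internal: stop with a consistent validation error class.
md_abort <- function(msg, class = "methdmc_error") {
  rlang::abort(msg, class = c(class, "methdmc_error"))
}

# Internal: check a numeric vector lies in [lo, hi].
check_range <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    md_abort(sprintf(
      "%s must be in [%g, %g]; %d value(s) outside (first offending: %g)",
      what, lo, hi, sum(bad), x[bad][1]
    ), class = "methdmc_validation_error")
  }
  invisible(x)
}

# Internal: warn when two inputs do not share the same chromosome names.
warn_unshared_chroms <- function(a, b, label_a = "first input", label_b = "second input") {
  ca <- unique(a)
  cb <- unique(b)
  only_a <- setdiff(ca, cb)
  only_b <- setdiff(cb, ca)
  if (length(only_a) || length(only_b)) {
    rlang::warn(sprintf(
      "chromosomes not shared between %s and %s: %s",
      label_a, label_b,
      paste(c(only_a, only_b), collapse = ", ")
    ), class = "methdmc_chrom_mismatch")
  }
  invisible(NULL)
}

# Internal: canonical site key "chrom:pos" used for set operations.
site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
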