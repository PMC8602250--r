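#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; cohort percentages here follow the
#' conventional half-up rule (26.67 -> 27, 23.33 -> 23).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Canonical variant key
#'
#' @param contig,pos,ref,alt vectors describing normalized biallelic variants.
#' @return character key `contig:pos:ref:alt`.
#' @export
variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

# internal: stop unless condition, with sprintf-style message
.check <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
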