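# Shared small helpers: rounding conventions and key handling.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; the reporting conventions here
#' (overlap percentages, purity percent) round half away from zero.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by a relative epsilon so values that are exact halves after decimal
  # arithmetic (e.g. 200 * 0.455) are not pulled down by representation error
  z <- abs(x) * m
  out <- trunc(z + 0.5 + sqrt(.Machine$double.eps) * z) / m
  out * sign(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical chromosome universe and ordering (1..22, X, Y).
#' @keywords internal
chrom_levels <- function() c(as.character(1:22), "X", "Y")

#' Normalize chromosome labels
#'
#' Strips a leading "chr" prefix and upper-cases X/Y. Labels outside the
#' canonical 1-22, X, Y universe are returned as-is (callers drop them).
#'
#' @param chrom character vector of chromosome labels.
#' @return normalized character vector.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  toupper(chrom)
}

# Compact string identity for a variant, used for all set arithmetic.
#' @keywords internal
variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

# Order of rows under the canonical (chrom, pos, ref, alt) total ordering.
#' @keywords internal
variant_order <- function(df) {
  order(factor(df$chrom, levels = chrom_levels()), df$pos, df$ref, df$alt,
        method = "radix")
}
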