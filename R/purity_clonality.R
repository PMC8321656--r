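# Tumor purity from a truncal driver's allelic fraction, pairwise clonality
# comparison of driver AFs, and assay detection limits.

#' Estimate tumor purity from a driver allelic fraction
#'
#' Under a diploid, copy-neutral model a heterozygous truncal driver is
#' carried by every tumor cell on one of two alleles, so purity = 2 x AF.
#' The percent is rounded half away from zero and clamped to [0, 100] (an AF
#' above 0.5 is flagged `capped`). When `depth` is supplied, a 95% Wilson
#' interval on the AF is propagated through the same x200 map.
#'
#' @param af allelic fraction in [0, 1].
#' @param depth optional total read depth at the driver site.
#' @param sample_id,gene optional labels carried into the result.
#' @return an object of class `purity_estimate`.
#' @export
estimate_purity <- function(af, depth = NULL, sample_id = NA_character_,
                            gene = NA_character_) {
  if (!is.numeric(af) || length(af) != 1 || is.na(af) || af < 0 || af > 1) {
    stop("af must be a single allelic fraction in [0, 1]")
  }
  pct <- min(max(round_half_away(200 * af), 0), 100)
  ci <- c(NA_real_, NA_real_)
  if (!is.null(depth) && !is.na(depth)) {
    stopifnot(depth > 0)
    w <- wilson_interval(af, depth)
    ci <- pmin(pmax(200 * w, 0), 100)
  }
  structure(list(sample_id = sample_id, gene = gene, af = af,
                 purity_percent = as.integer(pct), capped = af > 0.5,
                 ci_low = ci[1], ci_high = ci[2]),
            class = "purity_estimate")
}

# 95% Wilson score interval for a proportion.
#' @keywords internal
wilson_interval <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(center - half, center + half)
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat("purity ", x$purity_percent, "% (AF ", x$af, sep = "")
  if (!is.na(x$ci_low)) {
    cat(", 95% CI ", round(x$ci_low), "-", round(x$ci_high), "%", sep = "")
  }
  cat(")")
  if (x$capped) cat(" [capped: AF > 0.5]")
  cat("\n")
  invisible(x)
}

#' Compare a subclonal driver's AF against the truncal driver's
#'
#' The ratio AF_subclonal / AF_truncal approximates the fraction of tumor
#' cells carrying the subclonal mutation. Interpretation: `absent` when the
#' subclonal AF is zero; `near_clonal` when the ratio is at least
#' `near_clonal_min`; `minor_subclone` when it is positive but at most
#' `minor_max`; `intermediate` otherwise.
#'
#' @param af_sub,af_truncal allelic fractions in [0, 1].
#' @param near_clonal_min,minor_max interpretation bounds on the ratio.
#' @return list with `ratio` (NA with `undefined = TRUE` when the truncal AF
#'   is zero) and `interpretation`.
#' @export
clonal_ratio <- function(af_sub, af_truncal, near_clonal_min = 0.85,
                         minor_max = 0.5) {
  stopifnot(af_sub >= 0, af_sub <= 1, af_truncal >= 0, af_truncal <= 1)
  if (af_truncal == 0) {
    return(list(ratio = NA_real_, undefined = TRUE,
                interpretation = if (af_sub == 0) "absent" else "undefined"))
  }
  ratio <- af_sub / af_truncal
  interpretation <- if (af_sub == 0) {
    "absent"
  } else if (ratio >= near_clonal_min) {
    "near_clonal"
  } else if (ratio <= minor_max) {
    "minor_subclone"
  } else {
    "intermediate"
  }
  list(ratio = ratio, undefined = FALSE, interpretation = interpretation)
}

#' Assay detectability of an allelic fraction
#'
#' Locked nucleic acid (LNA) PCR enrichment detects variant alleles down to
#' about 1% allelic fraction; conventional exome sequencing calls are
#' reliable only above roughly 5%.
#'
#' @param af allelic fraction in [0, 1].
#' @param limit LNA-PCR detection limit.
#' @param wes_limit whole-exome sequencing detection limit.
#' @return list with logical flags `detectable_by_lna` and
#'   `detectable_by_wes`.
#' @export
detectable <- function(af, limit = 0.01, wes_limit = 0.05) {
  stopifnot(af >= 0, af <= 1)
  list(detectable_by_lna = af >= limit, detectable_by_wes = af >= wes_limit)
}
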