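# MLPA copy-number analysis: within-sample reference-probe normalization,
# cross-sample probe ratios, and loss/gain calls at the 0.7 / 1.3 borders.

#' Normalize MLPA probe peaks against reference samples
#'
#' Each sample's peaks are first divided by the mean of that sample's
#' designated reference-probe peaks (intra-normalization, making ratios
#' invariant to overall signal scale). The probe ratio is then the
#' intra-normalized test-sample value divided by the mean intra-normalized
#' value across reference samples. With two or more reference samples, a 95%
#' t-interval on the reference mean is propagated to the ratio.
#'
#' @param sample_peaks data.frame with columns `probe_id`, `chrom`, `pos`,
#'   `gene`, `peak_height` for the test sample.
#' @param reference_samples list of one or more data.frames of the same
#'   shape, from copy-number-normal reference individuals.
#' @param reference_probe_ids probe ids of the intra-normalization reference
#'   probes (control probes outside any test region); defaults to probes
#'   whose `gene` is `"REF"`.
#' @param loss_border,gain_border ratio borders for calling loss and gain.
#' @return data.frame of class `probe_ratios`: `probe_id`, `chrom`, `pos`,
#'   `gene`, `ratio`, `ci_low`, `ci_high`, `call`.
#' @export
normalize_probes <- function(sample_peaks, reference_samples,
                             reference_probe_ids = NULL,
                             loss_border = 0.7, gain_border = 1.3) {
  if (!is.list(reference_samples) || is.data.frame(reference_samples)) {
    reference_samples <- list(reference_samples)
  }
  if (length(reference_samples) < 1) stop("need at least one reference sample")
  if (is.null(reference_probe_ids)) {
    reference_probe_ids <- sample_peaks$probe_id[sample_peaks$gene == "REF"]
  }
  if (length(reference_probe_ids) == 0) {
    stop("no reference probes designated for intra-normalization")
  }
  intra <- function(tab) {
    m <- mean(tab$peak_height[tab$probe_id %in% reference_probe_ids])
    if (!is.finite(m) || m <= 0) stop("zero or invalid reference-probe mean")
    stats::setNames(tab$peak_height / m, tab$probe_id)
  }
  s <- intra(sample_peaks)
  refs <- lapply(reference_samples, intra)
  probe_ids <- sample_peaks$probe_id
  present <- vapply(probe_ids, function(p) {
    all(vapply(refs, function(r) p %in% names(r), logical(1)))
  }, logical(1))
  if (any(!present)) {
    warning(sum(!present), " probe(s) missing from a reference sample; dropped")
    probe_ids <- probe_ids[present]
  }
  ref_mat <- vapply(refs, function(r) r[probe_ids], numeric(length(probe_ids)))
  ref_mat <- matrix(ref_mat, nrow = length(probe_ids))
  ref_mean <- rowMeans(ref_mat)
  if (any(ref_mean <= 0)) stop("zero mean reference value for a probe")
  ratio <- s[probe_ids] / ref_mean
  n_ref <- ncol(ref_mat)
  if (n_ref >= 2) {
    se <- apply(ref_mat, 1, stats::sd) / sqrt(n_ref)
    tq <- stats::qt(0.975, df = n_ref - 1)
    lo_den <- ref_mean + tq * se
    hi_den <- pmax(ref_mean - tq * se, .Machine$double.eps)
    ci_low <- s[probe_ids] / lo_den
    ci_high <- s[probe_ids] / hi_den
  } else {
    ci_low <- ci_high <- rep(NA_real_, length(probe_ids))
  }
  idx <- match(probe_ids, sample_peaks$probe_id)
  out <- data.frame(probe_id = probe_ids,
                    chrom = sample_peaks$chrom[idx],
                    pos = sample_peaks$pos[idx],
                    gene = sample_peaks$gene[idx],
                    ratio = unname(ratio),
                    ci_low = unname(ci_low), ci_high = unname(ci_high),
                    stringsAsFactors = FALSE)
  out$call <- call_probe(out$ratio, loss_border, gain_border)
  class(out) <- c("probe_ratios", class(out))
  rownames(out) <- NULL
  out
}

#' Call a probe from its copy-number ratio
#'
#' Strict borders: a ratio below `loss_border` is a loss, above `gain_border`
#' a gain; a ratio exactly at a border is normal.
#'
#' @param ratio non-negative probe ratio(s).
#' @param loss_border,gain_border ratio borders.
#' @return character vector of calls in `loss`, `normal`, `gain`.
#' @export
call_probe <- function(ratio, loss_border = 0.7, gain_border = 1.3) {
  if (any(ratio < 0, na.rm = TRUE)) stop("probe ratios must be non-negative")
  ifelse(ratio < loss_border, "loss",
         ifelse(ratio > gain_border, "gain", "normal"))
}

#' Call a genomic region from its probe calls
#'
#' Majority rule over the in-region probes: the region takes the call made by
#' at least half of them; an exact half-half tie between an abnormal call and
#' `normal` resolves toward the abnormal call. If no call reaches half, the
#' region is `mixed`.
#'
#' @param probes `probe_ratios` data.frame from [normalize_probes()].
#' @param region list with `chrom`, `start`, `end` (1-based inclusive);
#'   defaults to the chr9 CDKN2A/CDKN2B deletion span
#'   9:21,948,801-22,163,300.
#' @return an object of class `region_call` with the verdict, agreeing
#'   fraction, and per-probe calls.
#' @export
call_region <- function(probes, region = cdkn2ab_region()) {
  in_region <- probes$chrom == normalize_chrom(region$chrom) &
    probes$pos >= region$start & probes$pos <= region$end
  if (!any(in_region)) stop("no probes fall inside the region")
  calls <- probes$call[in_region]
  frac <- table(factor(calls, levels = c("loss", "normal", "gain"))) /
    length(calls)
  best <- max(frac)
  verdict <- if (best < 0.5) {
    "mixed"
  } else {
    winners <- names(frac)[frac == best]
    if (length(winners) > 1) {
      # tie: prefer the abnormal call
      abnormal <- setdiff(winners, "normal")
      if (length(abnormal)) abnormal[1] else "normal"
    } else {
      winners
    }
  }
  structure(list(region = region, verdict = verdict,
                 fraction_agreeing = as.numeric(best),
                 n_probes = length(calls),
                 probe_calls = probes[in_region, , drop = FALSE]),
            class = "region_call")
}

#' Default CDKN2A/CDKN2B deletion region
#'
#' The focal homozygous deletion span on chromosome 9 covering CDKN2A and
#' CDKN2B (9:21,948,801-22,163,300, GRCh37).
#'
#' @return list with `chrom`, `start`, `end`, `genes`.
#' @export
cdkn2ab_region <- function() {
  list(chrom = "9", start = 21948801L, end = 22163300L,
       genes = c("CDKN2A", "CDKN2B"))
}

#' @export
print.region_call <- function(x, ...) {
  cat("region ", x$region$chrom, ":", x$region$start, "-", x$region$end,
      ": ", x$verdict, " (", round(100 * x$fraction_agreeing), "% of ",
      x$n_probes, " probes)\n", sep = "")
  invisible(x)
}
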