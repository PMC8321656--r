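# Transmission inference: overlap with the donor tumor, sex-chromosome
# discordance, cross-tumor intersection, tri-classification of shared coding
# variants, and the final verdict.

#' Overlap of a putative somatic profile with the donor tumor
#'
#' Counts, by identity key, how many variants of a post-subtraction putative
#' somatic profile (and of its common-polymorphism complement) are also seen
#' in the donor tumor. The full-profile percentage is reported to one
#' decimal, the common-subset percentage to the nearest integer (half away
#' from zero in both cases).
#'
#' @param profile putative somatic `sample_profile`.
#' @param donor_tumor donor tumor `sample_profile`.
#' @param removed_common optional `sample_profile` of the common variants
#'   removed from `profile` by [filter_common()].
#' @return an object of class `overlap_stats`.
#' @export
overlap_with_donor <- function(profile, donor_tumor, removed_common = NULL) {
  donor_keys <- profile_keys(donor_tumor)
  n <- n_variants(profile)
  shared <- sum(profile_keys(profile) %in% donor_keys)
  out <- list(
    profile_size = n,
    shared_with_donor = shared,
    percent_shared = if (n > 0) round_half_away(100 * shared / n, 1) else 0,
    common_subset_size = NA_integer_,
    common_shared = NA_integer_,
    percent_common_shared = NA_real_)
  if (!is.null(removed_common)) {
    m <- n_variants(removed_common)
    cs <- sum(profile_keys(removed_common) %in% donor_keys)
    out$common_subset_size <- m
    out$common_shared <- cs
    out$percent_common_shared <- if (m > 0) round_half_away(100 * cs / m) else 0
  }
  structure(out, class = "overlap_stats")
}

#' Count sex-discordant (chromosome Y) variants
#'
#' When the recipient is female and the donor male, any chrY variant in the
#' recipient tumor's putative somatic profile is donor-origin DNA.
#'
#' @param profile putative somatic `sample_profile`.
#' @param recipient_sex,donor_sex `"male"`, `"female"` or `"unknown"`.
#' @return list with `applicable` (logical), `count` (chrY variants; NA when
#'   not applicable) and `donor_dna_flag` (TRUE when applicable and count > 0).
#' @export
count_sex_discordant <- function(profile, recipient_sex, donor_sex) {
  applicable <- identical(recipient_sex, "female") && identical(donor_sex, "male")
  if (!applicable) {
    return(list(applicable = FALSE, count = NA_integer_,
                donor_dna_flag = FALSE))
  }
  count <- sum(profile$variants$chrom == "Y")
  list(applicable = TRUE, count = count, donor_dna_flag = count > 0)
}

#' Intersect variant profiles
#'
#' Variants (by identity key) present in every profile. With
#' `coding_only = TRUE` the intersection is restricted to the six coding
#' functional classes.
#'
#' @param profiles list of at least two `sample_profile` objects.
#' @param coding_only restrict to coding classes?
#' @return data.frame of the shared variants, with columns taken from the
#'   first profile.
#' @export
intersect_profiles <- function(profiles, coding_only = FALSE) {
  if (length(profiles) < 2) stop("need at least two profiles to intersect")
  keys <- lapply(profiles, profile_keys)
  shared <- Reduce(intersect, keys)
  v <- profiles[[1]]$variants
  v <- v[variant_key(v) %in% shared, , drop = FALSE]
  if (coding_only) {
    v <- v[!is.na(v$functional_class) &
             v$functional_class %in% coding_classes(), , drop = FALSE]
  }
  rownames(v) <- NULL
  v
}

#' Tri-classification thresholds for shared coding variants
#'
#' @param exac_somatic_max ExAC frequency at or below which a variant is
#'   probably somatic.
#' @param exac_germline_min,exac_germline_max ExAC band marking probable rare
#'   donor germline variants.
#' @param donor_af_low,donor_af_high donor-tumor allelic-fraction band marking
#'   probable heterozygous donor germline variants.
#' @return an object of class `shared_class_thresholds`.
#' @export
shared_class_thresholds <- function(exac_somatic_max = 0.000094,
                                    exac_germline_min = 0.0001,
                                    exac_germline_max = 0.0009,
                                    donor_af_low = 0.49,
                                    donor_af_high = 0.51) {
  stopifnot(exac_somatic_max < exac_germline_min,
            exac_germline_min <= exac_germline_max,
            donor_af_low < donor_af_high)
  structure(list(exac_somatic_max = exac_somatic_max,
                 exac_germline_min = exac_germline_min,
                 exac_germline_max = exac_germline_max,
                 donor_af_low = donor_af_low,
                 donor_af_high = donor_af_high),
            class = "shared_class_thresholds")
}

#' Classify shared coding variants into somatic and donor-germline tiers
#'
#' Each shared variant receives exactly one label, by precedence:
#' 1. ExAC frequency absent or <= `exac_somatic_max` -> `probably_somatic`;
#' 2. ExAC frequency within the germline band -> `rare_donor_germline_exac`;
#' 3. donor-tumor allelic fraction within the heterozygous band ->
#'    `donor_het_germline_af`;
#' 4. otherwise `unclassified`. A missing donor AF reached at rule 3 yields
#'    `unclassified` with a warning.
#'
#' @param shared data.frame of shared variants carrying columns `af_ExAC`
#'   (NA = absent from ExAC) and `donor_af` (observed allelic fraction in the
#'   donor tumor), e.g. from [intersect_profiles()] plus a donor-AF join.
#' @param thresholds a [shared_class_thresholds()].
#' @return list with `labels` (character vector, one per row of `shared`) and
#'   `counts` (named integer vector over the four labels).
#' @export
classify_shared_coding <- function(shared,
                                   thresholds = shared_class_thresholds()) {
  stopifnot(is.data.frame(shared))
  th <- thresholds
  exac <- shared$af_ExAC
  donor_af <- shared$donor_af
  if (is.null(donor_af)) donor_af <- rep(NA_real_, nrow(shared))
  n <- nrow(shared)
  labels <- rep("unclassified", n)
  r1 <- is.na(exac) | exac <= th$exac_somatic_max
  r2 <- !r1 & !is.na(exac) & exac >= th$exac_germline_min &
    exac <= th$exac_germline_max
  r3 <- !r1 & !r2 & !is.na(donor_af) & donor_af >= th$donor_af_low &
    donor_af <= th$donor_af_high
  r3_missing <- !r1 & !r2 & is.na(donor_af)
  if (any(r3_missing)) {
    warning(sum(r3_missing),
            " shared variant(s) lack a donor allelic fraction; unclassified")
  }
  labels[r1] <- "probably_somatic"
  labels[r2] <- "rare_donor_germline_exac"
  labels[r3] <- "donor_het_germline_af"
  lev <- c("probably_somatic", "rare_donor_germline_exac",
           "donor_het_germline_af", "unclassified")
  counts <- stats::setNames(as.integer(table(factor(labels, levels = lev))), lev)
  list(labels = labels, counts = counts)
}

#' Transmission decision thresholds
#'
#' @param overlap_threshold percent overlap with the donor tumor at or above
#'   which transmission is called.
#' @param clean_threshold percent overlap at or below which, with no other
#'   evidence, the profile is considered clean (not transmitted).
#' @param chry_threshold minimum sex-discordant chrY count calling
#'   transmission.
#' @param driver_threshold minimum number of shared probably-somatic driver
#'   genes calling transmission.
#' @param driver_genes driver gene symbols consulted by the shared-driver rule.
#' @return an object of class `transmission_thresholds`.
#' @export
transmission_thresholds <- function(overlap_threshold = 80.0,
                                    clean_threshold = 5.0,
                                    chry_threshold = 5L,
                                    driver_threshold = 2L,
                                    driver_genes = c("BRAF", "PIK3CA", "SDHC",
                                                     "DDR2", "FANCD2")) {
  structure(list(overlap_threshold = overlap_threshold,
                 clean_threshold = clean_threshold,
                 chry_threshold = as.integer(chry_threshold),
                 driver_threshold = as.integer(driver_threshold),
                 driver_genes = driver_genes),
            class = "transmission_thresholds")
}

#' Decide whether a recipient lesion is donor-derived
#'
#' Verdict `transmitted` if any of: the putative somatic profile shares at
#' least `overlap_threshold` percent of its variants with the donor tumor;
#' the sex-discordant chrY count reaches `chry_threshold`; or at least
#' `driver_threshold` probably-somatic driver genes are shared across all
#' lesions. Verdict `not_transmitted` if the profile is clean — at most
#' `clean_threshold` percent overlap with the donor tumor — and no rule
#' fired. Otherwise `indeterminate`. Cleanliness is judged on the
#' common-filtered profile (`evidence$overlap_clean`) when available:
#' germline subtraction alone leaves a residue of common polymorphisms
#' (capture differences between tumor and blood), which the filter removes.
#'
#' @param evidence list with elements `overlap` (an `overlap_stats`),
#'   optional `overlap_clean` (overlap of the common-filtered retained
#'   profile with the donor tumor), `sex_discordant` (from
#'   [count_sex_discordant()]), and `shared_drivers` (character vector of
#'   probably-somatic driver genes shared across all lesions).
#' @param thresholds a [transmission_thresholds()].
#' @return an object of class `transmission_decision` with the verdict, the
#'   rules that fired, and the evidence.
#' @export
decide_transmission <- function(evidence,
                                thresholds = transmission_thresholds()) {
  th <- thresholds
  pct <- evidence$overlap$percent_shared %||% NA_real_
  chry <- evidence$sex_discordant$count %||% NA_integer_
  drivers <- intersect(evidence$shared_drivers %||% character(0),
                       th$driver_genes)
  fired <- character(0)
  if (!is.na(pct) && pct >= th$overlap_threshold) {
    fired <- c(fired, "overlap_with_donor")
  }
  if (isTRUE(evidence$sex_discordant$applicable) && !is.na(chry) &&
      chry >= th$chry_threshold) {
    fired <- c(fired, "sex_discordant_chrY")
  }
  if (length(drivers) >= th$driver_threshold) {
    fired <- c(fired, "shared_somatic_drivers")
  }
  clean_pct <- evidence$overlap_clean$percent_shared %||% pct
  verdict <- if (length(fired) > 0) {
    "transmitted"
  } else if (!is.na(clean_pct) && clean_pct <= th$clean_threshold &&
             !isTRUE(evidence$sex_discordant$donor_dna_flag)) {
    "not_transmitted"
  } else {
    "indeterminate"
  }
  structure(list(verdict = verdict, rules_fired = fired,
                 shared_drivers = drivers, evidence = evidence,
                 thresholds = th),
            class = "transmission_decision")
}

#' @export
print.transmission_decision <- function(x, ...) {
  cat("transmission verdict:", x$verdict, "\n")
  if (length(x$rules_fired)) {
    cat("  rules fired:", paste(x$rules_fired, collapse = ", "), "\n")
  }
  ov <- x$evidence$overlap
  if (!is.null(ov)) {
    cat("  overlap with donor tumor: ", ov$shared_with_donor, "/",
        ov$profile_size, " (", ov$percent_shared, "%)\n", sep = "")
  }
  sd <- x$evidence$sex_discordant
  if (isTRUE(sd$applicable)) cat("  sex-discordant chrY variants:", sd$count, "\n")
  if (length(x$shared_drivers)) {
    cat("  shared drivers:", paste(x$shared_drivers, collapse = ", "), "\n")
  }
  invisible(x)
}
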