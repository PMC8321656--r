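# Cohort-level reporting: classification tables per sample, shared/unique
# coding-variant buckets across lesions, the purity table, MLPA region
# calls, and the per-lesion transmission decision, orchestrated end-to-end.

#' Shared/unique coding-variant table across tumor profiles
#'
#' For every coding variant in the union of the supplied profiles, computes
#' its presence pattern across profiles and tallies per functional class
#' into buckets: shared by all, shared by each proper subset (of size >= 2),
#' and unique to each profile. Bucket totals partition the coding union.
#'
#' @param profiles named list of at least two `sample_profile` objects
#'   (enriched somatic profiles).
#' @param coding_only restrict to the six coding classes (default TRUE).
#' @return list with `table` (long data.frame: `pattern`, `n_profiles`,
#'   `functional_class`, `count`), `union_size`, and `bucket_totals`.
#' @export
build_shared_unique_table <- function(profiles, coding_only = TRUE) {
  if (length(profiles) < 2) stop("need at least two profiles")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    names(profiles) <- vapply(profiles, function(p) p$sample_id, character(1))
  }
  vs <- lapply(profiles, function(p) {
    v <- p$variants
    if (coding_only) {
      v <- v[!is.na(v$functional_class) &
               v$functional_class %in% coding_classes(), , drop = FALSE]
    }
    v
  })
  all_keys <- unique(unlist(lapply(vs, variant_key), use.names = FALSE))
  presence <- vapply(vs, function(v) all_keys %in% variant_key(v),
                     logical(length(all_keys)))
  presence <- matrix(presence, nrow = length(all_keys),
                     dimnames = list(NULL, names(profiles)))
  pattern <- apply(presence, 1, function(row)
    paste(names(profiles)[row], collapse = "&"))
  # class of each union variant, from the first profile that carries it
  fc <- rep(NA_character_, length(all_keys))
  for (v in vs) {
    idx <- match(variant_key(v), all_keys)
    fill <- is.na(fc[idx])
    fc[idx[fill]] <- v$functional_class[fill]
  }
  tab <- as.data.frame(table(pattern = pattern,
                             functional_class = factor(
                               fc, levels = coding_classes())),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab <- tab[tab$count > 0, , drop = FALSE]
  tab$n_profiles <- lengths(strsplit(tab$pattern, "&", fixed = TRUE))
  tab <- tab[order(-tab$n_profiles, tab$pattern), c("pattern", "n_profiles",
                                                    "functional_class",
                                                    "count")]
  rownames(tab) <- NULL
  bucket_totals <- tapply(tab$count, tab$pattern, sum)
  list(table = tab, union_size = length(all_keys),
       bucket_totals = bucket_totals)
}

#' Run the full lineage-inference pipeline on a cohort
#'
#' Executes, in order: germline subtraction (when a matched blood sample
#' exists for the recipient), common-polymorphism filtering, overlap with
#' the donor tumor, sex-discordance counting, cross-lesion intersection and
#' tri-classification of shared coding variants, driver-based purity
#' estimation, MLPA region calling, and the transmission decision per
#' lesion.
#'
#' For lesions with a matched germline, the overlap rule is evaluated on the
#' post-subtraction putative somatic profile (which, for a donor-derived
#' tumor, still contains the donor germline). For lesions without one, it
#' is evaluated on the common-filtered retained profile, since the raw
#' profile of any human tumor shares most common polymorphisms with any
#' other human sample.
#'
#' @param cohort a `cohort` from [simulate_cohort()] or the list returned by
#'   [read_cohort()].
#' @param policy a [filter_policy()].
#' @param thresholds a [transmission_thresholds()].
#' @param class_thresholds a [shared_class_thresholds()].
#' @param truncal_gene gene whose AF anchors the purity estimate.
#' @param out_dir optional directory; when given, the report JSON and
#'   per-stage TSV intermediates are persisted there.
#' @return an object of class `cohort_report`.
#' @export
run_pipeline <- function(cohort, policy = filter_policy(),
                         thresholds = transmission_thresholds(),
                         class_thresholds = shared_class_thresholds(),
                         truncal_gene = "BRAF", out_dir = NULL) {
  samples <- cohort$samples
  roles <- vapply(samples, function(p) p$role, character(1))
  donor_id <- names(roles)[roles == "donor_tumor"]
  if (length(donor_id) != 1) stop("cohort needs exactly one donor tumor")
  donor_tumor <- samples[[donor_id]]
  donor_sex <- cohort$truth$donor_sex %||% donor_tumor$sex
  lesion_ids <- names(roles)[roles %in% c("recipient_tumor",
                                          "recipient_metastasis")]
  if (length(lesion_ids) < 1) stop("cohort needs at least one recipient lesion")
  blood_ids <- names(roles)[roles == "recipient_blood"]

  # recipient of each sample, from the config when present, else by prefix
  recipient_of <- function(sid) {
    cfg <- cohort$config$samples
    if (!is.null(cfg)) return(cfg$recipient[match(sid, cfg$sample_id)])
    sub("_.*$", "", sid)
  }

  per_sample <- list()
  retained_profiles <- list()
  stage_counts <- list()

  # donor tumor gets the same enrichment for cross-lesion comparison
  donor_filtered <- filter_common(donor_tumor, policy)
  retained_profiles[[donor_id]] <- donor_filtered$retained
  per_sample[[donor_id]] <- list(
    sample_id = donor_id, role = "donor_tumor",
    class_counts = tryCatch(as.list(unclass(classify_counts(donor_tumor))),
                            error = function(e) NULL),
    n_total = n_variants(donor_tumor),
    n_common = n_variants(donor_filtered$removed),
    n_retained = n_variants(donor_filtered$retained))

  for (sid in lesion_ids) {
    lesion <- samples[[sid]]
    rec <- recipient_of(sid)
    blood <- NULL
    for (b in blood_ids) {
      if (identical(recipient_of(b), rec)) blood <- samples[[b]]
    }
    if (!is.null(blood)) {
      putative <- subtract_germline(lesion, blood)
      basis <- "post_subtraction"
    } else {
      putative <- lesion
      basis <- "post_filter"
    }
    parts <- filter_common(putative, policy)
    retained_profiles[[sid]] <- parts$retained
    overlap_clean <- overlap_with_donor(parts$retained, donor_tumor)
    overlap <- if (basis == "post_subtraction") {
      overlap_with_donor(putative, donor_tumor, parts$removed)
    } else {
      overlap_clean
    }
    sexd <- count_sex_discordant(putative, lesion$sex, donor_sex)
    per_sample[[sid]] <- list(
      sample_id = sid, role = lesion$role, recipient = rec,
      germline_available = !is.null(blood), overlap_basis = basis,
      n_total = n_variants(lesion),
      n_after_subtraction = n_variants(putative),
      n_common = n_variants(parts$removed),
      n_retained = n_variants(parts$retained),
      class_counts = tryCatch(as.list(unclass(classify_counts(parts$retained))),
                              error = function(e) NULL),
      overlap = unclass(overlap), overlap_clean = unclass(overlap_clean),
      sex_discordant = sexd)
  }

  # shared coding variants across donor + all lesions, with donor tumor AF
  shared <- intersect_profiles(unname(retained_profiles), coding_only = TRUE)
  donor_af <- donor_tumor$variants$af[match(variant_key(shared),
                                            profile_keys(donor_tumor))]
  shared$donor_af <- donor_af
  shared_classes <- classify_shared_coding(shared, class_thresholds)
  somatic_shared <- shared[shared_classes$labels == "probably_somatic", ,
                           drop = FALSE]
  shared_drivers <- intersect(thresholds$driver_genes,
                              somatic_shared$gene[!is.na(somatic_shared$gene)])

  shared_unique <- if (length(retained_profiles) >= 2) {
    build_shared_unique_table(retained_profiles, coding_only = TRUE)
  } else {
    NULL
  }

  # purity per tumor sample from the truncal driver's AF
  purity <- list()
  for (sid in c(donor_id, lesion_ids)) {
    v <- samples[[sid]]$variants
    hit <- which(!is.na(v$gene) & v$gene == truncal_gene)
    purity[[sid]] <- if (length(hit) == 1) {
      unclass(estimate_purity(v$af[hit], depth = v$depth[hit],
                              sample_id = sid, gene = truncal_gene))
    } else {
      list(sample_id = sid, gene = truncal_gene, af = NA_real_,
           purity_percent = NA_integer_, capped = FALSE,
           ci_low = NA_real_, ci_high = NA_real_)
    }
  }

  # MLPA region calls, when probe tables are present
  mlpa_calls <- list()
  if (!is.null(cohort$mlpa)) {
    for (sid in names(cohort$mlpa)) {
      tab <- cohort$mlpa[[sid]]
      if (!is.null(tab$ratio)) {
        pr <- tab
        pr$call <- call_probe(pr$ratio)
        rc <- tryCatch(call_region(pr), error = function(e) NULL)
        if (!is.null(rc)) {
          mlpa_calls[[sid]] <- list(verdict = rc$verdict,
                                    fraction_agreeing = rc$fraction_agreeing,
                                    n_probes = rc$n_probes)
        }
      }
    }
  }

  decisions <- list()
  for (sid in lesion_ids) {
    ev <- list(overlap = per_sample[[sid]]$overlap,
               overlap_clean = per_sample[[sid]]$overlap_clean,
               sex_discordant = per_sample[[sid]]$sex_discordant,
               shared_drivers = shared_drivers)
    decisions[[sid]] <- decide_transmission(ev, thresholds)
  }

  report <- structure(list(
    per_sample = per_sample,
    shared_coding = list(n_shared = nrow(shared),
                         class_counts = as.list(shared_classes$counts),
                         shared_drivers = shared_drivers),
    shared_unique = shared_unique,
    purity = purity,
    mlpa = mlpa_calls,
    decisions = decisions,
    provenance = list(seed = cohort$truth$seed %||% NA,
                      policy = unclass(policy),
                      thresholds = unclass(thresholds))),
    class = "cohort_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sid in names(retained_profiles)) {
      write_profile(retained_profiles[[sid]],
                    file.path(out_dir, paste0(sid, "_retained.tsv")), "tsv")
    }
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  report
}

# plain-list view of a report for JSON serialization
#' @keywords internal
report_to_list <- function(report) {
  out <- unclass(report)
  out$decisions <- lapply(out$decisions, function(d) {
    list(verdict = d$verdict, rules_fired = d$rules_fired,
         shared_drivers = d$shared_drivers)
  })
  if (!is.null(out$shared_unique)) {
    out$shared_unique <- list(union_size = out$shared_unique$union_size,
                              table = out$shared_unique$table)
  }
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort report\n")
  for (sid in names(x$decisions)) {
    d <- x$decisions[[sid]]
    ov <- x$per_sample[[sid]]$overlap
    cat("  ", sid, ": ", d$verdict, sep = "")
    if (!is.null(ov) && !is.na(ov$percent_shared)) {
      cat(" (", ov$percent_shared, "% overlap with donor tumor", sep = "")
      sdv <- x$per_sample[[sid]]$sex_discordant
      if (isTRUE(sdv$applicable)) cat(", ", sdv$count, " chrY", sep = "")
      cat(")")
    }
    cat("\n")
  }
  sc <- x$shared_coding
  cat("  shared coding variants across all tumors: ", sc$n_shared,
      " (probably somatic: ", sc$class_counts$probably_somatic, ")\n",
      sep = "")
  if (length(sc$shared_drivers)) {
    cat("  shared drivers:", paste(sc$shared_drivers, collapse = ", "), "\n")
  }
  invisible(x)
}
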