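# Putative somatic profile construction: tumor minus germline, then removal
# of common population polymorphisms, with classification bookkeeping.

#' Common-polymorphism filter policy
#'
#' A variant is treated as a common population polymorphism when its allele
#' frequency is present and at least `af_threshold` in at least
#' `min_databases` of the consulted databases ("greater or equal to 0.001 in
#' more than one database" under the defaults). A frequency absent from a
#' database does not meet the threshold in that database.
#'
#' @param af_threshold allele-frequency threshold, in (0, 1].
#' @param min_databases minimum number of databases meeting the threshold.
#' @param databases database names consulted.
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(af_threshold = 0.001, min_databases = 2L,
                          databases = population_databases()) {
  stopifnot(af_threshold > 0, af_threshold <= 1, min_databases >= 1)
  structure(list(af_threshold = af_threshold,
                 min_databases = as.integer(min_databases),
                 databases = databases),
            class = "filter_policy")
}

#' Subtract a germline variant set from a tumor profile
#'
#' Removes from the tumor every variant whose identity key
#' (chrom, pos, ref, alt) appears in the germline profile. Depths and
#' allelic fractions of the surviving variants are those observed in the
#' tumor. Germline zygosity is ignored: subtraction is pure key membership.
#'
#' @param tumor,germline `sample_profile` objects.
#' @return a `sample_profile` holding the putative somatic variants; the
#'   number of subtracted variants is attached as attribute `n_subtracted`.
#' @export
subtract_germline <- function(tumor, germline) {
  stopifnot(inherits(tumor, "sample_profile"),
            inherits(germline, "sample_profile"))
  in_germline <- profile_keys(tumor) %in% profile_keys(germline)
  out <- profile_replace_variants(tumor, tumor$variants[!in_germline, ,
                                                        drop = FALSE])
  attr(out, "n_subtracted") <- sum(in_germline)
  out
}

#' Partition a profile into common polymorphisms and retained variants
#'
#' Applies a [filter_policy()]: a variant is removed iff its frequency is
#' present and >= the threshold in at least `min_databases` consulted
#' databases. The removed set is returned alongside the retained set because
#' downstream overlap analysis needs both.
#'
#' @param profile a `sample_profile`.
#' @param policy a [filter_policy()].
#' @return list with `sample_profile` elements `retained` and `removed`
#'   (disjoint; their union is the input).
#' @export
filter_common <- function(profile, policy = filter_policy()) {
  stopifnot(inherits(profile, "sample_profile"),
            inherits(policy, "filter_policy"))
  v <- profile$variants
  n_hits <- integer(nrow(v))
  for (db in policy$databases) {
    col <- db_column(db)
    if (is.null(v[[col]])) {
      warning("database '", db, "' absent from profile; ignored")
      next
    }
    f <- v[[col]]
    n_hits <- n_hits + (!is.na(f) & f >= policy$af_threshold)
  }
  common <- n_hits >= policy$min_databases
  list(retained = profile_replace_variants(profile, v[!common, , drop = FALSE]),
       removed = profile_replace_variants(profile, v[common, , drop = FALSE]))
}

#' Tally variants per functional class
#'
#' @param profile a `sample_profile` whose variants all carry a valid
#'   functional class.
#' @return an object of class `class_count_table`: named integer vector over
#'   the seven classes plus a `total` attribute equal to the profile size.
#' @export
classify_counts <- function(profile) {
  stopifnot(inherits(profile, "sample_profile"))
  fc <- profile$variants$functional_class
  if (anyNA(fc)) {
    stop("profile '", profile$sample_id, "' has ", sum(is.na(fc)),
         " variant(s) without a functional class")
  }
  counts <- table(factor(fc, levels = functional_classes()))
  out <- stats::setNames(as.integer(counts), functional_classes())
  structure(out, total = sum(out), class = "class_count_table")
}

#' @export
print.class_count_table <- function(x, ...) {
  df <- data.frame(class = names(unclass(x)), count = as.integer(x))
  print(df, row.names = FALSE)
  cat("total:", attr(x, "total"), "\n")
  invisible(x)
}
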