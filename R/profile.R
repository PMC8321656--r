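# Sample profiles: the central container. A profile is a named sample
# (role, sex) holding a set of observed variants unique by
# (chrom, pos, ref, alt) and iterated in canonical order.

#' Functional class vocabulary
#'
#' The seven mutually exclusive functional classes used for variant
#' classification counting. The first six are coding classes.
#'
#' @return character vector of the seven class labels.
#' @export
functional_classes <- function() {
  c("utr_or_unspecified_exonic", "indel", "nonsynonymous", "nonsense",
    "synonymous", "splice_site", "non_exonic_or_ncRNA")
}

#' Coding functional classes
#'
#' @return character vector of the six coding class labels.
#' @export
coding_classes <- function() setdiff(functional_classes(), "non_exonic_or_ncRNA")

#' Reference population databases
#'
#' @return character vector of the database names carried as per-variant
#'   allele-frequency annotations.
#' @export
population_databases <- function() c("1000G", "HapMap", "dbSNP", "ExAC", "gnomAD")

# Column name used to store the frequency for database `db`.
#' @keywords internal
db_column <- function(db) paste0("af_", db)

#' Sample roles
#' @keywords internal
sample_roles <- function() {
  c("donor_tumor", "recipient_blood", "recipient_tumor", "recipient_metastasis")
}

#' Construct a sample profile
#'
#' Builds a validated profile from a variant table. Chromosome labels are
#' normalized (leading "chr" stripped), alleles upper-cased, records on
#' non-canonical contigs (MT, decoys, ...) dropped with a count, and rows
#' sorted into the canonical (chrom, pos, ref, alt) order. Duplicate keys
#' are an error.
#'
#' @param variants data.frame with at least `chrom`, `pos`, `ref`, `alt`;
#'   optional `functional_class`, `gene`, `depth`, `alt_depth`, `af`, and
#'   per-database frequency columns `af_1000G`, `af_HapMap`, `af_dbSNP`,
#'   `af_ExAC`, `af_gnomAD` (NA means "not observed in that database").
#' @param sample_id sample name.
#' @param role one of `donor_tumor`, `recipient_blood`, `recipient_tumor`,
#'   `recipient_metastasis`.
#' @param sex one of `male`, `female`, `unknown`.
#' @return an object of class `sample_profile`.
#' @export
sample_profile <- function(variants, sample_id, role = "recipient_tumor",
                           sex = "unknown") {
  stopifnot(is.data.frame(variants))
  role <- match.arg(role, sample_roles())
  sex <- match.arg(sex, c("male", "female", "unknown"))
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss)) {
    stop("variant table is missing columns: ", paste(miss, collapse = ", "))
  }
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  v$chrom <- normalize_chrom(v$chrom)
  keep <- v$chrom %in% chrom_levels()
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sample_id, ": dropped ", n_dropped,
            " variant(s) on non-canonical contigs")
    v <- v[keep, , drop = FALSE]
  }
  v$pos <- as.integer(v$pos)
  v$ref <- toupper(as.character(v$ref))
  v$alt <- toupper(as.character(v$alt))
  if (nrow(v)) {
    if (any(is.na(v$pos)) || any(v$pos < 1L)) stop("pos must be an integer >= 1")
    if (any(!nzchar(v$ref)) || any(!nzchar(v$alt))) {
      stop("ref and alt alleles must be non-empty")
    }
    if (any(v$ref == v$alt)) stop("alt allele must differ from ref")
  }
  # fill optional columns
  for (col in c("functional_class", "gene")) {
    if (is.null(v[[col]])) v[[col]] <- rep(NA_character_, nrow(v))
  }
  bad <- !is.na(v$functional_class) & !(v$functional_class %in% functional_classes())
  if (any(bad)) {
    stop("unknown functional_class label(s): ",
         paste(unique(v$functional_class[bad]), collapse = ", "))
  }
  for (col in c("depth", "alt_depth")) {
    if (is.null(v[[col]])) v[[col]] <- rep(NA_integer_, nrow(v))
    v[[col]] <- as.integer(v[[col]])
  }
  ok <- !is.na(v$depth) & !is.na(v$alt_depth)
  if (any(ok & (v$alt_depth > v$depth | v$alt_depth < 0L))) {
    stop("alt_depth must satisfy 0 <= alt_depth <= depth")
  }
  if (is.null(v$af)) v$af <- rep(NA_real_, nrow(v))
  v$af <- as.numeric(v$af)
  recompute <- ok & v$depth > 0L
  v$af[recompute] <- v$alt_depth[recompute] / v$depth[recompute]
  v$af[ok & v$depth == 0L] <- NA_real_  # undefined when depth is zero
  for (db in population_databases()) {
    col <- db_column(db)
    if (is.null(v[[col]])) v[[col]] <- rep(NA_real_, nrow(v))
    v[[col]] <- as.numeric(v[[col]])
    if (any(!is.na(v[[col]]) & (v[[col]] < 0 | v[[col]] > 1))) {
      stop("population frequencies must lie in [0, 1] (", col, ")")
    }
  }
  key <- variant_key(v)
  if (anyDuplicated(key)) {
    stop("duplicate variant key(s) in profile '", sample_id, "': ",
         paste(utils::head(key[duplicated(key)], 3), collapse = ", "))
  }
  v <- v[variant_order(v), , drop = FALSE]
  rownames(v) <- NULL
  structure(
    list(sample_id = as.character(sample_id), role = role, sex = sex,
         variants = v, n_dropped_contigs = n_dropped),
    class = "sample_profile"
  )
}

#' Number of variants in a profile
#' @param profile a `sample_profile`.
#' @return integer count.
#' @export
n_variants <- function(profile) nrow(profile$variants)

#' Variant identity keys of a profile
#' @param profile a `sample_profile`.
#' @return character vector "chrom:pos:ref:alt" in canonical order.
#' @export
profile_keys <- function(profile) variant_key(profile$variants)

#' @export
print.sample_profile <- function(x, ...) {
  cat("sample_profile '", x$sample_id, "' (role: ", x$role, ", sex: ", x$sex,
      ")\n  ", n_variants(x), " variants", sep = "")
  if (x$n_dropped_contigs > 0) {
    cat(" (", x$n_dropped_contigs, " dropped on non-canonical contigs)", sep = "")
  }
  cat("\n")
  invisible(x)
}

# Rebuild a profile around a row subset, keeping metadata.
#' @keywords internal
profile_replace_variants <- function(profile, variants) {
  out <- profile
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants <- variants[variant_order(variants), , drop = FALSE]
  rownames(variants) <- NULL
  out$variants <- variants
  out
}

#' Attach annotations to a profile
#'
#' Joins functional classes, gene symbols and per-database population
#' frequencies from an annotation table onto matching variants of a profile
#' (by identity key). Unmatched profile variants keep their existing values.
#'
#' @param profile a `sample_profile`.
#' @param annotations data.frame as returned by [read_annotation_table()].
#' @return the annotated `sample_profile`.
#' @export
annotate_profile <- function(profile, annotations) {
  idx <- match(profile_keys(profile), variant_key(annotations))
  hit <- !is.na(idx)
  v <- profile$variants
  cols <- c("functional_class", "gene", vapply(population_databases(),
                                               db_column, character(1)))
  for (col in cols) {
    if (!is.null(annotations[[col]])) v[[col]][hit] <- annotations[[col]][idx[hit]]
  }
  profile_replace_variants(profile, v)
}
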