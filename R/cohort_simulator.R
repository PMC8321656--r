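# Synthetic transplant-cohort simulator. Generates a population frequency
# catalog, donor/recipient germlines, a donor tumor with clonal structure
# and a focal deletion, lesions rendered at chosen purities under Poisson
# depth / binomial allele sampling, MLPA probe ratios, and ground-truth
# labels for every emitted variant.

# Class sampling weights emulating the composition of a whole-exome variant
# set (UTR/unspecified exonic, indel, nonsynonymous, nonsense, synonymous,
# splice site, non-exonic/ncRNA).
#' @keywords internal
class_weights <- function() {
  stats::setNames(c(8014, 302, 10933, 84, 11866, 97, 100074),
                  functional_classes())
}

#' Clone specification
#'
#' @param clone_id clone label.
#' @param fraction cancer-cell fraction in (0, 1]; the truncal clone has
#'   fraction 1.
#' @param private_mutation_count number of random somatic mutations private
#'   to the clone.
#' @param drivers optional data.frame of driver mutations to plant, with
#'   columns `gene`, `chrom`, `pos`, `ref`, `alt`.
#' @return an object of class `clone_spec`.
#' @export
clone_spec <- function(clone_id, fraction, private_mutation_count,
                       drivers = NULL) {
  stopifnot(fraction > 0, fraction <= 1, private_mutation_count >= 0)
  structure(list(clone_id = clone_id, fraction = fraction,
                 private_mutation_count = as.integer(private_mutation_count),
                 drivers = drivers),
            class = "clone_spec")
}

#' Copy-number event specification
#'
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive span, `end > start`.
#' @param copy_state `homozygous_loss`, `heterozygous_loss`, or `gain`.
#' @param clone_id carrier clone.
#' @return an object of class `cnv_spec`.
#' @export
cnv_spec <- function(chrom = "9", start = 21948801L, end = 22163300L,
                     copy_state = "homozygous_loss", clone_id = "truncal") {
  stopifnot(end > start)
  copy_state <- match.arg(copy_state,
                          c("homozygous_loss", "heterozygous_loss", "gain"))
  structure(list(chrom = normalize_chrom(chrom), start = as.integer(start),
                 end = as.integer(end), copy_state = copy_state,
                 clone_id = clone_id),
            class = "cnv_spec")
}

#' Default clonal architecture
#'
#' A truncal clone (fraction 1) carrying the BRAF V600E, SDHC, DDR2 and
#' FANCD2 drivers, and a minor subclone (fraction 0.3) carrying PIK3CA
#' E545K.
#'
#' @return list of [clone_spec()] objects.
#' @export
default_clones <- function() {
  truncal_drivers <- data.frame(
    gene = c("BRAF", "SDHC", "DDR2", "FANCD2"),
    chrom = c("7", "1", "1", "3"),
    pos = c(140453136L, 161298257L, 162745490L, 10106532L),
    ref = c("A", "A", "C", "G"), alt = c("T", "G", "T", "A"),
    stringsAsFactors = FALSE)
  sub_drivers <- data.frame(gene = "PIK3CA", chrom = "3", pos = 178936091L,
                            ref = "G", alt = "A", stringsAsFactors = FALSE)
  list(clone_spec("truncal", 1, 150, truncal_drivers),
       clone_spec("pik3ca_subclone", 0.3, 40, sub_drivers))
}

#' Default cohort sample sheet
#'
#' One donor tumor (purity 0.5), the liver recipient's blood, and three
#' lesions at purities 0.97, 0.78, 0.78, all at mean depth 200.
#'
#' @param transmitted are the lesions donor-derived (`TRUE`) or
#'   recipient-origin (`FALSE`)?
#' @return data.frame sample sheet.
#' @export
default_samples <- function(transmitted = TRUE) {
  lesion_source <- if (transmitted) "donor_tumor" else "recipient_tumor"
  data.frame(
    sample_id = c("donor_TF", "LR_blood", "LR_Om", "KR_lesion", "KPR_lesion"),
    role = c("donor_tumor", "recipient_blood", "recipient_metastasis",
             "recipient_tumor", "recipient_tumor"),
    recipient = c(NA, "LR", "LR", "KR", "KPR"),
    source = c("donor_tumor", "recipient_germline", rep(lesion_source, 3)),
    purity = c(0.5, NA, 0.97, 0.78, 0.78),
    mean_depth = 200,
    stringsAsFactors = FALSE)
}

#' Cohort configuration
#'
#' @param seed RNG seed; a fixed seed makes every simulator output
#'   reproducible.
#' @param n_common number of common-tier catalog entries.
#' @param n_rare_per_individual rare private variants carried per individual.
#' @param rare_pool_factor rare catalog size as a multiple of
#'   `n_rare_per_individual`.
#' @param chry_count hemizygous chrY variants carried by a male germline.
#' @param common_af_range population allele-frequency range for common-tier
#'   entries.
#' @param donor_sex donor sex.
#' @param recipient_sexes named character vector of recipient sexes.
#' @param clones list of [clone_spec()] objects; at least one must have
#'   fraction 1 (the truncal clone).
#' @param cnvs list of [cnv_spec()] objects carried by the donor tumor.
#' @param samples sample sheet (see [default_samples()]).
#' @param post_transplant_private_count somatic mutations acquired privately
#'   by each lesion after transplantation.
#' @param dropout_rate uniform per-sample probability that a variant escapes
#'   exome capture.
#' @param detection_limit_af minimum allelic fraction detectable by the
#'   LNA-PCR assay (reported as a flag, not an emission filter).
#' @param mlpa list with `n_region_probes`, `n_reference_probes`, `noise_sd`.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_common = 350000L,
                          n_rare_per_individual = 1500L,
                          rare_pool_factor = 20L,
                          chry_count = 20L,
                          common_af_range = c(0.05, 0.5),
                          donor_sex = "male",
                          recipient_sexes = c(LR = "female", KR = "male",
                                              KPR = "male"),
                          clones = default_clones(),
                          cnvs = list(cnv_spec()),
                          samples = default_samples(),
                          post_transplant_private_count = 150L,
                          dropout_rate = 0.02,
                          detection_limit_af = 0.01,
                          mlpa = list(n_region_probes = 12L,
                                      n_reference_probes = 8L,
                                      noise_sd = 0.03)) {
  stopifnot(n_common >= 0, n_rare_per_individual >= 0,
            dropout_rate >= 0, dropout_rate < 1,
            detection_limit_af >= 0, detection_limit_af <= 1)
  fractions <- vapply(clones, function(cl) cl$fraction, numeric(1))
  if (length(clones) && !any(fractions == 1)) {
    stop("the clonal architecture needs a truncal clone (fraction 1)")
  }
  p <- samples$purity
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("purity must lie in [0, 1]")
  if (any(samples$mean_depth <= 0)) stop("mean_depth must be positive")
  structure(list(seed = as.integer(seed), n_common = as.integer(n_common),
                 n_rare_per_individual = as.integer(n_rare_per_individual),
                 rare_pool_factor = as.integer(rare_pool_factor),
                 chry_count = as.integer(chry_count),
                 common_af_range = common_af_range,
                 donor_sex = donor_sex, recipient_sexes = recipient_sexes,
                 clones = clones, cnvs = cnvs, samples = samples,
                 post_transplant_private_count =
                   as.integer(post_transplant_private_count),
                 dropout_rate = dropout_rate,
                 detection_limit_af = detection_limit_af, mlpa = mlpa),
            class = "cohort_config")
}

# Random distinct variant keys with functional classes.
#' @keywords internal
random_variant_keys <- function(n, chroms = c(as.character(1:22), "X")) {
  if (n == 0) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), functional_class = character(),
                      stringsAsFactors = FALSE))
  }
  bases <- c("A", "C", "G", "T")
  m <- ceiling(n * 1.05) + 10
  df <- data.frame(chrom = sample(chroms, m, replace = TRUE),
                   pos = sample.int(240000000L, m, replace = TRUE),
                   stringsAsFactors = FALSE)
  ref_i <- sample.int(4L, m, replace = TRUE)
  df$ref <- bases[ref_i]
  # alt drawn uniformly from the three non-reference bases
  df$alt <- bases[((ref_i - 1L + sample.int(3L, m, replace = TRUE)) %% 4L) + 1L]
  df <- df[!duplicated(paste(df$chrom, df$pos, sep = ":")), , drop = FALSE]
  while (nrow(df) < n) {  # extremely unlikely; top up
    extra <- random_variant_keys(n - nrow(df), chroms)
    df <- rbind(df, extra[, names(df)])
    df <- df[!duplicated(paste(df$chrom, df$pos, sep = ":")), , drop = FALSE]
  }
  df <- df[seq_len(n), , drop = FALSE]
  w <- class_weights()
  df$functional_class <- sample(names(w), n, replace = TRUE,
                                prob = w / sum(w))
  rownames(df) <- NULL
  df
}

#' Simulate a population frequency catalog
#'
#' Common-tier entries carry a population allele frequency in
#' `common_af_range` and are listed at or above 0.001 in at least two
#' databases (1000G and gnomAD always; the others with probability 0.95).
#' Rare-tier entries have every listed frequency below 0.001 (uniform in
#' [1e-6, 9e-4]), each database present with probability 0.5.
#'
#' @param config a [cohort_config()].
#' @param seed optional RNG seed (otherwise the current RNG state is used).
#' @return data.frame catalog with key columns, `functional_class`,
#'   `af_true` (sampling frequency), `tier`, and the five `af_<db>` columns.
#' @export
simulate_catalog <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_rare <- config$n_rare_per_individual * config$rare_pool_factor
  common <- random_variant_keys(config$n_common)
  rare <- random_variant_keys(n_rare)
  r <- config$common_af_range
  if (nrow(common)) {
    common$af_true <- stats::runif(nrow(common), r[1], r[2])
    common$tier <- "common"
  } else {
    common$af_true <- numeric(0); common$tier <- character(0)
  }
  if (nrow(rare)) {
    rare$af_true <- stats::runif(nrow(rare), 1e-6, 9e-4)
    rare$tier <- "rare"
  } else {
    rare$af_true <- numeric(0); rare$tier <- character(0)
  }
  cat_df <- rbind(common, rare)
  n <- nrow(cat_df)
  for (db in population_databases()) {
    col <- db_column(db)
    present_prob <- ifelse(cat_df$tier == "common",
                           ifelse(db %in% c("1000G", "gnomAD"), 1, 0.95), 0.5)
    present <- stats::runif(n) < present_prob
    val <- ifelse(cat_df$tier == "common",
                  pmin(cat_df$af_true * stats::runif(n, 0.8, 1.25), 1),
                  cat_df$af_true)
    cat_df[[col]] <- ifelse(present, val, NA_real_)
  }
  rownames(cat_df) <- NULL
  cat_df
}

#' Simulate an individual germline
#'
#' Common-tier catalog variants are carried under Hardy-Weinberg sampling at
#' the catalog frequency (heterozygous, expected AF 0.5, or homozygous,
#' AF 1). `n_rare_per_individual` rare-tier variants are drawn privately.
#' A male germline additionally carries `chry_count` hemizygous chrY
#' variants (expected AF 1); a female germline carries none.
#'
#' @param catalog catalog from [simulate_catalog()].
#' @param sex `"male"` or `"female"`.
#' @param config a [cohort_config()].
#' @param origin_common,origin_rare truth labels for the carried variants.
#' @param seed optional RNG seed.
#' @return data.frame germline truth: key columns, class, gene, `af_<db>`
#'   columns, `zygosity`, `af_pure`, `origin`.
#' @export
simulate_germline <- function(catalog, sex, config,
                              origin_common = "recipient_germline",
                              origin_rare = "recipient_germline",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  db_cols <- vapply(population_databases(), db_column, character(1))
  keep_cols <- c("chrom", "pos", "ref", "alt", "functional_class", db_cols)
  common <- catalog[catalog$tier == "common", , drop = FALSE]
  u <- stats::runif(nrow(common))
  f <- common$af_true
  hom <- u < f^2
  het <- !hom & u < f^2 + 2 * f * (1 - f)
  g_common <- common[hom | het, keep_cols, drop = FALSE]
  g_common$zygosity <- ifelse(hom[hom | het], "hom", "het")
  g_common$origin <- rep(origin_common, nrow(g_common))
  # private rare variants: fresh keys, listed in databases (if at all) at
  # rare-tier frequencies; unrelated individuals share these at a rate far
  # below the common-filter threshold, as in real cohorts
  g_rare <- random_variant_keys(config$n_rare_per_individual)
  n_r <- nrow(g_rare)
  for (col in db_cols) {
    f <- stats::runif(n_r, 1e-6, 9e-4)
    f[stats::runif(n_r) > 0.5] <- NA
    g_rare[[col]] <- f
  }
  g_rare <- g_rare[, keep_cols, drop = FALSE]
  g_rare$zygosity <- rep("het", n_r)
  g_rare$origin <- rep(origin_rare, n_r)
  out <- rbind(g_common, g_rare)
  if (identical(sex, "male") && config$chry_count > 0) {
    y <- random_variant_keys(config$chry_count, chroms = "Y")
    for (col in db_cols) y[[col]] <- rep(NA_real_, nrow(y))
    y$zygosity <- rep("hemi", nrow(y))
    y$origin <- rep(origin_rare, nrow(y))
    out <- rbind(out, y[, names(out)])
  }
  out$gene <- rep(NA_character_, nrow(out))
  out$af_pure <- ifelse(out$zygosity == "het", 0.5, 1.0)
  rownames(out) <- NULL
  out
}

# strip planted drivers from clones (recipient-origin tumors acquire their
# own private mutations instead)
#' @keywords internal
strip_drivers <- function(clones) {
  lapply(clones, function(cl) {
    extra <- if (is.null(cl$drivers)) 0L else nrow(cl$drivers)
    clone_spec(cl$clone_id, cl$fraction, cl$private_mutation_count + extra,
               drivers = NULL)
  })
}

#' Simulate the somatic truth of a tumor
#'
#' Somatic variants are assigned to clones; a heterozygous somatic variant
#' in a pure tumor has expected AF 0.5 x clone fraction (diploid,
#' copy-neutral). Somatic variants of a clone falling inside a homozygous
#' loss carried by that clone are removed from its emission; germline
#' variants are retained. Planting a driver inside its own homozygous loss
#' is a configuration error.
#'
#' @param germline germline truth from [simulate_germline()].
#' @param clones list of [clone_spec()] objects.
#' @param cnvs list of [cnv_spec()] objects.
#' @param config a [cohort_config()].
#' @param seed optional RNG seed.
#' @return data.frame tumor truth (germline + somatic rows) with `af_pure`,
#'   `origin`, `clone_id`.
#' @export
simulate_tumor_truth <- function(germline, clones, cnvs = list(),
                                 config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  db_cols <- vapply(population_databases(), db_column, character(1))
  somatic <- list()
  for (cl in clones) {
    rows <- random_variant_keys(cl$private_mutation_count)
    rows$gene <- rep(NA_character_, nrow(rows))
    if (!is.null(cl$drivers) && nrow(cl$drivers)) {
      drv <- cl$drivers
      drv$chrom <- normalize_chrom(drv$chrom)
      drv$functional_class <- "nonsynonymous"
      rows <- rbind(rows[, c("chrom", "pos", "ref", "alt", "functional_class",
                             "gene")],
                    drv[, c("chrom", "pos", "ref", "alt", "functional_class",
                            "gene")])
    } else {
      rows <- rows[, c("chrom", "pos", "ref", "alt", "functional_class",
                       "gene")]
    }
    for (col in db_cols) rows[[col]] <- rep(NA_real_, nrow(rows))
    rows$zygosity <- rep("het", nrow(rows))
    rows$origin <- rep(if (cl$fraction == 1) "somatic_truncal" else
      paste0("somatic_subclonal:", cl$clone_id), nrow(rows))
    rows$af_pure <- rep(0.5 * cl$fraction, nrow(rows))
    rows$clone_id <- rep(cl$clone_id, nrow(rows))
    # homozygous losses carried by this clone silence its variants inside
    for (cnv in cnvs) {
      if (cnv$copy_state != "homozygous_loss") next
      if (!identical(cnv$clone_id, cl$clone_id)) next
      inside <- rows$chrom == cnv$chrom & rows$pos >= cnv$start &
        rows$pos <= cnv$end
      if (any(inside & !is.na(rows$gene))) {
        stop("driver ", rows$gene[inside & !is.na(rows$gene)][1],
             " planted inside its own homozygous loss")
      }
      rows <- rows[!inside, , drop = FALSE]
    }
    somatic[[cl$clone_id]] <- rows
  }
  g <- germline
  g$clone_id <- rep(NA_character_, nrow(g))
  out <- rbind(g[, c("chrom", "pos", "ref", "alt", "functional_class", "gene",
                     db_cols, "zygosity", "origin", "af_pure", "clone_id")],
               do.call(rbind, somatic)[, c("chrom", "pos", "ref", "alt",
                                           "functional_class", "gene", db_cols,
                                           "zygosity", "origin", "af_pure",
                                           "clone_id")])
  # a somatic key colliding with a germline key is astronomically unlikely
  # but would break profile uniqueness; drop the somatic copy if it happens
  out <- out[!duplicated(paste(out$chrom, out$pos, out$ref, out$alt,
                               sep = ":")), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render an observed sample from truth at a given purity
#'
#' Expected AF is `purity x af_pure` for tumor-lineage (donor-origin)
#' variants and `af_pure` (0.5 het / 1 hom) for the host germline,
#' independent of purity. Key collisions between the two keep the maximum
#' expected AF with a merged origin note. Depth is Poisson(`mean_depth`),
#' alt reads Binomial(depth, expected AF); variants with zero alt reads are
#' not emitted (caller detection model), and a uniform capture dropout is
#' applied first.
#'
#' @param truth tumor truth from [simulate_tumor_truth()], or `NULL` for a
#'   pure germline (blood) sample.
#' @param host_germline germline truth of the individual hosting the sample.
#' @param purity tumor cell fraction in [0, 1].
#' @param mean_depth mean sequencing depth.
#' @param sample_id,role,sex sample metadata.
#' @param config a [cohort_config()] (dropout and detection limit).
#' @param seed optional RNG seed.
#' @return a `sample_profile`; its variant table carries `origin`,
#'   `expected_af` and `detectable_lna` truth columns.
#' @export
render_observed_sample <- function(truth = NULL, host_germline = NULL,
                                   purity = 1, mean_depth = 200,
                                   sample_id = "sample",
                                   role = "recipient_tumor", sex = "unknown",
                                   config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(purity >= 0, purity <= 1)
  db_cols <- vapply(population_databases(), db_column, character(1))
  cols <- c("chrom", "pos", "ref", "alt", "functional_class", "gene", db_cols)
  parts <- list()
  if (!is.null(truth) && nrow(truth)) {
    t_part <- truth[, cols, drop = FALSE]
    t_part$expected_af <- purity * truth$af_pure
    t_part$origin <- truth$origin
    parts$tumor <- t_part
  }
  if (!is.null(host_germline) && nrow(host_germline)) {
    h_part <- host_germline[, cols, drop = FALSE]
    h_part$expected_af <- host_germline$af_pure
    h_part$origin <- host_germline$origin
    parts$host <- h_part
  }
  v <- do.call(rbind, parts)
  if (is.null(v) || nrow(v) == 0) {
    prof <- sample_profile(data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character()),
                           sample_id, role, sex)
    return(prof)
  }
  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  if (anyDuplicated(key)) {
    # collisions: keep the max expected af, merge origin notes
    ord <- order(key, -v$expected_af)
    v <- v[ord, , drop = FALSE]
    key <- key[ord]
    first <- !duplicated(key)
    merged_origin <- tapply(v$origin, key, function(o)
      paste(unique(o), collapse = "+"))
    v <- v[first, , drop = FALSE]
    v$origin <- as.character(merged_origin[key[first]])
  }
  n <- nrow(v)
  keep <- stats::runif(n) >= config$dropout_rate
  v <- v[keep, , drop = FALSE]
  n <- nrow(v)
  depth <- stats::rpois(n, mean_depth)
  alt <- stats::rbinom(n, depth, pmin(v$expected_af, 1))
  emitted <- alt >= 1L
  v <- v[emitted, , drop = FALSE]
  v$depth <- depth[emitted]
  v$alt_depth <- alt[emitted]
  v$detectable_lna <- v$expected_af >= config$detection_limit_af
  sample_profile(v, sample_id = sample_id, role = role, sex = sex)
}

#' Simulate MLPA probe ratios
#'
#' Probes inside a homozygous loss have expected ratio `1 - purity`
#' (residual normal cells still contribute signal); heterozygous losses give
#' `1 - purity/2`, gains `1 + purity/2`; probes outside any event have
#' expected ratio 1. Observed ratios add Gaussian noise.
#'
#' @param cnvs list of [cnv_spec()] objects (may be empty).
#' @param purity tumor cell fraction.
#' @param n_region_probes probes tiled across each event span.
#' @param n_reference_probes control probes outside any event (gene `"REF"`).
#' @param noise_sd Gaussian noise SD on the ratio.
#' @param seed optional RNG seed.
#' @return data.frame with `probe_id`, `chrom`, `pos`, `gene`,
#'   `expected_ratio`, `ratio`.
#' @export
simulate_mlpa <- function(cnvs, purity, n_region_probes = 12L,
                          n_reference_probes = 8L, noise_sd = 0.03,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probes <- list()
  for (i in seq_along(cnvs)) {
    cnv <- cnvs[[i]]
    pos <- as.integer(round(seq(cnv$start, cnv$end,
                                length.out = n_region_probes)))
    expected <- switch(cnv$copy_state,
                       homozygous_loss = 1 - purity,
                       heterozygous_loss = 1 - purity / 2,
                       gain = 1 + purity / 2)
    probes[[i]] <- data.frame(
      probe_id = sprintf("cnv%d_p%02d", i, seq_along(pos)),
      chrom = cnv$chrom, pos = pos,
      gene = ifelse(pos <= 22000000L & cnv$chrom == "9", "CDKN2A", "CDKN2B"),
      expected_ratio = expected, stringsAsFactors = FALSE)
  }
  ref_chroms <- rep(c("2", "4", "6", "8", "12", "14", "16", "18"),
                    length.out = n_reference_probes)
  probes$ref <- data.frame(
    probe_id = sprintf("ref_p%02d", seq_len(n_reference_probes)),
    chrom = ref_chroms,
    pos = 50000000L + seq_len(n_reference_probes) * 1000000L,
    gene = "REF", expected_ratio = 1, stringsAsFactors = FALSE)
  out <- do.call(rbind, probes)
  out$ratio <- pmax(out$expected_ratio +
                      stats::rnorm(nrow(out), 0, noise_sd), 0)
  rownames(out) <- NULL
  out
}

#' Derive MLPA peak-height tables from simulated ratios
#'
#' Turns simulated probe ratios into raw peak heights for the test sample
#' and a set of copy-number-normal reference samples, each with its own
#' arbitrary overall signal scale, so that the [normalize_probes()] pipeline
#' can be exercised end to end.
#'
#' @param mlpa data.frame from [simulate_mlpa()].
#' @param n_reference_samples number of reference individuals.
#' @param ref_noise_sd multiplicative noise SD on reference peaks.
#' @param seed optional RNG seed.
#' @return list with `sample` (peak table) and `references` (list of peak
#'   tables).
#' @export
simulate_mlpa_peaks <- function(mlpa, n_reference_samples = 3,
                                ref_noise_sd = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- stats::runif(nrow(mlpa), 800, 1200)  # per-probe amplification
  mk <- function(ratios, scale) {
    data.frame(probe_id = mlpa$probe_id, chrom = mlpa$chrom, pos = mlpa$pos,
               gene = mlpa$gene, peak_height = scale * base * ratios,
               stringsAsFactors = FALSE)
  }
  sample_tab <- mk(mlpa$ratio, stats::runif(1, 0.5, 2))
  refs <- lapply(seq_len(n_reference_samples), function(i) {
    mk(pmax(1 + stats::rnorm(nrow(mlpa), 0, ref_noise_sd), 0),
       stats::runif(1, 0.5, 2))
  })
  list(sample = sample_tab, references = refs)
}

#' Simulate a full transplant cohort
#'
#' Runs the whole generative model under `config$seed`: catalog, donor and
#' recipient germlines, donor tumor truth (and per-recipient tumor truths
#' for recipient-origin lesions), rendered sample profiles, MLPA probe
#' tables for tumor samples, and a ground-truth record.
#'
#' @param config a [cohort_config()].
#' @return list of class `cohort` with elements `config`, `catalog`,
#'   `germlines`, `samples` (named list of `sample_profile`), `mlpa` (named
#'   list of probe tables), and `truth`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  catalog <- simulate_catalog(config)
  germlines <- list(
    donor = simulate_germline(catalog, config$donor_sex, config,
                              origin_common = "donor_germline_common",
                              origin_rare = "donor_germline_rare"))
  recipients <- unique(stats::na.omit(config$samples$recipient))
  for (r in recipients) {
    germlines[[r]] <- simulate_germline(catalog, config$recipient_sexes[[r]],
                                        config)
  }
  donor_truth <- simulate_tumor_truth(germlines$donor, config$clones,
                                      config$cnvs, config)
  recipient_truths <- list()
  for (r in recipients) {
    if (any(config$samples$recipient == r &
            config$samples$source == "recipient_tumor", na.rm = TRUE)) {
      recipient_truths[[r]] <- simulate_tumor_truth(
        germlines[[r]], strip_drivers(config$clones), cnvs = list(),
        config = config)
    }
  }
  samples <- list()
  mlpa <- list()
  truth_origins <- list()
  for (i in seq_len(nrow(config$samples))) {
    s <- config$samples[i, ]
    host <- if (is.na(s$recipient)) germlines$donor else
      germlines[[s$recipient]]
    host_sex <- if (is.na(s$recipient)) config$donor_sex else
      config$recipient_sexes[[s$recipient]]
    if (s$source == "recipient_germline") {
      prof <- render_observed_sample(NULL, host, purity = 0,
                                     mean_depth = s$mean_depth,
                                     sample_id = s$sample_id, role = s$role,
                                     sex = host_sex, config = config)
      cnvs_here <- list()
    } else {
      truth <- if (s$source == "donor_tumor") donor_truth else
        recipient_truths[[s$recipient]]
      if (!is.na(s$recipient) && config$post_transplant_private_count > 0) {
        priv <- random_variant_keys(config$post_transplant_private_count)
        np <- nrow(priv)
        priv$gene <- rep(NA_character_, np)
        for (db in population_databases()) {
          priv[[db_column(db)]] <- rep(NA_real_, np)
        }
        priv$zygosity <- rep("het", np)
        priv$origin <- rep("post_transplant_private", np)
        priv$af_pure <- rep(0.5, np)
        priv$clone_id <- rep(NA_character_, np)
        truth <- rbind(truth, priv[, names(truth)])
      }
      prof <- render_observed_sample(truth, host, purity = s$purity,
                                     mean_depth = s$mean_depth,
                                     sample_id = s$sample_id, role = s$role,
                                     sex = host_sex, config = config)
      cnvs_here <- if (s$source == "donor_tumor") config$cnvs else list()
      mlpa[[s$sample_id]] <- simulate_mlpa(
        cnvs_here, s$purity, n_region_probes = config$mlpa$n_region_probes,
        n_reference_probes = config$mlpa$n_reference_probes,
        noise_sd = config$mlpa$noise_sd)
    }
    samples[[s$sample_id]] <- prof
    truth_origins[[s$sample_id]] <- data.frame(
      key = profile_keys(prof), origin = prof$variants$origin,
      stringsAsFactors = FALSE)
  }
  truth <- list(
    seed = config$seed,
    purity = as.list(stats::setNames(config$samples$purity,
                                     config$samples$sample_id)),
    clone_fractions = as.list(stats::setNames(
      vapply(config$clones, function(cl) cl$fraction, numeric(1)),
      vapply(config$clones, function(cl) cl$clone_id, character(1)))),
    cnvs = lapply(config$cnvs, unclass),
    donor_sex = config$donor_sex,
    recipient_sexes = as.list(config$recipient_sexes),
    sources = as.list(stats::setNames(config$samples$source,
                                      config$samples$sample_id)),
    origins = truth_origins)
  structure(list(config = config, catalog = catalog, germlines = germlines,
                 samples = samples, mlpa = mlpa, truth = truth),
            class = "cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits one TSV and one VCF per sample, one MLPA probe TSV per tumor
#' sample, a ground-truth JSON, and a config echo YAML, all deterministic
#' under the config seed.
#'
#' @param config a [cohort_config()] (or an already simulated `cohort`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the simulated `cohort`.
#' @export
write_cohort <- function(config, out_dir) {
  cohort <- if (inherits(config, "cohort")) config else
    simulate_cohort(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(cohort$samples)) {
    write_profile(cohort$samples[[sid]],
                  file.path(out_dir, paste0(sid, ".tsv")), "tsv")
    write_profile(cohort$samples[[sid]],
                  file.path(out_dir, paste0(sid, ".vcf")), "vcf")
  }
  for (sid in names(cohort$mlpa)) {
    write_mlpa_table(cohort$mlpa[[sid]],
                     file.path(out_dir, paste0(sid, "_mlpa.tsv")))
  }
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  cfg <- cohort$config
  yaml::write_yaml(list(seed = cfg$seed, n_common = cfg$n_common,
                        n_rare_per_individual = cfg$n_rare_per_individual,
                        chry_count = cfg$chry_count,
                        donor_sex = cfg$donor_sex,
                        recipient_sexes = as.list(cfg$recipient_sexes),
                        detection_limit_af = cfg$detection_limit_af,
                        dropout_rate = cfg$dropout_rate,
                        samples = cfg$samples),
                   file.path(out_dir, "config.yaml"))
  invisible(cohort)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `samples` (named `sample_profile` list), `mlpa`, and
#'   `truth`.
#' @export
read_cohort <- function(dir) {
  tsvs <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  mlpa_files <- grep("_mlpa\\.tsv$", tsvs, value = TRUE)
  prof_files <- setdiff(tsvs, mlpa_files)
  samples <- lapply(prof_files, read_profile_tsv)
  names(samples) <- vapply(samples, function(p) p$sample_id, character(1))
  mlpa <- lapply(mlpa_files, read_mlpa_table)
  names(mlpa) <- sub("_mlpa\\.tsv$", "", basename(mlpa_files))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  list(samples = samples, mlpa = mlpa, truth = truth)
}
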