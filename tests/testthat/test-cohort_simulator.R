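test_that("the simulator is deterministic under a fixed seed", {
  cfg <- small_cohort_config(seed = 13)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  for (sid in names(a$samples)) {
    expect_identical(a$samples[[sid]]$variants, b$samples[[sid]]$variants)
  }
  expect_identical(a$mlpa, b$mlpa)
  expect_identical(a$truth, b$truth)

  # a different seed moves variant positions but keeps config-level shape
  c2 <- simulate_cohort(small_cohort_config(seed = 14))
  expect_identical(names(c2$samples), names(a$samples))
  expect_false(identical(profile_keys(a$samples$donor_TF),
                         profile_keys(c2$samples$donor_TF)))
})

test_that("catalog tiers satisfy their frequency predicates", {
  cfg <- cohort_config(n_common = 10000, n_rare_per_individual = 250,
                       rare_pool_factor = 8)
  catalog <- simulate_catalog(cfg, seed = 3)
  db_cols <- paste0("af_", population_databases())
  freq_mat <- as.matrix(catalog[, db_cols])
  n_at_least <- rowSums(!is.na(freq_mat) & freq_mat >= 0.001)
  common <- catalog$tier == "common"
  # every common entry is listed at >= 0.001 in at least two databases
  expect_true(all(n_at_least[common] >= 2))
  # every present rare frequency is below 0.001 (including ExAC)
  rare_freqs <- freq_mat[!common, ]
  expect_true(all(rare_freqs[!is.na(rare_freqs)] < 0.001))
  expect_equal(sum(common), 10000L)

  only_rare <- simulate_catalog(cohort_config(n_common = 0,
                                              n_rare_per_individual = 50,
                                              rare_pool_factor = 2), seed = 4)
  expect_true(all(only_rare$tier == "rare"))
})

test_that("germline sex model: chrY content is male-only and counted", {
  cfg <- cohort_config(n_common = 500, n_rare_per_individual = 50,
                       rare_pool_factor = 4, chry_count = 20)
  set.seed(8)
  catalog <- simulate_catalog(cfg)
  male <- simulate_germline(catalog, "male", cfg)
  female <- simulate_germline(catalog, "female", cfg)
  expect_equal(sum(male$chrom == "Y"), 20L)
  expect_equal(sum(female$chrom == "Y"), 0L)
  expect_true(all(male$af_pure[male$chrom == "Y"] == 1))
})

test_that("two germlines share common variants at the rate the catalog implies", {
  cfg <- cohort_config(n_common = 10000, n_rare_per_individual = 0,
                       rare_pool_factor = 1, chry_count = 0)
  set.seed(15)
  catalog <- simulate_catalog(cfg)
  g1 <- simulate_germline(catalog, "female", cfg)
  g2 <- simulate_germline(catalog, "female", cfg)
  k1 <- paste(g1$chrom, g1$pos, g1$ref, g1$alt)
  k2 <- paste(g2$chrom, g2$pos, g2$ref, g2$alt)
  observed <- length(intersect(k1, k2))
  # per entry, P(both carry) = p^2 with p = 2f(1-f) + f^2
  f <- catalog$af_true[catalog$tier == "common"]
  p <- 2 * f * (1 - f) + f^2
  expected <- sum(p^2)
  se <- sqrt(sum(p^2 * (1 - p^2)))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("tumor truth assigns clone-scaled allelic fractions and honors homozygous losses", {
  cfg <- small_cohort_config(seed = 23)
  set.seed(23)
  catalog <- simulate_catalog(cfg)
  germ <- simulate_germline(catalog, "male", cfg,
                            origin_common = "donor_germline_common",
                            origin_rare = "donor_germline_rare")
  truth <- simulate_tumor_truth(germ, cfg$clones, cfg$cnvs, cfg)
  truncal <- truth[truth$origin == "somatic_truncal", ]
  subclonal <- truth[grepl("^somatic_subclonal", truth$origin), ]
  expect_true(all(truncal$af_pure == 0.5))
  expect_true(all(subclonal$af_pure == 0.5 * 0.3))
  # every subclonal pure AF sits below every truncal pure AF
  expect_lt(max(subclonal$af_pure), min(truncal$af_pure))
  # no somatic variant of the carrier clone survives inside the deletion
  cnv <- cfg$cnvs[[1]]
  inside <- truth$chrom == cnv$chrom & truth$pos >= cnv$start &
    truth$pos <= cnv$end
  expect_false(any(inside & truth$origin == "somatic_truncal"))

  # planting a driver inside its own homozygous loss is a config error
  bad_clone <- clone_spec("truncal", 1, 0, data.frame(
    gene = "CDKN2A", chrom = "9", pos = 21970000L, ref = "A", alt = "G"))
  expect_error(simulate_tumor_truth(germ, list(bad_clone), cfg$cnvs, cfg),
               "homozygous loss")
})

test_that("rendering dilutes donor-origin AF by purity but not host germline AF", {
  cfg <- cohort_config(n_common = 400, n_rare_per_individual = 40,
                       rare_pool_factor = 4, dropout_rate = 0)
  set.seed(33)
  catalog <- simulate_catalog(cfg)
  donor_germ <- simulate_germline(catalog, "male", cfg,
                                  origin_common = "donor_germline_common",
                                  origin_rare = "donor_germline_rare")
  host_germ <- simulate_germline(catalog, "female", cfg)
  truth <- simulate_tumor_truth(donor_germ, cfg$clones, cfg$cnvs, cfg)
  prof <- render_observed_sample(truth, host_germ, purity = 0.78,
                                 mean_depth = 200, sex = "female",
                                 config = cfg, seed = 34)
  v <- prof$variants
  braf <- v[!is.na(v$gene) & v$gene == "BRAF", ]
  expect_equal(braf$expected_af, 0.39)
  host_only <- v[v$origin == "recipient_germline" & !grepl("\\+", v$origin), ]
  expect_true(all(host_only$expected_af %in% c(0.5, 1)))
  # chrY content of a female-host lesion is entirely donor-origin
  expect_true(all(grepl("donor", v$origin[v$chrom == "Y"])))
  expect_gt(sum(v$chrom == "Y"), 0)
  # every emitted variant carries exactly one (possibly merged) origin label
  expect_false(anyNA(v$origin))

  # purity zero: no donor-origin variant can be emitted
  none <- render_observed_sample(truth, NULL, purity = 0, mean_depth = 200,
                                 config = cfg, seed = 35)
  expect_equal(n_variants(none), 0L)
})

test_that("mean observed AF of truncal variants matches binomial moments", {
  cfg <- cohort_config(n_common = 0, n_rare_per_individual = 0,
                       chry_count = 0, dropout_rate = 0,
                       clones = list(clone_spec("truncal", 1, 1000)))
  set.seed(44)
  germ <- simulate_germline(simulate_catalog(cfg), "female", cfg)
  truth <- simulate_tumor_truth(germ, cfg$clones, list(), cfg)
  prof <- render_observed_sample(truth, NULL, purity = 0.5, mean_depth = 200,
                                 config = cfg, seed = 45)
  afs <- prof$variants$af
  # expected af 0.25; SE of the mean ~ sqrt(0.25*0.75/200/n)
  se <- sqrt(0.25 * 0.75 / 200 / length(afs))
  expect_lt(abs(mean(afs) - 0.25), 3 * se)
})

test_that("a written cohort reads back identical to the in-memory cohort", {
  cfg <- cohort_config(seed = 66, n_common = 300, n_rare_per_individual = 40,
                       rare_pool_factor = 4,
                       clones = list(
                         clone_spec("truncal", 1, 25,
                                    default_clones()[[1]]$drivers),
                         clone_spec("sub", 0.3, 10,
                                    default_clones()[[2]]$drivers)),
                       post_transplant_private_count = 10L)
  dir <- withr::local_tempdir()
  cohort <- write_cohort(cfg, dir)
  back <- read_cohort(dir)
  expect_setequal(names(back$samples), names(cohort$samples))
  for (sid in names(cohort$samples)) {
    expect_identical(profile_keys(back$samples[[sid]]),
                     profile_keys(cohort$samples[[sid]]))
    expect_identical(back$samples[[sid]]$variants$depth,
                     cohort$samples[[sid]]$variants$depth)
    expect_identical(back$samples[[sid]]$variants$alt_depth,
                     cohort$samples[[sid]]$variants$alt_depth)
  }
  for (sid in names(cohort$mlpa)) {
    expect_equal(back$mlpa[[sid]]$ratio, cohort$mlpa[[sid]]$ratio)
  }
  expect_equal(back$truth$purity[["LR_Om"]], 0.97)
  expect_true(file.exists(file.path(dir, "config.yaml")))
})

test_that("truth origin labels partition every rendered variant", {
  cohort <- simulate_cohort(small_cohort_config(seed = 71))
  known <- c("donor_germline_common", "donor_germline_rare",
             "recipient_germline", "somatic_truncal", "post_transplant_private")
  for (sid in names(cohort$samples)) {
    origins <- cohort$samples[[sid]]$variants$origin
    expect_false(anyNA(origins))
    atoms <- unlist(strsplit(origins, "+", fixed = TRUE))
    expect_true(all(atoms %in% known | grepl("^somatic_subclonal:", atoms)))
  }
})
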