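test_that("overlap statistics follow the stated rounding contract", {
  profile <- key_profile(8, sample_id = "P")
  donor <- key_profile(1, sample_id = "D", role = "donor_tumor")
  stats <- overlap_with_donor(profile, donor)
  # 1/8 = 12.5%, one decimal
  expect_equal(stats$shared_with_donor, 1L)
  expect_equal(stats$percent_shared, 12.5)

  # common-subset percentage rounds to the nearest integer, half away from 0
  common <- key_profile(8, chrom = "2", sample_id = "C")
  donor2 <- sample_profile(rbind(donor$variants,
                                 key_profile(3, chrom = "2",
                                             sample_id = "x")$variants),
                           "D2", role = "donor_tumor")
  stats2 <- overlap_with_donor(profile, donor2, removed_common = common)
  expect_equal(stats2$common_shared, 3L)
  expect_equal(stats2$percent_common_shared, 38)  # 37.5 -> 38

  disjoint <- key_profile(5, offset = 1000L, sample_id = "Q")
  stats3 <- overlap_with_donor(disjoint, donor)
  expect_equal(stats3$shared_with_donor, 0L)
  expect_equal(stats3$percent_shared, 0)
})

test_that("sex-discordant chrY counting applies only to female recipient / male donor", {
  df <- data.frame(chrom = c("1", "Y", "Y"), pos = 1:3, ref = "A", alt = "G")
  prof <- sample_profile(df, "S")
  hit <- count_sex_discordant(prof, "female", "male")
  expect_true(hit$applicable)
  expect_equal(hit$count, 2L)
  expect_true(hit$donor_dna_flag)

  same <- count_sex_discordant(prof, "female", "female")
  expect_false(same$applicable)
  expect_true(is.na(same$count))

  noy <- count_sex_discordant(key_profile(3, sample_id = "N"),
                              "female", "male")
  expect_equal(noy$count, 0L)
  expect_false(noy$donor_dna_flag)
})

test_that("profile intersection respects identity keys and the coding restriction", {
  a <- random_profile(300, seed = 21, sample_id = "A")
  b <- a; b$sample_id <- "B"
  both <- intersect_profiles(list(a, b))
  expect_identical(variant_key(both), profile_keys(a))

  empty <- key_profile(0, sample_id = "E")
  expect_equal(nrow(intersect_profiles(list(a, empty))), 0L)
  expect_error(intersect_profiles(list(a)), "two")

  coding <- intersect_profiles(list(a, b), coding_only = TRUE)
  expect_true(all(coding$functional_class %in% coding_classes()))
  expect_equal(nrow(coding),
               sum(a$variants$functional_class %in% coding_classes()))
})

test_that("tri-classification follows the precedence rules and partitions the input", {
  shared <- data.frame(
    af_ExAC = c(0.00005, NA, 0.0005, 0.005, 0.0005, 0.05),
    donor_af = c(0.3, 0.3, 0.50, 0.50, 0.50, 0.3))
  res <- classify_shared_coding(shared)
  expect_identical(res$labels,
                   c("probably_somatic",          # below the somatic cap
                     "probably_somatic",          # absent from ExAC
                     "rare_donor_germline_exac",  # in the ExAC band
                     "donor_het_germline_af",     # het AF band
                     "rare_donor_germline_exac",  # ExAC band wins over AF band
                     "unclassified"))
  expect_equal(sum(res$counts), nrow(shared))
})

test_that("tri-classification matches a per-variant brute-force oracle", {
  set.seed(42)
  n <- 10000
  shared <- data.frame(
    af_ExAC = ifelse(runif(n) < 0.3, NA, 10^runif(n, -6, -0.5)),
    donor_af = ifelse(runif(n) < 0.1, NA, runif(n)))
  th <- shared_class_thresholds()
  oracle <- vapply(seq_len(n), function(i) {
    e <- shared$af_ExAC[i]; d <- shared$donor_af[i]
    if (is.na(e) || e <= th$exac_somatic_max) return("probably_somatic")
    if (e >= th$exac_germline_min && e <= th$exac_germline_max) {
      return("rare_donor_germline_exac")
    }
    if (!is.na(d) && d >= th$donor_af_low && d <= th$donor_af_high) {
      return("donor_het_germline_af")
    }
    "unclassified"
  }, character(1))
  res <- suppressWarnings(classify_shared_coding(shared, th))
  expect_identical(res$labels, oracle)
  expect_equal(sum(res$counts), n)
})

test_that("a missing donor AF reaching the AF rule warns and stays unclassified", {
  shared <- data.frame(af_ExAC = 0.005, donor_af = NA_real_)
  expect_warning(res <- classify_shared_coding(shared), "donor allelic")
  expect_identical(res$labels, "unclassified")
})

test_that("the transmission verdict integrates overlap, chrY and driver evidence", {
  mk_ev <- function(pct, chry, drivers, clean_pct = pct) {
    list(overlap = list(percent_shared = pct),
         overlap_clean = list(percent_shared = clean_pct),
         sex_discordant = list(applicable = TRUE, count = chry,
                               donor_dna_flag = chry > 0),
         shared_drivers = drivers)
  }
  strong <- decide_transmission(mk_ev(85.5, 20L, c("BRAF", "PIK3CA")))
  expect_equal(strong$verdict, "transmitted")
  expect_setequal(strong$rules_fired,
                  c("overlap_with_donor", "sex_discordant_chrY",
                    "shared_somatic_drivers"))

  clean <- decide_transmission(mk_ev(0.8, 0L, character(0)))
  expect_equal(clean$verdict, "not_transmitted")

  mid <- decide_transmission(mk_ev(40, 0L, character(0)))
  expect_equal(mid$verdict, "indeterminate")

  # chrY evidence alone suffices, and blocks the clean branch
  ychr <- decide_transmission(mk_ev(1.0, 7L, character(0)))
  expect_equal(ychr$verdict, "transmitted")
  expect_equal(ychr$rules_fired, "sex_discordant_chrY")

  # genes outside the configured driver list do not count
  offlist <- decide_transmission(mk_ev(40, 0L, c("TTN", "MUC16")))
  expect_equal(offlist$verdict, "indeterminate")
})

test_that("raising the overlap threshold never flips not_transmitted to transmitted", {
  set.seed(9)
  for (i in 1:25) {
    ev <- list(overlap = list(percent_shared = runif(1, 0, 100)),
               sex_discordant = list(applicable = FALSE, count = NA,
                                     donor_dna_flag = FALSE),
               shared_drivers = character(0))
    verdicts <- vapply(c(20, 50, 80, 95), function(thr) {
      decide_transmission(ev, transmission_thresholds(
        overlap_threshold = thr))$verdict
    }, character(1))
    transitions <- paste(utils::head(verdicts, -1), verdicts[-1])
    expect_false(any(transitions == "not_transmitted transmitted"))
    # once not transmitted under a low threshold, stays so under higher ones
    if (verdicts[1] == "not_transmitted") {
      expect_true(all(verdicts == "not_transmitted"))
    }
  }
})
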