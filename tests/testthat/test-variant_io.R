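test_that("VCF ingestion computes AF from AD, strips chr prefixes, splits multi-allelics", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(c(
    "1\t100\t.\tA\tG\t.\t.\t.\tGT:AD:DP\t0/1:60,40:100",
    "chrY\t2655432\t.\tA\tG\t.\t.\t.\tGT:AD:DP\t0/1:50,50:100",
    "2\t500\t.\tA\tG,T\t.\t.\t.\tGT:AD:DP\t1/2:10,20,30:60"),
    path)
  prof <- read_vcf(path, role = "recipient_tumor")
  expect_s3_class(prof, "sample_profile")
  # multi-allelic record contributes one variant per ALT allele
  expect_equal(n_variants(prof), 4L)
  v <- prof$variants
  site1 <- v[v$chrom == "1" & v$pos == 100, ]
  expect_equal(site1$af, 0.40)
  expect_equal(site1$depth, 100L)
  # prefix stripped, stored under canonical label
  expect_true("Y" %in% v$chrom)
  expect_false(any(grepl("^chr", v$chrom)))
  # split alleles share (chrom, pos, ref) and take their own AD entry
  split <- v[v$chrom == "2", ]
  expect_equal(nrow(split), 2L)
  expect_setequal(split$alt, c("G", "T"))
  expect_equal(sort(split$alt_depth), c(20L, 30L))
})

test_that("records on non-canonical contigs are dropped with a count", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(c(
    "1\t100\t.\tA\tG\t.\t.\t.\tGT:AD:DP\t0/1:60,40:100",
    "MT\t200\t.\tA\tG\t.\t.\t.\tGT:AD:DP\t0/1:60,40:100",
    "GL000220.1\t300\t.\tA\tG\t.\t.\t.\tGT:AD:DP\t0/1:60,40:100"),
    path)
  expect_message(prof <- read_vcf(path), "2 variant")
  expect_equal(n_variants(prof), 1L)
  expect_equal(prof$n_dropped_contigs, 2L)
})

test_that("missing AD and DP leaves the allelic fraction undefined with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf("1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1", path)
  expect_warning(prof <- read_vcf(path), "undefined")
  expect_true(is.na(prof$variants$af))
})

test_that("profiles round-trip through TSV and VCF exactly", {
  cfg <- cohort_config(seed = 11, n_common = 300, n_rare_per_individual = 50,
                       rare_pool_factor = 4)
  set.seed(11)
  catalog <- simulate_catalog(cfg)
  germ <- simulate_germline(catalog, "male", cfg)
  prof <- render_observed_sample(NULL, germ, purity = 0, mean_depth = 80,
                                 sample_id = "G1", role = "recipient_blood",
                                 sex = "male", config = cfg)
  expect_gt(n_variants(prof), 50)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, tsv, "tsv")
  back <- read_profile_tsv(tsv)
  expect_identical(profile_keys(back), profile_keys(prof))
  expect_identical(back$variants$functional_class,
                   prof$variants$functional_class)
  expect_identical(back$variants$depth, prof$variants$depth)
  expect_identical(back$variants$alt_depth, prof$variants$alt_depth)
  expect_equal(back$variants$af_ExAC, prof$variants$af_ExAC)
  expect_identical(back$sample_id, "G1")
  expect_identical(back$role, "recipient_blood")
  expect_identical(back$sex, "male")

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_profile(prof, vcf, "vcf")
  back2 <- read_vcf(vcf, role = "recipient_blood", sex = "male")
  expect_identical(profile_keys(back2), profile_keys(prof))
  expect_identical(back2$variants$functional_class,
                   prof$variants$functional_class)
  expect_identical(back2$variants$depth, prof$variants$depth)
  expect_identical(back2$variants$alt_depth, prof$variants$alt_depth)
})

test_that("an empty profile writes a header-only VCF and an undefined AF writes NA in TSV", {
  empty <- key_profile(0, sample_id = "E")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_profile(empty, vcf, "vcf")
  lines <- readLines(vcf)
  expect_true(all(grepl("^#", lines)))
  expect_equal(n_variants(read_vcf(vcf)), 0L)

  zero <- sample_profile(data.frame(chrom = "1", pos = 1L, ref = "A",
                                    alt = "G", depth = 0L, alt_depth = 0L),
                         "Z")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_profile(zero, tsv, "tsv")
  body <- utils::read.delim(tsv, skip = 3)
  expect_true(is.na(body$af))
})

test_that("profile iteration follows the canonical chromosome/position order", {
  df <- data.frame(chrom = c("X", "2", "chr1", "10", "1", "Y"),
                   pos = c(5L, 9L, 7L, 1L, 2L, 3L),
                   ref = "A", alt = "C", stringsAsFactors = FALSE)
  prof <- sample_profile(df[sample(nrow(df)), ], "ORD")
  expect_identical(prof$variants$chrom, c("1", "1", "2", "10", "X", "Y"))
  expect_identical(prof$variants$pos[1:2], c(2L, 7L))
})

test_that("duplicate keys and invalid alleles are rejected", {
  dup <- data.frame(chrom = c("1", "chr1"), pos = 5L, ref = "A", alt = "G")
  expect_error(sample_profile(dup, "D"), "duplicate")
  expect_error(sample_profile(data.frame(chrom = "1", pos = 5L, ref = "A",
                                         alt = "A"), "D"),
               "differ")
})

test_that("annotation tables validate the class vocabulary and blank cells mean absent", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\tfunctional_class\tgene\tExAC_af\tgnomAD_af",
    "1\t10\tA\tG\tnonsynonymous\tGENE1\t\t0.5",
    paste(paste("2", 10 + seq_along(functional_classes()), "A", "G",
                functional_classes(), "", "0.01", "0.01", sep = "\t"),
          collapse = "\n")), path)
  ann <- read_annotation_table(path)
  expect_equal(nrow(ann), 8L)
  expect_true(is.na(ann$af_ExAC[ann$pos == 10]))      # blank = absent
  expect_equal(ann$af_gnomAD[ann$pos == 10], 0.5)
  expect_setequal(ann$functional_class[ann$chrom == "2"],
                  functional_classes())

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tfunctional_class",
               "1\t10\tA\tG\tmissense"), bad)
  expect_error(read_annotation_table(bad), "missense")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tfunctional_class",
               "1\t10\tA\tG\tnonsynonymous",
               "chr1\t10\tA\tG\tnonsense"), dup)
  expect_error(read_annotation_table(dup), "duplicate")
})

test_that("annotations join onto matching profile variants by identity key", {
  prof <- key_profile(3, sample_id = "A")
  ann <- data.frame(chrom = "1", pos = 2L, ref = "A", alt = "G",
                    functional_class = "nonsense", gene = "TP53",
                    af_ExAC = 0.25, stringsAsFactors = FALSE)
  out <- annotate_profile(prof, ann)
  hit <- out$variants[out$variants$pos == 2L, ]
  expect_equal(hit$functional_class, "nonsense")
  expect_equal(hit$gene, "TP53")
  expect_equal(hit$af_ExAC, 0.25)
  expect_true(all(is.na(out$variants$functional_class[out$variants$pos != 2L])))
})
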