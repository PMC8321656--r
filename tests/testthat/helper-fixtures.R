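# Fixture builders shared across the test files. All fixtures are built in
# code; nothing is read from disk except files the tests themselves write.

# A profile of n distinct SNVs at consecutive positions on one chromosome.
# `common` rows (by index) are flagged as common polymorphisms in two
# databases; others carry no population frequency.
key_profile <- function(n, chrom = "1", offset = 0L, common = integer(0),
                        sample_id = "S", role = "recipient_tumor",
                        sex = "unknown", functional_class = NULL) {
  if (n == 0) {
    return(sample_profile(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), stringsAsFactors = FALSE),
      sample_id, role, sex))
  }
  df <- data.frame(chrom = chrom, pos = offset + seq_len(n), ref = "A",
                   alt = "G", stringsAsFactors = FALSE)
  if (!is.null(functional_class)) df$functional_class <- functional_class
  df$af_1000G <- NA_real_
  df$af_gnomAD <- NA_real_
  df$af_1000G[common] <- 0.2
  df$af_gnomAD[common] <- 0.2
  sample_profile(df, sample_id, role, sex)
}

# Random annotated profile for property tests: random keys, classes and
# database frequencies (each database present with probability p_present).
random_profile <- function(n, seed, sample_id = "R", p_present = 0.5) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chrom <- sample(c(as.character(1:22), "X", "Y"), n, replace = TRUE)
  pos <- sample.int(5e7, n)
  df <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(chrom, pos)), , drop = FALSE]
  m <- nrow(df)
  ref_i <- sample.int(4, m, replace = TRUE)
  df$ref <- bases[ref_i]
  df$alt <- bases[((ref_i - 1 + sample.int(3, m, replace = TRUE)) %% 4) + 1]
  df$functional_class <- sample(functional_classes(), m, replace = TRUE)
  df$depth <- rpois(m, 150)
  df$alt_depth <- rbinom(m, df$depth, 0.4)
  for (db in population_databases()) {
    f <- 10^runif(m, -6, -0.4)  # frequencies spanning rare to common
    f[runif(m) > p_present] <- NA
    df[[paste0("af_", db)]] <- f
  }
  sample_profile(df, sample_id)
}

# Scaled-down cohort configuration for simulation loops. Small catalog and
# clone sizes keep a full simulate + pipeline round under ~0.5 s while
# preserving the structure of the default cohort.
small_cohort_config <- function(seed, transmitted = TRUE, ...) {
  cohort_config(
    seed = seed,
    n_common = 2000L, n_rare_per_individual = 200L, rare_pool_factor = 8L,
    clones = list(
      clone_spec("truncal", 1, 60, default_clones()[[1]]$drivers),
      clone_spec("pik3ca_subclone", 0.3, 20, default_clones()[[2]]$drivers)),
    samples = default_samples(transmitted),
    post_transplant_private_count = 40L,
    ...)
}

# write a small VCF from raw lines (header prepended)
write_test_vcf <- function(body_lines, path,
                           sample = "S1",
                           extra_header = character(0)) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    extra_header,
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  writeLines(c(header, body_lines), path)
  path
}
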