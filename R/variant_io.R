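# Reading and writing the formats the pipeline touches: single-sample VCF
# v4.2 (FORMAT AD/DP), annotation TSV sidecars, profile TSVs, and MLPA probe
# tables. VCF parsing is delegated to vcfR; writing serializes our own
# records so that read(write(p)) round-trips exactly.

# default INFO keys carrying population frequencies and annotations
#' @keywords internal
default_info_keys <- function() {
  c(`1000G` = "AF_1000G", HapMap = "AF_HAPMAP", dbSNP = "AF_DBSNP",
    ExAC = "AF_EXAC", gnomAD = "AF_GNOMAD")
}

#' Read a single-sample VCF into a sample profile
#'
#' Reads a VCF v4.2 with one genotype column carrying `AD` (allelic depths)
#' and/or `DP`. Multi-allelic records are split into one observed variant per
#' ALT allele; `chr` prefixes are stripped; records on non-canonical contigs
#' are dropped with a logged count. Population frequencies are picked up from
#' INFO keys (configurable), functional class and gene from INFO keys
#' `FCLASS`/`GENE` when present.
#'
#' @param path VCF file path.
#' @param sample_id sample name; defaults to the VCF genotype column name.
#' @param role,sex sample metadata (see [sample_profile()]).
#' @param info_freq_keys named character vector mapping database name to the
#'   INFO key carrying its allele frequency.
#' @return a `sample_profile`.
#' @export
read_vcf <- function(path, sample_id = NULL, role = "recipient_tumor",
                     sex = "unknown", info_freq_keys = default_info_keys()) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  fixm <- vcfR::getFIX(vcf)
  if (is.null(dim(fixm))) {  # single-record VCFs come back as a bare vector
    fixm <- matrix(fixm, nrow = 1, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(sample_profile(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), stringsAsFactors = FALSE),
      sample_id = sample_id %||% "sample", role = role, sex = sex))
  }
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2) stop("VCF '", path, "' has no sample column")
  if (is.null(sample_id)) sample_id <- colnames(gt)[2]
  fmt <- strsplit(gt[, 1], ":", fixed = TRUE)
  smp <- strsplit(gt[, 2], ":", fixed = TRUE)
  field <- function(i, name) {
    j <- match(name, fmt[[i]])
    if (is.na(j) || j > length(smp[[i]])) NA_character_ else smp[[i]][j]
  }
  n <- nrow(fix)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- rep.int(seq_len(n), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  ad_raw <- vapply(seq_len(n), field, character(1), name = "AD")
  dp_raw <- vapply(seq_len(n), field, character(1), name = "DP")
  ad <- strsplit(ad_raw, ",", fixed = TRUE)
  alt_depth <- mapply(function(i, k) {
    a <- ad[[i]]
    if (length(a) >= k + 1 && !is.na(a[1])) suppressWarnings(as.integer(a[k + 1]))
    else NA_integer_
  }, rec, alt_idx)
  depth <- suppressWarnings(as.integer(dp_raw))[rec]
  ad_total <- vapply(ad, function(a) {
    if (length(a) && !anyNA(a)) suppressWarnings(sum(as.integer(a))) else NA_integer_
  }, integer(1))[rec]
  depth[is.na(depth)] <- ad_total[is.na(depth)]
  n_undefined <- sum(is.na(depth) | is.na(alt_depth))
  if (n_undefined > 0) {
    warning(n_undefined, " record(s) in '", path,
            "' lack AD/DP; allelic fraction left undefined")
  }

  out <- data.frame(chrom = fix$CHROM[rec], pos = as.integer(fix$POS)[rec],
                    ref = fix$REF[rec],
                    alt = unlist(alts, use.names = FALSE),
                    depth = depth, alt_depth = alt_depth,
                    stringsAsFactors = FALSE)
  info_chr <- function(key) {
    val <- tryCatch(vcfR::extract.info(vcf, element = key),
                    error = function(e) rep(NA_character_, n))
    if (is.null(val)) rep(NA_character_, n) else val
  }
  for (db in names(info_freq_keys)) {
    out[[db_column(db)]] <- suppressWarnings(
      as.numeric(info_chr(info_freq_keys[[db]]))[rec])
  }
  fclass <- info_chr("FCLASS")[rec]
  gene <- info_chr("GENE")[rec]
  if (!all(is.na(fclass))) out$functional_class <- fclass
  if (!all(is.na(gene))) out$gene <- ifelse(gene == ".", NA_character_, gene)
  sample_profile(out, sample_id = sample_id, role = role, sex = sex)
}

#' Read an annotation table
#'
#' TSV sidecar with columns `chrom`, `pos`, `ref`, `alt`, `functional_class`,
#' `gene`, and per-database frequency columns `1000G_af`, `HapMap_af`,
#' `dbSNP_af`, `ExAC_af`, `gnomAD_af`. Empty frequency cells mean "not
#' observed in that database". Unknown columns are ignored.
#'
#' @param path TSV file path.
#' @return data.frame of annotated variants keyed by (chrom, pos, ref, alt).
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  req <- c("chrom", "pos", "ref", "alt", "functional_class")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("annotation table missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- which(!(tab$functional_class %in% functional_classes()))
  if (length(bad)) {
    stop("unknown functional_class '", tab$functional_class[bad[1]],
         "' in row ", bad[1], " of ", path)
  }
  out <- data.frame(chrom = normalize_chrom(tab$chrom),
                    pos = as.integer(tab$pos),
                    ref = toupper(tab$ref), alt = toupper(tab$alt),
                    functional_class = tab$functional_class,
                    gene = if (is.null(tab$gene)) NA_character_ else tab$gene,
                    stringsAsFactors = FALSE)
  for (db in population_databases()) {
    src <- paste0(db, "_af")
    out[[db_column(db)]] <- if (is.null(tab[[src]])) NA_real_ else
      as.numeric(tab[[src]])
  }
  key <- variant_key(out)
  if (anyDuplicated(key)) {
    stop("duplicate variant key in annotation table: ",
         key[duplicated(key)][1])
  }
  out
}

#' Write a sample profile
#'
#' `tsv` writes the full observed-variant table with `#sample_id=`, `#role=`
#' and `#sex=` header comment lines (undefined allelic fractions become
#' `NA`). `vcf` writes a VCF v4.2 with FORMAT `GT:AD:DP` and INFO keys for
#' population frequencies, functional class and gene, so that a profile
#' round-trips through [read_vcf()] exactly (keys, classes, depths).
#'
#' @param profile a `sample_profile`.
#' @param path output file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return invisibly, `path`.
#' @export
write_profile <- function(profile, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  v <- profile$variants
  if (format == "tsv") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(c(paste0("#sample_id=", profile$sample_id),
                 paste0("#role=", profile$role),
                 paste0("#sex=", profile$sex)), con)
    utils::write.table(v, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    return(invisible(path))
  }
  keys <- default_info_keys()
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=graftrace",
    vapply(names(keys), function(db) sprintf(
      '##INFO=<ID=%s,Number=A,Type=Float,Description="%s allele frequency">',
      keys[[db]], db), character(1)),
    '##INFO=<ID=FCLASS,Number=A,Type=String,Description="Functional class">',
    '##INFO=<ID=GENE,Number=A,Type=String,Description="Gene symbol">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           profile$sample_id))
  lines <- hdr
  if (nrow(v)) {
    info <- vapply(seq_len(nrow(v)), function(i) {
      parts <- character(0)
      for (db in names(keys)) {
        f <- v[[db_column(db)]][i]
        if (!is.na(f)) parts <- c(parts, paste0(keys[[db]], "=", format(f, scientific = FALSE, trim = TRUE, digits = 15)))
      }
      if (!is.na(v$functional_class[i])) {
        parts <- c(parts, paste0("FCLASS=", v$functional_class[i]))
      }
      if (!is.na(v$gene[i])) parts <- c(parts, paste0("GENE=", v$gene[i]))
      if (length(parts)) paste(parts, collapse = ";") else "."
    }, character(1))
    dp <- ifelse(is.na(v$depth), ".", v$depth)
    ad <- ifelse(is.na(v$depth) | is.na(v$alt_depth), ".",
                 paste0(pmax(v$depth - v$alt_depth, 0L), ",", v$alt_depth))
    lines <- c(lines, paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", ".",
                            info, "GT:AD:DP",
                            paste0("0/1:", ad, ":", dp), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a profile TSV written by [write_profile()]
#'
#' @param path TSV file path.
#' @return a `sample_profile`.
#' @export
read_profile_tsv <- function(path) {
  head_lines <- readLines(path, n = 10)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  meta <- function(name, default) {
    hit <- grep(paste0("^#", name, "="), meta_lines, value = TRUE)
    if (length(hit)) sub(paste0("^#", name, "="), "", hit[1]) else default
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           skip = length(meta_lines), na.strings = "NA",
                           check.names = FALSE)
  sample_profile(tab, sample_id = meta("sample_id", basename(path)),
                 role = meta("role", "recipient_tumor"),
                 sex = meta("sex", "unknown"))
}

#' Read an MLPA probe peak table
#'
#' TSV with columns `probe_id`, `chrom`, `pos`, `gene`, `peak_height`.
#'
#' @param path TSV file path.
#' @return data.frame of probe peaks.
#' @export
read_mlpa_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("probe_id", "chrom", "pos", "gene")
  miss <- setdiff(req, names(tab))
  if (length(miss) || !any(c("peak_height", "ratio") %in% names(tab))) {
    stop("MLPA table missing columns: ",
         paste(c(miss, "peak_height or ratio"), collapse = ", "))
  }
  tab$chrom <- normalize_chrom(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  if (!is.null(tab$peak_height)) tab$peak_height <- as.numeric(tab$peak_height)
  if (!is.null(tab$ratio)) tab$ratio <- as.numeric(tab$ratio)
  tab
}

#' Write an MLPA probe peak table
#' @param probes data.frame of probe peaks.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_mlpa_table <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
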