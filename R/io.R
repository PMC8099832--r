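#' Table schemas used by the pipeline
#'
#' Named lists of required columns and their types for each interchange
#' table. Types are `"character"`, `"double"`, `"integer"`, `"logical"` or
#' `"date"`.
#'
#' @format A named list of named character vectors.
#' @export
mito_schemas <- list(
  intensities = c(sample_id = "character", probe_id = "character",
                  panel = "character", l2r = "double"),
  coverage = c(sample_id = "character", normalized_mt_coverage = "double"),
  phenotypes = c(sample_id = "character"),
  events = c(sample_id = "character", code = "character",
             event_date = "date"),
  phecode_map = c(code = "character", phecode = "double",
                  excl_low = "double", excl_high = "double"),
  probe_weights = c(probe_id = "character", weight = "double",
                    p_value = "double", selected = "logical"),
  baf = c(sample_id = "character", pos = "double", baf = "double",
          hap_a_alt = "logical")
)

schema_col <- function(type) {
  switch(type,
         character = readr::col_character(),
         double = readr::col_double(),
         integer = readr::col_integer(),
         logical = readr::col_logical(),
         date = readr::col_date(),
         abort(sprintf("unknown schema type `%s`.", type)))
}

#' Read and validate a TSV table
#'
#' Reads a tab-separated table with header, coerces the schema columns to
#' their declared types, and treats empty strings and `"NA"` as missing.
#' Extra columns are tolerated (and mentioned); a missing required column
#' or an unparseable cell is an error naming the column / row.
#'
#' @param path File path.
#' @param schema A named character vector of column types, or the name of
#'   an entry of [mito_schemas].
#' @return A tibble with typed columns.
#' @export
read_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1 && is.null(names(schema))) {
    if (!schema %in% names(mito_schemas)) {
      abort(sprintf("unknown schema `%s`.", schema))
    }
    schema <- mito_schemas[[schema]]
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  hdr <- names(readr::read_tsv(path, n_max = 0, col_types = readr::cols(),
                               show_col_types = FALSE))
  missing_cols <- setdiff(names(schema), hdr)
  if (length(missing_cols)) {
    abort(sprintf("%s is missing required column(s): %s",
                  basename(path), paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(hdr, names(schema))
  if (length(extra)) {
    inform(sprintf("%s: %d extra column(s) tolerated (%s%s).",
                   basename(path), length(extra),
                   paste(head(extra, 5), collapse = ", "),
                   if (length(extra) > 5) ", ..." else ""))
  }
  ct <- do.call(readr::cols,
                c(lapply(schema, schema_col), .default = readr::col_guess()))
  tb <- suppressWarnings(readr::read_tsv(path, col_types = ct, na = c("", "NA"),
                                         show_col_types = FALSE))
  pb <- readr::problems(tb)
  if (nrow(pb)) {
    abort(sprintf("unparseable cell in %s at file line %d (expected %s).",
                  basename(path), pb$row[1], pb$expected[1]))
  }
  inform(sprintf("%s: read %d rows.", basename(path), nrow(tb)))
  tb
}

#' Write a TSV table
#'
#' @param x A data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Write genotypes as a minimal VCF 4.2
#'
#' Emits one record per variant with `GT` (hard calls rounded from dosage)
#' and `DS` (dosage) FORMAT fields. Reference/alternate alleles are
#' placeholders (`A`/`G`) since only dosages are consumed downstream.
#'
#' @param genotypes List with a `variants` tibble (`variant_id, chrom,
#'   pos`) and a samples-by-variants `dosages` matrix.
#' @param path Destination path (plain text).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  d <- genotypes$dosages
  samples <- rownames(d) %||% sprintf("S%06d", seq_len(nrow(d)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    ds <- d[, j]
    hard <- round(ds)
    cells <- ifelse(is.na(ds), "./.:.",
                    paste0(gt_code[hard + 1], ":", format(ds, trim = TRUE)))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], "A", "G", ".",
                       "PASS", ".", "GT:DS", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a dosage matrix from a VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise counts alternate
#' alleles in `GT`.
#'
#' @param path VCF path.
#' @return List with `variants` (tibble `variant_id, chrom, pos`) and
#'   `dosages` (samples-by-variants matrix, `NA` for missing).
#' @export
read_dosages_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf)
  fmt <- unique(vcf@gt[, "FORMAT"])
  if (any(grepl("DS", fmt))) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || g %in% c("./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
  }
  vid <- fx[, "ID"]
  vid[is.na(vid)] <- sprintf("var%04d", which(is.na(vid)))
  rownames(ds) <- vid
  list(
    variants = tibble(variant_id = vid,
                      chrom = as.character(fx[, "CHROM"]),
                      pos = as.numeric(fx[, "POS"])),
    dosages = t(ds)
  )
}
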