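#' Variant record tables
#'
#' Throughout the package a cohort of annotated somatic mutations is a tibble
#' with one row per mutation call in one sample. Coordinates are 1-based
#' inclusive (VCF convention). Columns:
#'
#' * `sample_id`, `patient_id`, `group` — sample identity; `group` is one of
#'   `"CASE"`/`"CONTROL"`. `patient_id` may differ from `sample_id` when one
#'   patient contributed several samples.
#' * `chrom`, `pos` — 1-based position of the first affected base.
#' * `ref`, `alt` — allele strings over A/C/G/T; `ref` may be `""` for a pure
#'   insertion.
#' * `gene`, `transcript` — annotation symbols; gene symbols are matched
#'   case-insensitively everywhere.
#' * `hgvs_c`, `hgvs_p` — HGVS coding/protein notation (optional).
#' * `dbsnp_id` — rs identifier; a non-empty value marks a catalogued
#'   polymorphism, `NA` marks a novel call. No external lookup is ever done.
#' * `pop_af` — population allele frequency in `[0, 1]` (optional).
#' * `tri_context` — 3-mer centred on `pos`, middle base equal to `ref` for
#'   substitutions (optional).
#' * `consequence` — precomputed consequence class (optional; see
#'   [classify_variants()]).
#'
#' @name variant_table
NULL

VARIANT_COLS <- c(
  "sample_id", "patient_id", "group", "chrom", "pos", "ref", "alt",
  "gene", "transcript", "hgvs_c", "hgvs_p", "dbsnp_id", "pop_af",
  "tri_context", "consequence"
)

VARIANT_REQUIRED <- c("sample_id", "chrom", "pos", "ref", "alt", "gene")

#' Construct a sample sheet for a two-cohort study
#'
#' @param sample_id character; unique sample identifiers.
#' @param group character; `"CASE"` or `"CONTROL"` per sample.
#' @param patient_id character; defaults to `sample_id`. Several samples may
#'   share a patient (e.g. resections of one patient at different times).
#' @return a tibble with columns `sample_id`, `patient_id`, `group`.
#' @examples
#' sample_sheet(c("S1", "S2", "S3"), c("CASE", "CASE", "CONTROL"))
#' @export
sample_sheet <- function(sample_id, group, patient_id = sample_id) {
  group <- toupper(group)
  if (!all(group %in% c("CASE", "CONTROL"))) {
    abort("sample_sheet(): group must be 'CASE' or 'CONTROL'")
  }
  if (anyDuplicated(sample_id)) {
    abort("sample_sheet(): duplicated sample_id")
  }
  tibble::tibble(
    sample_id = as.character(sample_id),
    patient_id = as.character(patient_id),
    group = group
  )
}

## Coerce a data frame of variant rows to the canonical column set/types.
## Missing optional columns are added as NA; unknown columns are kept.
as_variant_tbl <- function(df) {
  df <- tibble::as_tibble(df)
  missing_req <- setdiff(VARIANT_REQUIRED, names(df))
  if (length(missing_req)) {
    abort(sprintf(
      "variant table is missing required column(s): %s",
      paste(missing_req, collapse = ", ")
    ))
  }
  for (col in setdiff(VARIANT_COLS, names(df))) {
    df[[col]] <- if (col == "pop_af") NA_real_ else NA_character_
  }
  if (all(is.na(df$patient_id))) df$patient_id <- df$sample_id
  df$pos <- as.integer(df$pos)
  df$pop_af <- as.double(df$pop_af)
  chr_cols <- setdiff(VARIANT_COLS, c("pos", "pop_af"))
  for (col in chr_cols) df[[col]] <- as.character(df[[col]])
  df$ref[is.na(df$ref)] <- ""
  df$gene <- toupper(trimws(df$gene))
  dplyr::relocate(df, dplyr::all_of(VARIANT_COLS))
}

#' Read an annotated variant table
#'
#' Reads a tab-separated table with at least the columns `sample_id`, `chrom`,
#' `pos`, `ref`, `alt`, `gene`; the optional columns of [variant_table] may be
#' present in any order. Each record's `group` and `patient_id` are resolved
#' from the sample sheet, so every returned row carries a cohort label.
#'
#' @param path path to a tab-separated file with a header row.
#' @param samples a sample sheet from [sample_sheet()].
#' @return a variant tibble (see [variant_table]).
#' @export
read_variant_table <- function(path, samples) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  missing_req <- setdiff(VARIANT_REQUIRED, names(raw))
  if (length(missing_req)) {
    abort(sprintf(
      "%s: missing required column(s): %s",
      path, paste(missing_req, collapse = ", ")
    ))
  }
  ## empty cells in optional columns mean "unset"
  for (col in setdiff(names(raw), "ref")) {
    raw[[col]][raw[[col]] == ""] <- NA_character_
  }
  if (nrow(raw)) {
    bad_pos <- which(is.na(suppressWarnings(as.integer(raw$pos))))
    if (length(bad_pos)) {
      abort(sprintf(
        "%s: non-integer pos at data line %s (value '%s')",
        path, bad_pos[1], raw$pos[bad_pos[1]]
      ))
    }
    unknown <- which(!raw$sample_id %in% samples$sample_id)
    if (length(unknown)) {
      abort(sprintf(
        "%s: unknown sample_id '%s' at data line %s",
        path, raw$sample_id[unknown[1]], unknown[1]
      ))
    }
  }
  raw$patient_id <- NULL
  raw$group <- NULL
  out <- dplyr::left_join(raw, samples, by = "sample_id")
  as_variant_tbl(out)
}

#' Read a minimal VCF into the variant table schema
#'
#' A deliberately small VCF 4.x reader: it uses only the mandatory CHROM, POS,
#' ID, REF, ALT columns plus the INFO keys named in `info_keys`. Multiallelic
#' rows are split into one record per ALT allele; an ID of `"."` marks a novel
#' variant (`dbsnp_id` unset).
#'
#' @param path path to an uncompressed VCF file.
#' @param sample_id sample identifier to stamp on every record.
#' @param info_keys named character vector mapping variant-table fields onto
#'   INFO keys, e.g. `c(gene = "GENE", hgvs_c = "HGVSC", pop_af = "AF")`.
#'   Recognized names: `gene`, `transcript`, `hgvs_c`, `hgvs_p`, `pop_af`,
#'   `tri_context`.
#' @return a variant tibble (without `group`; resolve via a sample sheet or
#'   [as_cohort()]).
#' @export
read_vcf_lite <- function(path, sample_id,
                          info_keys = c(gene = "GENE")) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) abort(sprintf("%s: no #CHROM header line", path))
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t", fixed = TRUE)[[1]]
  need <- c("CHROM", "POS", "ID", "REF", "ALT")
  if (!all(need %in% cols)) {
    abort(sprintf(
      "%s: missing mandatory VCF column(s): %s",
      path, paste(setdiff(need, cols), collapse = ", ")
    ))
  }
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  if (!length(body)) {
    return(as_variant_tbl(tibble::tibble(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), gene = character()
    )))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  get <- function(name) {
    i <- match(name, cols)
    vapply(fields, function(f) f[[i]], character(1))
  }
  info_raw <- if ("INFO" %in% cols) get("INFO") else rep(".", length(body))
  info_value <- function(key) {
    padded <- paste0(";", info_raw)
    m <- regexpr(paste0(";", key, "=[^;]*"), padded, fixed = FALSE)
    out <- rep(NA_character_, length(padded))
    hit <- m > 0
    out[hit] <- sub(paste0("^;", key, "="), "", regmatches(padded, m))
    out
  }
  rec <- tibble::tibble(
    sample_id = sample_id,
    chrom = get("CHROM"),
    pos = as.integer(get("POS")),
    ref = get("REF"),
    alt = get("ALT"),
    dbsnp_id = dplyr::na_if(get("ID"), "."),
    gene = NA_character_
  )
  for (field in intersect(
    names(info_keys),
    c("gene", "transcript", "hgvs_c", "hgvs_p", "pop_af", "tri_context")
  )) {
    rec[[field]] <- info_value(info_keys[[field]])
  }
  if ("pop_af" %in% names(rec)) rec$pop_af <- as.double(rec$pop_af)
  ## split multiallelic rows: one record per ALT allele
  rec <- tidyr::separate_rows(rec, "alt", sep = ",")
  rec$gene[is.na(rec$gene)] <- ""
  as_variant_tbl(rec)
}

#' Attach cohort labels to variant records
#'
#' @param records a variant tibble.
#' @param samples a sample sheet from [sample_sheet()].
#' @return `records` with `group` and `patient_id` resolved from `samples`.
#' @export
as_cohort <- function(records, samples) {
  unknown <- setdiff(unique(records$sample_id), samples$sample_id)
  if (length(unknown)) {
    abort(sprintf(
      "as_cohort(): sample_id not in sample sheet: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  records$group <- NULL
  records$patient_id <- NULL
  as_variant_tbl(dplyr::left_join(records, samples, by = "sample_id"))
}

#' Read a gene list
#'
#' One symbol per line; `#` starts a comment; blank lines ignored. Symbols are
#' trimmed, upper-cased and deduplicated, so matching against them is
#' case-insensitive.
#'
#' @param path path to a plain-text gene list.
#' @param name provenance label (e.g. `"driver_catalog"`).
#' @return a [gene_set()]: sorted unique character vector with a `name`
#'   attribute. An empty file yields an empty set with a warning.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warn(sprintf("gene list '%s' is empty", path))
  }
  gene_set(lines, name = name)
}

#' Construct a gene set
#'
#' @param symbols character vector of gene symbols (any case).
#' @param name provenance label.
#' @return sorted, unique, upper-cased character vector with attribute `name`.
#' @examples
#' gene_set(c("TP53", "tp53", "KDM6A"), name = "demo")
#' @export
gene_set <- function(symbols, name = "gene_set") {
  out <- sort(unique(toupper(trimws(as.character(symbols)))))
  out <- out[nzchar(out)]
  attr(out, "name") <- name
  out
}

#' Write a tabular result as tab-separated text
#'
#' Unset (`NA`) cells are written empty; [read_variant_table()] restores them
#' as unset, so variant tables round-trip field-by-field.
#'
#' @param x a data frame.
#' @param path output path.
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "", progress = FALSE)
  invisible(x)
}
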