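# Domain tables: variant observations, gene metadata, control counts.
#
# The pipeline is tabular throughout: one VariantObservation is one row of a
# tibble (one carrier x variant observation), gene metadata is one row per
# gene, and the gnomAD-like control table is one row per gene. Readers
# validate invariants up front so downstream stages can assume clean input.

# Canonical variant-table columns, in their fixed output order.
VARIANT_COLUMNS <- c(
  "participant_id", "disease", "gene", "transcript", "hgvs_c",
  "chrom", "pos", "ref", "alt", "consequence_annotation",
  "af_overall", "af_afr", "af_eas", "af_amr", "af_nfe", "af_sas",
  "allele_count_controls", "exon_boundary_distance",
  "mes_ref", "mes_alt", "mes_delta", "ada", "rf", "spliceai",
  "proband_count", "informative_meioses",
  "functional_kind", "functional_length_nt",
  "sequencing_mode", "minor_intron"
)

VARIANT_NUMERIC <- c(
  "pos", "af_overall", "af_afr", "af_eas", "af_amr", "af_nfe", "af_sas",
  "allele_count_controls", "exon_boundary_distance",
  "mes_ref", "mes_alt", "mes_delta", "ada", "rf",
  "spliceai", "proband_count", "informative_meioses", "functional_length_nt"
)

# Columns a table must carry; everything else may be absent and is filled
# with NA so missingness is explicit, never coerced to 0.
VARIANT_MANDATORY <- c("participant_id", "disease", "gene", "transcript", "hgvs_c")

HI_SCORES <- c("3", "2", "1", "not_curated")

#' Construct a variant-observation tibble
#'
#' Builds the canonical one-row-per-carrier-observation table used by every
#' pipeline stage, filling unspecified columns with `NA` and validating the
#' field invariants (allele frequencies in \[0, 1\], non-negative counts,
#' known disease labels, `mes_delta = mes_alt - mes_ref` when all three are
#' present).
#'
#' @param ... Vectors for any subset of the canonical columns (see
#'   [read_variant_table()] for the full list). `participant_id`, `disease`,
#'   `gene`, `transcript` and `hgvs_c` are mandatory.
#' @return A validated tibble with all canonical columns.
#' @export
#' @examples
#' variant_table(
#'   participant_id = "P1", disease = "LQTS", gene = "KCNQ1",
#'   transcript = "NM_000218.3", hgvs_c = "c.477+5G>A",
#'   mes_delta = -5.37, ada = 0.99, rf = 0.97, spliceai = 0.23
#' )
variant_table <- function(...) {
  df <- tibble::tibble(...)
  unknown <- setdiff(names(df), VARIANT_COLUMNS)
  if (length(unknown) > 0) {
    stop("unknown variant-table column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_mand <- setdiff(VARIANT_MANDATORY, names(df))
  if (length(missing_mand) > 0 && nrow(df) > 0) {
    stop("missing mandatory column(s): ", paste(missing_mand, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(VARIANT_COLUMNS, names(df))) {
    df[[col]] <- if (col %in% VARIANT_NUMERIC) NA_real_
                 else if (col == "minor_intron") NA
                 else NA_character_
  }
  df <- df[, VARIANT_COLUMNS, drop = FALSE]
  df[VARIANT_NUMERIC] <- lapply(df[VARIANT_NUMERIC], as.numeric)
  # AT/AC minor-intron status is an annotation flag only; no scoring rule
  # consumes it (prediction tools are trained on the major GT/AG spliceosome)
  df$minor_intron <- as.logical(df$minor_intron)
  validate_variant_table(df)
}

#' @rdname variant_table
#' @param df A data frame holding (at least) the mandatory variant columns.
#' @export
validate_variant_table <- function(df) {
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0) {
    return(df)
  }
  row_fail <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad) > 0) {
      stop(sprintf("variant table row %d: %s", bad[1], what), call. = FALSE)
    }
  }
  row_fail(!is.na(df$disease) & df$disease %in% DISEASES,
           "disease must be one of " %+% paste(DISEASES, collapse = "/"))
  row_fail(!is.na(df$gene) & nzchar(df$gene), "gene symbol is empty")
  row_fail(!is.na(df$hgvs_c) & nzchar(df$hgvs_c), "hgvs_c is empty")
  row_fail(is.na(df$pos) | df$pos >= 1, "pos must be >= 1")
  for (col in c("af_overall", "af_afr", "af_eas", "af_amr", "af_nfe", "af_sas")) {
    row_fail(is.na(df[[col]]) | (df[[col]] >= 0 & df[[col]] <= 1),
             sprintf("%s outside [0, 1]", col))
  }
  for (col in c("ada", "rf", "spliceai")) {
    row_fail(is.na(df[[col]]) | (df[[col]] >= 0 & df[[col]] <= 1),
             sprintf("%s outside [0, 1]", col))
  }
  for (col in c("allele_count_controls", "proband_count", "informative_meioses",
                "functional_length_nt")) {
    row_fail(is.na(df[[col]]) | df[[col]] >= 0,
             sprintf("%s must be non-negative", col))
  }
  all3 <- !is.na(df$mes_ref) & !is.na(df$mes_alt) & !is.na(df$mes_delta)
  row_fail(!all3 | abs(df$mes_delta - (df$mes_alt - df$mes_ref)) <= 1e-9,
           "mes_delta inconsistent with mes_alt - mes_ref")
  row_fail(is.na(df$functional_kind) | df$functional_kind %in% FUNCTIONAL_KINDS,
           "unknown functional_kind")
  row_fail(is.na(df$functional_kind) |
             !(df$functional_kind %in% LENGTH_CHANGING_KINDS) |
             !is.na(df$functional_length_nt),
           "length-changing functional_kind without functional_length_nt")
  row_fail(is.na(df$sequencing_mode) | df$sequencing_mode %in% SEQ_MODES,
           "unknown sequencing_mode")
  df
}

`%+%` <- function(a, b) paste0(a, b)

#' Read a variant table from TSV
#'
#' Reads a tab-delimited table of carrier x variant observations. A dialect
#' (column-mapping) file lets the same reader ingest tables with foreign
#' headers: each line maps `canonical_name=file_column`. Missing scores and
#' frequencies stay `NA`; they are never coerced to 0.
#'
#' @param path Path to the TSV file.
#' @param dialect Optional path to a `key=value` mapping file, or a named
#'   character vector mapping canonical column names to file column names.
#' @return A validated variant tibble (see [variant_table()]).
#' @export
read_variant_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  map <- read_dialect(dialect)
  for (canon in names(map)) {
    from <- map[[canon]]
    if (!from %in% names(raw)) {
      stop("dialect maps '", canon, "' to missing column '", from, "'",
           call. = FALSE)
    }
    names(raw)[names(raw) == from] <- canon
  }
  raw <- raw[, intersect(names(raw), VARIANT_COLUMNS), drop = FALSE]
  missing_mand <- setdiff(VARIANT_MANDATORY, names(raw))
  if (length(missing_mand) > 0) {
    stop("missing mandatory column(s): ", paste(missing_mand, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(VARIANT_NUMERIC, names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & raw[[col]] != "NA" & is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("row %d: malformed numeric value '%s' in column %s",
                   bad[1], raw[[col]][bad[1]], col), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  do.call(variant_table, as.list(raw))
}

read_dialect <- function(dialect) {
  if (is.null(dialect)) return(character(0))
  if (is.character(dialect) && length(dialect) == 1 && file.exists(dialect)) {
    lines <- readLines(dialect, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- lengths(kv) != 2
    if (any(bad)) stop("malformed dialect line: ", lines[which(bad)[1]], call. = FALSE)
    return(setNames(trimws(vapply(kv, `[`, "", 2)),
                    trimws(vapply(kv, `[`, "", 1))))
  }
  if (!is.character(dialect) || is.null(names(dialect))) {
    stop("dialect must be a file path or a named character vector", call. = FALSE)
  }
  dialect
}

#' Write a variant table to TSV
#'
#' Round-trip companion of [read_variant_table()]: column order is canonical
#' and `NA` is written literally so that read-write-read is lossless.
#'
#' @param df A variant tibble.
#' @param path Output path.
#' @export
write_variant_table <- function(df, path) {
  readr::write_tsv(df[, VARIANT_COLUMNS, drop = FALSE], path, na = "NA",
                   progress = FALSE)
  invisible(path)
}

#' Gene metadata: disease validity, LoF mechanism and control denominators
#'
#' One row per gene: the set of diseases for which the gene is definitively
#' disease-associated (semicolon-separated), whether loss-of-function is an
#' established disease mechanism, the ClinGen dosage haploinsufficiency score
#' (3/2/1/not_curated), the gnomAD LoF observed/expected ratio, and the mean
#' number of sequenced control individuals for the gene (the coverage-adjusted
#' burden-test denominator).
#'
#' @param gene,definitive_for,lof_mechanism,haploinsufficiency_score,lof_oe,mean_sequenced_controls,is_ttn
#'   Vectors of equal length; see Details.
#' @return A validated gene-metadata tibble.
#' @export
gene_meta_table <- function(gene, definitive_for, lof_mechanism,
                            haploinsufficiency_score = "not_curated",
                            lof_oe = NA_real_,
                            mean_sequenced_controls = 1e5,
                            is_ttn = gene == "TTN") {
  df <- tibble::tibble(
    gene = as.character(gene),
    definitive_for = as.character(definitive_for),
    lof_mechanism = as.logical(lof_mechanism),
    haploinsufficiency_score = as.character(haploinsufficiency_score),
    lof_oe = as.numeric(lof_oe),
    mean_sequenced_controls = as.numeric(mean_sequenced_controls),
    is_ttn = as.logical(is_ttn)
  )
  validate_gene_meta(df)
}

validate_gene_meta <- function(df) {
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0) return(df)
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup) > 0) {
    stop("duplicate gene symbol(s) in gene metadata: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad <- !df$haploinsufficiency_score %in% HI_SCORES
  if (any(bad)) {
    stop("haploinsufficiency_score must be one of ",
         paste(HI_SCORES, collapse = "/"), " (gene ",
         df$gene[which(bad)[1]], ")", call. = FALSE)
  }
  if (any(!is.na(df$mean_sequenced_controls) & df$mean_sequenced_controls <= 0)) {
    stop("mean_sequenced_controls must be positive", call. = FALSE)
  }
  if (any(!is.na(df$lof_oe) & df$lof_oe < 0)) {
    stop("lof_oe must be >= 0", call. = FALSE)
  }
  known <- df$definitive_for == "" |
    vapply(strsplit(df$definitive_for, ";", fixed = TRUE),
           function(x) all(x %in% DISEASES), TRUE)
  if (any(!known)) {
    stop("unknown disease in definitive_for for gene ",
         df$gene[which(!known)[1]], call. = FALSE)
  }
  df
}

#' Read gene metadata from TSV
#'
#' @param path Path to a TSV with columns `gene`, `definitive_for`
#'   (semicolon-separated disease labels), `lof_mechanism`,
#'   `haploinsufficiency_score`, `lof_oe`, `mean_sequenced_controls`, `is_ttn`.
#' @return A gene-metadata tibble keyed by gene (duplicates rejected).
#' @export
read_gene_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    definitive_for = readr::col_character(),
    lof_mechanism = readr::col_logical(),
    haploinsufficiency_score = readr::col_character(),
    lof_oe = readr::col_double(),
    mean_sequenced_controls = readr::col_double(),
    is_ttn = readr::col_logical()
  ), progress = FALSE)
  df$definitive_for[is.na(df$definitive_for)] <- ""
  validate_gene_meta(df)
}

#' Read a gnomAD-like control count table from TSV
#'
#' @param path TSV with columns `gene`, `qualifying_allele_count` (rare
#'   qualifying splice-variant alleles observed in controls) and
#'   `mean_sequenced_individuals` (coverage-adjusted denominator).
#' @return A control-count tibble.
#' @export
read_control_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    qualifying_allele_count = readr::col_double(),
    mean_sequenced_individuals = readr::col_double()
  ), progress = FALSE)
  if (any(df$mean_sequenced_individuals <= 0)) {
    stop("mean_sequenced_individuals must be positive", call. = FALSE)
  }
  if (any(df$qualifying_allele_count < 0)) {
    stop("qualifying_allele_count must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(df$gene)) stop("duplicate gene in control table", call. = FALSE)
  df
}

#' Variants excluded from analysis
#'
#' The default exclusion list carries the TNNT2 NM_001276345.2:c.601-1G>A
#' acceptor variant, a rare Oceanian polymorphism that would otherwise pass
#' the rarity filter on global frequencies.
#'
#' @return A tibble with columns `transcript`, `hgvs_c`, `reason`.
#' @export
default_exclusion_list <- function() {
  tibble::tibble(
    transcript = "NM_001276345.2",
    hgvs_c = "c.601-1G>A",
    reason = "rare Oceanian polymorphism"
  )
}

# Round half up (the convention used for printed percentages, where R's
# round() would round half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render a fraction as a printed percentage
#'
#' Percentages are rendered round-half-up to one decimal place (so 0.10305
#' becomes `"10.3"`); pass `digits = 0` for whole-number style.
#'
#' @param x Fraction(s) in \[0, 1\].
#' @param digits Decimal places (default 1).
#' @return Character vector.
#' @export
format_percent <- function(x, digits = 1) {
  ifelse(is.na(x), NA_character_,
         formatC(round_half_up(100 * x, digits), format = "f", digits = digits))
}

#' Write a pipeline result table or list to disk
#'
#' TSV output keeps the object's column order; JSON output is written with
#' unboxed scalars. Percent-like columns (named `*_pct`) are rendered with
#' [format_percent()]'s one-decimal convention and p-value columns
#' (`p`, `*_p`, `p_*`) in scientific notation.
#'
#' @param results A data frame or (for JSON) any serialisable list.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(path))
  }
  if (!is.data.frame(results)) {
    stop("TSV output requires a data frame", call. = FALSE)
  }
  out <- results
  for (col in names(out)) {
    if (grepl("_pct$", col) && is.numeric(out[[col]])) {
      out[[col]] <- formatC(round_half_up(out[[col]], 1), format = "f", digits = 1)
    } else if (grepl("(^p$|_p$|^p_)", col) && is.numeric(out[[col]])) {
      out[[col]] <- formatC(out[[col]], format = "e", digits = 3)
    }
  }
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
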