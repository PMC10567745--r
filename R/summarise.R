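# Cohort-level summary and the end-to-end pipeline driver.

#' Summarise a prioritised (and optionally classified) cohort
#'
#' Produces the headline tallies of the analysis: per-disease participants
#' and carriers of at least one candidate variant (with percentages rendered
#' round-half-up to one decimal), per-gene unique candidate variants and
#' their share of all unique variants, the location histogram over the
#' splice-region taxonomy (with essential-dinucleotide, exon-edge and
#' mechanism breakdowns), the tool-concordance tallies, and, when a
#' classification table is supplied, pathogenicity and transition tallies.
#'
#' @param verdicts Output of [prioritise()].
#' @param group_sizes Named vector of participants per disease (the carrier
#'   percentage denominators).
#' @param classifications Optional output of [classify_variants()].
#' @return A list of tibbles: `per_disease`, `per_gene`, `locations`,
#'   `concordance_canonical`, `concordance_non_canonical`, `overall`, and
#'   (when supplied) `classification`.
#' @export
summarise_cohort <- function(verdicts, group_sizes, classifications = NULL) {
  cand <- dplyr::filter(verdicts, .data$candidate)
  uv <- unique_variants(cand)

  per_disease <- tibble::tibble(disease = names(group_sizes),
                                participants = as.integer(group_sizes))
  carriers <- cand |>
    dplyr::distinct(.data$disease, .data$participant_id) |>
    dplyr::count(.data$disease, name = "carriers")
  per_disease <- dplyr::left_join(per_disease, carriers, by = "disease")
  per_disease$carriers[is.na(per_disease$carriers)] <- 0L
  per_disease$carrier_pct <- 100 * per_disease$carriers / per_disease$participants

  per_gene <- uv |>
    dplyr::count(.data$gene, name = "unique_variants") |>
    dplyr::arrange(dplyr::desc(.data$unique_variants))
  per_gene$share_pct <- 100 * per_gene$unique_variants / max(nrow(uv), 1)

  locations <- uv |>
    dplyr::count(.data$region, .data$essential_dinucleotide, .data$exon_edge,
                 .data$mechanism, name = "n_variants")

  conc <- concordance_tally(verdicts)
  total_participants <- sum(per_disease$participants)
  total_carriers <- sum(per_disease$carriers)
  overall <- tibble::tibble(
    participants = total_participants,
    carriers = total_carriers,
    carrier_pct = 100 * total_carriers / total_participants,
    unique_variants = nrow(uv)
  )
  out <- list(per_disease = per_disease, per_gene = per_gene,
              locations = locations,
              concordance_canonical = conc$canonical,
              concordance_non_canonical = conc$non_canonical,
              overall = overall)
  if (!is.null(classifications)) {
    out$classification <- tibble::tibble(
      n_classified = nrow(classifications),
      n_p_lp = sum(classifications$cls %in% c("pathogenic", "likely_pathogenic")),
      n_vus = sum(classifications$cls == "VUS"),
      n_with_rna = sum(!is.na(classifications$cls_after)),
      n_upgraded = sum(classifications$transition == "upgrade", na.rm = TRUE)
    )
  }
  out
}

#' Run the full pipeline on a simulated or supplied cohort
#'
#' Stages run in order: simulate (or load) -> anatomy -> prioritise ->
#' burden (per disease) -> classify -> summarise. All stage outputs are
#' returned and, when `out_dir` is given, written as TSV/JSON with
#' deterministic column order.
#'
#' @param cfg A [sim_config()] (used when `variants` is `NULL`).
#' @param variants,controls,gene_meta Pre-loaded input tables; all three must
#'   be supplied together to skip simulation.
#' @param mode Prioritisation mode for the discovery arm.
#' @param alpha Burden-test family-wise level.
#' @param out_dir Optional output directory.
#' @return A list with `variants`, `verdicts`, `burden`, `classifications`,
#'   `summary`, and a `funnel` log of rows in/passed/failed per filter.
#' @export
run_pipeline <- function(cfg = sim_config(), variants = NULL, controls = NULL,
                         gene_meta = NULL, mode = "discovery", alpha = 0.05,
                         out_dir = NULL) {
  supplied <- !vapply(list(variants, controls, gene_meta), is.null, TRUE)
  if (any(supplied) && !all(supplied)) {
    stop("variants, controls and gene_meta must be supplied together",
         call. = FALSE)
  }
  if (!all(supplied)) {
    sim <- simulate_cohort(cfg)
    variants <- sim$variants
    controls <- sim$controls
    gene_meta <- sim$gene_meta
  }
  annotated <- annotate_anatomy(variants)
  verdicts <- prioritise(annotated, gene_meta, mode = mode)
  funnel <- filter_funnel(verdicts)

  burden_verdicts <- prioritise(annotated, gene_meta, mode = "burden_75bp")
  burden <- dplyr::bind_rows(lapply(intersect(DISEASES, unique(variants$disease)),
    function(d) {
      run_burden(burden_verdicts, controls, gene_meta, d,
                 case_n = cfg$group_sizes[[d]], alpha = alpha)
    }))
  classifications <- classify_variants(verdicts, gene_meta)
  summary <- summarise_cohort(verdicts, cfg$group_sizes, classifications)

  out <- list(variants = variants, verdicts = verdicts, burden = burden,
              classifications = classifications, summary = summary,
              funnel = funnel)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_variant_table(variants, file.path(out_dir, "variants.tsv"))
    verdict_cols <- verdicts
    verdict_cols$tools_flagging <- vapply(verdict_cols$tools_flagging,
                                          paste, "", collapse = ";")
    verdict_cols$failed_filters <- vapply(verdict_cols$failed_filters,
                                          paste, "", collapse = ";")
    write_report(verdict_cols, file.path(out_dir, "verdicts.tsv"))
    write_report(burden, file.path(out_dir, "burden.tsv"))
    write_report(classifications, file.path(out_dir, "classifications.tsv"))
    write_report(summary, file.path(out_dir, "summary.json"), format = "json")
    write_report(funnel, file.path(out_dir, "filter_funnel.tsv"))
  }
  out
}

# Rows in/passed/failed per filter; conservation (in = passed + failed) holds
# by construction and is asserted in tests.
filter_funnel <- function(verdicts) {
  filters <- c("phenotype", "frequency", "region", "exclusion_list", "no_tool")
  n <- nrow(verdicts)
  tibble::tibble(
    filter = filters,
    rows_in = n,
    rows_failed = vapply(filters, function(f) {
      sum(vapply(verdicts$failed_filters, function(x) f %in% x, TRUE))
    }, 0L),
    rows_passed = rows_in - rows_failed
  )
}
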