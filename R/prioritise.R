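# Candidate splice-variant prioritisation: rarity, region, phenotype
# concordance and in silico tool thresholds.

#' Default in silico thresholds
#'
#' Strict inequalities, as recommended by the tool developers: a canonical
#' site-loss variant must reduce the MaxEntScan score by more than 4; a
#' site-gain variant must create a site scoring more than 4 with an increase
#' of more than 4 over the wild-type sequence; dbscSNV ADA/RF flag above 0.6;
#' SpliceAI above 0.5 (max delta score). Boundary values fail.
#'
#' @param mes_loss_delta,mes_gain_min,mes_gain_delta,ada,rf,spliceai Numeric
#'   overrides.
#' @return Named list of thresholds.
#' @export
default_thresholds <- function(mes_loss_delta = 4, mes_gain_min = 4,
                               mes_gain_delta = 4, ada = 0.6, rf = 0.6,
                               spliceai = 0.5) {
  list(mes_loss_delta = mes_loss_delta, mes_gain_min = mes_gain_min,
       mes_gain_delta = mes_gain_delta, ada = ada, rf = rf,
       spliceai = spliceai)
}

#' Default disease gene panels (ClinGen definitive associations)
#'
#' Representative panels of genes definitively associated with each inherited
#' heart disease by ClinGen gene curation expert panels: 8 for HCM, 12 for
#' DCM, 6 for ACM, 6 for LQTS, 1 for BrS and 7 for CPVT, a union of 32 unique
#' genes. SUD, having no phenotype of its own, is screened against the union.
#'
#' @return Named list mapping disease to a character vector of gene symbols.
#' @export
default_gene_panels <- function() {
  panels <- list(
    HCM  = c("MYBPC3", "MYH7", "TNNT2", "TNNI3", "TPM1", "ACTC1", "MYL2", "MYL3"),
    DCM  = c("TTN", "LMNA", "MYH7", "TNNT2", "BAG3", "DES", "FLNC", "PLN",
             "RBM20", "SCN5A", "TNNC1", "DSP"),
    ACM  = c("PKP2", "DSP", "DSG2", "DSC2", "JUP", "TMEM43"),
    LQTS = c("KCNQ1", "KCNH2", "SCN5A", "CALM1", "CALM2", "CALM3"),
    BrS  = c("SCN5A"),
    CPVT = c("RYR2", "CASQ2", "CALM1", "CALM2", "CALM3", "TRDN", "TECRL")
  )
  panels$SUD <- sort(unique(unlist(panels)))
  panels
}

#' Population rarity filter
#'
#' A variant passes when its overall control allele frequency and every
#' supplied sub-population frequency (African, East Asian, Latino,
#' Non-Finnish European, South Asian) are below the threshold, and, when a
#' control allele count is supplied, that count does not exceed `max_ac`.
#' Missing frequencies count as absent from controls and pass.
#'
#' @param af_overall,allele_count_controls Numeric vectors (NA = missing).
#' @param af_subpops Optional data frame / list of sub-population frequency
#'   vectors (any subset of `af_afr`, `af_eas`, `af_amr`, `af_nfe`, `af_sas`).
#' @param threshold Allele-frequency cut-off (default 1e-4).
#' @param max_ac Maximum control allele count (default 15).
#' @return Logical vector.
#' @export
frequency_filter <- function(af_overall = NA_real_,
                             allele_count_controls = NA_real_,
                             af_subpops = NULL,
                             threshold = 1e-4, max_ac = 15) {
  n <- max(length(af_overall), length(allele_count_controls),
           if (is.null(af_subpops)) 0L else vapply(af_subpops, length, 1L))
  af_overall <- rep_len(as.numeric(af_overall), n)
  ac <- rep_len(as.numeric(allele_count_controls), n)
  if (any(af_overall < 0, na.rm = TRUE)) {
    stop("negative allele frequency", call. = FALSE)
  }
  pass <- is.na(af_overall) | af_overall < threshold
  if (!is.null(af_subpops)) {
    for (col in names(af_subpops)) {
      v <- rep_len(as.numeric(af_subpops[[col]]), n)
      if (any(v < 0, na.rm = TRUE)) {
        stop("negative allele frequency in ", col, call. = FALSE)
      }
      pass <- pass & (is.na(v) | v < threshold)
    }
  }
  pass & (is.na(ac) | ac <= max_ac)
}

#' Intronic-depth region filter
#'
#' In `burden_75bp` mode only exonic variants and intronic variants within
#' the first/last 75 bp of intron sequence qualify, mirroring exome
#' sequencing target regions so that case and control ascertainment match.
#' `discovery` mode passes everything (genome-sequenced participants
#' contribute deep intronic variants).
#'
#' @param intron_offset Signed intronic offsets (0 = exonic).
#' @param mode `"burden_75bp"` or `"discovery"`.
#' @param max_intron_bp Intronic depth limit for burden mode (default 75).
#' @return Logical vector.
#' @export
region_filter <- function(intron_offset, mode = c("burden_75bp", "discovery"),
                          max_intron_bp = 75) {
  mode <- match.arg(mode)
  off <- as.integer(intron_offset)
  if (mode == "discovery") {
    return(rep(TRUE, length(off)))
  }
  is.na(off) | abs(off) <= max_intron_bp
}

#' Which in silico tools flag a variant
#'
#' MaxEntScan flags a site-loss variant when the score drop (`mes_ref -
#' mes_alt`, or `-mes_delta` when only the difference is recorded) exceeds
#' the loss threshold, and a site-gain variant when the created site scores
#' above the gain threshold with an increase above it (a missing `mes_ref`
#' for a de novo site counts as 0). ADA and RF flag above their probability
#' thresholds (they only score canonical-splice-site variants, so they are
#' simply missing elsewhere); SpliceAI flags above its delta threshold.
#' A missing score never flags.
#'
#' @param mes_ref,mes_alt,mes_delta,ada,rf,spliceai Score vectors.
#' @param mechanism `site_loss` / `site_gain` / `ambiguous` per variant.
#' @param thresholds See [default_thresholds()].
#' @return List of character vectors, each a subset of
#'   `c("MES", "ADA", "RF", "SpliceAI")`.
#' @export
tool_calls <- function(mes_ref = NA_real_, mes_alt = NA_real_,
                       mes_delta = NA_real_, ada = NA_real_, rf = NA_real_,
                       spliceai = NA_real_, mechanism = "ambiguous",
                       thresholds = default_thresholds()) {
  n <- max(length(mes_ref), length(mes_alt), length(mes_delta), length(ada),
           length(rf), length(spliceai), length(mechanism))
  mes_ref <- rep_len(as.numeric(mes_ref), n)
  mes_alt <- rep_len(as.numeric(mes_alt), n)
  mes_delta <- rep_len(as.numeric(mes_delta), n)
  ada <- rep_len(as.numeric(ada), n)
  rf <- rep_len(as.numeric(rf), n)
  spliceai <- rep_len(as.numeric(spliceai), n)
  mechanism <- rep_len(mechanism, n)

  delta <- ifelse(!is.na(mes_delta), mes_delta, mes_alt - mes_ref)
  ref0 <- ifelse(is.na(mes_ref), 0, mes_ref)
  mes_loss <- mechanism == "site_loss" & !is.na(delta) &
    -delta > thresholds$mes_loss_delta
  mes_gain <- mechanism == "site_gain" & !is.na(mes_alt) &
    mes_alt > thresholds$mes_gain_min &
    (mes_alt - ref0) > thresholds$mes_gain_delta
  flags <- cbind(
    MES = mes_loss | mes_gain,
    ADA = !is.na(ada) & ada > thresholds$ada,
    RF = !is.na(rf) & rf > thresholds$rf,
    SpliceAI = !is.na(spliceai) & spliceai > thresholds$spliceai
  )
  lapply(seq_len(n), function(i) colnames(flags)[flags[i, ]])
}

#' Prioritise putative splice-disrupting variants
#'
#' Applies, per observation: phenotype concordance (the gene must be
#' definitively associated with the participant's disease; SUD is screened
#' against every panel gene), the population rarity filter, the region
#' filter, the exclusion list, and the in silico tool thresholds. A variant
#' is a candidate when no filter fails and at least one tool flags it.
#'
#' @param variants An anatomy-annotated variant tibble (see
#'   [annotate_anatomy()]; plain variant tibbles are annotated on the fly).
#' @param gene_meta Gene-metadata tibble; every observed gene must be present.
#' @param mode Region-filter mode (`"discovery"` keeps deep intronic
#'   variants; `"burden_75bp"` restricts to exome-like target regions and the
#'   five-sub-population rarity rule).
#' @param exclusion Exclusion-list tibble (see [default_exclusion_list()]).
#' @param thresholds See [default_thresholds()].
#' @return The input tibble with columns `candidate` (logical),
#'   `tools_flagging` (list of character vectors), `n_tools` (integer) and
#'   `failed_filters` (list; subset of `phenotype`, `frequency`, `region`,
#'   `exclusion_list`, `no_tool`).
#' @export
prioritise <- function(variants, gene_meta,
                       mode = c("discovery", "burden_75bp"),
                       exclusion = default_exclusion_list(),
                       thresholds = default_thresholds()) {
  mode <- match.arg(mode)
  if (!"region" %in% names(variants)) {
    variants <- annotate_anatomy(variants, thresholds = thresholds)
  }
  absent <- setdiff(unique(variants$gene), gene_meta$gene)
  if (length(absent) > 0) {
    stop("gene(s) absent from metadata: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(variants)
  panel_ok <- logical(n)
  meta_sets <- strsplit(gene_meta$definitive_for, ";", fixed = TRUE)
  names(meta_sets) <- gene_meta$gene
  for (i in seq_len(n)) {
    dis <- variants$disease[i]
    assoc <- meta_sets[[variants$gene[i]]]
    panel_ok[i] <- if (identical(dis, "SUD")) length(assoc) > 0 else dis %in% assoc
  }
  freq_ok <- frequency_filter(
    variants$af_overall, variants$allele_count_controls,
    af_subpops = variants[, intersect(names(SUBPOPS), names(variants)),
                          drop = FALSE]
  )
  region_ok <- region_filter(variants$intron_offset, mode)
  excl_key <- paste(exclusion$transcript, exclusion$hgvs_c)
  not_excluded <- !(paste(variants$transcript, variants$hgvs_c) %in% excl_key)
  tools <- tool_calls(variants$mes_ref, variants$mes_alt, variants$mes_delta,
                      variants$ada, variants$rf, variants$spliceai,
                      variants$mechanism, thresholds)
  has_tool <- lengths(tools) > 0

  failed <- lapply(seq_len(n), function(i) {
    c(if (!panel_ok[i]) "phenotype",
      if (!freq_ok[i]) "frequency",
      if (!region_ok[i]) "region",
      if (!not_excluded[i]) "exclusion_list",
      if (!has_tool[i]) "no_tool")
  })
  variants$candidate <- lengths(failed) == 0
  variants$tools_flagging <- tools
  variants$n_tools <- lengths(tools)
  variants$failed_filters <- failed
  variants
}

#' Deduplicate carrier observations to unique variants
#'
#' Variant identity is the (transcript, hgvs_c) pair: the same variant seen
#' in several participants counts once in variant tallies.
#'
#' @param variants A variant tibble.
#' @return One row per unique variant (first observation kept), plus a
#'   `n_carriers` column.
#' @export
unique_variants <- function(variants) {
  variants |>
    dplyr::group_by(.data$transcript, .data$hgvs_c) |>
    dplyr::mutate(n_carriers = dplyr::n()) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Tool-concordance tally over unique candidate variants
#'
#' Canonical-splice-site variants (donor/acceptor regions, where all four
#' tools apply) are tallied by how many tools flagged them (1-4);
#' non-canonical variants (deep intronic and exonic-other, where only
#' MaxEntScan and SpliceAI apply) by their MES/SpliceAI pattern.
#'
#' @param verdicts Output of [prioritise()] (anatomy columns included),
#'   restricted internally to unique candidate variants.
#' @return A list with tibbles `canonical` (`n_tools`, `n_variants`) and
#'   `non_canonical` (`pattern` in `MES only` / `both` / `SpliceAI only`,
#'   `n_variants`), zero-filled.
#' @export
concordance_tally <- function(verdicts) {
  uv <- unique_variants(dplyr::filter(verdicts, .data$candidate))
  canon <- dplyr::filter(uv, .data$region %in% c("donor_site", "acceptor_site"))
  canonical <- tibble::tibble(n_tools = 1:4)
  canonical$n_variants <- vapply(
    canonical$n_tools, function(k) sum(canon$n_tools == k), 0L
  )
  noncanon <- dplyr::filter(uv, .data$region %in% c("deep_intronic", "exonic_other"))
  has_mes <- vapply(noncanon$tools_flagging, function(t) "MES" %in% t, TRUE)
  has_sai <- vapply(noncanon$tools_flagging, function(t) "SpliceAI" %in% t, TRUE)
  non_canonical <- tibble::tibble(
    pattern = c("MES only", "both", "SpliceAI only"),
    n_variants = c(sum(has_mes & !has_sai), sum(has_mes & has_sai),
                   sum(!has_mes & has_sai))
  )
  list(canonical = canonical, non_canonical = non_canonical)
}
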