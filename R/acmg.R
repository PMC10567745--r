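# ACMG/AMP evidence assignment at customised strengths, and combination into
# a pathogenicity class.
#
# Evidence codes are represented as character tokens: the base code with an
# optional strength suffix ("PS4", "PS4_moderate", "PVS1_strong", "PP1",
# ...). A token without suffix carries the code's default strength (PVS1
# very strong, PS* strong, PM* moderate, PP* supporting).

STRENGTH_POINTS <- c(supporting = 1, moderate = 2, strong = 4, very_strong = 8)
CLASS_ORDER <- c(VUS = 1, likely_pathogenic = 2, pathogenic = 3)

default_strength <- function(code) {
  dplyr::case_when(
    startsWith(code, "PVS") ~ "very_strong",
    startsWith(code, "PS") ~ "strong",
    startsWith(code, "PM") ~ "moderate",
    startsWith(code, "PP") ~ "supporting",
    TRUE ~ NA_character_
  )
}

#' Parse evidence tokens into code and strength
#'
#' @param tokens Character vector like `c("PS4_moderate", "PM2", "PP1")`.
#' @return A tibble with columns `token`, `code`, `strength`, `points`.
#' @export
parse_evidence <- function(tokens) {
  m <- regmatches(tokens, regexec(
    "^(PVS1|PS[1-4]|PM[1-6]|PP[1-5])(?:_(very_strong|strong|moderate|supporting))?$",
    tokens))
  bad <- vapply(m, length, 1L) == 0
  if (any(bad)) {
    stop("unrecognised evidence token: ", tokens[which(bad)[1]], call. = FALSE)
  }
  code <- vapply(m, `[`, "", 2)
  strength <- vapply(m, `[`, "", 3)
  strength <- ifelse(nzchar(strength), strength, default_strength(code))
  tibble::tibble(
    token = tokens, code = code, strength = strength,
    points = unname(STRENGTH_POINTS[strength])
  )
}

evidence_token <- function(code, strength) {
  ifelse(strength == default_strength(code), code,
         paste0(code, "_", strength))
}

#' Assign PVS1 (loss of function) on the dosage-sensitivity ladder
#'
#' For a variant whose consequence is loss of function (a frameshift with
#' premature termination, or an asserted LoF prediction): full PVS1 when LoF
#' is an established disease mechanism for the gene or its ClinGen
#' haploinsufficiency score is 3; PVS1_strong for a score of 2 and for titin
#' (emerging dosage sensitivity); PVS1_moderate for a score of 1;
#' PVS1_supporting for uncurated genes whose gnomAD LoF observed/expected
#' ratio is below 0.35; otherwise no code.
#'
#' @param gene_meta_row One row of the gene-metadata tibble.
#' @param frame Frame consequence (`frameshift_ptc` / `in_frame_change` /
#'   `none`).
#' @param predicted_lof Treat the variant as LoF even without frame evidence.
#' @return An evidence token or `NULL`.
#' @export
assign_pvs1 <- function(gene_meta_row, frame, predicted_lof = FALSE) {
  is_lof <- identical(frame, "frameshift_ptc") || isTRUE(predicted_lof)
  if (!is_lof) return(NULL)
  hi <- gene_meta_row$haploinsufficiency_score[1]
  if (isTRUE(gene_meta_row$lof_mechanism[1]) || identical(hi, "3")) {
    return("PVS1")
  }
  if (identical(hi, "2") || isTRUE(gene_meta_row$is_ttn[1])) {
    return("PVS1_strong")
  }
  if (identical(hi, "1")) return("PVS1_moderate")
  oe <- gene_meta_row$lof_oe[1]
  if (identical(hi, "not_curated") && !is.na(oe) && oe < 0.35) {
    return("PVS1_supporting")
  }
  NULL
}

#' Assign PS4 from the count of unrelated concordant-phenotype probands
#'
#' At least 15 probands: strong; at least 6: moderate; at least 2:
#' supporting; otherwise none.
#'
#' @param proband_count Non-negative integer.
#' @return An evidence token or `NULL`.
#' @export
assign_ps4 <- function(proband_count) {
  if (is.na(proband_count) || proband_count < 2) return(NULL)
  if (proband_count >= 15) return("PS4")
  if (proband_count >= 6) return("PS4_moderate")
  "PS4_supporting"
}

#' Assign PP1 from informative co-segregating meioses
#'
#' At least 7 meioses: strong; at least 5: moderate; at least 3: supporting;
#' otherwise none.
#'
#' @param meioses Non-negative integer.
#' @return An evidence token or `NULL`.
#' @export
assign_pp1 <- function(meioses) {
  if (is.na(meioses) || meioses < 3) return(NULL)
  if (meioses >= 7) return("PP1_strong")
  if (meioses >= 5) return("PP1_moderate")
  "PP1"
}

#' Assign functional (RNA study) evidence
#'
#' An out-of-frame splicing outcome (frameshift with premature termination)
#' earns PS3; an in-frame insertion or deletion earns PM4; an outcome of no
#' change earns nothing (and removes PP3 eligibility upstream). Outcomes with
#' unreported consequences earn nothing, with a warning.
#'
#' @param kind Functional outcome kind.
#' @param frame Frame consequence for the outcome (see [frame_consequence()]).
#' @return An evidence token or `NULL`.
#' @export
assign_functional <- function(kind, frame) {
  if (is.na(kind)) return(NULL)
  if (identical(kind, "unreported_consequence")) {
    warning("functional study with unreported consequence: no code assigned",
            call. = FALSE)
    return(NULL)
  }
  if (identical(frame, "frameshift_ptc")) return("PS3")
  if (identical(frame, "in_frame_change")) return("PM4")
  NULL
}

#' Assign PM2 (population rarity) and PP3 (in silico concordance)
#'
#' PM2 applies when the rarity filter passes and the variant is essentially
#' absent from controls (allele count at or below `pm2_max_ac`, default 1).
#' PP3 applies when at least one in silico tool flags the variant and no RNA
#' evidence supersedes prediction (PP3 and PS3/PM4 are mutually exclusive on
#' the same variant).
#'
#' @param freq_pass Did the rarity filter pass?
#' @param allele_count_controls Control allele count (NA = unobserved).
#' @param n_tools Number of in silico tools flagging the variant.
#' @param has_rna_evidence Is an RNA functional result available?
#' @param pm2_max_ac Maximum control allele count compatible with PM2.
#' @return Character vector of evidence tokens (possibly empty).
#' @export
assign_pm2_pp3 <- function(freq_pass, allele_count_controls, n_tools,
                           has_rna_evidence = FALSE, pm2_max_ac = 1) {
  out <- character(0)
  ac <- if (is.na(allele_count_controls)) 0 else allele_count_controls
  if (isTRUE(freq_pass) && ac <= pm2_max_ac) out <- c(out, "PM2")
  if (n_tools >= 1 && !isTRUE(has_rna_evidence)) out <- c(out, "PP3")
  out
}

#' Combine evidence codes into a pathogenicity class
#'
#' The point-based combiner sums strength points (supporting 1, moderate 2,
#' strong 4, very strong 8): pathogenic at 10 or more points, likely
#' pathogenic at 6-9, otherwise VUS. The categorical combiner applies the
#' classical ACMG/AMP rule combinations instead. Benign-side criteria are out
#' of scope.
#'
#' @param tokens Character vector of evidence tokens.
#' @param combiner `"points"` (default) or `"categorical"`.
#' @return A list with `cls` (`pathogenic` / `likely_pathogenic` / `VUS`),
#'   `points`, and the parsed `codes` tibble.
#' @export
#' @examples
#' combine_acmg(c("PS3", "PM2"))  # 6 points -> likely pathogenic
combine_acmg <- function(tokens, combiner = c("points", "categorical")) {
  combiner <- match.arg(combiner)
  codes <- parse_evidence(unique(tokens))
  points <- sum(codes$points)
  cls <- if (combiner == "points") {
    if (points >= 10) "pathogenic" else if (points >= 6) "likely_pathogenic" else "VUS"
  } else {
    categorical_class(codes)
  }
  list(cls = cls, points = points, codes = codes)
}

# Classical ACMG/AMP rule combinations (pathogenic-side only).
categorical_class <- function(codes) {
  nvs <- sum(codes$strength == "very_strong")
  ns <- sum(codes$strength == "strong")
  nm <- sum(codes$strength == "moderate")
  np <- sum(codes$strength == "supporting")
  pathogenic <-
    (nvs >= 1 && (ns >= 1 || nm >= 2 || (nm == 1 && np == 1) || np >= 2)) ||
    ns >= 2 ||
    (ns == 1 && (nm >= 3 || (nm == 2 && np >= 2) || (nm == 1 && np >= 4)))
  if (pathogenic) return("pathogenic")
  likely <-
    (nvs == 1 && nm == 1) ||
    (ns == 1 && nm >= 1 && nm <= 2) ||
    (ns == 1 && np >= 2) ||
    nm >= 3 ||
    (nm == 2 && np >= 2) ||
    (nm == 1 && np >= 4)
  if (likely) return("likely_pathogenic")
  "VUS"
}

#' Reclassify a variant after an RNA functional study
#'
#' Drops PP3 (prediction is superseded by observation), adds the functional
#' code from [assign_functional()], recombines, and labels the transition.
#' The pre-RNA class defaults to the combiner's own result for the pre-RNA
#' codes, but an externally asserted class (for example one drawn from a
#' clinical report) can be supplied.
#'
#' @param tokens_before Evidence tokens before RNA evidence.
#' @param kind,frame Functional outcome and its frame consequence.
#' @param before_cls Optional externally supplied pre-RNA class.
#' @param combiner Passed to [combine_acmg()].
#' @return A list with `before`, `after` (both [combine_acmg()] results;
#'   `before$cls` honours `before_cls`), `tokens_after` and `transition`
#'   (`upgrade` / `downgrade` / `no_change`).
#' @export
reclassify_with_rna <- function(tokens_before, kind, frame,
                                before_cls = NULL,
                                combiner = c("points", "categorical")) {
  combiner <- match.arg(combiner)
  before <- combine_acmg(tokens_before, combiner)
  if (!is.null(before_cls)) {
    stopifnot(before_cls %in% names(CLASS_ORDER))
    before$cls <- before_cls
  }
  tokens_after <- setdiff(tokens_before, c("PP3", "PP3_supporting"))
  func <- assign_functional(kind, frame)
  tokens_after <- unique(c(tokens_after, func))
  after <- combine_acmg(tokens_after, combiner)
  delta <- CLASS_ORDER[after$cls] - CLASS_ORDER[before$cls]
  transition <- if (delta > 0) "upgrade" else if (delta < 0) "downgrade" else "no_change"
  list(before = before, after = after, tokens_after = tokens_after,
       transition = transition)
}

#' Classify prioritised variants for pathogenicity
#'
#' Table-level driver: for each unique candidate variant, assigns PVS1 (from
#' the in silico predicted consequence where RNA evidence is absent, or the
#' observed frame where present), PS4, PP1, PM2/PP3 and functional codes, and
#' combines them. When an RNA functional outcome is recorded the variant is
#' additionally reclassified and the transition reported.
#'
#' @param verdicts Output of [prioritise()].
#' @param gene_meta Gene-metadata tibble.
#' @param combiner Passed to [combine_acmg()].
#' @param pm2_max_ac Passed to [assign_pm2_pp3()].
#' @return One row per unique candidate variant with evidence tokens
#'   (semicolon-separated), points, class, and (where RNA evidence exists)
#'   the post-RNA class and transition.
#' @export
classify_variants <- function(verdicts, gene_meta,
                              combiner = c("points", "categorical"),
                              pm2_max_ac = 1) {
  combiner <- match.arg(combiner)
  uv <- unique_variants(dplyr::filter(verdicts, .data$candidate))
  rows <- lapply(seq_len(nrow(uv)), function(i) {
    v <- uv[i, ]
    meta <- gene_meta[gene_meta$gene == v$gene, , drop = FALSE]
    has_rna <- !is.na(v$functional_kind)
    frame_obs <- if (has_rna) {
      frame_consequence(v$functional_kind, v$functional_length_nt)$frame
    } else {
      NA_character_
    }
    # PVS1 is assigned from the predicted consequence (essential-dinucleotide
    # site loss presumed LoF); observed RNA outcomes enter as PS3/PM4 at
    # reclassification, never retroactively here.
    predicted_lof <- isTRUE(v$essential_dinucleotide)
    tokens <- character(0)
    tokens <- c(tokens, assign_pvs1(meta, "none", predicted_lof = predicted_lof))
    tokens <- c(tokens, assign_ps4(v$proband_count))
    tokens <- c(tokens, assign_pp1(v$informative_meioses))
    freq_pass <- !any(vapply(v$failed_filters, function(f) "frequency" %in% f, TRUE))
    tokens <- c(tokens, assign_pm2_pp3(freq_pass, v$allele_count_controls,
                                       v$n_tools, has_rna_evidence = FALSE,
                                       pm2_max_ac = pm2_max_ac))
    before <- combine_acmg(tokens, combiner)
    out <- tibble::tibble(
      transcript = v$transcript, hgvs_c = v$hgvs_c, gene = v$gene,
      disease = v$disease,
      evidence = paste(tokens, collapse = ";"),
      points = before$points, cls = before$cls,
      evidence_after = NA_character_, cls_after = NA_character_,
      transition = NA_character_
    )
    if (has_rna) {
      rec <- suppressWarnings(
        reclassify_with_rna(tokens, v$functional_kind, frame_obs,
                            combiner = combiner)
      )
      out$evidence_after <- paste(rec$tokens_after, collapse = ";")
      out$cls_after <- rec$after$cls
      out$transition <- rec$transition
    }
    out
  })
  dplyr::bind_rows(rows)
}
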