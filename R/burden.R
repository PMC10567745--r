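# Coverage-adjusted case vs population burden testing.
#
# For each definitively disease-associated gene, case carriers of qualifying
# rare splice variants are compared with a gnomAD-like control count using a
# one-sided Fisher's exact test (enrichment in cases). The control
# denominator is the mean number of individuals sequenced for that gene, so
# genes with poor exome coverage are not penalised. Bonferroni correction is
# applied per disease over its definitive gene panel.

#' One-sided Fisher's exact test for case enrichment
#'
#' Exact upper-tail hypergeometric probability of observing at least `a` case
#' carriers given the table margins; the enrichment direction is cases.
#'
#' @param a Case carriers.
#' @param b Case non-carriers.
#' @param c Control carriers.
#' @param d Control non-carriers.
#' @return P(X >= a) under the null hypergeometric distribution, in (0, 1].
#' @export
#' @examples
#' fisher_one_sided(2, 8, 1, 9)
fisher_one_sided <- function(a, b, c, d) {
  counts <- cbind(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  # margins: a+c carriers among a+b+c+d, a+b cases drawn
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Run the per-gene burden test for one disease group
#'
#' Case carriers are distinct participants carrying at least one qualifying
#' variant in the gene (an observation qualifies when it passes the
#' burden-mode filters: five-sub-population rarity, 75 bp intronic region,
#' exclusion list and, by default, the same in silico splice thresholds
#' applied to cases and controls symmetrically). The control arm uses the
#' gene's qualifying allele count over its mean sequenced-individuals
#' denominator, rounded to integers for the exact test; each rare allele is
#' taken as a distinct carrier.
#'
#' @param case_obs Prioritised observations for the disease's participants
#'   (output of [prioritise()] with `mode = "burden_75bp"`); pass the full
#'   tibble, qualifying rows are selected internally.
#' @param control_table Control-count tibble (see [read_control_table()]).
#' @param gene_meta Gene-metadata tibble; the disease's panel is the set of
#'   genes listing the disease in `definitive_for`.
#' @param disease Disease group being tested.
#' @param case_n Number of participants in the disease group (the case
#'   denominator; defaults to the number of distinct participants observed,
#'   but should be supplied since non-carriers need not appear in the table).
#' @param alpha Family-wise significance level before Bonferroni division.
#' @param require_candidate Apply the in silico thresholds to case
#'   observations (default `TRUE`, symmetric with a control table built under
#'   the same thresholds); set `FALSE` when the control counts were filtered
#'   by rarity and region only.
#' @return A tibble of per-gene burden results: carrier counts, frequencies,
#'   case excess, one-sided p, Bonferroni significance at `alpha / m_tests`,
#'   and post hoc power at the observed frequencies.
#' @export
run_burden <- function(case_obs, control_table, gene_meta, disease,
                       case_n = NULL, alpha = 0.05, require_candidate = TRUE) {
  stopifnot(disease %in% DISEASES)
  meta_sets <- strsplit(gene_meta$definitive_for, ";", fixed = TRUE)
  panel <- if (identical(disease, "SUD")) {
    gene_meta$gene[lengths(meta_sets) > 0 & gene_meta$definitive_for != ""]
  } else {
    gene_meta$gene[vapply(meta_sets, function(x) disease %in% x, TRUE)]
  }
  if (length(panel) == 0) {
    stop("no definitive gene panel for disease ", disease, call. = FALSE)
  }
  obs <- dplyr::filter(case_obs, .data$disease == !!disease)
  if (is.null(case_n)) {
    case_n <- dplyr::n_distinct(obs$participant_id)
  }
  qualifying <- obs
  if (nrow(qualifying) > 0) {
    keep <- if (require_candidate) {
      qualifying$candidate
    } else {
      # rarity + region + exclusion only
      vapply(qualifying$failed_filters,
             function(f) !any(f %in% c("frequency", "region", "exclusion_list")),
             TRUE)
    }
    qualifying <- qualifying[keep, , drop = FALSE]
  }
  m <- length(panel)
  idx <- match(panel, control_table$gene)
  if (anyNA(idx)) {
    stop("gene ", panel[which(is.na(idx))[1]], " absent from control table",
         call. = FALSE)
  }
  carriers <- vapply(panel, function(g) {
    dplyr::n_distinct(qualifying$participant_id[qualifying$gene == g])
  }, 0L)
  control_q <- control_table$qualifying_allele_count[idx]
  control_n <- control_table$mean_sequenced_individuals[idx]
  cc <- round(control_q)
  p <- fisher_one_sided(carriers, case_n - carriers, cc, round(control_n) - cc)
  case_freq <- carriers / case_n
  control_freq <- control_q / control_n
  tibble::new_tibble(list(
    gene = panel, disease = rep(disease, m),
    case_carriers = unname(carriers), case_n = rep(case_n, m),
    control_qualifying = control_q, control_n = control_n,
    case_freq = unname(case_freq), control_freq = control_freq,
    excess = unname(case_freq - control_freq),
    p_one_sided = unname(p), m_tests = rep(m, m),
    significant = unname(p < alpha / m),
    power = unname(power_two_proportions(case_freq, control_freq, case_n,
                                         round(control_n), alpha = alpha / m))
  ), nrow = m)
}

#' Power of the one-sided two-proportion test (arcsine effect size)
#'
#' Cohen's effect size `h = 2 asin(sqrt(p1)) - 2 asin(sqrt(p2))`; for unequal
#' group sizes the one-sided power is
#' `Phi(|h| sqrt(n1 n2 / (n1 + n2)) - z_(1 - alpha))`.
#'
#' @param p1,p2 The two proportions (in \[0, 1\]).
#' @param n1,n2 Group sizes.
#' @param alpha One-sided significance level.
#' @return Power in \[0, 1\] (equal to `alpha` when `p1 == p2`).
#' @export
power_two_proportions <- function(p1, p2, n1, n2, alpha = 0.05) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) {
    stop("proportions must be in [0, 1]", call. = FALSE)
  }
  if (any(n1 <= 0 | n2 <= 0)) stop("group sizes must be positive", call. = FALSE)
  h <- 2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
  pnorm(abs(h) * sqrt(n1 * n2 / (n1 + n2)) - qnorm(1 - alpha))
}
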