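# Shared fixtures and independent oracles.

# The six functionally studied variants with their printed score columns.
# Site-loss rows record the MaxEntScan score difference (mes_delta); the
# deep intronic site-gain row records the created site's score (mes_alt).
table1_scores <- function() {
  t1 <- tibble::tribble(
    ~fam, ~gene, ~transcript, ~hgvs_c, ~mes_ref, ~mes_alt, ~mes_delta,
    ~ada, ~rf, ~spliceai, ~mechanism,
    "014", "KCNQ1", "NM_000218.3", "c.477+5G>A", NA, NA, -5.37,
    0.99, 0.97, 0.23, "site_loss",
    "015", "KCNQ1", "NM_000218.3", "c.781G>A", NA, NA, 1.81,
    0.91, 0.61, 0.76, "site_loss",
    "051", "MYBPC3", "NM_000256.3", "c.1224-80G>A", NA, 7.96, NA,
    NA, NA, 0.94, "site_gain",
    "054", "MYBPC3", "NM_000256.3", "c.1458-7C>A", NA, NA, -3.93,
    0.99, 0.45, 0.99, "site_loss",
    "102", "RYR2", "NM_001035.3", "c.848+1G>A", NA, NA, -8.18,
    1.0, 0.94, 0.74, "site_loss",
    "125", "TTN", "NM_001267550.2", "c.63793G>A", NA, NA, -4.57,
    1.0, 0.99, 0.74, "site_loss"
  )
  t1$expected_tools <- list(
    c("MES", "ADA", "RF"), c("ADA", "RF", "SpliceAI"), c("MES", "SpliceAI"),
    c("ADA", "SpliceAI"), c("MES", "ADA", "RF", "SpliceAI"),
    c("MES", "ADA", "RF", "SpliceAI")
  )
  t1
}

# Printed evidence code sets and functional outcomes for the six families.
# frames/lengths: exon 2 skip 91 nt; exon 6 skip 47 aa = 141 nt; exon 14
# extension 78 nt; exon 17 extension 5 nt; exon 11 skip 25 aa = 75 nt;
# intron 307 retention (length unreported; any non-multiple-of-3 stands in).
table1_evidence <- function() {
  list(
    `014` = list(pre = c("PS4_moderate", "PM2", "PP1", "PP3"),
                 post = c("PS3", "PS4_moderate", "PM2", "PP1"),
                 kind = "exon_skip", len = 91,
                 printed_pre = "VUS", printed_post = "likely_pathogenic",
                 printed_transition = "upgrade"),
    `015` = list(pre = c("PM2", "PS4_supporting", "PP3"),
                 post = c("PM2", "PM4", "PS4_supporting"),
                 kind = "exon_skip", len = 141,
                 printed_pre = "VUS", printed_post = "VUS",
                 printed_transition = "no_change"),
    `051` = list(pre = c("PS4", "PP3"),
                 post = c("PS4", "PM2", "PM4"),
                 kind = "new_exon_inclusion", len = 78,
                 printed_pre = "VUS", printed_post = "likely_pathogenic",
                 printed_transition = "upgrade"),
    `054` = list(pre = c("PM2", "PP3"),
                 post = c("PS3", "PM2"),
                 kind = "exon_extension", len = 5,
                 printed_pre = "VUS", printed_post = "likely_pathogenic",
                 printed_transition = "upgrade"),
    `102` = list(pre = c("PP1_strong", "PM2", "PS4_supporting"),
                 post = c("PP1_strong", "PM2", "PM4", "PS4_supporting"),
                 kind = "exon_skip", len = 75,
                 printed_pre = "likely_pathogenic",
                 printed_post = "likely_pathogenic",
                 printed_transition = "no_change"),
    `125` = list(pre = c("PP1_moderate", "PM2", "PS4_supporting", "PP3"),
                 post = c("PS3", "PP1_moderate", "PM2", "PS4_supporting"),
                 kind = "intron_retention", len = 100,
                 printed_pre = "likely_pathogenic",
                 printed_post = "likely_pathogenic",
                 printed_transition = "no_change")
  )
}

# Independent brute-force oracle for the one-sided Fisher test: direct
# enumeration of the hypergeometric upper tail with choose().
fisher_enum_oracle <- function(a, b, c, d) {
  K <- a + c; N <- a + b + c + d; R <- a + b
  ks <- a:min(K, R)
  sum(choose(K, ks) * choose(N - K, R - ks)) / choose(N, R)
}

# Monte-Carlo oracle for the one-sided arcsine-transformed two-proportion
# z-test at the estimated effect size.
mc_power_oracle <- function(p1, p2, n1, n2, alpha, R = 1e5) {
  x1 <- rbinom(R, n1, p1)
  x2 <- rbinom(R, n2, p2)
  h <- 2 * asin(sqrt(x1 / n1)) - 2 * asin(sqrt(x2 / n2))
  mean(h * sqrt(n1 * n2 / (n1 + n2)) > qnorm(1 - alpha))
}

# A single candidate observation with sensible defaults, overridable.
make_obs <- function(...) {
  args <- list(...)
  defaults <- list(
    participant_id = "P1", disease = "HCM", gene = "MYBPC3",
    transcript = "NM_000256.3", hgvs_c = "c.927+1G>A",
    af_overall = 0, af_afr = 0, af_eas = 0, af_amr = 0, af_nfe = 0,
    af_sas = 0, allele_count_controls = 0, spliceai = 0.9
  )
  defaults[names(args)] <- args
  do.call(variant_table, defaults)
}

mini_gene_meta <- function() {
  gene_meta_table(
    gene = c("MYBPC3", "TTN", "MYH7", "PKP2", "KCNQ1", "TNNT2", "RYR2"),
    definitive_for = c("HCM", "DCM", "HCM;DCM", "ACM", "LQTS", "HCM;DCM", "CPVT"),
    lof_mechanism = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    haploinsufficiency_score = c("not_curated", "not_curated", "not_curated",
                                 "3", "not_curated", "not_curated", "not_curated"),
    lof_oe = c(0.18, 0.31, 0.6, 0.2, 0.12, 0.6, 0.45),
    mean_sequenced_controls = 1e5
  )
}
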