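#!/usr/bin/env Rscript
# Stage 3: coverage-adjusted rare splice-variant burden testing.
#
# Re-prioritises under the burden rules (exome-like 75 bp intronic window,
# five-sub-population rarity) and tests each disease group's definitive
# genes against the gnomAD-like control table with a one-sided Fisher's
# exact test, Bonferroni-corrected per disease, with post hoc arcsine power.

suppressPackageStartupMessages(library(spliceburden))

variants <- read_variant_table("results/variants.tsv")
gene_meta <- read_gene_meta("results/gene_meta.tsv")
controls <- read_control_table("results/controls.tsv")
group_sizes <- sim_config()$group_sizes

verdicts <- prioritise(annotate_anatomy(variants), gene_meta,
                       mode = "burden_75bp")
burden <- dplyr::bind_rows(lapply(names(group_sizes), function(d) {
  run_burden(verdicts, controls, gene_meta, d, case_n = group_sizes[[d]])
}))
burden$excess_pct <- 100 * burden$excess
write_report(burden, "results/burden.tsv")

sig <- burden[burden$significant, ]
cat(sprintf("%d of %d gene x disease tests significant after Bonferroni:\n",
            nrow(sig), nrow(burden)))
for (i in seq_len(nrow(sig))) {
  cat(sprintf("  %s in %s: excess %s%%, p = %.2e (power %.2f)\n",
              sig$gene[i], sig$disease[i], format_percent(sig$excess[i]),
              sig$p_one_sided[i], sig$power[i]))
}
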