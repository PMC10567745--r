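#!/usr/bin/env Rscript
# Stage 5: cohort summary report.
#
# Carrier percentages per disease, per-gene unique-variant shares, the
# splice-region location histogram, tool-concordance tallies and the
# classification tally, written as TSV/JSON under results/.

suppressPackageStartupMessages(library(spliceburden))

variants <- read_variant_table("results/variants.tsv")
gene_meta <- read_gene_meta("results/gene_meta.tsv")
group_sizes <- sim_config()$group_sizes

verdicts <- prioritise(annotate_anatomy(variants), gene_meta,
                       mode = "discovery")
cls <- classify_variants(verdicts, gene_meta)
s <- summarise_cohort(verdicts, group_sizes, cls)

write_report(s$per_disease, "results/summary_per_disease.tsv")
write_report(s$per_gene, "results/summary_per_gene.tsv")
write_report(s$locations, "results/summary_locations.tsv")
write_report(s, "results/summary.json", format = "json")

cat(sprintf("%d of %d participants (%s%%) carry a candidate variant\n",
            s$overall$carriers, s$overall$participants,
            format_percent(s$overall$carriers / s$overall$participants)))
top <- head(s$per_gene, 5)
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %s: %d unique variants (%s%%)\n", top$gene[i],
              top$unique_variants[i], format_percent(top$share_pct[i] / 100)))
}
cat("concordance (canonical sites, number of tools 1-4):",
    s$concordance_canonical$n_variants, "\n")
cat("concordance (non-canonical: MES only / both / SpliceAI only):",
    s$concordance_non_canonical$n_variants, "\n")
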