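#!/usr/bin/env Rscript
# Stage 2: splice anatomy and candidate prioritisation.
#
# Parses each variant's HGVS c. notation, classifies it into the
# donor/acceptor/deep-intronic/exonic taxonomy, infers site-loss vs
# site-gain, and applies the rarity, phenotype-concordance, exclusion-list
# and in silico thresholds (MES > 4 change, ADA/RF > 0.6, SpliceAI > 0.5).

suppressPackageStartupMessages(library(spliceburden))

variants <- read_variant_table("results/variants.tsv")
gene_meta <- read_gene_meta("results/gene_meta.tsv")

annotated <- annotate_anatomy(variants)
verdicts <- prioritise(annotated, gene_meta, mode = "discovery")

flat <- verdicts
flat$tools_flagging <- vapply(flat$tools_flagging, paste, "", collapse = ";")
flat$failed_filters <- vapply(flat$failed_filters, paste, "", collapse = ";")
write_report(flat, "results/verdicts.tsv")

anatomy_cols <- c("transcript", "hgvs_c", "gene", "region", "intron_offset",
                  "exon_edge", "essential_dinucleotide", "mechanism")
write_report(unique_variants(verdicts)[, anatomy_cols], "results/anatomy.tsv")

uv <- unique_variants(verdicts[verdicts$candidate, ])
carriers <- length(unique(verdicts$participant_id[verdicts$candidate]))
cat(sprintf("%d candidate observations in %d carriers; %d unique variants\n",
            sum(verdicts$candidate), carriers, nrow(uv)))
print(table(uv$region))
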