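#!/usr/bin/env Rscript
# Stage 4: ACMG/AMP classification with RNA-evidence reclassification.
#
# Assigns PVS1 (dosage-sensitivity ladder), PS4/PP1 (proband and
# segregation thresholds), PM2/PP3 (rarity and in silico concordance) and,
# for variants with an RNA functional outcome, PS3/PM4 via frame
# arithmetic, then combines points (supporting 1 / moderate 2 / strong 4 /
# very strong 8; VUS <= 5, LP 6-9, P >= 10).

suppressPackageStartupMessages(library(spliceburden))

variants <- read_variant_table("results/variants.tsv")
gene_meta <- read_gene_meta("results/gene_meta.tsv")

verdicts <- prioritise(annotate_anatomy(variants), gene_meta,
                       mode = "discovery")
cls <- classify_variants(verdicts, gene_meta)
write_report(cls, "results/classifications.tsv")

cat(sprintf("classified %d unique candidate variants: %d P/LP, %d VUS\n",
            nrow(cls),
            sum(cls$cls %in% c("pathogenic", "likely_pathogenic")),
            sum(cls$cls == "VUS")))
rna <- cls[!is.na(cls$cls_after), ]
cat(sprintf("%d variants had RNA evidence; %d upgraded on reclassification\n",
            nrow(rna), sum(rna$transition == "upgrade")))
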