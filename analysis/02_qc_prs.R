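#!/usr/bin/env Rscript
# Step 2 - panel filtering, call-rate QC, polygenic risk score and genotype
# principal components.
#
# The 123-SNP candidate panel is reduced by removing SNPs with OR strictly
# inside (0.95, 1.05) and SNPs flagged as genotyping failures (123 - 28 - 3
# = 92 retained). Samples with call rate < 0.95 and SNPs with genotyping
# rate < 0.95 or duplicate-control errors are discarded. The PRS is the
# weighted sum of effect-allele counts with log-OR weights, normalized by
# the control median and standardized by the control mean/SD; the first
# five genotype principal components are computed for structure adjustment.

library(prsband)

inp <- read_inputs("results/cohort/panel.tsv",
                   "results/cohort/dosages.tsv",
                   "results/cohort/phenotypes.csv")

panel <- filter_snp_panel(inp$panel)
cat(sprintf("panel: %d of %d SNPs retained (%d removed)\n",
            nrow(panel), nrow(inp$panel), nrow(attr(panel, "removed"))))
print(table(attr(panel, "removed")$reason))

gt <- inp$cohort$genotypes[, panel$rsid, drop = FALSE]
gt <- qc_samples(gt, threshold = 0.95)
gt <- qc_snps(gt, threshold = 0.95, panel = panel)
panel <- panel[panel$rsid %in% colnames(gt), ]
cat(sprintf("QC: %d samples x %d SNPs retained\n", nrow(gt), ncol(gt)))

phen <- inp$cohort$phenotypes
phen <- phen[phen$sample_id %in% rownames(gt), ]
raw <- compute_prs(gt, panel)
prs <- normalize_prs(raw, phen$sample_id[phen$outcome == 0])
cat(sprintf("PRS: control median %.3f, control SD %.3f\n",
            attr(prs, "control_median"), attr(prs, "control_sd")))

pcs <- genotype_pcs(gt, k = 5)

dir.create("results", showWarnings = FALSE)
write.table(prs, "results/prs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(sample_id = rownames(pcs), pcs),
            "results/pcs.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/prs.tsv and results/pcs.tsv\n")
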