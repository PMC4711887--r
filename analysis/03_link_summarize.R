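#!/usr/bin/env Rscript
# Stage 3: link assessments to occurrences and summarize prevalence.
#
# Inner join on the six-field verbatim name key, covariate
# standardization with machine-readable exclusions, the per-category
# prevalence table, the 15-cell issue-overlap partition, and the
# person-hours projection for hand-vetting at the published rate of
# 4 hours per 100 records.

suppressPackageStartupMessages(library(taxonvet))

assessed <- read_assessment_table("results/assessments.tsv")
occurrences <- read_occurrence_table("results/bundle/occurrences.tsv")

lk <- link_occurrences(assessed, occurrences)
std <- standardize_covariates(lk$matched)
readr::write_tsv(std$covariates, "results/covariates.tsv")
readr::write_tsv(std$exclusions, "results/covariate_exclusions.tsv")

summary_tbl <- summarize_issues(assessed, lk$matched)
readr::write_tsv(summary_tbl, "results/summary.tsv", na = "")
overlap <- issue_overlap(assessed)
readr::write_tsv(overlap, "results/issue_overlap.tsv")

cat(sprintf("matched %d occurrences (%d names unmatched); %d usable for modelling, %d excluded\n",
            nrow(lk$matched), length(lk$unmatched_names),
            nrow(std$covariates), nrow(std$exclusions)))
cat("\nprevalence summary:\n")
print(as.data.frame(summary_tbl), row.names = FALSE)
cat("\nnon-empty issue overlaps:\n")
print(as.data.frame(overlap[overlap$n > 0, ]), row.names = FALSE)

hours <- project_effort(nrow(assessed), 4, 100)
cat(sprintf("\nhand-vetting this corpus at 4 h / 100 records: %d person-hours\n",
            hours))
cat(sprintf("(the same arithmetic for a 522,163-name corpus gives %d person-hours)\n",
            project_effort(522163, 4, 100)))
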