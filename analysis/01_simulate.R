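#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study bundle.
#
# Emulates the study conditions: 1,000 distinct name combinations drawn
# from a synthetic authority, corrupted by the four issue classes at the
# reference prevalence rates (misspelling 12.9%, format 8.9%, conceptual
# 13.7%, synonymy 27%), each name linked to a heavy-tailed number of
# occurrence records carrying modelling covariates. Everything is a
# deterministic function of the seed.

suppressPackageStartupMessages(library(taxonvet))

seed <- 1
out_dir <- "results/bundle"

bundle <- generate_dataset(generator_config(seed = seed))
write_dataset(bundle, out_dir)

cat(sprintf("authority: %d entries (%d accepted, %d synonyms)\n",
            length(bundle$authority),
            sum(bundle$authority$entries$status == "accepted"),
            sum(bundle$authority$entries$status == "synonym")))
cat(sprintf("names: %d combinations; occurrences: %d records from %d institutions\n",
            nrow(bundle$names), nrow(bundle$occurrences),
            nrow(bundle$institution_counts)))
rates <- colMeans(bundle$truth[, c("has_misspelling", "has_format",
                                   "has_conceptual", "has_synonym")])
cat("realized issue rates:",
    paste(sprintf("%s %.3f", sub("has_", "", names(rates)), rates),
          collapse = ", "), "\n")
cat("bundle written to", out_dir, "\n")
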