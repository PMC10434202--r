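#!/usr/bin/env Rscript
# Call genomic alterations in the simulated cohort: RC profiles from the
# allele depths, penalized minimal-misfit copy-state segmentation, event
# typing/classification, and translocation pairing. Compares the calls
# with the generator's ground truth and writes called_events.tsv,
# translocations.tsv and calling_summary.tsv under results/sim/.

suppressMessages(library(lohscan))

cfg <- run_config(out_dir = "results/sim", seed = 20230703,
                  n_isolates = 31,
                  divisions_per_isolate = c(rep(400L, 28), rep(50L, 3)),
                  n_snps = 50000, design = design_furfural_subculture())

res <- run_call(cfg)
calls <- res$events
message(sprintf("called %d events across %d isolates", nrow(calls),
                length(unique(calls$isolate))))
print(table(calls$type, calls$class))
if (!is.null(res$hypotheses)) {
  message("translocation hypotheses:")
  print(res$hypotheses[, c("isolate", "kind", "centric_chrom",
                           "acentric_chrom", "predicted_size")])
}

# score against ground truth (events spanning >= 3 SNPs)
truth <- read.table("results/sim/true_events.tsv", sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
names(truth) <- sub("^true_", "", names(truth))
truth <- truth[truth$end_snp - truth$start_snp + 1 >= 3, ]
hits <- 0L
for (iso in unique(truth$isolate)) {
  m <- match_event_sets(calls[calls$isolate == iso, , drop = FALSE],
                        truth[truth$isolate == iso, , drop = FALSE],
                        exact = FALSE)
  hits <- hits + sum(m$recall_hits)
}
summary <- data.frame(n_truth = nrow(truth), n_calls = nrow(calls),
                      recall = hits / nrow(truth))
write.table(summary, "results/sim/calling_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("recall vs ground truth: %.3f (%d/%d)", summary$recall,
                hits, nrow(truth)))
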