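#!/usr/bin/env Rscript
# Simulate the furfural subculture cohort: 31 hybrid-diploid isolates
# (28 subcultured for 8 cycles = 400 divisions, 3 for a single cycle = 50
# divisions) with genomic alterations spiked at the furfural-arm rates,
# sequenced at 50x over ~50,000 homolog-specific SNP sites. Writes
# per-isolate allele-depth tables, the ground-truth event list and a run
# manifest under results/sim/.

suppressMessages(library(lohscan))

cfg <- run_config(out_dir = "results/sim", seed = 20230703,
                  n_isolates = 31,
                  divisions_per_isolate = c(rep(400L, 28), rep(50L, 3)),
                  n_snps = 50000, mean_depth = 50,
                  event_rates = furfural_event_rates(),
                  design = design_furfural_subculture())

sim <- run_simulate(cfg)
truth <- do.call(rbind, sim$truth[vapply(sim$truth, nrow, 0L) > 0])

message(sprintf("simulated %d isolates over %s genome-divisions",
                cfg$n_isolates, format(total_divisions(cfg$design),
                                       big.mark = ",")))
message(sprintf("spiked %d events: %s", nrow(truth),
                paste(sprintf("%s=%d", names(table(truth$type)),
                              table(truth$type)), collapse = ", ")))
message("outputs under results/sim/ (depths, true_events.tsv, manifest.json)")
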