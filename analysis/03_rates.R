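#!/usr/bin/env Rscript
# Rate arithmetic: per-genome per-cell-division rates of each event class
# under the reconstructed subculture designs, fold changes against the
# untreated control, per-base mutation rates, and the relative-ratio table
# across conditions. Uses (a) the study's published event counts as inputs
# and (b) the simulated cohort's called events from 02_call_events.R.

suppressMessages(library(lohscan))
dir.create("results", showWarnings = FALSE)

furf <- design_furfural_subculture()
ctrl <- design_untreated_subculture()
seqd <- design_furfural_sequenced()

## ---- published event counts through the rate estimators ------------------
study <- data.frame(
  group = c(rep("furfural_0.6g", 4), rep("untreated", 2)),
  event_type = c("T-LOH", "I-LOH", "rearrangement", "aneuploidy",
                 "I-LOH", "T-LOH"),
  n = c(39, 25, 8, 36, 12, 4))
study$divisions <- ifelse(study$group == "untreated",
                          total_divisions(ctrl), total_divisions(furf))
study$rate <- mapply(function(n, grp)
  estimate_event_rate(n, if (grp == "untreated") ctrl else furf)$rate,
  study$n, study$group)
study$rate_reported <- signif(study$rate, 2)
study$fold_vs_untreated <- NA
study$fold_vs_untreated[1] <-
  fold_change(study$rate_reported[1], study$rate_reported[6])$fold_reported
study$fold_vs_untreated[2] <-
  fold_change(study$rate[2], study$rate[5])$fold_reported
write.table(study, "results/rates_study.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("per-division rates from published counts:")
print(study)

snv <- estimate_base_rate(53, seqd, 24e6)
indel <- estimate_base_rate(3, seqd, 24e6)
message(sprintf("SNV rate %.2g /bp/division; indel rate %.2g /bp/division",
                snv$rate_reported, indel$rate_reported))

## ---- relative-ratio table across conditions ------------------------------
counts <- rbind(
  spontaneous = c(trisomy = 12, monosomy = 3, del_dup = 47,
                  i_loh = 859, t_loh = 356),
  furfural_20g = c(3, 0, 4, 109, 41),
  furfural_0.6g = c(14, 13, 8, 25, 39))
rt <- ratio_table(counts)
write.table(data.frame(condition = rownames(rt$percent), rt$percent),
            "results/ratio_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("relative ratios (%):")
print(rt$percent)

## ---- T:I LOH shift (Fisher) ----------------------------------------------
ft <- fisher_exact_2x2(rbind(c(39, 25), c(4, 12)))
message(sprintf("T-LOH:I-LOH shift, furfural vs untreated: p = %.4f",
                ft$p_value))

## ---- simulated cohort rates ----------------------------------------------
called <- "results/sim/called_events.tsv"
if (file.exists(called)) {
  cfg <- run_config(out_dir = "results/sim", seed = 20230703,
                    n_isolates = 31, design = furf)
  rates <- run_report(cfg)
  message("simulated-cohort rates (results/sim/rates.tsv):")
  print(rates)
} else {
  message("run 01_simulate.R and 02_call_events.R first for cohort rates")
}
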