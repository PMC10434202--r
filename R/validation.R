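#' Match called events against a ground-truth event list
#'
#' Greedy one-to-one matching by chromosome, event type and affected
#' homolog; two events pair when their SNP ranges are identical
#' (`exact = TRUE`) or overlap reciprocally (Jaccard index of the SNP
#' ranges at least 0.5).
#'
#' @param calls event-call table ([call_events()] output).
#' @param truth ground-truth event table ([spike_events()] output).
#' @param exact require identical SNP ranges (default) or reciprocal
#'   overlap.
#' @return list with logical vectors `recall_hits` (per truth row) and
#'   `precision_hits` (per call row), and `pairs`, an integer vector giving
#'   for each truth row the index of its matched call (NA if unmatched).
#' @export
match_event_sets <- function(calls, truth, exact = TRUE) {
  used <- logical(nrow(calls))
  hit <- logical(nrow(truth))
  pairs <- rep(NA_integer_, nrow(truth))
  for (k in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(calls))) {
      if (used[j]) next
      if (calls$chrom[j] != truth$chrom[k]) next
      if (calls$type[j] != truth$type[k]) next
      if (!identical(calls$homolog[j], truth$homolog[k])) next
      if (exact) {
        ok <- calls$start_snp[j] == truth$start_snp[k] &&
          calls$end_snp[j] == truth$end_snp[k]
      } else {
        inter <- min(calls$end_snp[j], truth$end_snp[k]) -
          max(calls$start_snp[j], truth$start_snp[k]) + 1
        uni <- max(calls$end_snp[j], truth$end_snp[k]) -
          min(calls$start_snp[j], truth$start_snp[k]) + 1
        ok <- inter > 0 && inter / uni >= 0.5
      }
      if (ok) { used[j] <- TRUE; hit[k] <- TRUE; pairs[k] <- j; break }
    }
  }
  list(recall_hits = hit, precision_hits = used, pairs = pairs)
}

#' Caller-versus-simulator oracle study
#'
#' Simulates a cohort of isolates with known spiked events, runs the full
#' calling pipeline (RC computation, segmentation, event calling) on each,
#' and scores the calls against the ground truth: recall and precision over
#' events spanning at least `min_snps` SNP sites, and the fraction of true
#' breakpoints (the inter-SNP midpoints the generator snapped to) contained
#' in the reported breakpoint intervals. With `noiseless = TRUE` the depths
#' are the exact Poisson means, so the caller is expected to recover every
#' qualifying event exactly.
#'
#' @param genome a [genome_map()].
#' @param n_isolates number of simulated isolates.
#' @param seed base RNG seed (each isolate derives its own).
#' @param divisions genome-divisions per isolate.
#' @param event_rates per-division event rates.
#' @param mean_depth sequencing depth.
#' @param noiseless use exact expected depths instead of Poisson draws.
#' @param min_snps minimum truth-event span scored (default 3).
#' @return list with `n_truth`, `n_calls`, `recall`, `precision`,
#'   `breakpoints_scored`, `breakpoint_coverage`, `exact_all` (TRUE when
#'   every qualifying truth event was recovered exactly and no extra call
#'   was made).
#' @export
caller_oracle_study <- function(genome, n_isolates, seed,
                                divisions = 400,
                                event_rates = furfural_event_rates(),
                                mean_depth = 50, noiseless = FALSE,
                                min_snps = 3L) {
  n_truth <- 0L; n_calls <- 0L; rec <- 0L; prec <- 0L
  bp_tot <- 0L; bp_cov <- 0L; exact_all <- TRUE
  for (i in seq_len(n_isolates)) {
    cfg <- simulation_config(rng_seed = seed + 13L * i,
                             mean_depth = mean_depth,
                             event_rates = event_rates)
    sp <- spike_events(genome, cfg, divisions = divisions)
    dep <- if (noiseless) expected_depths(sp$karyotype, genome, mean_depth)
           else simulate_allele_depths(sp$karyotype, genome, cfg)
    calls <- call_events(segment_copy_states(compute_rc(dep, genome)),
                         genome)
    truth <- sp$events[sp$events$end_snp - sp$events$start_snp + 1L >=
                         min_snps, , drop = FALSE]
    m <- match_event_sets(calls, truth, exact = noiseless)
    n_truth <- n_truth + nrow(truth)
    n_calls <- n_calls + nrow(calls)
    rec <- rec + sum(m$recall_hits)
    prec <- prec + sum(m$precision_hits)
    if (!all(m$recall_hits) || nrow(calls) != nrow(truth))
      exact_all <- FALSE
    for (k in which(m$recall_hits)) {
      j <- m$pairs[k]
      n_c <- length(genome$snps$pos[genome$snps$chrom == truth$chrom[k]])
      if (truth$start_snp[k] > 1L) {
        bp_tot <- bp_tot + 1L
        if (truth$start[k] >= calls$bp_left_lo[j] &&
            truth$start[k] <= calls$bp_left_hi[j]) bp_cov <- bp_cov + 1L
      }
      if (truth$end_snp[k] < n_c) {
        bp_tot <- bp_tot + 1L
        if (truth$end[k] >= calls$bp_right_lo[j] &&
            truth$end[k] <= calls$bp_right_hi[j]) bp_cov <- bp_cov + 1L
      }
    }
  }
  list(n_truth = n_truth, n_calls = n_calls,
       recall = if (n_truth) rec / n_truth else NA_real_,
       precision = if (n_calls) prec / n_calls else NA_real_,
       breakpoints_scored = bp_tot,
       breakpoint_coverage = if (bp_tot) bp_cov / bp_tot else NA_real_,
       exact_all = exact_all)
}

# exact expected depths (the Poisson means): mean_depth * copies / 2
expected_depths <- function(karyotype, genome, mean_depth = 50) {
  out <- genome$snps[, c("chrom", "pos")]
  w <- numeric(nrow(out)); y <- numeric(nrow(out))
  off <- 0L
  for (cc in karyotype$genome_chroms) {
    cp <- karyotype$copies[[cc]]
    n <- nrow(cp)
    if (n) {
      w[off + seq_len(n)] <- mean_depth * cp[, "W"] / 2
      y[off + seq_len(n)] <- mean_depth * cp[, "Y"] / 2
    }
    off <- off + n
  }
  out$w_depth <- w; out$y_depth <- y
  out
}

#' Event-rate parameter recovery study
#'
#' Spikes one event type at a known per-division rate into replicate
#' simulated experiments, re-estimates the rate from the called events of
#' each experiment through the full pipeline, and reports the mean estimate
#' with the binomial standard error of the truth — the estimate should sit
#' within a few SE of the spiked rate.
#'
#' @param genome a [genome_map()].
#' @param rate spiked per-division rate.
#' @param type event type to spike (default "T-LOH").
#' @param n_replicates replicate experiments (default 20).
#' @param n_isolates isolates per experiment (default 50).
#' @param divisions divisions per isolate (default 400).
#' @param seed base RNG seed.
#' @param mean_depth sequencing depth.
#' @return list with `true_rate`, `mean_estimate`, `se` (binomial SE of the
#'   mean over all divisions), `z` (standardized deviation), and the
#'   per-replicate estimates.
#' @export
rate_recovery_study <- function(genome, rate = 3.4e-3, type = "T-LOH",
                                n_replicates = 20, n_isolates = 50,
                                divisions = 400, seed = 1,
                                mean_depth = 50) {
  rates <- stats::setNames(rate, type)
  est <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    n_ev <- 0L
    for (i in seq_len(n_isolates)) {
      cfg <- simulation_config(rng_seed = seed + 1009L * r + 13L * i,
                               mean_depth = mean_depth,
                               event_rates = rates)
      sp <- spike_events(genome, cfg, divisions = divisions)
      dep <- simulate_allele_depths(sp$karyotype, genome, cfg)
      calls <- call_events(segment_copy_states(compute_rc(dep, genome)),
                           genome)
      n_ev <- n_ev + sum(calls$type == type)
    }
    est[r] <- n_ev / (n_isolates * divisions)
  }
  D <- n_replicates * n_isolates * divisions
  se <- sqrt(rate * (1 - rate) / D)
  list(true_rate = rate, mean_estimate = mean(est), se = se,
       z = (mean(est) - rate) / se, estimates = est)
}
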