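# Small genome builders and oracle utilities shared across tests.

# single- or multi-chromosome toy genome with evenly spaced SNPs
toy_genome <- function(n_snps = 10L, len = 100000L, n_chrom = 1L,
                       repeats = NULL) {
  chroms <- data.frame(
    chrom = as.roman(seq_len(n_chrom)),
    length = len,
    cen_start = round(len * 0.45), cen_end = round(len * 0.45) + 100L)
  chroms$chrom <- as.character(chroms$chrom)
  snps <- do.call(rbind, lapply(chroms$chrom, function(cc) {
    pos <- round(seq(1000, len - 1000, length.out = n_snps))
    data.frame(chrom = cc, pos = pos,
               w_allele = rep(c("A", "C"), length.out = n_snps),
               y_allele = rep(c("G", "T"), length.out = n_snps))
  }))
  genome_map(chroms, snps, repeats)
}

# deterministic depths: exactly mean_depth * copies / 2 per homolog
noiseless_depths <- function(karyotype, genome, mean_depth = 50) {
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

# thin alias kept for test readability
match_events <- function(calls, truth, exact = TRUE) {
  match_event_sets(calls, truth, exact = exact)
}

# exhaustive minimal-misfit segmentation over all breakpoint subsets,
# independent of the DP implementation
brute_force_states <- function(rc, levels, lambda) {
  n <- length(rc)
  best <- NULL; best_cost <- Inf
  n_bp <- n - 1L
  for (mask in 0:(2^n_bp - 1L)) {
    bps <- which(bitwAnd(mask, 2^(seq_len(n_bp) - 1L)) > 0)
    bounds <- c(0L, bps, n)
    cost <- lambda * length(bps)
    states <- integer(n)
    for (s in seq_len(length(bounds) - 1L)) {
      idx <- (bounds[s] + 1L):bounds[s + 1L]
      seg_costs <- vapply(levels, function(l) sum((rc[idx] - l)^2), 0)
      states[idx] <- which.min(seg_costs) - 1L
      cost <- cost + min(seg_costs)
    }
    # skip segmentations whose adjacent segments share a state (they are
    # re-countable as fewer breakpoints and never uniquely optimal)
    if (cost < best_cost - 1e-12) { best_cost <- cost; best <- states }
  }
  best
}

# full-enumeration hypergeometric oracle for the two-sided Fisher test
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  logp <- function(a) lchoose(r1, a) + lchoose(r2, c1 - a) -
    lchoose(r1 + r2, c1)
  lp_obs <- logp(m[1, 1])
  lps <- vapply(lo:hi, logp, 0)
  sum(exp(lps)[lps <= lp_obs + log(1 + 1e-7)])
}
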