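test_that("event rates reproduce the printed per-division values", {
  furf <- design_furfural_subculture()
  ctrl <- design_untreated_subculture()
  expect_equal(estimate_event_rate(39, furf)$rate_reported, 3.4e-3)
  expect_equal(estimate_event_rate(25, furf)$rate_reported, 2.2e-3)
  expect_equal(estimate_event_rate(8, furf)$rate_reported, 7.0e-4)
  expect_equal(estimate_event_rate(36, furf)$rate_reported, 3.2e-3)
  expect_equal(estimate_event_rate(12, ctrl)$rate_reported, 1.2e-3)
  expect_equal(estimate_event_rate(4, ctrl)$rate_reported, 4e-4)
  expect_equal(estimate_event_rate(0, ctrl)$rate, 0)
  expect_error(estimate_event_rate(-1, ctrl), ">= 0")
})

test_that("per-base mutation rates use divisions x genome size", {
  seqd <- design_furfural_sequenced()
  expect_equal(estimate_base_rate(53, seqd, 24e6)$rate_reported, 3.0e-10)
  expect_equal(estimate_base_rate(3, seqd, 24e6)$rate_reported, 1.7e-11)
  expect_equal(estimate_base_rate(0, seqd)$rate, 0)
})

test_that("rate estimators are scale-invariant", {
  base <- culture_design(data.frame(n_isolates = 5, cycles = 4,
                                    colonies_per_cycle = 1,
                                    divisions_per_colony = 25))
  r1 <- estimate_event_rate(7, base)$rate
  for (k in c(2, 3, 10)) {
    scaled <- culture_design(data.frame(n_isolates = 5 * k, cycles = 4,
                                        colonies_per_cycle = 1,
                                        divisions_per_colony = 25))
    expect_equal(estimate_event_rate(7 * k, scaled)$rate, r1)
  }
})

test_that("fold changes match the printed comparisons", {
  furf <- design_furfural_subculture()
  ctrl <- design_untreated_subculture()
  t_fold <- fold_change(estimate_event_rate(39, furf),
                        estimate_event_rate(4, ctrl))
  i_fold <- fold_change(estimate_event_rate(25, furf),
                        estimate_event_rate(12, ctrl))
  expect_equal(t_fold$fold_reported, 8.6, tolerance = 0.02)
  expect_equal(i_fold$fold_reported, 1.8)
  expect_equal(fold_change(3.4e-3, 4e-4)$fold_reported, 8.5)
  expect_equal(fold_change(1, 1)$fold, 1)
  expect_error(fold_change(1, 0), "baseline")
})

test_that("Fisher's exact test matches enumeration and finds the T:I shift", {
  shift <- fisher_exact_2x2(rbind(c(39, 25), c(4, 12)))
  expect_lt(shift$p_value, 0.05)
  expect_equal(shift$p_value, fisher_oracle(rbind(c(39, 25), c(4, 12))),
               tolerance = 1e-10)
  expect_equal(fisher_exact_2x2(rbind(c(10, 10), c(10, 10)))$p_value, 1)
  expect_warning(p0 <- fisher_exact_2x2(rbind(c(0, 0), c(3, 4)))$p_value,
                 "margin")
  expect_equal(p0, 1)
})

test_that("Fisher p-values agree with the hypergeometric oracle on random tables", {
  set.seed(21)
  for (i in 1:150) {
    m <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p <- fisher_exact_2x2(m)$p_value
    expect_equal(p, fisher_oracle(m), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-9)
    expect_equal(p, fisher_exact_2x2(t(m))$p_value, tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(m[2:1, 2:1])$p_value, tolerance = 1e-12)
    expect_true(p > 0 && p <= 1)
  }
})

test_that("SNV enrichment in LOH regions reproduces the worked example", {
  e <- region_enrichment(4, 53, 557567, 24000000)
  expect_equal(e$expected_reported, 1.2)
  expect_equal(e$expected, 557567 / 24e6 * 53, tolerance = 1e-12)
  expect_equal(e$chi_square, 6.68, tolerance = 0.01)
  expect_lt(e$p_value, 0.01)
  # direction cross-check with an exact binomial tail at the same fraction
  bin <- stats::binom.test(4, 53, 557567 / 24e6,
                           alternative = "greater")$p.value
  expect_lt(bin, 0.05)
  # region = genome forces expected = total and p = 1
  e2 <- region_enrichment(53, 53, 24e6, 24e6)
  expect_equal(e2$expected, 53)
  expect_equal(e2$chi_square, 0)
  expect_equal(e2$p_value, 1)
  expect_error(region_enrichment(4, 53, 25e6, 24e6), "region_bp")
  expect_error(region_enrichment(54, 53, 1e6, 24e6), "observed")
})

test_that("spectrum tallies collapse complementary substitutions", {
  t1 <- tally_spectrum(data.frame(ref = "C", alt = "T"))
  expect_equal(unname(t1$proportions["CG>TA"]), 1)
  t2 <- tally_spectrum(data.frame(ref = "G", alt = "A"))
  expect_equal(unname(t2$counts["CG>TA"]), 1L)   # strand collapse
  snvs <- data.frame(ref = c("C", "G", "T", "A", "C", "G"),
                     alt = c("T", "T", "C", "C", "G", "C"))
  t3 <- tally_spectrum(snvs)
  expect_equal(t3$total, 6L)
  expect_equal(sum(t3$proportions), 1, tolerance = 1e-12)
  expect_equal(unname(t3$counts[c("CG>TA", "CG>AT", "TA>CG", "TA>GC",
                                  "CG>GC")]),
               c(1L, 1L, 1L, 1L, 2L))
  expect_warning(t4 <- tally_spectrum(data.frame(ref = c("C", "N"),
                                                 alt = c("T", "A"))),
                 "skipped")
  expect_equal(t4$total, 1L)
})

test_that("spectra comparisons use the oxidation split", {
  a <- tally_spectrum(data.frame(ref = rep("C", 10),
                                 alt = rep(c("T", "G"), 5)))
  expect_equal(compare_spectra(a, a)$p_value, 1)
  # (60,40) vs (48,52) against the enumeration oracle
  mk <- function(oxi, oth) tally_spectrum(data.frame(
    ref = "C", alt = c(rep("T", oxi), rep("G", oth))))
  p <- compare_spectra(mk(60, 40), mk(48, 52))$p_value
  expect_equal(p, fisher_oracle(rbind(c(60, 40), c(48, 52))),
               tolerance = 1e-10)
  # extreme spectra separate at n = 20 per group
  all_oxi <- mk(20, 0)
  uniform <- tally_spectrum(data.frame(
    ref = rep(c("C", "C", "C", "T", "T", "T"), length.out = 20),
    alt = rep(c("T", "A", "G", "C", "A", "G"), length.out = 20)))
  expect_lt(compare_spectra(all_oxi, uniform)$p_value, 0.05)
})

test_that("mutant frequency summarizes parallel cultures robustly", {
  expect_equal(mutant_frequency(c(0, 0, 0), c(1e6, 1e6, 1e6))$median, 0)
  expect_equal(mutant_frequency(23, 1e6)$median, 2.3e-5)
  expect_error(mutant_frequency(c(1, 2), 1e6), "equal length")
  expect_error(mutant_frequency(1, 0), "positive")
  # Luria-Delbruck style cultures: median tracks the simulation's median
  set.seed(31)
  sim_culture <- function() {
    n0 <- 1; gens <- 20; mu <- 2e-7
    mutants <- 0; n <- n0
    for (g in seq_len(gens)) {
      new_mut <- rpois(1, n * mu)
      mutants <- 2 * mutants + new_mut
      n <- 2 * n
    }
    c(mutants = mutants, viable = n)
  }
  cultures <- t(replicate(1000, sim_culture()))
  mf <- mutant_frequency(cultures[, "mutants"], cultures[, "viable"])
  direct <- median(cultures[, "mutants"] / cultures[, "viable"])
  expect_true(mf$median <= 2 * direct + 1e-12 &&
                mf$median >= direct / 2 - 1e-12)
  expect_gte(mf$mean, mf$median)   # jackpot cultures drag the mean up
})

test_that("breakpoint distributions report window proportions", {
  expect_equal(breakpoint_distribution(c(500, 600, 700), c(450, 1050)), 1)
  expect_equal(breakpoint_distribution(c(100, 200), c(450, 1050)), 0)
  expect_error(breakpoint_distribution(numeric(0), c(1, 2)), "no breakpoints")
  set.seed(41)
  L <- 1531933
  mids <- runif(10000, 1, L)
  prop <- breakpoint_distribution(mids, c(1, L / 4))
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(prop - 0.25), 3 * se)
})

test_that("relative-ratio tables convert counts to row percentages", {
  counts <- rbind(
    spontaneous = c(trisomy = 12, monosomy = 3, del_dup = 47,
                    i_loh = 859, t_loh = 356),
    furfural_20g = c(3, 0, 4, 109, 41))
  rt <- ratio_table(counts)
  expect_equal(unname(rt$percent["spontaneous", c("i_loh", "t_loh")]),
               c(67.3, 27.9))
  expect_equal(unname(rt$percent["furfural_20g", "i_loh"]), 69.4)
  expect_equal(unname(ratio_table(matrix(c(5, 0), 1))$percent[1, 1]), 100)
  expect_error(ratio_table(rbind(c(0, 0))), "row total")
})
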