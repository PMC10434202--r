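test_that("explicit interstitial LOH sets copy numbers as specified", {
  g <- yeast_genome_map(20000)
  cfg <- simulation_config(rng_seed = 1, events = data.frame(
    type = "I-LOH", chrom = "XV", start = 369905, end = 372085,
    homolog = "W"))
  sp <- spike_events(g, cfg)
  cp <- sp$karyotype$copies[["XV"]]
  rng <- sp$events$start_snp:sp$events$end_snp
  expect_true(all(cp[rng, "W"] == 0L) && all(cp[rng, "Y"] == 2L))
  expect_true(all(cp[-rng, "W"] == 1L) && all(cp[-rng, "Y"] == 1L))
})

test_that("empty event list yields the fully heterozygous diploid", {
  g <- toy_genome(n_snps = 50)
  cfg <- simulation_config(rng_seed = 1, events = data.frame(
    type = character(), chrom = character(), homolog = character(),
    start = numeric(), end = numeric()))
  sp <- spike_events(g, cfg)
  expect_equal(nrow(sp$events), 0)
  expect_true(all(sp$karyotype$copies[["I"]] == 1L))
})

test_that("event classes change total copy number as defined", {
  g <- yeast_genome_map(8000)
  ev <- data.frame(
    type = c("I-LOH", "T-LOH", "T-DEL", "T-DUP", "TRISOMY", "MONOSOMY",
             "UPD"),
    chrom = c("IV", "XIV", "III", "II", "IX", "V", "VIII"),
    start = c(500000, 1, 1, 1, NA, NA, NA),
    end = c(600000, 400000, 175342, 300000, NA, NA, NA),
    homolog = c("W", "Y", "W", "W", "Y", "W", "W"))
  sp <- spike_events(g, simulation_config(rng_seed = 3, events = ev))
  total <- function(cc) rowSums(sp$karyotype$copies[[cc]])
  ev2 <- sp$events
  rng <- function(k) ev2$start_snp[k]:ev2$end_snp[k]
  expect_true(all(total("IV")[rng(1)] == 2))   # copy-neutral I-LOH
  expect_true(all(total("XIV")[rng(2)] == 2))  # copy-neutral T-LOH
  expect_true(all(total("III")[rng(3)] == 1))  # T-DEL loses one copy
  expect_true(all(total("II")[rng(4)] == 3))   # T-DUP gains one copy
  expect_true(all(total("IX") == 3))           # trisomy
  expect_true(all(total("V") == 1))            # monosomy
  expect_true(all(total("VIII") == 2))         # UPD copy-neutral
  cp <- sp$karyotype$copies[["VIII"]]
  expect_true(all(cp[, "W"] == 0L) && all(cp[, "Y"] == 2L))
})

test_that("conflicting explicit events are rejected with their ids", {
  g <- toy_genome(n_snps = 100)
  ev <- data.frame(type = c("I-LOH", "I-LOH"), chrom = "I",
                   start = c(20000, 30000), end = c(50000, 60000),
                   homolog = c("W", "Y"),
                   event_id = c("a", "b"))
  expect_error(spike_events(g, simulation_config(rng_seed = 1, events = ev)),
               "a vs b|conflict")
})

test_that("same seed gives bit-identical simulator output", {
  g <- yeast_genome_map(5000)
  cfg <- simulation_config(rng_seed = 42)
  a <- spike_events(g, cfg, divisions = 400)
  b <- spike_events(g, cfg, divisions = 400)
  expect_identical(a$events, b$events)
  expect_identical(simulate_allele_depths(a$karyotype, g, cfg),
                   simulate_allele_depths(b$karyotype, g, cfg))
  expect_identical(simulate_array(a$karyotype, g, cfg),
                   simulate_array(b$karyotype, g, cfg))
  expect_identical(simulate_mutations(cfg, 100), simulate_mutations(cfg, 100))
})

test_that("rate-driven event counts follow the Poisson expectation", {
  g <- yeast_genome_map(4000)
  lambda <- 5e-3
  n_iso <- 50; divisions <- 400
  counts <- vapply(seq_len(n_iso), function(i) {
    cfg <- simulation_config(rng_seed = 1000 + i,
                             event_rates = c("T-LOH" = lambda))
    nrow(spike_events(g, cfg, divisions = divisions)$events)
  }, 0L)
  mu <- lambda * divisions
  se <- sqrt(mu / n_iso)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("simulated depths have the configured mean", {
  g <- toy_genome(n_snps = 10000, len = 5e6)
  cfg <- simulation_config(rng_seed = 9, mean_depth = 50)
  sp <- spike_events(g, simulation_config(rng_seed = 9, events = data.frame(
    type = character(), chrom = character(), homolog = character())))
  d <- simulate_allele_depths(sp$karyotype, g, cfg)
  expect_lt(abs(mean(d$w_depth + d$y_depth) - 50) / 50, 0.01)
  # UPD chromosome: lost homolog gets zero depth, kept one the full depth
  g2 <- toy_genome(n_snps = 2000)
  sp2 <- spike_events(g2, simulation_config(rng_seed = 9, events = data.frame(
    type = "UPD", chrom = "I", homolog = "W", start = NA, end = NA)))
  d2 <- simulate_allele_depths(sp2$karyotype, g2, cfg)
  expect_true(all(d2$w_depth == 0))
  expect_lt(abs(mean(d2$y_depth) - 50) / 50, 0.05)
})

test_that("array ratios sit at the 0.2/1/1.5 levels", {
  g <- toy_genome(n_snps = 1000)
  noiseless <- simulation_config(rng_seed = 5, array_noise_sd = 0)
  het <- spike_events(g, simulation_config(rng_seed = 5, events = data.frame(
    type = character(), chrom = character(), homolog = character())))
  a <- simulate_array(het$karyotype, g, noiseless)
  expect_true(all(a$hyb_ratio == 1.0))
  del <- spike_events(g, simulation_config(rng_seed = 5, events = data.frame(
    type = "MONOSOMY", chrom = "I", homolog = "W", start = NA, end = NA)))
  a2 <- simulate_array(del$karyotype, g, noiseless)
  expect_true(all(a2$hyb_ratio[a2$homolog == "W"] == 0.2))
  expect_true(all(a2$hyb_ratio[a2$homolog == "Y"] == 1.0))
  # noisy mean concentrates at the level
  noisy <- simulation_config(rng_seed = 5, array_noise_sd = 0.05)
  a3 <- simulate_array(het$karyotype, g, noisy)
  w <- a3$hyb_ratio[a3$homolog == "W"]
  expect_lt(abs(mean(w) - 1.0), 3 * 0.05 / sqrt(length(w)))
})

test_that("simulated mutations follow the configured spectrum", {
  degenerate <- c("CG>TA" = 1, "CG>AT" = 0, "CG>GC" = 0,
                  "TA>CG" = 0, "TA>AT" = 0, "TA>GC" = 0)
  cfg <- simulation_config(rng_seed = 2, spectrum = degenerate)
  m <- simulate_mutations(cfg, 10)
  expect_true(all(m$class == "CG>TA"))
  expect_true(all(paste0(m$ref, ">", m$alt) %in% c("C>T", "G>A")))
  expect_equal(nrow(simulate_mutations(cfg, 0)), 0)
  expect_error(simulate_mutations(cfg, -1), ">= 0")
  uniform <- setNames(rep(1 / 6, 6), names(degenerate))
  m2 <- simulate_mutations(simulation_config(rng_seed = 7,
                                             spectrum = uniform), 6000)
  counts <- table(factor(m2$class, levels = names(uniform)))
  tol <- 3 * sqrt(6000 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - 1000) < tol))
})

test_that("spiking requires a seed and validates the spectrum", {
  expect_error(simulation_config(), "rng_seed")
  expect_error(simulation_config(rng_seed = 1, mean_depth = 0), "mean_depth")
  bad <- c("CG>TA" = 0.5, "CG>AT" = 0.1, "CG>GC" = 0.1,
           "TA>CG" = 0.1, "TA>AT" = 0.1, "TA>GC" = 0.05)
  expect_error(simulation_config(rng_seed = 1, spectrum = bad), "sum to 1")
})
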