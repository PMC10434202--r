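test_that("an interstitial LOH tract segments into 1/0/1 and 1/2/1 runs", {
  g <- yeast_genome_map(20000)
  sp <- spike_events(g, simulation_config(rng_seed = 1, events = data.frame(
    type = "I-LOH", chrom = "XV", start = 369905, end = 372085,
    homolog = "W")))
  p <- compute_rc(noiseless_depths(sp$karyotype, g, 50), g)
  segs <- segment_copy_states(p)
  w <- segs[segs$chrom == "XV" & segs$homolog == "W", ]
  y <- segs[segs$chrom == "XV" & segs$homolog == "Y", ]
  expect_equal(w$state, c(1L, 0L, 1L))
  expect_equal(y$state, c(1L, 2L, 1L))
  expect_equal(w$start_snp[2], sp$events$start_snp)
  expect_equal(w$end_snp[2], sp$events$end_snp)
})

test_that("a constant heterozygous profile yields one state-1 segment per homolog", {
  g <- toy_genome(n_snps = 50)
  p <- compute_rc(data.frame(chrom = "I", pos = g$snps$pos,
                             w_depth = 25, y_depth = 25), g)
  segs <- segment_copy_states(p)
  expect_equal(nrow(segs), 2)
  expect_true(all(segs$state == 1L))
  expect_true(all(segs$n_snps == 50))
})

test_that("the DP fit equals exhaustive minimal-misfit segmentation", {
  levels <- c(0, 0.5, 1, 1.5)
  lambda <- 0.3
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    # piecewise-constant truth with optional noise
    k <- sample(1:3, 1)
    bounds <- sort(c(0, sample(seq_len(n - 1), k - 1), n))
    rc <- unlist(lapply(seq_len(k), function(s)
      rep(sample(levels, 1), bounds[s + 1] - bounds[s])))
    if (rep > 12) rc <- rc + rnorm(n, 0, 0.12)
    dp <- lohscan:::fit_states_dp(rc, levels, lambda)
    bf <- brute_force_states(rc, levels, lambda)
    misfit <- function(st) {
      sum((rc - levels[st + 1])^2) + lambda * sum(diff(st) != 0)
    }
    expect_equal(misfit(dp), misfit(bf), tolerance = 1e-10)
  }
})

test_that("joint copy states map onto the event taxonomy", {
  g <- yeast_genome_map(20000)
  ev <- data.frame(
    type = c("T-LOH", "UPD", "T-DEL", "I-LOH"),
    chrom = c("XIV", "VIII", "III", "XV"),
    start = c(1, NA, 1, 369905),
    end = c(518591, NA, 175342, 372085),
    homolog = c("W", "W", "W", "W"))
  sp <- spike_events(g, simulation_config(rng_seed = 2, events = ev))
  p <- compute_rc(noiseless_depths(sp$karyotype, g, 50), g)
  calls <- call_events(segment_copy_states(p), g)
  expect_equal(nrow(calls), 4)
  got <- calls[order(calls$chrom), ]
  expect_equal(got$type[got$chrom == "XIV"], "T-LOH")
  expect_equal(got$type[got$chrom == "VIII"], "UPD")
  expect_equal(got$class[got$chrom == "VIII"], "D4")
  expect_equal(got$type[got$chrom == "III"], "T-DEL")
  expect_equal(got$class[got$chrom == "III"], "C1")
  expect_equal(got$type[got$chrom == "XV"], "I-LOH")
  expect_equal(got$class[got$chrom == "XV"], "A1")
  # copy-neutrality of every LOH call and the no-overlap partition
  for (k in which(calls$type %in% c("I-LOH", "T-LOH", "UPD"))) {
    cp <- sp$karyotype$copies[[calls$chrom[k]]]
    rng <- calls$start_snp[k]:calls$end_snp[k]
    expect_true(all(rowSums(cp[rng, , drop = FALSE]) == 2))
  }
})

test_that("fully heterozygous isolates produce no calls", {
  g <- toy_genome(n_snps = 60, n_chrom = 3)
  d <- data.frame(chrom = g$snps$chrom, pos = g$snps$pos,
                  w_depth = 25, y_depth = 25)
  calls <- call_events(segment_copy_states(compute_rc(d, g)), g)
  expect_equal(nrow(calls), 0)
})

test_that("class codes follow the taxonomy scheme", {
  g <- yeast_genome_map(8000)
  # simple T-LOH retaining W on the right arm of IV -> B2 (Y lost)
  ev <- data.frame(type = "T-LOH", chrom = "IV", start = 1000000,
                   end = 1531933, homolog = "Y")
  sp <- spike_events(g, simulation_config(rng_seed = 4, events = ev))
  p <- compute_rc(noiseless_depths(sp$karyotype, g, 50), g)
  calls <- call_events(segment_copy_states(p), g)
  expect_equal(calls$class, "B2")
  # trisomy via extra Y -> D2; monosomy -> D3
  ev2 <- data.frame(type = c("TRISOMY", "MONOSOMY"), chrom = c("IX", "V"),
                    start = NA, end = NA, homolog = c("Y", "W"))
  sp2 <- spike_events(g, simulation_config(rng_seed = 4, events = ev2))
  p2 <- compute_rc(noiseless_depths(sp2$karyotype, g, 50), g)
  calls2 <- call_events(segment_copy_states(p2), g)
  expect_setequal(calls2$class, c("D2", "D3"))
  # class remapping is config-driven
  expect_equal(classify_event(calls[1, ], g,
                              class_map = c("T-LOH.right.Y" = "Bx")), "Bx")
})

test_that("a conversion tract adjacent to a T-LOH breakpoint flags class B5", {
  g <- toy_genome(n_snps = 400, len = 400000)
  pos <- g$snps$pos
  # T-LOH from SNP 200 to the right end, I-LOH at SNPs 190..195 (gap 4)
  ev <- data.frame(type = c("T-LOH", "I-LOH"), chrom = "I",
                   start = c(pos[200], pos[190]),
                   end = c(400000, pos[195]),
                   homolog = "W")
  sp <- spike_events(g, simulation_config(rng_seed = 6, events = ev))
  p <- compute_rc(noiseless_depths(sp$karyotype, g, 50), g)
  calls <- call_events(segment_copy_states(p), g)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "T-LOH")
  expect_true(calls$conv_assoc)
  expect_equal(calls$class, "B5")
  # far-away I-LOH stays its own call
  ev2 <- ev; ev2$start[2] <- pos[100]; ev2$end[2] <- pos[110]
  sp2 <- spike_events(g, simulation_config(rng_seed = 6, events = ev2))
  p2 <- compute_rc(noiseless_depths(sp2$karyotype, g, 50), g)
  calls2 <- call_events(segment_copy_states(p2), g)
  expect_setequal(calls2$type, c("T-LOH", "I-LOH"))
  expect_false(any(calls2$conv_assoc))
})

test_that("breakpoint intervals bracket the state transition", {
  g <- toy_genome(n_snps = 100)
  pos <- g$snps$pos
  ev <- data.frame(type = "I-LOH", chrom = "I", start = pos[40],
                   end = pos[60], homolog = "W")
  sp <- spike_events(g, simulation_config(rng_seed = 8, events = ev))
  p <- compute_rc(noiseless_depths(sp$karyotype, g, 50), g)
  calls <- call_events(segment_copy_states(p), g)
  bl <- resolve_breakpoint(calls[1, ], p, "left")
  expect_equal(bl$lo, pos[39])
  expect_equal(bl$hi, pos[40])
  expect_equal(bl$midpoint, (pos[39] + pos[40]) / 2)
  expect_equal(calls$bp_left_lo, pos[39])
  expect_equal(calls$bp_right_hi, pos[61])
  # terminal transition clamps to the chromosome start
  ev2 <- data.frame(type = "T-LOH", chrom = "I", start = 1, end = pos[50],
                    homolog = "W")
  sp2 <- spike_events(g, simulation_config(rng_seed = 8, events = ev2))
  p2 <- compute_rc(noiseless_depths(sp2$karyotype, g, 50), g)
  calls2 <- call_events(segment_copy_states(p2), g)
  expect_equal(resolve_breakpoint(calls2[1, ], p2, "left")$lo, 1)
  expect_equal(calls2$bp_left_lo, 1)
})

test_that("paired terminal CNVs form monocentric translocation hypotheses", {
  g <- yeast_genome_map(20000)
  # the LF4-like pair: printed duplication intervals on II and XIII
  dup <- data.frame(
    event_id = c("e1", "e2"), chrom = c("II", "XIII"), type = "T-DUP",
    homolog = "W", start = c(1, 1), end = c(635650, 182683),
    start_snp = NA, end_snp = NA)
  tr <- pair_translocations(dup, g)
  expect_equal(nrow(tr$hypotheses), 1)
  expect_equal(tr$hypotheses$predicted_size, 635650 + 182683)  # 818 kb
  expect_equal(tr$hypotheses$centric_chrom, "II")
  expect_null(tr$unresolved)
  # the LF6-like pair: deletions whose retained complements recombine
  del <- data.frame(
    event_id = c("e3", "e4"), chrom = c("III", "XIV"), type = "T-DEL",
    homolog = "W", start = c(1, 1), end = c(175342, 518591),
    start_snp = NA, end_snp = NA)
  tr2 <- pair_translocations(del, g)
  expect_equal(nrow(tr2$hypotheses), 1)
  expect_equal(tr2$hypotheses$predicted_size,
               (316620 - 175342) + (784333 - 518591))          # ~400 kb
  expect_equal(tr2$hypotheses$centric_chrom, "XIV")
  # exactly one centromere per hypothesis, by construction: check both
  for (h in list(tr$hypotheses, tr2$hypotheses)) {
    expect_true(lohscan:::contains_centromere(g, h$centric_chrom,
                                        h$centric_start, h$centric_end))
    expect_false(lohscan:::contains_centromere(g, h$acentric_chrom,
                                         h$acentric_start, h$acentric_end))
  }
  # a lone terminal deletion stays unresolved
  tr3 <- pair_translocations(del[1, ], g)
  expect_equal(nrow(tr3$hypotheses), 0)
  expect_equal(nrow(tr3$unresolved), 1)
})

test_that("noiseless simulated isolates are recovered exactly", {
  g <- yeast_genome_map(8000)
  for (seed in 1:5) {
    cfg <- simulation_config(rng_seed = 100 + seed,
                             event_rates = furfural_event_rates() * 4)
    sp <- spike_events(g, cfg, divisions = 400)
    p <- compute_rc(noiseless_depths(sp$karyotype, g, 50), g)
    calls <- call_events(segment_copy_states(p), g)
    truth <- sp$events[sp$events$end_snp - sp$events$start_snp + 1 >= 3, ]
    m <- match_events(calls, truth, exact = TRUE)
    expect_true(all(m$recall_hits))
    expect_equal(nrow(calls), nrow(truth))
  }
})
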