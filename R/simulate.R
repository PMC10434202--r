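EVENT_TYPES <- c("I-LOH", "T-LOH", "T-DEL", "T-DUP",
                 "TRISOMY", "MONOSOMY", "UPD")

SPECTRUM_CLASSES <- c("CG>TA", "CG>AT", "CG>GC", "TA>CG", "TA>AT", "TA>GC")

#' Default furfural-arm event rates
#'
#' Per-genome per-cell-division rates of each alteration class under chronic
#' 0.6 g/L furfural exposure: I-LOH 2.2e-3, T-LOH 3.4e-3, large terminal
#' rearrangements 7e-4 (split 6:2 between deletions and duplications, as
#' observed), and aneuploidy 3.2e-3 (split 15:17:4 between trisomy, monosomy
#' and UPD, as observed).
#'
#' @return named numeric vector of rates, one per event type.
#' @export
furfural_event_rates <- function() {
  c("I-LOH" = 2.2e-3, "T-LOH" = 3.4e-3,
    "T-DEL" = 7e-4 * 6 / 8, "T-DUP" = 7e-4 * 2 / 8,
    "TRISOMY" = 3.2e-3 * 15 / 36, "MONOSOMY" = 3.2e-3 * 17 / 36,
    "UPD" = 3.2e-3 * 4 / 36)
}

#' Stylized six-class SNV spectra
#'
#' `spectrum_untreated()` puts 22% / 26% of mass on CG>TA / CG>AT (the
#' proportions reported for untreated cells) with the remainder spread over
#' the other four classes; `spectrum_furfural()` raises the cumulative
#' oxidation-associated mass (CG>TA + CG>AT) to 60%.
#'
#' @return named probability vector over the six collapsed substitution
#'   classes.
#' @name snv_spectra
NULL

#' @rdname snv_spectra
#' @export
spectrum_untreated <- function() {
  c("CG>TA" = 0.22, "CG>AT" = 0.26, "CG>GC" = 0.08,
    "TA>CG" = 0.16, "TA>AT" = 0.16, "TA>GC" = 0.12)
}

#' @rdname snv_spectra
#' @export
spectrum_furfural <- function() {
  c("CG>TA" = 0.30, "CG>AT" = 0.30, "CG>GC" = 0.05,
    "TA>CG" = 0.13, "TA>AT" = 0.12, "TA>GC" = 0.10)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic hybrid-diploid generator. Defaults
#' are the study conditions: total per-SNP sequencing depth 50 at the diploid
#' baseline, microarray noise SD 0.05 around the 0.2/1/1.5 hybridization
#' levels, the furfural-arm event rates, and the untreated six-class SNV
#' spectrum.
#'
#' @param rng_seed integer seed; mandatory, every generator draw is
#'   reproducible under it.
#' @param mean_depth expected total reads per SNP site for the unaltered
#'   diploid (each homolog copy contributes `mean_depth/2`).
#' @param array_noise_sd Gaussian SD added to array hybridization levels.
#' @param event_rates named per-division rates for the seven event types;
#'   ignored when `events` is given.
#' @param events optional explicit event table (columns `type`, `chrom`,
#'   `start`, `end`, `homolog`; `start`/`end` in bp, whole chromosome for
#'   aneuploidy/UPD when NA).
#' @param spectrum six-class SNV spectrum (probabilities summing to 1).
#' @param i_loh_span bp range (min, max) from which interstitial tract
#'   lengths are drawn uniformly.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(rng_seed, mean_depth = 50,
                              array_noise_sd = 0.05,
                              event_rates = furfural_event_rates(),
                              events = NULL,
                              spectrum = spectrum_untreated(),
                              i_loh_span = c(2000, 50000)) {
  if (missing(rng_seed) || is.null(rng_seed) || is.na(rng_seed))
    stop("rng_seed is mandatory")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (array_noise_sd < 0) stop("array_noise_sd must be >= 0")
  if (abs(sum(spectrum) - 1) > 1e-8)
    stop("spectrum probabilities must sum to 1")
  if (!all(SPECTRUM_CLASSES %in% names(spectrum)))
    stop("spectrum needs the six classes: ",
         paste(SPECTRUM_CLASSES, collapse = ", "))
  if (is.null(events)) {
    if (!all(names(event_rates) %in% EVENT_TYPES) || any(event_rates < 0))
      stop("event_rates must be nonnegative and named by event type")
  }
  structure(list(rng_seed = as.integer(rng_seed), mean_depth = mean_depth,
                 array_noise_sd = array_noise_sd, event_rates = event_rates,
                 events = events, spectrum = spectrum[SPECTRUM_CLASSES],
                 i_loh_span = i_loh_span),
            class = "simulation_config")
}

# snap an SNP-index range to true bp boundaries at inter-SNP midpoints,
# extended to the chromosome ends when the range is terminal
snap_bp <- function(pos, i, j, chrom_len) {
  start_bp <- if (i == 1L) 1 else (pos[i - 1L] + pos[i]) / 2
  end_bp <- if (j == length(pos)) chrom_len else (pos[j] + pos[j + 1L]) / 2
  c(start_bp, end_bp)
}

#' Spike genomic alterations into a hybrid-diploid karyotype
#'
#' Builds a karyotype (per-chromosome, per-homolog copy number over SNP
#' sites; 1/1 everywhere by default) and applies either an explicit event
#' list or events drawn at the configured per-division rates over `divisions`
#' genome-divisions. Copy-neutral LOH sets the affected homolog to 0 and the
#' other to 2; terminal deletion/duplication changes one homolog only;
#' trisomy/monosomy add/remove one whole-chromosome copy; UPD sets one
#' homolog to 0 and duplicates the other chromosome-wide.
#'
#' When events are drawn from rates, breakpoints snap to inter-SNP midpoints
#' so the ground truth is well-defined at SNP resolution, and draws that
#' would conflict with an already-placed event on the same chromosome are
#' re-drawn (up to 20 times, then dropped).
#'
#' @param genome a [genome_map()].
#' @param config a [simulation_config()].
#' @param divisions genome-divisions over which rate-driven events accrue
#'   (ignored for explicit event lists).
#' @return list with `karyotype` (class `karyotype`: per-chromosome integer
#'   copy matrices with columns W, Y) and `events` (the ground-truth table:
#'   `event_id`, `type`, `chrom`, `homolog`, `start_snp`, `end_snp`,
#'   `start`, `end`).
#' @export
spike_events <- function(genome, config, divisions = 400) {
  stopifnot(inherits(genome, "genome_map"),
            inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  chroms <- genome$chromosomes$chrom
  pos_by <- lapply(chroms, function(cc) genome$snps$pos[genome$snps$chrom == cc])
  names(pos_by) <- chroms
  nsnp <- vapply(pos_by, length, 0L)

  if (!is.null(config$events)) {
    ev <- normalize_explicit_events(config$events, genome, pos_by)
  } else {
    ev <- draw_events(config, chroms, pos_by, nsnp, divisions,
                      genome$chromosomes$length)
  }

  # reject/resolve conflicts: no two events may overlap on one chromosome
  if (nrow(ev) > 1) {
    drop <- logical(nrow(ev))
    for (cc in unique(ev$chrom)) {
      idx <- which(ev$chrom == cc)
      if (length(idx) < 2) next
      idx <- idx[order(ev$start_snp[idx])]
      for (k in seq_along(idx)[-1]) {
        prev <- idx[seq_len(k - 1)]
        prev <- prev[!drop[prev]]
        if (length(prev) &&
            any(ev$start_snp[idx[k]] <= ev$end_snp[prev])) {
          if (!is.null(config$events))
            stop("conflicting overlapping events: ",
                 paste(ev$event_id[c(prev[ev$end_snp[prev] >=
                                            ev$start_snp[idx[k]]][1],
                                     idx[k])], collapse = " vs "))
          drop[idx[k]] <- TRUE
        }
      }
    }
    ev <- ev[!drop, , drop = FALSE]
  }
  rownames(ev) <- NULL

  copies <- lapply(nsnp, function(n)
    matrix(1L, nrow = n, ncol = 2, dimnames = list(NULL, c("W", "Y"))))
  for (k in seq_len(nrow(ev))) {
    cc <- ev$chrom[k]
    rng <- ev$start_snp[k]:ev$end_snp[k]
    aff <- ev$homolog[k]
    oth <- if (aff == "W") "Y" else "W"
    ty <- ev$type[k]
    if (ty %in% c("I-LOH", "T-LOH", "UPD")) {
      copies[[cc]][rng, aff] <- 0L
      copies[[cc]][rng, oth] <- 2L
    } else if (ty == "T-DEL") {
      copies[[cc]][rng, aff] <- 0L
    } else if (ty %in% c("T-DUP", "TRISOMY")) {
      copies[[cc]][rng, aff] <- 2L
    } else if (ty == "MONOSOMY") {
      copies[[cc]][rng, aff] <- 0L
    } else stop("unknown event type: ", ty)
  }
  kar <- structure(list(copies = copies, genome_chroms = chroms),
                   class = "karyotype")
  list(karyotype = kar, events = ev)
}

normalize_explicit_events <- function(events, genome, pos_by) {
  ev <- as.data.frame(events)
  need <- c("type", "chrom", "homolog")
  if (!all(need %in% names(ev)))
    stop("explicit events need columns: ", paste(need, collapse = ", "))
  if (!nrow(ev))
    return(data.frame(event_id = character(), type = character(),
                      chrom = character(), homolog = character(),
                      start_snp = integer(), end_snp = integer(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  if (is.null(ev$start)) ev$start <- NA_real_
  if (is.null(ev$end)) ev$end <- NA_real_
  if (is.null(ev$event_id)) ev$event_id <- sprintf("ev%d", seq_len(nrow(ev)))
  if (!all(ev$type %in% EVENT_TYPES))
    stop("unknown event type(s): ",
         paste(setdiff(ev$type, EVENT_TYPES), collapse = ", "))
  if (!all(ev$homolog %in% c("W", "Y")))
    stop("homolog must be W or Y")
  out <- ev[, c("event_id", "type", "chrom", "homolog", "start", "end")]
  out$start_snp <- NA_integer_; out$end_snp <- NA_integer_
  for (k in seq_len(nrow(out))) {
    cc <- out$chrom[k]
    pos <- pos_by[[cc]]
    if (is.null(pos) || !length(pos)) stop("no SNPs on chromosome ", cc)
    L <- chrom_length(genome, cc)
    whole <- out$type[k] %in% c("TRISOMY", "MONOSOMY", "UPD")
    if (whole || is.na(out$start[k])) { out$start[k] <- 1; out$end[k] <- L }
    s <- out$start[k]; e <- out$end[k]
    if (s < 1 || e > L || s > e) stop("event interval outside chromosome ", cc)
    i <- findInterval(s - 1, pos) + 1L          # first SNP >= s
    j <- findInterval(e, pos)                   # last SNP <= e
    if (i > j) stop("event ", out$event_id[k], " spans no SNP site")
    if (out$type[k] == "I-LOH" && (i == 1L || j == length(pos)))
      stop("I-LOH must exclude both chromosome ends: ", out$event_id[k])
    if (out$type[k] %in% c("T-LOH", "T-DEL", "T-DUP")) {
      left <- s <= pos[1]; right <- e >= pos[length(pos)]
      if (left == right)
        stop(out$type[k], " must abut exactly one chromosome end: ",
             out$event_id[k])
    }
    out$start_snp[k] <- i; out$end_snp[k] <- j
  }
  out[, c("event_id", "type", "chrom", "homolog", "start_snp", "end_snp",
          "start", "end")]
}

draw_events <- function(config, chroms, pos_by, nsnp, divisions, lens) {
  rates <- config$event_rates
  rows <- list()
  eligible <- chroms[nsnp >= 6L]
  wts <- nsnp[eligible] / sum(nsnp[eligible])
  for (ty in names(rates)) {
    n <- stats::rpois(1, rates[[ty]] * divisions)
    if (n == 0) next
    for (r in seq_len(n)) {
      placed <- FALSE
      for (attempt in 1:20) {
        whole <- ty %in% c("TRISOMY", "MONOSOMY", "UPD")
        cc <- if (whole) sample(eligible, 1)
              else sample(eligible, 1, prob = wts)
        pos <- pos_by[[cc]]; nn <- length(pos)
        L <- lens[match(cc, chroms)]
        # segmental events keep a >= 3-SNP margin to each chromosome end so
        # the truth stays resolvable at SNP resolution
        m <- 3L
        if (whole) {
          i <- 1L; j <- nn
        } else if (ty == "I-LOH") {
          span <- stats::runif(1, config$i_loh_span[1], config$i_loh_span[2])
          i <- sample((m + 1L):(nn - m), 1)
          j <- min(nn - m, findInterval(pos[i] + span, pos))
          if (j < i) j <- i
        } else {  # terminal: pick side and interior breakpoint SNP
          left <- stats::runif(1) < 0.5
          b <- sample(m:(nn - m), 1)
          if (left) { i <- 1L; j <- b } else { i <- b; j <- nn }
        }
        cand <- data.frame(type = ty, chrom = cc,
                           homolog = sample(c("W", "Y"), 1),
                           start_snp = i, end_snp = j,
                           stringsAsFactors = FALSE)
        clash <- FALSE
        for (prev in rows) {
          if (prev$chrom == cc &&
              cand$start_snp <= prev$end_snp &&
              prev$start_snp <= cand$end_snp) { clash <- TRUE; break }
        }
        if (!clash) { rows[[length(rows) + 1L]] <- cand; placed <- TRUE; break }
      }
      # unplaceable after 20 attempts: dropped (documented behaviour)
    }
  }
  if (!length(rows))
    return(data.frame(event_id = character(), type = character(),
                      chrom = character(), homolog = character(),
                      start_snp = integer(), end_snp = integer(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  ev <- do.call(rbind, rows)
  ev$event_id <- sprintf("ev%d", seq_len(nrow(ev)))
  ev$start <- NA_real_; ev$end <- NA_real_
  for (k in seq_len(nrow(ev))) {
    pos <- pos_by[[ev$chrom[k]]]
    L <- lens[match(ev$chrom[k], chroms)]
    bp <- snap_bp(pos, ev$start_snp[k], ev$end_snp[k], L)
    ev$start[k] <- bp[1]; ev$end[k] <- bp[2]
  }
  ev[, c("event_id", "type", "chrom", "homolog", "start_snp", "end_snp",
         "start", "end")]
}

#' Simulate homolog-specific sequencing depths
#'
#' Draws, for every SNP site, independent Poisson read depths per homolog
#' with mean `mean_depth x copies/2`, emulating whole-genome sequencing of
#' the hybrid diploid at the configured coverage.
#'
#' @param karyotype karyotype from [spike_events()].
#' @param genome the [genome_map()] the karyotype was built on.
#' @param config a [simulation_config()]; `rng_seed` (offset by 1) fixes the
#'   draw.
#' @return an allele-depth table: data.frame `chrom`, `pos`, `w_depth`,
#'   `y_depth`.
#' @export
simulate_allele_depths <- function(karyotype, genome, config) {
  stopifnot(inherits(karyotype, "karyotype"),
            inherits(config, "simulation_config"))
  set.seed(config$rng_seed + 1L)
  out <- genome$snps[, c("chrom", "pos")]
  w <- integer(nrow(out)); y <- integer(nrow(out))
  off <- 0L
  for (cc in karyotype$genome_chroms) {
    cp <- karyotype$copies[[cc]]
    n <- nrow(cp)
    if (n) {
      w[off + seq_len(n)] <- stats::rpois(n, config$mean_depth * cp[, "W"] / 2)
      y[off + seq_len(n)] <- stats::rpois(n, config$mean_depth * cp[, "Y"] / 2)
    }
    off <- off + n
  }
  out$w_depth <- w
  out$y_depth <- y
  out
}

ARRAY_LEVELS <- c(0.2, 1.0, 1.5, 1.5)  # copies 0,1,2,3+ (>=2 clamps to 1.5)

#' Simulate SNP-microarray hybridization ratios
#'
#' Emits per-SNP, per-homolog hybridization ratios at the levels 0.2 / 1.0 /
#' 1.5 for 0 / 1 / 2 homolog copies (copies above 2 clamp to 1.5), plus
#' Gaussian noise of SD `array_noise_sd`.
#'
#' @inheritParams simulate_allele_depths
#' @return array table: data.frame `chrom`, `pos`, `homolog`, `hyb_ratio`.
#' @export
simulate_array <- function(karyotype, genome, config) {
  stopifnot(inherits(karyotype, "karyotype"),
            inherits(config, "simulation_config"))
  set.seed(config$rng_seed + 2L)
  rows <- lapply(karyotype$genome_chroms, function(cc) {
    cp <- karyotype$copies[[cc]]
    pos <- genome$snps$pos[genome$snps$chrom == cc]
    n <- nrow(cp)
    if (!n) return(NULL)
    data.frame(chrom = cc, pos = rep(pos, 2),
               homolog = rep(c("W", "Y"), each = n),
               level = c(ARRAY_LEVELS[pmin(cp[, "W"], 3L) + 1L],
                         ARRAY_LEVELS[pmin(cp[, "Y"], 3L) + 1L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$hyb_ratio <- out$level + stats::rnorm(nrow(out), 0, config$array_noise_sd)
  out$level <- NULL
  out
}

#' Simulate point mutations under a six-class spectrum
#'
#' Draws `n` SNVs with substitution classes multinomially distributed per
#' the configured spectrum, assigning each a strand orientation and the
#' matching ref/alt bases, and a uniform genomic position.
#'
#' @param config a [simulation_config()] (uses `spectrum` and `rng_seed`,
#'   offset by 3).
#' @param n number of SNVs (>= 0).
#' @param genome optional [genome_map()] used to draw positions; positions
#'   are omitted when NULL.
#' @return data.frame `type` ("SNV"), `class`, `ref`, `alt` (+ `chrom`,
#'   `pos` when a genome is given).
#' @export
simulate_mutations <- function(config, n, genome = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (n < 0) stop("n must be >= 0")
  set.seed(config$rng_seed + 3L)
  if (n == 0)
    return(data.frame(type = character(), class = character(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  cls <- sample(SPECTRUM_CLASSES, n, replace = TRUE, prob = config$spectrum)
  # pyrimidine-strand representative of each class, complemented at random
  pyr <- list("CG>TA" = c("C", "T"), "CG>AT" = c("C", "A"),
              "CG>GC" = c("C", "G"), "TA>CG" = c("T", "C"),
              "TA>AT" = c("T", "A"), "TA>GC" = c("T", "G"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  base <- t(vapply(cls, function(k) pyr[[k]], character(2)))
  flip <- stats::runif(n) < 0.5
  ref <- ifelse(flip, comp[base[, 1]], base[, 1])
  alt <- ifelse(flip, comp[base[, 2]], base[, 2])
  out <- data.frame(type = "SNV", class = cls, ref = unname(ref),
                    alt = unname(alt), stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    lens <- genome$chromosomes$length
    cc <- sample(genome$chromosomes$chrom, n, replace = TRUE,
                 prob = lens / sum(lens))
    out$chrom <- cc
    out$pos <- floor(stats::runif(n, 1, lens[match(cc, genome$chromosomes$chrom)] + 1))
  }
  out
}
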