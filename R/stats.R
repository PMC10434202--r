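#' Event rate per genome per cell division
#'
#' Divides an event count by the total genome-divisions of a subculture
#' design. The reported value is rounded to 2 significant figures (matching
#' the conventional presentation of such rates); the full-precision value is
#' retained.
#'
#' @param n_events nonnegative event count.
#' @param design a [culture_design()].
#' @return object of class `rate_estimate` with `n_events`,
#'   `total_divisions`, `rate` (full precision) and `rate_reported`
#'   (2 significant figures).
#' @export
estimate_event_rate <- function(n_events, design) {
  if (n_events < 0) stop("n_events must be >= 0")
  D <- total_divisions(design)
  if (D <= 0) stop("design has no divisions")
  r <- n_events / D
  structure(list(n_events = n_events, total_divisions = D, rate = r,
                 rate_reported = signif(r, 2)),
            class = "rate_estimate")
}

#' Per-base mutation rate per cell division
#'
#' Divides a mutation count by genome-divisions times (diploid) genome
#' size, as when estimating SNV/indel rates from sequenced subcultured
#' isolates against the 24-Mb diploid genome.
#'
#' @param n nonnegative mutation count.
#' @param design a [culture_design()].
#' @param genome_size genome size in bp (default 24e6, the diploid genome).
#' @return a `rate_estimate` with additional fields `genome_size` and the
#'   per-base `rate`.
#' @export
estimate_base_rate <- function(n, design, genome_size = 24e6) {
  if (n < 0) stop("n must be >= 0")
  if (genome_size <= 0) stop("genome_size must be > 0")
  D <- total_divisions(design)
  r <- n / (D * genome_size)
  structure(list(n_events = n, total_divisions = D,
                 genome_size = genome_size, rate = r,
                 rate_reported = signif(r, 2)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  unit <- if (is.null(x$genome_size)) "events/genome/division"
          else "events/bp/division"
  cat(sprintf("%d events over %s divisions%s: %.3g %s (reported %.2g)\n",
              x$n_events, format(x$total_divisions, big.mark = ","),
              if (is.null(x$genome_size)) ""
              else sprintf(" x %.3g bp", x$genome_size),
              x$rate, unit, x$rate_reported))
  invisible(x)
}

#' Fold change between two rates
#'
#' @param rate_a,rate_b `rate_estimate`s (or bare numeric rates); `rate_b`
#'   is the baseline and must be positive.
#' @return list with `fold` (full precision) and `fold_reported`
#'   (2 significant figures).
#' @export
fold_change <- function(rate_a, rate_b) {
  a <- if (inherits(rate_a, "rate_estimate")) rate_a$rate else rate_a
  b <- if (inherits(rate_b, "rate_estimate")) rate_b$rate else rate_b
  if (b <= 0)
    stop("baseline rate must be > 0; compare counts directly instead")
  list(fold = a / b, fold_reported = signif(a / b, 2))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value by the point-probability rule: with the table's
#' margins fixed, sum the hypergeometric point probabilities of every table
#' whose probability does not exceed that of the observed table (with a
#' relative slack of 1e-7 for ties). An empty margin returns p = 1 with a
#' warning.
#'
#' @param table 2x2 matrix (or coercible) of nonnegative integer counts.
#' @return list with `p_value`, `odds_ratio` (sample ad/bc, Inf/NaN
#'   allowed), and the observed table.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("need a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  a <- m[1, 1]
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(m[, 2]) == 0) {
    warning("empty margin; p = 1")
    return(list(p_value = 1, odds_ratio = NaN, table = m))
  }
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  x <- lo:hi
  px <- stats::dhyper(x, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(px[px <= p_obs * (1 + 1e-7)])
  list(p_value = min(1, p),
       odds_ratio = (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]),
       table = m)
}

#' Enrichment of events in a genomic region (chi-square)
#'
#' Tests whether `observed` of `total` events falling inside a region of
#' `region_bp` out of `genome_bp` exceeds the uniform expectation
#' `region_bp / genome_bp x total`. The chi-square statistic (df = 1, no
#' continuity correction) is formed over the in-region / out-of-region
#' cells against the expectation rounded to `expected_digits` significant
#' figures — i.e. the test is carried out against the expectation at
#' reported precision (set `expected_digits = NULL` for full precision).
#'
#' @param observed events inside the region.
#' @param total all events.
#' @param region_bp,genome_bp region and genome sizes in bp.
#' @param expected_digits significant figures at which the expectation
#'   enters the statistic (default 2).
#' @return list with `observed`, `expected` (full precision),
#'   `expected_reported`, `chi_square`, `p_value`.
#' @export
region_enrichment <- function(observed, total, region_bp, genome_bp,
                              expected_digits = 2) {
  if (region_bp > genome_bp) stop("region_bp must be <= genome_bp")
  if (observed > total) stop("observed must be <= total")
  expected <- region_bp / genome_bp * total
  if (expected <= 0) stop("zero expected count; enlarge the region")
  e_in <- if (is.null(expected_digits)) expected
          else signif(expected, expected_digits)
  o <- c(observed, total - observed)
  e <- c(e_in, total - e_in)
  if (any(e == 0 & o != 0)) stop("zero expected cell with observations")
  terms <- ifelse(e == 0, 0, (o - e)^2 / e)
  chi <- sum(terms)
  list(observed = observed, expected = expected, expected_reported = e_in,
       chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Tally the six-class substitution spectrum
#'
#' Collapses complementary substitutions onto six classes (CG>TA, CG>AT,
#' CG>GC, TA>CG, TA>AT, TA>GC): e.g. both C>T and G>A count as CG>TA.
#' Records with a non-ACGT ref or alt are skipped with a warning. The
#' cumulative proportion of the two oxidation-associated classes
#' (CG>TA + CG>AT) is reported alongside the per-class proportions.
#'
#' @param snvs data.frame with character columns `ref` and `alt` (single
#'   bases).
#' @return object of class `spectrum_tally`: `counts` (named, the six
#'   classes), `total`, `proportions`, `oxidation_proportion`.
#' @export
tally_spectrum <- function(snvs) {
  ref <- toupper(as.character(snvs$ref))
  alt <- toupper(as.character(snvs$alt))
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (any(!ok))
    warning(sum(!ok), " record(s) with non-ACGT or degenerate bases skipped")
  ref <- ref[ok]; alt <- alt[ok]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # collapse to the pyrimidine strand (ref C or T)
  flip <- ref %in% c("G", "A")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  key <- paste0(ref, ">", alt)
  map <- c("C>T" = "CG>TA", "C>A" = "CG>AT", "C>G" = "CG>GC",
           "T>C" = "TA>CG", "T>A" = "TA>AT", "T>G" = "TA>GC")
  cls <- factor(map[key], levels = SPECTRUM_CLASSES)
  counts <- table(cls)
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  props <- if (total > 0) counts / total else counts * NA_real_
  structure(list(counts = counts, total = total, proportions = props,
                 oxidation_proportion =
                   unname(props["CG>TA"] + props["CG>AT"])),
            class = "spectrum_tally")
}

#' @export
print.spectrum_tally <- function(x, ...) {
  cat("spectrum_tally:", x$total, "SNVs\n")
  print(data.frame(class = names(x$counts), count = x$counts,
                   proportion = round(x$proportions, 3), row.names = NULL))
  cat(sprintf("oxidation-associated (CG>TA + CG>AT): %.1f%%\n",
              100 * x$oxidation_proportion))
  invisible(x)
}

#' Compare two mutation spectra (Fisher's exact test)
#'
#' Collapses each spectrum to oxidation-associated (CG>TA + CG>AT) versus
#' all other classes and applies [fisher_exact_2x2()] to the resulting 2x2
#' table.
#'
#' @param tally_a,tally_b `spectrum_tally` objects with nonzero totals.
#' @return the [fisher_exact_2x2()] result.
#' @export
compare_spectra <- function(tally_a, tally_b) {
  stopifnot(inherits(tally_a, "spectrum_tally"),
            inherits(tally_b, "spectrum_tally"))
  if (tally_a$total == 0 || tally_b$total == 0)
    stop("both tallies must be nonempty")
  oxi <- function(t) sum(t$counts[c("CG>TA", "CG>AT")])
  m <- rbind(c(oxi(tally_a), tally_a$total - oxi(tally_a)),
             c(oxi(tally_b), tally_b$total - oxi(tally_b)))
  fisher_exact_2x2(m)
}

#' Mutant frequency across parallel cultures
#'
#' Per-culture frequencies are mutants/viable; the summary across cultures
#' is the median (robust to Luria–Delbrück jackpot cultures), with the mean
#' reported alongside.
#'
#' @param mutant_counts,viable_counts equal-length nonnegative count
#'   vectors; viable counts must be positive.
#' @return list with `frequencies`, `median`, `mean`.
#' @export
mutant_frequency <- function(mutant_counts, viable_counts) {
  if (length(mutant_counts) != length(viable_counts))
    stop("mutant and viable count vectors must have equal length")
  if (any(viable_counts <= 0)) stop("viable counts must be positive")
  if (any(mutant_counts < 0)) stop("mutant counts must be >= 0")
  f <- mutant_counts / viable_counts
  list(frequencies = f, median = stats::median(f), mean = mean(f))
}

#' Fraction of breakpoints inside a window
#'
#' The proportion of breakpoint-interval midpoints falling inside a bp
#' window on one chromosome, e.g. the share of T-LOH breakpoints between
#' kb 450 and kb 1050 on chromosome IV.
#'
#' @param midpoints numeric vector of breakpoint midpoints (bp); may also be
#'   a list of breakpoint intervals with `midpoint` elements.
#' @param window length-2 numeric `c(lo, hi)`, inclusive.
#' @return proportion in `[0, 1]`.
#' @export
breakpoint_distribution <- function(midpoints, window) {
  if (is.list(midpoints) && !is.null(midpoints[[1]]$midpoint))
    midpoints <- vapply(midpoints, function(b) b$midpoint, 0)
  midpoints <- as.numeric(midpoints)
  if (!length(midpoints)) stop("no breakpoints supplied")
  stopifnot(length(window) == 2, window[1] <= window[2])
  mean(midpoints >= window[1] & midpoints <= window[2])
}

#' Relative-ratio table of event classes per condition
#'
#' Converts a per-condition table of event-class counts into row
#' percentages (class count / row total x 100, one decimal), the form of a
#' relative-ratio summary across conditions.
#'
#' @param event_counts matrix or data.frame of nonnegative counts, rows =
#'   conditions, columns = event classes.
#' @return list with `counts` and `percent` (same shape, one decimal).
#' @export
ratio_table <- function(event_counts) {
  m <- as.matrix(event_counts)
  if (any(m < 0)) stop("counts must be nonnegative")
  tot <- rowSums(m)
  if (any(tot == 0)) stop("zero row total for condition(s): ",
                          paste(rownames(m)[tot == 0], collapse = ", "))
  list(counts = m, percent = round(100 * m / tot, 1))
}
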