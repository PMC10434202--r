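#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: output directory, genome
#' parameters, per-isolate culture accounting, caller thresholds and the
#' random seed. Used by [run_simulate()], [run_call()] and [run_report()];
#' the analysis drivers construct it once and pass it through.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer RNG seed; recorded in the run manifest.
#' @param n_isolates number of isolates to simulate.
#' @param divisions_per_isolate genome-divisions each isolate accrues;
#'   a vector is recycled across isolates (e.g. 400 for 8-cycle and 50 for
#'   single-cycle isolates).
#' @param n_snps SNP sites in the simulated genome.
#' @param mean_depth sequencing depth (total per SNP, diploid baseline).
#' @param event_rates per-division event rates (see
#'   [furfural_event_rates()]).
#' @param thresholds,min_snps,window caller parameters (see
#'   [segment_copy_states()]).
#' @param design a [culture_design()] used by [run_report()] for rates.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed, n_isolates = 31L,
                       divisions_per_isolate = 400L, n_snps = 50000L,
                       mean_depth = 50, event_rates = furfural_event_rates(),
                       thresholds = c(0.25, 0.75, 1.25), min_snps = 3L,
                       window = 5L, design = design_furfural_subculture()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_isolates = as.integer(n_isolates),
                 divisions_per_isolate = as.integer(divisions_per_isolate),
                 n_snps = as.integer(n_snps), mean_depth = mean_depth,
                 event_rates = event_rates, thresholds = thresholds,
                 min_snps = as.integer(min_snps), window = as.integer(window),
                 design = design),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields override [run_config()] defaults; a `design: groups:` block
#' is parsed with [culture_design()].
#'
#' @param path YAML file.
#' @param out_dir,seed required run parameters (overridable from the YAML).
#' @return a `run_config`.
#' @export
load_run_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$design))
    y$design <- culture_design(do.call(rbind,
                                       lapply(y$design$groups, as.data.frame)))
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(seed)) y$seed <- seed
  do.call(run_config, y)
}

#' Simulate a cohort of subcultured isolates
#'
#' Builds the genome map, spikes events into each isolate at the configured
#' rates over its divisions, simulates homolog-specific allele depths, and
#' writes per-isolate depth TSVs, the pooled ground-truth event table
#' (`true_events.tsv`, columns prefixed `true_`), the genome map files, and
#' a JSON manifest recording the seed, package version and file checksums.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the genome, per-isolate truth tables, and
#'   written file paths.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- yeast_genome_map(n_snps = config$n_snps)
  write_genome_map(genome,
                   file.path(config$out_dir, "genome_chroms.tsv"),
                   file.path(config$out_dir, "genome_snps.tsv"),
                   file.path(config$out_dir, "genome_repeats.bed"))
  truth <- list(); paths <- character()
  if (config$n_isolates == 0)
    warning("0 isolates configured; writing empty outputs")
  div <- rep(config$divisions_per_isolate, length.out = config$n_isolates)
  for (i in seq_len(config$n_isolates)) {
    cfg <- simulation_config(rng_seed = config$seed + 13L * i,
                             mean_depth = config$mean_depth,
                             event_rates = config$event_rates)
    sp <- spike_events(genome, cfg, divisions = div[i])
    depths <- simulate_allele_depths(sp$karyotype, genome, cfg)
    p <- file.path(config$out_dir, sprintf("isolate_%02d_depths.tsv", i))
    write_depths_tsv(depths, p)
    paths <- c(paths, p)
    ev <- sp$events
    if (nrow(ev)) ev$isolate <- sprintf("isolate_%02d", i)
    truth[[i]] <- ev
  }
  tru <- do.call(rbind, truth[vapply(truth, nrow, 0L) > 0])
  if (is.null(tru)) tru <- cbind(empty_truth(), isolate = character())
  names(tru) <- paste0("true_", names(tru))
  tp <- file.path(config$out_dir, "true_events.tsv")
  utils::write.table(tru, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(seed = config$seed,
                   n_isolates = config$n_isolates,
                   divisions_per_isolate = config$divisions_per_isolate,
                   package_version =
                     as.character(utils::packageVersion("lohscan")),
                   files = as.list(tools::md5sum(c(paths, tp))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genome = genome, truth = truth,
                 depth_files = paths, truth_file = tp))
}

empty_truth <- function() {
  data.frame(event_id = character(), type = character(), chrom = character(),
             homolog = character(), start_snp = integer(),
             end_snp = integer(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

#' Call events for every simulated isolate
#'
#' Reads the genome map and per-isolate depth tables written by
#' [run_simulate()], computes RC profiles, segments copy states, calls and
#' classifies events, pairs translocation hypotheses, and writes
#' `called_events.tsv` and `translocations.tsv` under the run directory.
#'
#' @param config the same [run_config()] used for [run_simulate()].
#' @return invisibly, a list with the pooled call table and hypotheses.
#' @export
run_call <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cf <- file.path(config$out_dir, "genome_chroms.tsv")
  if (!file.exists(cf)) stop("missing genome map under ", config$out_dir)
  genome <- load_genome_map(cf,
                            file.path(config$out_dir, "genome_snps.tsv"),
                            file.path(config$out_dir, "genome_repeats.bed"))
  files <- sort(list.files(config$out_dir, "^isolate_.*_depths\\.tsv$",
                           full.names = TRUE))
  calls <- list(); hyps <- list()
  for (p in files) {
    iso <- sub("_depths\\.tsv$", "", basename(p))
    prof <- compute_rc(read_allele_depths(p), genome)
    segs <- segment_copy_states(prof, thresholds = config$thresholds,
                                min_snps = config$min_snps,
                                window = config$window)
    ev <- call_events(segs, genome)
    tr <- pair_translocations(ev, genome)
    if (nrow(ev)) { ev$isolate <- iso; calls[[length(calls) + 1L]] <- ev }
    if (nrow(tr$hypotheses)) {
      tr$hypotheses$isolate <- iso
      hyps[[length(hyps) + 1L]] <- tr$hypotheses
    }
  }
  ev <- if (length(calls)) do.call(rbind, calls) else
    cbind(empty_events(), event_id = character(), class = character(),
          isolate = character())
  hy <- if (length(hyps)) do.call(rbind, hyps) else NULL
  utils::write.table(ev, file.path(config$out_dir, "called_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(hy))
    utils::write.table(hy, file.path(config$out_dir, "translocations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(events = ev, hypotheses = hy))
}

#' Summarize called events into rates and a report
#'
#' Aggregates a call table into per-type counts and per-genome
#' per-cell-division rates under the configured culture design, writes
#' `rates.tsv` and a small markdown `report.md`, and returns the rate table.
#' An empty call table produces an all-zero table, not a failure.
#'
#' @param config a [run_config()]; reads `called_events.tsv` from its
#'   `out_dir` unless `events` is supplied.
#' @param events optional call table overriding the file.
#' @return invisibly, the rates data.frame.
#' @export
run_report <- function(config, events = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(events)) {
    p <- file.path(config$out_dir, "called_events.tsv")
    events <- if (file.exists(p))
      utils::read.table(p, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    else empty_events()
  }
  D <- total_divisions(config$design)
  types <- c(EVENT_TYPES, "UNCLASSIFIED")
  n <- vapply(types, function(t) sum(events$type == t), 0)
  rates <- data.frame(event_type = types, n = n, divisions = D,
                      rate = n / D, rate_reported = signif(n / D, 2),
                      row.names = NULL)
  utils::write.table(rates, file.path(config$out_dir, "rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- c("# Instability run report", "",
             sprintf("- isolates: %d", config$n_isolates),
             sprintf("- genome-divisions (design): %s",
                     format(D, big.mark = ",")),
             sprintf("- events called: %d", nrow(events)), "",
             "| type | n | rate/genome/division |",
             "|------|---|----------------------|",
             sprintf("| %s | %d | %.2g |", rates$event_type, rates$n,
                     rates$rate))
  writeLines(lines, file.path(config$out_dir, "report.md"))
  invisible(rates)
}
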