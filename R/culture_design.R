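#' Subculture design and genome-division accounting
#'
#' A culture design converts a subculture experiment (isolates streaked for a
#' number of cycles, forming one or more colonies per cycle) into the total
#' number of genome-divisions, the denominator of every per-genome
#' per-cell-division rate. One colony formed from a single cell corresponds
#' to ~25 cell divisions.
#'
#' @param groups a data.frame (or list coercible to one) with integer columns
#'   `n_isolates`, `cycles`, `colonies_per_cycle`, `divisions_per_colony`
#'   (default 25), one row per homogeneous group of isolates.
#' @return an object of class `culture_design`.
#' @export
culture_design <- function(groups) {
  g <- as.data.frame(groups)
  if (!"divisions_per_colony" %in% names(g)) g$divisions_per_colony <- 25L
  need <- c("n_isolates", "cycles", "colonies_per_cycle",
            "divisions_per_colony")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("culture design needs columns: ", paste(miss, collapse = ", "))
  g <- g[, need, drop = FALSE]
  for (cc in need) {
    v <- g[[cc]]
    if (any(is.na(v)) || any(v <= 0) || any(v != round(v)))
      stop("culture design field '", cc, "' must be a positive integer")
    g[[cc]] <- as.integer(v)
  }
  structure(list(groups = g), class = "culture_design")
}

#' @export
print.culture_design <- function(x, ...) {
  cat("culture_design:", nrow(x$groups), "group(s),",
      format(total_divisions(x), big.mark = ","), "genome-divisions\n")
  print(x$groups)
  invisible(x)
}

#' Total genome-divisions of a subculture design
#'
#' Sums, over groups, n_isolates x cycles x colonies_per_cycle x
#' divisions_per_colony.
#'
#' @param design a [culture_design()].
#' @return total number of genome-divisions (numeric scalar).
#' @export
total_divisions <- function(design) {
  stopifnot(inherits(design, "culture_design"))
  g <- design$groups
  sum(as.numeric(g$n_isolates) * g$cycles * g$colonies_per_cycle *
        g$divisions_per_colony)
}

#' Load a culture design from YAML
#'
#' The YAML file holds a list `groups`, each entry with the four integer
#' fields of [culture_design()].
#'
#' @param path YAML file path.
#' @return a [culture_design()].
#' @export
load_culture_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$groups)) stop("culture design YAML needs a 'groups' list")
  culture_design(do.call(rbind, lapply(y$groups, as.data.frame)))
}

#' Study subculture designs
#'
#' Ready-made [culture_design()] objects for the three arms of the furfural
#' subculture study:
#' \describe{
#'   \item{`design_furfural_subculture()`}{all 31 isolates grown on
#'   0.6 g/L furfural plates: 28 isolates for 8 cycles and 3 isolates for a
#'   single cycle. Each cycle comprises two colony formations (selection on
#'   the furfural plate, then purification on YPD), i.e. 50 divisions per
#'   cycle; 11,350 genome-divisions in total.}
#'   \item{`design_untreated_subculture()`}{the untreated control: 20
#'   isolates subcultured on YPD for 20 cycles, one colony formation per
#'   cycle (500 divisions per isolate); 10,000 genome-divisions.}
#'   \item{`design_furfural_sequenced()`}{the 21 sequenced furfural isolates
#'   only (18 at 8 cycles, 3 at 1 cycle, two colony formations per cycle);
#'   7,350 genome-divisions, the denominator of the per-base mutation
#'   rates.}
#' }
#' @return a [culture_design()].
#' @name study_designs
NULL

#' @rdname study_designs
#' @export
design_furfural_subculture <- function() {
  culture_design(data.frame(
    n_isolates = c(28L, 3L), cycles = c(8L, 1L),
    colonies_per_cycle = c(2L, 2L), divisions_per_colony = c(25L, 25L)))
}

#' @rdname study_designs
#' @export
design_untreated_subculture <- function() {
  culture_design(data.frame(
    n_isolates = 20L, cycles = 20L,
    colonies_per_cycle = 1L, divisions_per_colony = 25L))
}

#' @rdname study_designs
#' @export
design_furfural_sequenced <- function() {
  culture_design(data.frame(
    n_isolates = c(18L, 3L), cycles = c(8L, 1L),
    colonies_per_cycle = c(2L, 2L), divisions_per_colony = c(25L, 25L)))
}
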