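#' @keywords internal
"_PACKAGE"

ROMAN16 <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
             "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI")

#' Construct a hybrid-diploid genome map
#'
#' A genome map holds the chromosome coordinate system of the hybrid diploid:
#' chromosome lengths, one centromere interval per chromosome, repeat (Ty)
#' intervals, and the list of homolog-specific SNP sites that distinguish the
#' two parental homologs ("W" for the W303-1A-derived homolog, "Y" for the
#' YJM789-derived homolog). All coordinates are 1-based inclusive.
#'
#' @param chromosomes data.frame with columns `chrom`, `length`, `cen_start`,
#'   `cen_end` (one row per chromosome, chromosomes in karyotype order).
#' @param snps data.frame with columns `chrom`, `pos`, `w_allele`, `y_allele`;
#'   positions must be strictly increasing within each chromosome.
#' @param repeats data.frame with columns `chrom`, `start`, `end` (and
#'   optionally `name`) giving repeat intervals excluded from the RC
#'   normalizer; may be empty.
#'
#' @return An object of class `genome_map` with elements `chromosomes`,
#'   `snps`, `repeats`, `haploid_size`, `diploid_size`.
#' @export
genome_map <- function(chromosomes, snps, repeats = NULL) {
  chromosomes <- as.data.frame(chromosomes)
  need <- c("chrom", "length", "cen_start", "cen_end")
  if (!all(need %in% names(chromosomes)))
    stop("genome map needs columns: ", paste(need, collapse = ", "))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (anyDuplicated(chromosomes$chrom))
    stop("duplicate chromosome (overlapping centromere definitions): ",
         chromosomes$chrom[duplicated(chromosomes$chrom)][1])
  if (any(is.na(chromosomes$cen_start)) || any(is.na(chromosomes$cen_end)))
    stop("missing centromere for at least one chromosome")
  bad <- chromosomes$cen_start < 1 | chromosomes$cen_end > chromosomes$length |
    chromosomes$cen_start > chromosomes$cen_end
  if (any(bad))
    stop("centromere interval outside chromosome bounds: ",
         paste(chromosomes$chrom[bad], collapse = ", "))

  if (is.null(repeats))
    repeats <- data.frame(chrom = character(), start = integer(),
                          end = integer(), name = character())
  repeats <- as.data.frame(repeats)
  if (nrow(repeats)) {
    repeats$chrom <- as.character(repeats$chrom)
    if (!all(repeats$chrom %in% chromosomes$chrom))
      stop("repeat interval on unknown chromosome")
    len <- chromosomes$length[match(repeats$chrom, chromosomes$chrom)]
    if (any(repeats$start < 1 | repeats$end > len | repeats$start > repeats$end))
      stop("repeat interval outside chromosome bounds")
    if (is.null(repeats$name)) repeats$name <- sprintf("rep%d", seq_len(nrow(repeats)))
  }

  snps <- as.data.frame(snps)
  if (!all(c("chrom", "pos", "w_allele", "y_allele") %in% names(snps)))
    stop("SNP map needs columns chrom, pos, w_allele, y_allele")
  snps$chrom <- as.character(snps$chrom)
  if (!all(snps$chrom %in% chromosomes$chrom))
    stop("SNP on unknown chromosome")
  for (cc in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == cc]
    if (any(diff(p) <= 0))
      stop("SNP positions not strictly increasing on chromosome ", cc)
    L <- chromosomes$length[chromosomes$chrom == cc]
    if (min(p) < 1 || max(p) > L)
      stop("SNP position outside chromosome ", cc)
  }
  snps <- snps[order(match(snps$chrom, chromosomes$chrom)), , drop = FALSE]
  rownames(snps) <- NULL

  hap <- sum(as.numeric(chromosomes$length))
  structure(list(chromosomes = chromosomes, snps = snps, repeats = repeats,
                 haploid_size = hap, diploid_size = 2 * hap),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %d chromosomes, %d SNP sites, %d repeat intervals\n",
              nrow(x$chromosomes), nrow(x$snps), nrow(x$repeats)))
  cat(sprintf("haploid size %.2f Mb, diploid size %.2f Mb\n",
              x$haploid_size / 1e6, x$diploid_size / 1e6))
  invisible(x)
}

# SNP table for one chromosome, with a repeat-overlap flag
chrom_snps <- function(genome, chrom) {
  s <- genome$snps[genome$snps$chrom == chrom, , drop = FALSE]
  rep <- genome$repeats[genome$repeats$chrom == chrom, , drop = FALSE]
  inrep <- rep(FALSE, nrow(s))
  if (nrow(rep) && nrow(s)) {
    for (i in seq_len(nrow(rep)))
      inrep <- inrep | (s$pos >= rep$start[i] & s$pos <= rep$end[i])
  }
  s$in_repeat <- inrep
  s
}

# does [start, end] on chrom contain the centromere?
contains_centromere <- function(genome, chrom, start, end) {
  i <- match(chrom, genome$chromosomes$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  cs <- genome$chromosomes$cen_start[i]
  ce <- genome$chromosomes$cen_end[i]
  start <= cs && end >= ce
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$chrom)
  if (anyNA(i)) stop("unknown chromosome")
  genome$chromosomes$length[i]
}

#' Load a genome map from TSV files
#'
#' Reads the chromosome table (`chrom`, `length`, `cen_start`, `cen_end`),
#' the SNP map (`chrom`, `pos`, `w_allele`, `y_allele`) and optionally a
#' repeat BED file (0-based half-open; converted to 1-based inclusive).
#'
#' @param chrom_file TSV with the chromosome/centromere table.
#' @param snp_file TSV with the homolog-specific SNP map.
#' @param repeat_bed optional BED file of repeat (Ty) intervals.
#' @return a [genome_map()].
#' @export
load_genome_map <- function(chrom_file, snp_file, repeat_bed = NULL) {
  chroms <- read_tsv_checked(chrom_file,
                             c("chrom", "length", "cen_start", "cen_end"))
  snps <- read_tsv_checked(snp_file, c("chrom", "pos", "w_allele", "y_allele"))
  repeats <- NULL
  if (!is.null(repeat_bed)) {
    bed <- utils::read.table(repeat_bed, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 3) stop("malformed BED: ", repeat_bed)
    repeats <- data.frame(chrom = as.character(bed[[1]]),
                          start = bed[[2]] + 1L, end = bed[[3]],
                          name = if (ncol(bed) >= 4) as.character(bed[[4]])
                                 else sprintf("rep%d", seq_len(nrow(bed))))
  }
  genome_map(chroms, snps, repeats)
}

#' Write a genome map to TSV/BED files
#'
#' Inverse of [load_genome_map()]; the round trip is lossless.
#'
#' @param genome a [genome_map()].
#' @param chrom_file,snp_file,repeat_bed output paths (`repeat_bed` optional).
#' @return invisibly, the paths written.
#' @export
write_genome_map <- function(genome, chrom_file, snp_file, repeat_bed = NULL) {
  utils::write.table(genome$chromosomes[, c("chrom", "length", "cen_start",
                                            "cen_end")],
                     chrom_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genome$snps[, c("chrom", "pos", "w_allele", "y_allele")],
                     snp_file, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(chrom_file, snp_file)
  if (!is.null(repeat_bed)) {
    bed <- data.frame(chrom = genome$repeats$chrom,
                      start = genome$repeats$start - 1L,
                      end = genome$repeats$end,
                      name = genome$repeats$name)
    utils::write.table(bed, repeat_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, repeat_bed)
  }
  invisible(paths)
}

read_tsv_checked <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(utils::read.table(path, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE),
                error = function(e) stop("parse error in ", path, ": ",
                                         conditionMessage(e)))
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  x
}

# S288C chromosome lengths and approximate centromere midpoint coordinates
# (SGD R64 assembly, rounded); lengths sum to ~12.07 Mb.
YEAST_CHROMS <- data.frame(
  chrom = ROMAN16,
  length = c(230218L, 813184L, 316620L, 1531933L, 576874L, 270161L,
             1090940L, 562643L, 439888L, 745751L, 666816L, 1078177L,
             924431L, 784333L, 1091291L, 948066L),
  cen_start = c(151465L, 238207L, 114385L, 449711L, 151987L, 148510L,
                496920L, 105586L, 355629L, 436307L, 440129L, 150828L,
                268031L, 628758L, 326584L, 555957L),
  cen_end = c(151582L, 238323L, 114501L, 449821L, 152104L, 148627L,
              497038L, 105703L, 355745L, 436425L, 440246L, 150947L,
              268149L, 628875L, 326702L, 556073L),
  stringsAsFactors = FALSE
)

#' Packaged S. cerevisiae hybrid genome map
#'
#' Builds the W303-1A x YJM789 hybrid-diploid genome model used throughout:
#' the 16 S. cerevisiae chromosomes (haploid ~12 Mb, diploid 24 Mb),
#' one centromere each, synthetic Ty-like repeat intervals, and approximately
#' `n_snps` homolog-specific SNP sites placed at near-uniform spacing
#' (about one SNP per 240 bp at the default density, mirroring the ~50,000
#' SNPs that distinguish the two parental homologs). SNP placement is
#' deterministic; sites falling inside repeat intervals are dropped when
#' `exclude_repeats` is TRUE.
#'
#' @param n_snps target number of SNP sites genome-wide (default 50000).
#' @param exclude_repeats drop SNPs inside repeat intervals (default TRUE).
#' @return a [genome_map()].
#' @export
yeast_genome_map <- function(n_snps = 50000, exclude_repeats = TRUE) {
  chroms <- YEAST_CHROMS
  reps <- yeast_repeats(chroms)
  dens <- chroms$length / sum(chroms$length)
  per <- pmax(10L, round(n_snps * dens))
  snp_list <- vector("list", nrow(chroms))
  alle <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2,
                 byrow = TRUE)
  for (i in seq_len(nrow(chroms))) {
    pos <- unique(round(seq(500, chroms$length[i] - 500,
                            length.out = per[i])))
    if (exclude_repeats) {
      r <- reps[reps$chrom == chroms$chrom[i], , drop = FALSE]
      if (nrow(r)) {
        keep <- rep(TRUE, length(pos))
        for (j in seq_len(nrow(r)))
          keep <- keep & !(pos >= r$start[j] & pos <= r$end[j])
        pos <- pos[keep]
      }
    }
    k <- (seq_along(pos) - 1L) %% 4L + 1L
    snp_list[[i]] <- data.frame(chrom = chroms$chrom[i], pos = pos,
                                w_allele = alle[k, 1], y_allele = alle[k, 2],
                                stringsAsFactors = FALSE)
  }
  genome_map(chroms, do.call(rbind, snp_list), reps)
}

# Deterministic Ty-like repeat placement: ~one 6-kb element per 150 kb,
# avoiding the centromere and the chromosome ends. Synthetic stand-in for
# the repeat annotation; positions are not the real Ty coordinates.
yeast_repeats <- function(chroms) {
  out <- list()
  for (i in seq_len(nrow(chroms))) {
    L <- chroms$length[i]
    n <- max(0L, floor(L / 150000))
    if (n == 0L) next
    starts <- round(seq(60000, L - 66000, length.out = n))
    ends <- starts + 5900L
    ok <- !(starts <= chroms$cen_end[i] + 10000 &
              ends >= chroms$cen_start[i] - 10000)
    if (!any(ok)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = chroms$chrom[i], start = starts[ok], end = ends[ok],
      name = sprintf("Ty_%s_%d", chroms$chrom[i], seq_len(sum(ok))),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  do.call(rbind, out)
}
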