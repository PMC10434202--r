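#' Relative-coverage (RC) profile from homolog-specific allele depths
#'
#' RC is the per-SNP homolog-specific read depth divided by the average
#' per-SNP sequencing coverage over all SNPs in nonrepeat sequence, so that
#' RC values of 0, 0.5 and 1 correspond to 0, 1 and 2 copies of a homolog.
#' SNPs inside repeat intervals stay in the profile (flagged `in_repeat`)
#' but are excluded from the normalizer.
#'
#' @param depths allele-depth table (`chrom`, `pos`, `w_depth`, `y_depth`),
#'   one isolate; positions must exist in the genome's SNP map.
#' @param genome a [genome_map()].
#' @param center how the per-SNP total coverage is averaged: `"mean"` (the
#'   RC definition) or `"median"`, which resists the baseline shift a
#'   heavily aneuploid genome imposes on the mean.
#' @return an `rc_profile`: data.frame `chrom`, `pos`, `rc_w`, `rc_y`,
#'   `in_repeat`, with the normalizer in attribute `normalizer`.
#' @export
compute_rc <- function(depths, genome, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(inherits(genome, "genome_map"))
  d <- as.data.frame(depths)
  need <- c("chrom", "pos", "w_depth", "y_depth")
  if (!all(need %in% names(d)))
    stop("allele-depth table needs columns: ", paste(need, collapse = ", "))
  if (any(d$w_depth < 0) || any(d$y_depth < 0)) stop("negative depth")
  key_g <- paste(genome$snps$chrom, genome$snps$pos)
  key_d <- paste(d$chrom, d$pos)
  if (!all(key_d %in% key_g))
    stop("depth table contains positions absent from the genome SNP map")
  d <- d[order(match(d$chrom, genome$chromosomes$chrom), d$pos), ,
         drop = FALSE]

  inrep <- rep(FALSE, nrow(d))
  for (cc in unique(d$chrom)) {
    r <- genome$repeats[genome$repeats$chrom == cc, , drop = FALSE]
    if (!nrow(r)) next
    sel <- which(d$chrom == cc)
    for (i in seq_len(nrow(r)))
      inrep[sel] <- inrep[sel] |
        (d$pos[sel] >= r$start[i] & d$pos[sel] <= r$end[i])
  }
  if (all(inrep)) stop("all SNPs fall in repeats; cannot normalize")
  tot <- d$w_depth[!inrep] + d$y_depth[!inrep]
  norm <- if (center == "mean") mean(tot) else stats::median(tot)
  if (norm <= 0) stop("zero normalizer: no coverage on nonrepeat SNPs")
  out <- data.frame(chrom = d$chrom, pos = d$pos,
                    rc_w = d$w_depth / norm, rc_y = d$y_depth / norm,
                    in_repeat = inrep, stringsAsFactors = FALSE)
  attr(out, "normalizer") <- norm
  class(out) <- c("rc_profile", "data.frame")
  out
}

ARRAY_LEVEL_MAP <- c(0.2, 1.0, 1.5)   # hybridization levels for 0/1/2 copies
ARRAY_RC_MAP <- c(0.0, 0.5, 1.0)      # corresponding RC-scale values

#' Convert array hybridization ratios to an RC-scale copy signal
#'
#' Maps each per-homolog hybridization ratio to the RC scale by
#' nearest-level assignment (0.2 -> 0.0, 1.0 -> 0.5, 1.5 -> 1.0; thresholds
#' at the midpoints 0.6 and 1.25, with ties going to the higher level),
#' yielding a profile usable by the same segmentation caller as sequencing
#' data. The raw ratios are retained in `raw_w` / `raw_y`.
#'
#' @param array array table (`chrom`, `pos`, `homolog`, `hyb_ratio`) with
#'   homolog labels W and Y.
#' @return an `rc_profile` with columns `chrom`, `pos`, `rc_w`, `rc_y`,
#'   `raw_w`, `raw_y`, `in_repeat` (FALSE; arrays carry no repeat flag).
#' @export
array_to_copy_signal <- function(array) {
  a <- as.data.frame(array)
  need <- c("chrom", "pos", "homolog", "hyb_ratio")
  if (!all(need %in% names(a)))
    stop("array table needs columns: ", paste(need, collapse = ", "))
  if (!all(a$homolog %in% c("W", "Y")))
    stop("unknown homolog label(s): ",
         paste(unique(setdiff(a$homolog, c("W", "Y"))), collapse = ", "))
  lev <- findInterval(a$hyb_ratio, c(0.6, 1.25)) + 1L  # ties -> higher level
  a$rc <- ARRAY_RC_MAP[lev]
  w <- a[a$homolog == "W", c("chrom", "pos", "rc", "hyb_ratio")]
  y <- a[a$homolog == "Y", c("chrom", "pos", "rc", "hyb_ratio")]
  names(w)[3:4] <- c("rc_w", "raw_w"); names(y)[3:4] <- c("rc_y", "raw_y")
  out <- merge(w, y, by = c("chrom", "pos"), all = TRUE, sort = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out$in_repeat <- FALSE
  class(out) <- c("rc_profile", "data.frame")
  out
}

#' Running-median smoothing of an RC profile
#'
#' Applies a running median over `window` consecutive SNPs to each homolog
#' track within each chromosome (shrunken windows at the ends), suppressing
#' isolated mismapped or noisy sites before copy-state assignment. Window 1
#' is the identity.
#'
#' @param profile an `rc_profile` (from [compute_rc()] or
#'   [array_to_copy_signal()]).
#' @param window odd positive SNP count.
#' @return the smoothed `rc_profile`.
#' @export
smooth_profile <- function(profile, window = 5L) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (window == 1) return(profile)
  out <- profile
  for (cc in unique(out$chrom)) {
    sel <- which(out$chrom == cc)
    if (length(sel) < 2) next
    k <- min(window, if (length(sel) %% 2 == 0) length(sel) - 1
                     else length(sel))
    out$rc_w[sel] <- stats::runmed(out$rc_w[sel], k, endrule = "median")
    out$rc_y[sel] <- stats::runmed(out$rc_y[sel], k, endrule = "median")
  }
  out
}

#' Read / write allele-depth and RC tables
#'
#' TSV round-trip helpers for the pipeline's tabular interfaces.
#'
#' @param path file path.
#' @name depth_io
NULL

#' @rdname depth_io
#' @export
read_allele_depths <- function(path) {
  read_tsv_checked(path, c("chrom", "pos", "w_depth", "y_depth"))
}

#' @rdname depth_io
#' @param x table to write.
#' @export
write_depths_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read homolog-specific allele depths from a VCF
#'
#' Splits the VCF AD (allele depth) field into W- and Y-homolog depths by
#' matching each record's REF/ALT alleles against the genome SNP map's
#' `w_allele` / `y_allele`. Records at positions absent from the SNP map, or
#' whose alleles do not match it, are dropped with a warning. Requires the
#' vcfR package.
#'
#' @param path VCF file (plain or gzipped).
#' @param genome a [genome_map()].
#' @return an allele-depth table (`chrom`, `pos`, `w_depth`, `y_depth`).
#' @export
read_allele_depths_vcf <- function(path, genome) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  parts <- strsplit(ad, ",", fixed = TRUE)
  ref_d <- as.integer(vapply(parts, `[`, "", 1))
  alt_d <- as.integer(vapply(parts, function(p)
    if (length(p) >= 2) p[2] else "0", ""))
  key_g <- paste(genome$snps$chrom, genome$snps$pos)
  idx <- match(paste(fix$CHROM, fix$POS), key_g)
  keep <- !is.na(idx)
  w <- genome$snps$w_allele[idx[keep]]
  y <- genome$snps$y_allele[idx[keep]]
  ref <- fix$REF[keep]; alt <- fix$ALT[keep]
  ok <- (ref == w & alt == y) | (ref == y & alt == w)
  if (any(!keep) || any(!ok))
    warning(sum(!keep) + sum(!ok),
            " VCF record(s) not matching the SNP map were dropped")
  w_depth <- ifelse(ref[ok] == w[ok], ref_d[keep][ok], alt_d[keep][ok])
  y_depth <- ifelse(ref[ok] == y[ok], ref_d[keep][ok], alt_d[keep][ok])
  data.frame(chrom = fix$CHROM[keep][ok],
             pos = as.integer(fix$POS[keep][ok]),
             w_depth = w_depth, y_depth = y_depth,
             stringsAsFactors = FALSE)
}
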