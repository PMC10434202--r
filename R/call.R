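#' Segment homolog copy states along each chromosome
#'
#' Assigns every SNP a copy state (0–3) per homolog and collapses the
#' per-SNP states into maximal runs. State assignment is a penalized
#' minimal-misfit segmentation: over the smoothed RC track, the piecewise
#' state sequence minimizing the summed squared deviation from the state
#' levels (0, 0.5, 1, 1.5 at the default thresholds) plus `lambda` per
#' state change is found by dynamic programming. With `lambda = 0` this
#' reduces to plain nearest-level thresholding (defaults: RC < 0.25 -> 0
#' copies, < 0.75 -> 1, < 1.25 -> 2, else 3); the positive default makes a
#' state change require more evidence than a short cluster of depth
#' outliers can supply. Runs shorter than `min_snps` are then merged into
#' their dominant (longer) neighbor.
#'
#' @param profile an `rc_profile`, sorted by chromosome and position.
#' @param thresholds three increasing cut points separating copy states
#'   0/1/2/3 on the RC scale; the state levels used by the misfit are their
#'   midpoint-consistent reflections (defaults give 0, 0.5, 1, 1.5).
#' @param min_snps minimum run length kept as its own segment (default 3).
#' @param window odd running-median window applied before state assignment
#'   (default 5; 1 disables smoothing).
#' @param lambda per-changepoint penalty of the minimal-misfit fit
#'   (default 0.2; 0 disables the penalty).
#' @return data.frame of `homolog_segment`s: `chrom`, `homolog`, `start_snp`,
#'   `end_snp`, `start`, `end` (bp of the first/last SNP in the run),
#'   `state`, `n_snps`; SNP positions per chromosome are attached as
#'   attribute `positions`.
#' @export
segment_copy_states <- function(profile, thresholds = c(0.25, 0.75, 1.25),
                                min_snps = 3L, window = 5L, lambda = 0.2) {
  stopifnot(length(thresholds) == 3, !is.unsorted(thresholds))
  levels <- threshold_levels(thresholds)
  sm <- smooth_profile(profile, window)
  chroms <- unique(sm$chrom)
  segs <- list()
  pos_by <- list()
  rc_by <- list()
  for (cc in chroms) {
    sel <- which(sm$chrom == cc)
    if (!length(sel)) {
      warning("empty chromosome skipped: ", cc)
      next
    }
    pos <- sm$pos[sel]
    pos_by[[cc]] <- pos
    rc_by[[cc]] <- list(W = profile$rc_w[sel], Y = profile$rc_y[sel])
    for (h in c("W", "Y")) {
      rc <- if (h == "W") sm$rc_w[sel] else sm$rc_y[sel]
      st <- if (lambda > 0) fit_states_dp(rc, levels, lambda)
            else findInterval(rc, thresholds)    # 0..3
      st <- merge_short_runs(st, min_snps)
      r <- rle(st)
      e <- cumsum(r$lengths)
      s <- c(1L, utils::head(e, -1) + 1L)
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = cc, homolog = h, start_snp = s, end_snp = e,
        start = pos[s], end = pos[e], state = r$values,
        n_snps = r$lengths, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs)
         else data.frame(chrom = character(), homolog = character(),
                         start_snp = integer(), end_snp = integer(),
                         start = numeric(), end = numeric(),
                         state = integer(), n_snps = integer())
  rownames(out) <- NULL
  attr(out, "positions") <- pos_by
  attr(out, "rc") <- rc_by
  out
}

# state levels whose successive midpoints are the given thresholds
# (defaults 0.25/0.75/1.25 -> levels 0, 0.5, 1, 1.5)
threshold_levels <- function(thresholds) {
  l0 <- max(0, 2 * thresholds[1] - thresholds[2])
  l1 <- 2 * thresholds[1] - l0
  l2 <- 2 * thresholds[2] - l1
  c(l0, l1, l2, 2 * thresholds[3] - l2)
}

# penalized minimal-misfit state fit: minimize sum((rc - level[state])^2)
# + lambda * (#state changes), by dynamic programming over the 4 states
fit_states_dp <- function(rc, levels, lambda) {
  n <- length(rc)
  if (!n) return(integer(0))
  cost <- outer(rc, levels, function(x, l) (x - l)^2)   # n x 4
  V <- cost[1, ]
  back <- matrix(0L, n, 4L)
  for (i in seq_len(n)[-1]) {
    jmin <- which.min(V)
    stay <- V
    jump <- V[jmin] + lambda
    take_jump <- jump < stay
    back[i, ] <- ifelse(take_jump, jmin, 1:4)
    V <- cost[i, ] + pmin(stay, jump)
  }
  st <- integer(n)
  st[n] <- which.min(V)
  for (i in n:2) st[i - 1L] <- back[i, st[i]]
  st - 1L
}

# merge runs shorter than min_snps into the longer neighbor (ties -> left)
merge_short_runs <- function(states, min_snps) {
  if (min_snps <= 1L) return(states)
  repeat {
    r <- rle(states)
    if (length(r$lengths) == 1L || all(r$lengths >= min_snps)) return(states)
    short <- which(r$lengths < min_snps)
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1L) r$lengths[i - 1L] else -1L
    right <- if (i < length(r$lengths)) r$lengths[i + 1L] else -1L
    r$values[i] <- if (left >= right) r$values[i - 1L] else r$values[i + 1L]
    states <- inverse.rle(r)
  }
}

JOINT_TYPE <- function(w, y) {
  key <- paste(w, y)
  switch(key,
         "0 2" = , "2 0" = "LOH",
         "0 1" = , "1 0" = "DEL",
         "2 1" = , "1 2" = "DUP",
         "1 1" = "NORMAL",
         "OTHER")
}

#' Call and classify genomic alterations from homolog segments
#'
#' Combines the W and Y segmentations of each chromosome into joint-state
#' runs and maps them onto the event taxonomy: copy-neutral (0,2) regions
#' are interstitial LOH when flanked by heterozygosity on both sides and
#' terminal LOH when they reach exactly one telomere; (0,1) / (2,1) regions
#' reaching a telomere are terminal deletions / duplications; a non-normal
#' joint state covering at least `aneuploidy_frac` of a chromosome's SNPs
#' *and* both chromosome ends is promoted to a whole-chromosome call
#' (trisomy, monosomy, or UPD). A terminal LOH with a same-configuration
#' interstitial tract within `b5_gap` SNPs of its breakpoint is flagged
#' conversion-associated (class B5) and the tract is absorbed into it.
#' Uninterpretable joint states are reported as UNCLASSIFIED, never dropped.
#'
#' The `homolog` column reports the affected homolog: the one lost for
#' LOH / UPD / monosomy / deletion, the one gained for duplication /
#' trisomy.
#'
#' @param segments output of [segment_copy_states()].
#' @param genome a [genome_map()].
#' @param aneuploidy_frac minimum SNP fraction for a whole-chromosome call
#'   (default 0.95; tolerates edge noise).
#' @param b5_gap maximum heterozygous gap (SNPs) between a T-LOH breakpoint
#'   and an adjacent conversion tract (default 5).
#' @param min_snps joint-state runs shorter than this merge into their
#'   dominant neighbor, absorbing slivers where the W and Y transition
#'   boundaries misalign by a site or two (default 3).
#' @param class_map optional named remapping of class codes (see
#'   [classify_event()]).
#' @return data.frame of event calls: `event_id`, `chrom`, `type`, `class`,
#'   `homolog`, `start`, `end`, `start_snp`, `end_snp`, `n_snps`,
#'   `conv_assoc`, and breakpoint intervals `bp_left_lo`, `bp_left_hi`,
#'   `bp_right_lo`, `bp_right_hi`.
#' @export
call_events <- function(segments, genome, aneuploidy_frac = 0.95,
                        b5_gap = 5L, min_snps = 3L, class_map = NULL) {
  stopifnot(inherits(genome, "genome_map"))
  pos_by <- attr(segments, "positions")
  if (is.null(pos_by)) {
    pos_by <- lapply(unique(segments$chrom), function(cc)
      genome$snps$pos[genome$snps$chrom == cc])
    names(pos_by) <- unique(segments$chrom)
  }
  rows <- list()
  for (cc in unique(segments$chrom)) {
    pos <- pos_by[[cc]]
    n <- length(pos)
    L <- chrom_length(genome, cc)
    sw <- expand_states(segments, cc, "W", n)
    sy <- expand_states(segments, cc, "Y", n)
    key <- paste(sw, sy)
    # joint-level short-run merging: sub-min_snps slivers where the W and Y
    # transition boundaries misalign by a site or two are absorbed
    f <- factor(key)
    key <- levels(f)[merge_short_runs(as.integer(f), min_snps) ]
    # polish each joint-run boundary on the raw RC of both homolog tracks:
    # the smoothed fit localizes the transition to +/- a couple of SNPs,
    # the raw misfit pins down the exact flanking-site pair
    rc_raw <- if (!is.null(attr(segments, "rc"))) attr(segments, "rc")[[cc]]
              else NULL
    if (!is.null(rc_raw))
      key <- refine_boundaries(key, rc_raw, window = 4L)
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)

    # whole-chromosome call: dominant non-normal joint state covering
    # >= aneuploidy_frac of SNPs and both chromosome ends
    tab <- tapply(r$lengths, r$values, sum)
    tab <- tab[names(tab) != "1 1"]
    whole <- FALSE
    if (length(tab)) {
      js <- names(tab)[which.max(tab)]
      if (tab[js] / n >= aneuploidy_frac && key[1] == js && key[n] == js) {
        st <- as.integer(strsplit(js, " ")[[1]])
        ty_h <- whole_chrom_type(st[1], st[2])
        rows[[length(rows) + 1L]] <- event_row(
          cc, ty_h$type, ty_h$homolog, 1, L, 1L, n, n,
          pos, L, touches_left = TRUE, touches_right = TRUE)
        whole <- TRUE
      }
    }
    if (whole) next

    for (k in seq_along(r$values)) {
      st <- as.integer(strsplit(r$values[k], " ")[[1]])
      jt <- JOINT_TYPE(st[1], st[2])
      if (jt == "NORMAL") next
      i <- starts[k]; j <- ends[k]
      tl <- i == 1L; tr <- j == n
      if (jt == "LOH") {
        affected <- if (st[1] == 0L) "W" else "Y"
        type <- if (tl != tr) "T-LOH" else if (!tl && !tr) "I-LOH"
                else "UPD"
      } else if (jt == "DEL") {
        affected <- if (st[1] == 0L) "W" else "Y"
        type <- if (tl != tr) "T-DEL"
                else if (tl && tr) "MONOSOMY" else "UNCLASSIFIED"
      } else if (jt == "DUP") {
        affected <- if (st[1] == 2L) "W" else "Y"
        type <- if (tl != tr) "T-DUP"
                else if (tl && tr) "TRISOMY" else "UNCLASSIFIED"
      } else {
        affected <- NA_character_
        type <- "UNCLASSIFIED"
      }
      rows[[length(rows) + 1L]] <- event_row(
        cc, type, affected, NA, NA, i, j, j - i + 1L, pos, L, tl, tr)
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else empty_events()
  rownames(ev) <- NULL
  ev <- absorb_conversion_tracts(ev, b5_gap)
  ev$event_id <- sprintf("call%d", seq_len(nrow(ev)))
  ev$class <- vapply(seq_len(nrow(ev)), function(k)
    classify_event(ev[k, ], genome, class_map), character(1))
  ev[, c("event_id", "chrom", "type", "class", "homolog", "start", "end",
         "start_snp", "end_snp", "n_snps", "conv_assoc",
         "bp_left_lo", "bp_left_hi", "bp_right_lo", "bp_right_hi")]
}

# re-place each boundary between adjacent joint-state runs at the cut that
# minimizes the raw squared misfit of both homolog tracks to their run
# levels, searching +/- window SNPs around the smoothed-fit cut
refine_boundaries <- function(key, rc_raw, window = 4L) {
  r <- rle(key)
  if (length(r$lengths) < 2) return(key)
  lev <- c(0, 0.5, 1, 1.5)
  level_of <- function(k) {
    st <- as.integer(strsplit(k, " ")[[1]])
    c(lev[st[1] + 1L], lev[st[2] + 1L])
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  cuts <- ends[-length(ends)]        # boundary after site `cut`
  for (b in seq_along(cuts)) {
    la <- level_of(r$values[b]); lb <- level_of(r$values[b + 1L])
    lo <- max(starts[b], cuts[b] - window + 1L)
    hi <- min(ends[b + 1L] - 1L, cuts[b] + window)
    if (b > 1L) lo <- max(lo, cuts[b - 1L] + 1L)
    cand <- lo:hi
    miss <- vapply(cand, function(cut) {
      ia <- lo:cut
      ib <- if (cut < hi) (cut + 1L):hi else integer(0)
      sum((rc_raw$W[ia] - la[1])^2) + sum((rc_raw$Y[ia] - la[2])^2) +
        sum((rc_raw$W[ib] - lb[1])^2) + sum((rc_raw$Y[ib] - lb[2])^2)
    }, 0)
    cuts[b] <- cand[which.min(miss)]
  }
  # rebuild the per-site keys from the refined cuts
  bounds <- c(0L, cuts, length(key))
  unlist(lapply(seq_along(r$values), function(k)
    rep(r$values[k], bounds[k + 1L] - bounds[k])))
}

whole_chrom_type <- function(w, y) {
  key <- paste(w, y)
  switch(key,
         "0 2" = list(type = "UPD", homolog = "W"),
         "2 0" = list(type = "UPD", homolog = "Y"),
         "0 1" = list(type = "MONOSOMY", homolog = "W"),
         "1 0" = list(type = "MONOSOMY", homolog = "Y"),
         "2 1" = list(type = "TRISOMY", homolog = "W"),
         "1 2" = list(type = "TRISOMY", homolog = "Y"),
         list(type = "UNCLASSIFIED", homolog = NA_character_))
}

event_row <- function(chrom, type, homolog, start, end, i, j, n_snps,
                      pos, L, touches_left, touches_right) {
  if (is.na(start)) start <- if (touches_left) 1 else pos[i]
  if (is.na(end)) end <- if (touches_right) L else pos[j]
  bl <- if (touches_left) c(1, pos[i]) else c(pos[i - 1L], pos[i])
  br <- if (touches_right) c(pos[j], L) else c(pos[j], pos[j + 1L])
  data.frame(chrom = chrom, type = type, homolog = homolog,
             start = start, end = end, start_snp = i, end_snp = j,
             n_snps = n_snps, conv_assoc = FALSE,
             bp_left_lo = bl[1], bp_left_hi = bl[2],
             bp_right_lo = br[1], bp_right_hi = br[2],
             stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(chrom = character(), type = character(), homolog = character(),
             start = numeric(), end = numeric(), start_snp = integer(),
             end_snp = integer(), n_snps = integer(), conv_assoc = logical(),
             bp_left_lo = numeric(), bp_left_hi = numeric(),
             bp_right_lo = numeric(), bp_right_hi = numeric(),
             stringsAsFactors = FALSE)
}

# flag conversion-associated T-LOH (class B5): an I-LOH with the same
# affected homolog within b5_gap SNPs of a T-LOH breakpoint is absorbed
absorb_conversion_tracts <- function(ev, b5_gap) {
  if (!nrow(ev)) return(ev)
  drop <- logical(nrow(ev))
  for (t in which(ev$type == "T-LOH")) {
    for (i in which(ev$type == "I-LOH" & !drop)) {
      if (ev$chrom[i] != ev$chrom[t] || ev$homolog[i] != ev$homolog[t]) next
      gap <- if (ev$start_snp[t] > ev$end_snp[i])
               ev$start_snp[t] - ev$end_snp[i] - 1L
             else ev$start_snp[i] - ev$end_snp[t] - 1L
      if (gap >= 0L && gap <= b5_gap) {
        ev$conv_assoc[t] <- TRUE
        drop[i] <- TRUE
      }
    }
  }
  ev[!drop, , drop = FALSE]
}

expand_states <- function(segments, chrom, homolog, n) {
  s <- segments[segments$chrom == chrom & segments$homolog == homolog, ,
                drop = FALSE]
  if (!nrow(s)) return(rep(1L, n))
  st <- integer(n)
  for (k in seq_len(nrow(s))) st[s$start_snp[k]:s$end_snp[k]] <- s$state[k]
  st
}

#' Assign the taxonomy class code of a typed event
#'
#' Class codes: A1/A2 = I-LOH with the W/Y homolog lost (Y/W retained);
#' B1/B2 = simple T-LOH on the right chromosome arm retaining Y/W;
#' B3/B4 = the same on the left arm (arm taken relative to the centromere,
#' by which telomere the tract abuts); B5 = conversion-associated T-LOH;
#' C1/C2 = terminal deletion of W/Y; C3/C4 = terminal duplication of W/Y;
#' D1/D2 = trisomy via an extra W/Y copy; D3 = monosomy; D4 = UPD. The
#' arm-based B1–B4 split is an interpretation and can be remapped through
#' `class_map`.
#'
#' @param event one event-call row (as produced by [call_events()]).
#' @param genome a [genome_map()] (for the centromere/arm lookup).
#' @param class_map optional named character vector remapping internal keys
#'   (e.g. `c("T-LOH.right.W" = "B1")`) to custom codes.
#' @return a class code string ("UNCLASSIFIED" passes through).
#' @export
classify_event <- function(event, genome, class_map = NULL) {
  defaults <- c("I-LOH.W" = "A1", "I-LOH.Y" = "A2",
                "T-LOH.right.W" = "B1", "T-LOH.right.Y" = "B2",
                "T-LOH.left.W" = "B3", "T-LOH.left.Y" = "B4",
                "T-LOH.conv" = "B5",
                "T-DEL.W" = "C1", "T-DEL.Y" = "C2",
                "T-DUP.W" = "C3", "T-DUP.Y" = "C4",
                "TRISOMY.W" = "D1", "TRISOMY.Y" = "D2",
                "MONOSOMY" = "D3", "UPD" = "D4")
  if (!is.null(class_map)) defaults[names(class_map)] <- class_map
  ty <- event$type
  if (ty == "UNCLASSIFIED") return("UNCLASSIFIED")
  key <- switch(ty,
    "I-LOH" = paste0("I-LOH.", event$homolog),
    "T-LOH" = {
      if (isTRUE(event$conv_assoc)) "T-LOH.conv"
      else {
        L <- chrom_length(genome, event$chrom)
        side <- if (event$end >= L) "right" else "left"
        paste0("T-LOH.", side, ".", event$homolog)
      }
    },
    "T-DEL" = paste0("T-DEL.", event$homolog),
    "T-DUP" = paste0("T-DUP.", event$homolog),
    "TRISOMY" = paste0("TRISOMY.", event$homolog),
    "MONOSOMY" = "MONOSOMY",
    "UPD" = "UPD")
  unname(defaults[key])
}

#' Resolve the breakpoint interval of a state transition
#'
#' The breakpoint of an event is localized between the last SNP in the old
#' state and the first SNP in the new state; the interval's midpoint is
#' their arithmetic mean. At a chromosome end the interval is clamped to
#' the chromosome start or end.
#'
#' @param event one event-call row.
#' @param profile the `rc_profile` the event was called from (supplies SNP
#'   positions).
#' @param side which transition, "left" (event start) or "right" (event
#'   end).
#' @return list with `lo`, `hi` (bp of the two bracketing sites) and
#'   `midpoint`.
#' @export
resolve_breakpoint <- function(event, profile, side = c("left", "right")) {
  side <- match.arg(side)
  pos <- profile$pos[profile$chrom == event$chrom]
  n <- length(pos)
  i <- event$start_snp; j <- event$end_snp
  if (side == "left") {
    lo <- if (i <= 1L) 1 else pos[i - 1L]
    hi <- pos[i]
  } else {
    lo <- pos[j]
    hi <- if (j >= n) max(event$end, pos[n]) else pos[j + 1L]
  }
  list(lo = lo, hi = hi, midpoint = (lo + hi) / 2)
}

#' Pair terminal copy-number changes into translocation hypotheses
#'
#' Paired terminal duplications (or the retained complements of paired
#' terminal deletions) on two different chromosomes are interpreted as a
#' translocation joining a centromere-containing fragment to an acentric
#' fragment, forming a monocentric recombined chromosome. A hypothesis is
#' emitted only when exactly one fragment of a pair carries its centromere;
#' its predicted size is the sum of the two fragment lengths. When several
#' pairings are possible the one minimizing the total unexplained fragment
#' length is chosen (ties broken by chromosome order). Terminal CNVs left
#' unpaired are reported as unresolved.
#'
#' @param events event-call table of one isolate (uses T-DUP and T-DEL
#'   rows).
#' @param genome a [genome_map()].
#' @return list with `hypotheses` (data.frame: centric/acentric fragment
#'   coordinates, `predicted_size`, `kind` dup|del, supporting event ids)
#'   and `unresolved` (unpaired fragments).
#' @export
pair_translocations <- function(events, genome) {
  stopifnot(inherits(genome, "genome_map"))
  frags <- translocation_fragments(events, genome)
  hyp <- list(); unres <- list()
  for (kind in c("dup", "del")) {
    f <- frags[frags$kind == kind, , drop = FALSE]
    if (!nrow(f)) next
    m <- best_matching(f)
    for (p in m$pairs) {
      a <- f[p[1], ]; b <- f[p[2], ]
      centric <- if (a$has_centromere) a else b
      acentric <- if (a$has_centromere) b else a
      hyp[[length(hyp) + 1L]] <- data.frame(
        kind = kind,
        centric_chrom = centric$chrom, centric_start = centric$start,
        centric_end = centric$end,
        acentric_chrom = acentric$chrom, acentric_start = acentric$start,
        acentric_end = acentric$end,
        predicted_size = centric$len + acentric$len,
        events = paste(sort(c(a$event_id, b$event_id)), collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (length(m$unmatched))
      unres[[length(unres) + 1L]] <- cbind(f[m$unmatched, , drop = FALSE],
                                           reason = "no admissible partner")
  }
  list(hypotheses = if (length(hyp)) do.call(rbind, hyp) else
         data.frame(kind = character(), centric_chrom = character(),
                    centric_start = numeric(), centric_end = numeric(),
                    acentric_chrom = character(), acentric_start = numeric(),
                    acentric_end = numeric(), predicted_size = numeric(),
                    events = character(), stringsAsFactors = FALSE),
       unresolved = if (length(unres)) do.call(rbind, unres) else NULL)
}

# duplicated intervals of T-DUPs; retained complements of T-DELs
translocation_fragments <- function(events, genome) {
  out <- list()
  for (k in seq_len(nrow(events))) {
    e <- events[k, ]
    if (!e$type %in% c("T-DUP", "T-DEL")) next
    L <- chrom_length(genome, e$chrom)
    if (e$type == "T-DUP") {
      s <- e$start; en <- e$end; kind <- "dup"
    } else {
      # retained complement of a terminal deletion
      if (e$start <= 1) { s <- e$end + 1; en <- L } else { s <- 1; en <- e$start - 1 }
      kind <- "del"
    }
    out[[length(out) + 1L]] <- data.frame(
      event_id = e$event_id, kind = kind, chrom = e$chrom,
      start = s, end = en, len = en - s + 1,
      has_centromere = contains_centromere(genome, e$chrom, s, en),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(event_id = character(), kind = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      len = numeric(), has_centromere = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# exhaustive matching over admissible pairs (different chromosome, exactly
# one centric), minimizing total unexplained fragment length; deterministic
# tie-break by pair order (chromosome index)
best_matching <- function(f) {
  n <- nrow(f)
  idx <- seq_len(n)
  admissible <- function(a, b)
    f$chrom[a] != f$chrom[b] && xor(f$has_centromere[a], f$has_centromere[b])
  best <- list(pairs = list(), unexplained = sum(f$len))
  recurse <- function(remaining, pairs, explained) {
    un <- sum(f$len) - explained
    if (un < best$unexplained) best <<- list(pairs = pairs, unexplained = un)
    if (length(remaining) < 2) return()
    a <- remaining[1]
    # branch: leave a unmatched
    recurse(remaining[-1], pairs, explained)
    for (b in remaining[-1]) {
      if (admissible(a, b))
        recurse(setdiff(remaining, c(a, b)), c(pairs, list(c(a, b))),
                explained + f$len[a] + f$len[b])
    }
  }
  if (n <= 10) recurse(idx, list(), 0)
  else {
    # greedy fallback for unusually large fragment sets
    remaining <- idx; pairs <- list()
    for (a in idx) {
      if (!a %in% remaining) next
      cands <- remaining[remaining != a]
      cands <- cands[vapply(cands, function(b) admissible(a, b), TRUE)]
      if (length(cands)) {
        b <- cands[which.max(f$len[cands])]
        pairs <- c(pairs, list(c(a, b)))
        remaining <- setdiff(remaining, c(a, b))
      }
    }
    best <- list(pairs = pairs,
                 unexplained = sum(f$len) -
                   sum(vapply(pairs, function(p) sum(f$len[p]), 0)))
  }
  matched <- unlist(best$pairs)
  list(pairs = best$pairs, unmatched = setdiff(idx, matched))
}
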