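# Amplicon calling from a paired tumor/normal probe track: germline masking,
# running-median smoothing, recursive binary segmentation and thresholding at
# 4.8 arbitrary units (>7 copies), with arm/band/gene annotation.

#' Caller configuration
#'
#' `theta` (4.8 arbitrary units, >7 DNA copies) is the published
#' amplification threshold; it deliberately excludes broad polyploid gains
#' (a tetraploid segment sits near 3.5 units). The remaining knobs are
#' caller policy: `window` probes of running-median smoothing, `min_probes`
#' per segment/amplicon, `merge_gap` bp between retained segments that are
#' merged (never across a centromere), `germline_delta` units of deviation
#' from diploid in the matched normal that masks a probe, and
#' `whole_chrom_frac` of a chromosome above which an amplicon is flagged as
#' a whole-chromosome suspect. `split_crit` is the fixed two-sample
#' t-statistic threshold accepting a segmentation split (fixed, not
#' permutation-based, for determinism).
#'
#' @param theta amplification threshold in arbitrary units (> 2).
#' @param window running-median window (odd number of probes).
#' @param min_probes minimum probes per segment and per amplicon (>= 1).
#' @param merge_gap maximum gap (bp) between merged amplicons.
#' @param germline_delta normal-track deviation masking a probe.
#' @param whole_chrom_frac chromosome fraction flagging a suspect.
#' @param split_crit t-statistic critical value for accepting a split.
#' @return a `caller_config` list.
#' @export
caller_config <- function(theta = 4.8, window = 5, min_probes = 5,
                          merge_gap = 1e6, germline_delta = 0.6,
                          whole_chrom_frac = 0.9, split_crit = 5) {
  stopifnot(theta > 2, window >= 1, window %% 2 == 1, min_probes >= 1,
            merge_gap >= 0, germline_delta > 0, whole_chrom_frac > 0,
            split_crit > 0)
  structure(list(theta = theta, window = as.integer(window),
                 min_probes = as.integer(min_probes), merge_gap = merge_gap,
                 germline_delta = germline_delta,
                 whole_chrom_frac = whole_chrom_frac,
                 split_crit = split_crit),
            class = "caller_config")
}

.check_track <- function(track) {
  stopifnot(is.data.frame(track), all(c("chrom", "pos", "value") %in%
                                        names(track)))
  if (any(!is.finite(track$value)) || any(track$value < 0))
    stop("probe track values must be finite and >= 0")
  dt <- as.data.table(track)
  bad <- dt[, any(diff(pos) <= 0), by = chrom][V1 == TRUE]
  if (nrow(bad))
    stop("probe positions must be strictly increasing within chromosome ",
         bad$chrom[1])
  dt
}

#' Mask germline copy-number variation using the matched normal
#'
#' Probes whose matched-normal value deviates from diploid by more than
#' `delta` are removed from the tumor track, so germline CNVs (and their
#' boundaries) can never surface as somatic amplicons. Both tracks must
#' share an identical probe grid.
#'
#' @param tumor,normal probe tracks (data.frame: chrom, pos, value) on the
#'   same grid.
#' @param delta masking threshold in arbitrary units.
#' @return the masked tumor track, with attributes `n_masked` and `n_total`.
#' @export
germline_mask <- function(tumor, normal, delta = 0.6) {
  tumor <- .check_track(tumor); normal <- .check_track(normal)
  if (nrow(tumor) != nrow(normal) ||
      !all(tumor$chrom == normal$chrom) || !all(tumor$pos == normal$pos)) {
    i <- if (nrow(tumor) != nrow(normal)) min(nrow(tumor), nrow(normal)) + 1L
    else which(tumor$chrom != normal$chrom | tumor$pos != normal$pos)[1]
    stop("tumor/normal probe grids differ at probe ", i,
         " (tumor ", tumor$chrom[min(i, nrow(tumor))], ":",
         tumor$pos[min(i, nrow(tumor))], ")")
  }
  keep <- abs(normal$value - 2) <= delta
  out <- tumor[keep]
  message(sum(!keep), " of ", length(keep),
          " probes masked as germline deviation (delta=", delta, ")")
  setattr(out, "n_masked", sum(!keep))
  setattr(out, "n_total", length(keep))
  out[]
}

#' Running-median smoothing
#'
#' Per-chromosome running median of window `w` probes; edges use shrinking
#' windows (window truncation). `w = 1` is the identity and constant tracks
#' are unchanged.
#'
#' @param track probe track.
#' @param w odd window size in probes.
#' @return track with smoothed values.
#' @export
smooth_track <- function(track, w = 5) {
  stopifnot(w >= 1, w %% 2 == 1)
  dt <- copy(.check_track(track))
  if (w == 1) return(dt)
  dt[, value := {
    if (.N < w) as.numeric(stats::runmed(value, max(1, min(w, .N - (1 - .N %% 2))),
                                         endrule = "median"))
    else as.numeric(stats::runmed(value, w, endrule = "median"))
  }, by = chrom]
  dt[]
}

# Best split of x by the between-segment mean-difference t statistic.
# The scale is a robust per-chromosome noise estimate (MAD of successive
# differences), not the pooled within-split variance: a short high-level
# amplicon inside a long diploid segment inflates the pooled variance and
# masks its own change-points, while the successive-difference MAD is
# insensitive to level shifts. With a fixed scale the maximizing split is
# exactly the split minimizing the within-segment sum of squares.
# O(n) with prefix sums; ties broken leftmost.
.best_split <- function(x, min_probes, sigma) {
  n <- length(x)
  if (n < 2 * min_probes) return(NULL)
  cs <- cumsum(x)
  k <- seq(min_probes, n - min_probes)          # left part is x[1..k]
  nl <- k; nr <- n - k
  ml <- cs[k] / nl; mr <- (cs[n] - cs[k]) / nr
  gap <- abs(mr - ml)
  # maximize the between-segment sum of squares (the split minimizing the
  # within-segment SSE); the t statistic only gates acceptance
  bss <- gap^2 / (1 / nl + 1 / nr)
  i <- which.max(bss)                           # leftmost maximum
  tt <- if (sigma > 1e-12) sqrt(bss[i]) / sigma
  else if (gap[i] > 1e-9) Inf else 0
  list(k = k[i], t = tt)
}

.segment_chrom <- function(values, min_probes, crit) {
  # robust noise scale, shared by all recursion levels of this chromosome
  sigma <- stats::mad(diff(values)) / sqrt(2)
  # returns integer vector of segment end indices (cumulative)
  rec <- function(lo, hi) {
    sp <- .best_split(values[lo:hi], min_probes, sigma)
    if (is.null(sp) || sp$t <= crit) return(hi)
    cut <- lo + sp$k - 1L
    c(rec(lo, cut), rec(cut + 1L, hi))
  }
  rec(1L, length(values))
}

#' Segment a smoothed probe track
#'
#' Recursive binary segmentation per chromosome: each candidate change-point
#' is scored with the t statistic between the flanking means, scaled by a
#' robust per-chromosome noise estimate (MAD of successive differences,
#' insensitive to the level shifts being sought); the best split is accepted
#' when both sides hold at least `min_probes` probes and the statistic
#' exceeds `crit`. With the fixed scale the chosen split is exactly the one
#' minimizing the within-segment sum of squares. Ties go to the leftmost
#' split; a noiseless track splits wherever means genuinely differ. Segment
#' means are the plain means of member probe values and the segments
#' partition every probe exactly once.
#'
#' @param track smoothed probe track.
#' @param min_probes minimum probes per segment.
#' @param crit fixed critical value for the split statistic.
#' @return data.table of segments: chrom, start, end (0-based half-open over
#'   member probe positions), num_probes, seg_mean.
#' @export
segment_track <- function(track, min_probes = 5, crit = 5) {
  dt <- .check_track(track)
  dt[, {
    ends <- .segment_chrom(value, min_probes, crit)
    starts <- c(1L, head(ends, -1L) + 1L)
    .(start = pos[starts], end = pos[ends] + 1,
      num_probes = ends - starts + 1L,
      seg_mean = vapply(seq_along(ends), function(i)
        mean(value[starts[i]:ends[i]]), 0))
  }, by = chrom]
}

#' Call amplicons from segments
#'
#' Retains segments with mean above `theta` and at least `min_probes`
#' probes; merges retained neighbours on the same chromosome arm closer
#' than `merge_gap` bp (probe-weighted mean; never across the centromere);
#' annotates each amplicon with its cytobands, genes and arm(s); and flags
#' amplicons spanning more than `whole_chrom_frac` of their chromosome as
#' whole-chromosome suspects (still reported).
#'
#' @param segments segment table from [segment_track()].
#' @param config a [caller_config()].
#' @param annotation list with `map` and (optionally) `genes`; when `genes`
#'   is `NULL` the gene column is left empty.
#' @return data.table of amplicons: chrom, start, end, num_probes, seg_mean,
#'   arm, bands, genes (comma-separated), whole_chrom_suspect.
#' @export
call_amplicons <- function(segments, config = caller_config(),
                           annotation = default_annotation()) {
  map <- annotation$map; genes <- annotation$genes
  empty <- data.table(chrom = character(), start = numeric(),
                      end = numeric(), num_probes = integer(),
                      seg_mean = numeric(), arm = character(),
                      bands = character(), genes = character(),
                      whole_chrom_suspect = logical())
  if (is.null(segments) || !nrow(segments)) return(empty)
  hits <- as.data.table(segments)[seg_mean > config$theta &
                                    num_probes >= config$min_probes]
  if (!nrow(hits)) return(empty)
  hits[, arm := vapply(seq_len(.N), function(i)
    paste(arm_of(chrom[i], start[i], end[i], map), collapse = ","), "")]
  setorder(hits, chrom, start)
  # merge neighbours on the same arm closer than merge_gap
  merged <- list(); cur <- NULL
  for (i in seq_len(nrow(hits))) {
    row <- hits[i]
    if (!is.null(cur) && row$chrom == cur$chrom && row$arm == cur$arm &&
        row$start - cur$end < config$merge_gap) {
      w <- cur$num_probes + row$num_probes
      cur$seg_mean <- (cur$seg_mean * cur$num_probes +
                         row$seg_mean * row$num_probes) / w
      cur$num_probes <- w
      cur$end <- row$end
    } else {
      if (!is.null(cur)) merged[[length(merged) + 1L]] <- cur
      cur <- row
    }
  }
  merged[[length(merged) + 1L]] <- cur
  amp <- rbindlist(merged)
  amp[, arm := vapply(seq_len(.N), function(i)
    paste(arm_of(chrom[i], start[i], end[i], map), collapse = ","), "")]
  amp[, bands := vapply(seq_len(.N), function(i)
    paste(bands_overlapping(chrom[i], start[i], end[i], map),
          collapse = ","), "")]
  amp[, genes := if (is.null(genes)) "" else vapply(seq_len(.N), function(i)
    paste(genes_overlapping(chrom[i], start[i], end[i], genes),
          collapse = ","), "")]
  chrom_len <- map$chroms$length[match(amp$chrom, map$chroms$chrom)]
  amp[, whole_chrom_suspect := (end - start) >
        config$whole_chrom_frac * chrom_len]
  amp[]
}

#' Full caller pipeline for one paired sample
#'
#' Germline masking, smoothing, segmentation and amplicon calling in one
#' call.
#'
#' @param tumor,normal probe tracks on the same grid.
#' @param config a [caller_config()].
#' @param annotation list with `map` and `genes`.
#' @return list with `amplicons`, `segments` and the masked track.
#' @export
call_sample <- function(tumor, normal, config = caller_config(),
                        annotation = default_annotation()) {
  masked <- suppressMessages(germline_mask(tumor, normal,
                                           config$germline_delta))
  sm <- smooth_track(masked, config$window)
  seg <- segment_track(sm, config$min_probes, config$split_crit)
  amp <- call_amplicons(seg, config, annotation)
  list(amplicons = amp, segments = seg, masked = masked)
}

#' Write/read SEG-dialect segment files
#'
#' Tab-separated `sample, chrom, loc.start, loc.end, num.mark, seg.mean`
#' preceded by a header comment declaring that `seg.mean` is in arbitrary
#' copy-number units (diploid = 2), *not* a log2 ratio. Coordinates are
#' presented 1-based inclusive in the file and converted back to the
#' package's 0-based half-open convention on read.
#'
#' @param segments segment or amplicon table (chrom, start, end,
#'   num_probes, seg_mean).
#' @param sample sample identifier written in the first column.
#' @param path file path.
#' @return `write_seg` returns the path; `read_seg` a data.table with
#'   columns sample_id, chrom, start, end, num_probes, seg_mean.
#' @export
write_seg <- function(segments, sample, path) {
  hdr <- "#seg.mean: arbitrary copy-number units, diploid=2 (not log2 ratio)"
  dt <- as.data.table(segments)[, .(sample = sample, chrom = paste0("chr", chrom),
                                    loc.start = as.integer(start) + 1L,
                                    loc.end = as.integer(end),
                                    num.mark = num_probes,
                                    seg.mean = seg_mean)]
  con <- file(path, "w")
  writeLines(c(hdr, paste(names(dt), collapse = "\t")), con)
  close(con)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  dt <- fread(path, skip = 1, header = TRUE, sep = "\t")
  setnames(dt, c("sample_id", "chrom", "start", "end", "num_probes",
                 "seg_mean"))
  dt[, chrom := normalize_chrom(chrom)]
  dt[, start := as.numeric(start) - 1]
  dt[, end := as.numeric(end)]
  dt[]
}

#' Write/read the probe TSV interchange format
#'
#' Tab-separated `sample, chrom, pos, value` with header.
#'
#' @param track probe track; `sample` id added on write.
#' @param sample sample identifier.
#' @param path file path.
#' @export
write_probe_tsv <- function(track, sample, path) {
  dt <- as.data.table(track)[, .(sample = sample, chrom, pos, value)]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_probe_tsv
#' @export
read_probe_tsv <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  stopifnot(all(c("sample", "chrom", "pos", "value") %in% names(dt)))
  dt[, chrom := normalize_chrom(chrom)]
  dt[]
}
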