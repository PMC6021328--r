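# Paired tumor/normal copy-number simulator with class-dependent survival.
# The generator states the world the caller and classifier are tested in:
# focal high-level amplicons planted at named cytobands, broad 3-4 copy
# polyploid gains that must NOT be called, germline CNVs shared by both
# tracks, additive Gaussian probe noise on the value scale, and exponential
# overall survival with class-specific medians.

.gap_levels <- c("NO_AMP", "EGFR_ONLY", "NON_EGFR_SINGLE",
                 "MULTI_WITH_EGFR", "MULTI_WITHOUT_EGFR")

#' The five GAP class labels
#' @return character vector of the five class labels, in canonical order.
#' @export
gap_classes <- function() .gap_levels

#' Simulator configuration
#'
#' Defaults encode the stated world: 50 kb probe spacing (~60k probes
#' genome-wide), additive Gaussian noise sd 0.4 on the value scale,
#' saturation exponent alpha = log(2.8)/log(5) so that 7 copies map to
#' exactly 4.8 arbitrary units, about two germline CNVs per genome,
#' class medians 13/17/6/13/8 months and administrative censoring at a
#' uniform 18-84 month follow-up horizon.
#'
#' @param probe_spacing probe grid spacing in bp.
#' @param noise_sd additive Gaussian noise sd (value scale), >= 0.
#' @param alpha saturation exponent of the copies-to-value transform, in
#'   (0, 1].
#' @param germline_rate expected number of germline CNVs per genome.
#' @param germline_len_mean mean germline CNV length (bp, exponential).
#' @param event_copies true copy number planted for focal amplicons.
#' @param event_length planted amplicon length (bp).
#' @param polyploid_prob probability of a whole-chromosome 3-4 copy gain.
#' @param surv_medians named per-class median OS in months.
#' @param followup_range administrative censoring horizon (months),
#'   `c(lo, hi)` for uniform draws; use `c(Inf, Inf)` to observe all events.
#' @param class_proportions named class frequencies, summing to 1.
#' @param seed integer RNG seed recorded in all outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(probe_spacing = 5e4,
                       noise_sd = 0.4,
                       alpha = log(2.8) / log(5),
                       germline_rate = 2,
                       germline_len_mean = 2e5,
                       event_copies = 12,
                       event_length = 1.5e6,
                       polyploid_prob = 0.3,
                       surv_medians = c(NO_AMP = 13, EGFR_ONLY = 17,
                                        NON_EGFR_SINGLE = 6,
                                        MULTI_WITH_EGFR = 13,
                                        MULTI_WITHOUT_EGFR = 8),
                       followup_range = c(18, 84),
                       class_proportions = c(NO_AMP = 0.44, EGFR_ONLY = 0.21,
                                             NON_EGFR_SINGLE = 0.13,
                                             MULTI_WITH_EGFR = 0.16,
                                             MULTI_WITHOUT_EGFR = 0.06),
                       seed = 1L) {
  stopifnot(noise_sd >= 0, alpha > 0, alpha <= 1,
            all(surv_medians > 0), probe_spacing >= 1e3,
            all(.gap_levels %in% names(surv_medians)),
            all(.gap_levels %in% names(class_proportions)))
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1")
  structure(list(probe_spacing = probe_spacing, noise_sd = noise_sd,
                 alpha = alpha, germline_rate = germline_rate,
                 germline_len_mean = germline_len_mean,
                 event_copies = event_copies, event_length = event_length,
                 polyploid_prob = polyploid_prob,
                 surv_medians = surv_medians[.gap_levels],
                 followup_range = followup_range,
                 class_proportions = class_proportions[.gap_levels],
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Copies-to-value transform
#'
#' Maps true DNA copy number to dChip-like arbitrary units: `v(c) = 2 +
#' (c - 2)^alpha` for `c >= 2` (saturating), linear below 2, with `v(2) = 2`
#' exactly. The default `alpha = log(2.8)/log(5)` makes `v(7) = 4.8`, the
#' amplification threshold, so ">7 copies" and ">4.8 units" coincide; a
#' tetraploid gain maps to about 3.54 units and stays below threshold.
#'
#' @param c true copy number, >= 0 (vectorized).
#' @param alpha saturation exponent in (0, 1].
#' @return value in arbitrary units.
#' @export
copies_to_value <- function(c, alpha = log(2.8) / log(5)) {
  if (any(c < 0)) stop("copy number must be >= 0")
  ifelse(c >= 2, 2 + (c - 2)^alpha, c)
}

# uniform probe grid over all chromosomes of the map
.probe_grid <- function(map, spacing) {
  grids <- map$chroms[, .(pos = seq(round(spacing / 2), length - 1,
                                    by = spacing)), by = chrom]
  setkey(grids, chrom, pos)
  grids
}

# default per-class somatic event menus; bands must exist in the annotation
.class_menu <- function(class, config, map, genes) {
  band_iv <- function(lbl) {
    ch <- sub("^([0-9XY]+)([pq].*)$", "\\1", lbl)
    bd <- sub("^([0-9XY]+)([pq].*)$", "\\2", lbl)
    hit <- map$bands[chrom == ch & band == bd]
    if (!nrow(hit)) stop("event band absent from annotation: ", lbl)
    list(chrom = ch, start = hit$start[1], end = hit$end[1], band = lbl)
  }
  center_event <- function(lbl, copies, len) {
    iv <- band_iv(lbl)
    mid <- (iv$start + iv$end) / 2
    s <- max(iv$start, round(mid - len / 2))
    data.table(band = lbl, chrom = iv$chrom, start = s, end = s + len,
               copies = copies)
  }
  egfr_event <- function() {
    # amplicon covering the EGFR locus inside 7p11.2
    eg <- genes[gene == "EGFR"]
    if (!nrow(eg)) stop("event band absent from annotation: 7p11.2/EGFR")
    pad <- max(0, (config$event_length - (eg$end - eg$start)) / 2)
    data.table(band = "7p11.2", chrom = "7",
               start = round(eg$start - pad), end = round(eg$end + pad),
               copies = config$event_copies)
  }
  k <- config$event_copies; len <- config$event_length
  non_egfr_pool <- c("4q12", "12q14.1", "1q32.1")
  switch(class,
    NO_AMP = data.table(),
    EGFR_ONLY = egfr_event(),
    NON_EGFR_SINGLE = center_event(sample(non_egfr_pool, 1), k - 2, len),
    MULTI_WITH_EGFR = rbind(
      egfr_event(),
      center_event(sample(c(non_egfr_pool, "12q15"), 1), k - 2, len)),
    MULTI_WITHOUT_EGFR = {
      pool <- c("4q12", "12q14.1", "1q32.1", "11p13")
      picks <- sample(pool, 2)
      # distinct arms guaranteed: pool bands sit on 4 different arms
      rbind(center_event(picks[1], k - 2, len),
            center_event(picks[2], k, len))
    },
    stop("unknown GAP class: ", class))
}

#' Simulate a paired tumor/normal patient
#'
#' The normal track is diploid baseline plus germline CNVs plus noise; the
#' tumor track shares the germline baseline and adds the class-specific
#' somatic events (and, with probability `polyploid_prob`, a broad 3-4 copy
#' whole-chromosome gain that must not be called as amplification).
#' Germline CNVs are re-drawn if they would overlap a planted somatic event,
#' so the recorded truth table is unambiguous.
#'
#' @param config a [sim_config()].
#' @param class one of [gap_classes()].
#' @param seed integer seed; same seed and config give a bit-identical
#'   patient.
#' @param annotation list with `map` and `genes` (default packaged).
#' @param id sample identifier.
#' @return a `sim_patient`: list with `id`, `class`, `events` (truth table
#'   of planted intervals incl. germline ones), `tumor` and `normal` probe
#'   tracks (data.table chrom/pos/value) and a `clinical` one-row data.table.
#' @export
simulate_pair <- function(config, class, seed,
                          annotation = default_annotation(),
                          id = "S1") {
  stopifnot(inherits(config, "sim_config"), class %in% .gap_levels)
  map <- annotation$map; genes <- annotation$genes
  set.seed(as.integer(seed))
  grid <- .probe_grid(map, config$probe_spacing)
  somatic <- .class_menu(class, config, map, genes)
  if (nrow(somatic)) somatic[, somatic := TRUE]

  # broad polyploid gain (tumor only); always present for NO_AMP patients in
  # half the cases so the "polyploidy without amplification" situation occurs
  poly <- data.table()
  if (runif(1) < config$polyploid_prob) {
    ch <- sample(map$chroms$chrom, 1)
    poly <- data.table(band = paste0(ch, "_whole"), chrom = ch, start = 0,
                       end = map$chroms[chrom == ch]$length,
                       copies = sample(3:4, 1), somatic = TRUE)
  }

  # germline CNVs, identical in both tracks, never overlapping somatic events
  n_g <- rpois(1, config$germline_rate)
  germ <- NULL
  if (n_g > 0) {
    lens <- map$chroms$length
    for (i in seq_len(n_g)) {
      for (try in 1:50) {
        ch <- sample(map$chroms$chrom, 1, prob = lens / sum(lens))
        L <- max(3 * config$probe_spacing, round(rexp(1, 1 / config$germline_len_mean)))
        s <- round(runif(1, 0, map$chroms[chrom == ch]$length - L))
        clash <- nrow(somatic) && somatic[chrom == ch & start < s + L & end > s, .N] > 0
        if (!clash) break
      }
      germ <- rbind(germ, data.table(band = paste0(ch, "_germline"),
                                     chrom = ch, start = s, end = s + L,
                                     copies = sample(c(1, 3), 1),
                                     somatic = FALSE))
    }
  }

  paint <- function(base_copies, events) {
    cp <- base_copies
    if (!is.null(events) && nrow(events)) {
      for (i in seq_len(nrow(events))) {
        idx <- grid$chrom == events$chrom[i] & grid$pos >= events$start[i] &
          grid$pos < events$end[i]
        cp[idx] <- events$copies[i]
      }
    }
    cp
  }
  germ_copies <- paint(rep(2, nrow(grid)), germ)
  tumor_copies <- germ_copies
  if (nrow(poly)) tumor_copies <- paint(tumor_copies, poly)
  if (nrow(somatic)) tumor_copies <- paint(tumor_copies, somatic)

  noisy <- function(cp) pmax(0, copies_to_value(cp, config$alpha) +
                                  rnorm(length(cp), 0, config$noise_sd))
  normal <- data.table(chrom = grid$chrom, pos = grid$pos,
                       value = noisy(germ_copies))
  tumor <- data.table(chrom = grid$chrom, pos = grid$pos,
                      value = noisy(tumor_copies))

  surv <- simulate_survival(class, config)
  clinical <- data.table(
    id = id, age = round(pmin(90, pmax(20, rnorm(1, 62, 13)))),
    sex = sample(c("M", "F"), 1),
    karnofsky = sample(seq(40, 100, 10), 1),
    os_months = surv$os_months, event = surv$event,
    surgery = sample(c("T", "P", "B"), 1, prob = c(.32, .54, .14)),
    chemotherapy = sample(c("Stupp", "Sequential", "-"), 1,
                          prob = c(.55, .15, .3)))

  events <- rbind(if (nrow(somatic)) somatic, poly, germ, fill = TRUE)
  structure(list(id = id, class = class, events = events,
                 tumor = tumor, normal = normal, clinical = clinical,
                 seed = as.integer(seed)),
            class = "sim_patient")
}

#' Simulate overall survival for one patient
#'
#' OS is exponential with the class-specific median (rate = log(2)/median),
#' rounded to whole months with a floor of one month; an administrative
#' censoring horizon is drawn uniformly from `followup_range` (months).
#' Deaths after the horizon are censored at the horizon, so every censored
#' patient has at least the configured minimum follow-up.
#'
#' @param class one of [gap_classes()].
#' @param config a [sim_config()].
#' @param seed optional integer seed (otherwise uses the current RNG state).
#' @return list with `os_months` (integer >= 1) and `event` (1 = death).
#' @export
simulate_survival <- function(class, config, seed = NULL) {
  stopifnot(class %in% .gap_levels)
  if (!is.null(seed)) set.seed(as.integer(seed))
  med <- config$surv_medians[[class]]
  os <- max(1, round(rexp(1, rate = log(2) / med)))
  lo <- config$followup_range[1]; hi <- config$followup_range[2]
  horizon <- if (is.infinite(lo)) Inf else round(runif(1, lo, hi))
  if (os <= horizon) list(os_months = os, event = 1L)
  else list(os_months = as.integer(horizon), event = 0L)
}

#' Simulate a full cohort
#'
#' Draws each patient's GAP class from `class_proportions`, simulates the
#' paired tracks, clinical record and survival, and (optionally) writes the
#' declared file formats: probe TSVs for tumor and normal tracks, a clinical
#' TSV and a truth table enabling recovery scoring. Per-patient seeds are
#' derived deterministically from `config$seed`, so a fixed seed yields an
#' identical cohort and identical files.
#'
#' @param config a [sim_config()].
#' @param n number of patients.
#' @param dir optional output directory.
#' @param annotation list with `map` and `genes` (default packaged).
#' @param keep_tracks keep probe tracks in the returned object (set `FALSE`
#'   to save memory when only files are needed).
#' @return list with `patients` (list of `sim_patient`), `truth`
#'   (data.table id, class, planted events) and `clinical`.
#' @export
simulate_cohort <- function(config, n, dir = NULL,
                            annotation = default_annotation(),
                            keep_tracks = TRUE) {
  stopifnot(inherits(config, "sim_config"), n >= 0)
  set.seed(config$seed)
  classes <- if (n > 0)
    sample(.gap_levels, n, replace = TRUE, prob = config$class_proportions)
  else character()
  sub_seeds <- if (n > 0) sample.int(.Machine$integer.max - 1L, n) else integer()
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    patients[[i]] <- simulate_pair(config, classes[i], sub_seeds[i],
                                   annotation = annotation,
                                   id = sprintf("P%03d", i))
  }
  truth <- if (n > 0) rbindlist(lapply(patients, function(p)
    if (!is.null(p$events) && nrow(p$events))
      data.table(id = p$id, class = p$class, p$events)
    else data.table(id = p$id, class = p$class, band = NA_character_,
                    chrom = NA_character_, start = NA_real_, end = NA_real_,
                    copies = NA_real_, somatic = NA)), fill = TRUE)
  else data.table(id = character(), class = character())
  clinical <- if (n > 0) rbindlist(lapply(patients, `[[`, "clinical"))
  else data.table(id = character())
  if (n > 0) clinical[, gap_class_true := classes]

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    empty_track <- data.table(sample = character(), chrom = character(),
                              pos = numeric(), value = numeric())
    tw <- function(p, which) data.table(sample = p$id, chrom = p[[which]]$chrom,
                                        pos = p[[which]]$pos,
                                        value = p[[which]]$value)
    fwrite(rbindlist(c(list(empty_track), lapply(patients, tw, "tumor"))),
           file.path(dir, "tumor_probes.tsv"), sep = "\t")
    fwrite(rbindlist(c(list(empty_track), lapply(patients, tw, "normal"))),
           file.path(dir, "normal_probes.tsv"), sep = "\t")
    fwrite(clinical, file.path(dir, "clinical.tsv"), sep = "\t")
    fwrite(truth, file.path(dir, "truth.tsv"), sep = "\t")
    writeLines(c(paste0("seed=", config$seed),
                 paste0("noise_sd=", config$noise_sd),
                 paste0("probe_spacing=", config$probe_spacing),
                 paste0("alpha=", config$alpha)),
               file.path(dir, "provenance.txt"))
  }
  if (!keep_tracks) patients <- lapply(patients, function(p) {
    p$tumor <- NULL; p$normal <- NULL; p
  })
  list(patients = patients, truth = truth, clinical = clinical,
       seed = config$seed)
}
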