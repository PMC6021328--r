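# Orchestration and a file-driven command-line interface:
#   simulate | call | classify | survive | report | reproduce-paper
# Stages compose through the declared text formats (probe TSV, SEG dialect,
# clinical TSV, JSON report); every stage fails fast with a coded error and
# a provenance block is serialized alongside every output directory.

.fail <- function(code, ...) stop("[", code, "] ", ..., call. = FALSE)

# flat key=value config file; '#' comments allowed
.read_flat_config <- function(path) {
  if (!file.exists(path)) .fail("E_CONFIG", "config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) .fail("E_CONFIG", "malformed config line: ",
                      lines[bad][1])
  setNames(lapply(kv, function(x) trimws(paste(x[-1], collapse = "="))),
           trimws(vapply(kv, `[`, "", 1)))
}

.parse_args <- function(args) {
  # --key value / --key=value / bare flags
  out <- list(positional = character())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (grepl("=", key, fixed = TRUE)) {
        kv <- strsplit(key, "=", fixed = TRUE)[[1]]
        out[[gsub("-", "_", kv[1])]] <- paste(kv[-1], collapse = "=")
      } else if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        out[[gsub("-", "_", key)]] <- args[i + 1L]
        i <- i + 1L
      } else out[[gsub("-", "_", key)]] <- TRUE
    } else out$positional <- c(out$positional, a)
    i <- i + 1L
  }
  out
}

.opt <- function(opts, key, default = NULL) {
  if (!is.null(opts[[key]])) opts[[key]] else default
}

.load_annotation_opt <- function(opts) {
  ann_dir <- .opt(opts, "annotation")
  if (is.null(ann_dir)) return(default_annotation())
  map <- read_cytobands(file.path(ann_dir, "cytoBand.txt"))
  gene_path <- file.path(ann_dir, "genes.bed")
  genes <- if (file.exists(gene_path)) read_gene_catalog(gene_path, map)
  else NULL
  list(map = map, genes = genes)
}

.provenance <- function(dir, opts, stage) {
  writeLines(c(paste0("stage=", stage),
               paste0("package=gapstrat ",
                      as.character(utils::packageVersion("gapstrat"))),
               paste0(names(opts), "=",
                      vapply(opts, function(x) paste(format(x),
                                                     collapse = " "), ""))),
             file.path(dir, paste0("provenance_", stage, ".txt")))
}

.cli_simulate <- function(opts) {
  out <- .opt(opts, "out") %||% .fail("E_ARGS", "simulate needs --out DIR")
  n <- as.integer(.opt(opts, "n", 20))
  seed <- as.integer(.opt(opts, "seed", 1))
  sigma <- as.numeric(.opt(opts, "noise-sd", .opt(opts, "noise_sd", 0.4)))
  spacing <- as.numeric(.opt(opts, "probe-spacing",
                             .opt(opts, "probe_spacing", 5e4)))
  cfg <- sim_config(seed = seed, noise_sd = sigma, probe_spacing = spacing)
  ann <- .load_annotation_opt(opts)
  simulate_cohort(cfg, n, dir = out, annotation = ann, keep_tracks = FALSE)
  dir.create(out, showWarnings = FALSE)
  .provenance(out, opts, "simulate")
  message("simulate: wrote cohort of ", n, " to ", out)
  invisible(out)
}

.cli_call <- function(opts) {
  tumor_p <- .opt(opts, "tumor") %||% .fail("E_ARGS", "call needs --tumor")
  normal_p <- .opt(opts, "normal") %||% .fail("E_ARGS", "call needs --normal")
  out <- .opt(opts, "out") %||% .fail("E_ARGS", "call needs --out DIR")
  cfg <- caller_config(theta = as.numeric(.opt(opts, "theta", 4.8)),
                       min_probes = as.integer(.opt(opts, "min-probes",
                                                    .opt(opts, "min_probes",
                                                         5))))
  ann <- .load_annotation_opt(opts)
  tum <- read_probe_tsv(tumor_p); nor <- read_probe_tsv(normal_p)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  amps <- list()
  for (s in sort(unique(tum$sample))) {
    tt <- tum[sample == s, .(chrom, pos, value)]
    nn <- nor[sample == s, .(chrom, pos, value)]
    if (!nrow(nn)) .fail("E_INPUT", "no normal track for sample ", s)
    res <- call_sample(tt, nn, cfg, ann)
    write_seg(res$segments, s, file.path(out, paste0(s, ".seg")))
    a <- copy(res$amplicons); a[, sample_id := s]
    amps[[s]] <- a
  }
  amp <- rbindlist(amps)
  fwrite(amp, file.path(out, "amplicons.tsv"), sep = "\t")
  .provenance(out, opts, "call")
  message("call: ", nrow(amp), " amplicons over ", length(amps),
          " samples -> ", out)
  invisible(amp)
}

.cli_classify <- function(opts) {
  out <- .opt(opts, "out") %||% .fail("E_ARGS", "classify needs --out FILE")
  ann <- .load_annotation_opt(opts)
  if (!is.null(.opt(opts, "amplicons"))) {
    amp <- fread(.opt(opts, "amplicons"), sep = "\t")
    if (!"sample_id" %in% names(amp))
      .fail("E_INPUT", "amplicon table lacks sample_id")
  } else if (!is.null(.opt(opts, "seg"))) {
    seg <- read_seg(.opt(opts, "seg"))
    cfg <- caller_config(theta = as.numeric(.opt(opts, "theta", 4.8)),
                         min_probes = as.integer(.opt(opts, "min-probes",
                                                      .opt(opts,
                                                           "min_probes", 5))))
    warning("classify: SEG input carries no gene annotation; EGFR ",
            "involvement falls back to overlap with band 7p11.2")
    amps <- lapply(split(seg, seg$sample_id), function(d)
      call_amplicons(d[, .(chrom, start, end, num_probes, seg_mean)], cfg,
                     list(map = ann$map, genes = NULL)))
    amp <- rbindlist(Map(function(a, s) {
      if (nrow(a)) a[, sample_id := s] else a
    }, amps, names(amps)), fill = TRUE)
  } else .fail("E_ARGS", "classify needs --amplicons or --seg")
  ids <- sort(unique(amp$sample_id))
  profs <- lapply(ids, function(s)
    build_profile(amp[sample_id == s], s))
  res <- data.table(
    id = ids,
    gap_class = vapply(profs, classify_gap, ""),
    n_regions = vapply(profs, `[[`, 0L, "n_regions"),
    egfr_involved = vapply(profs, `[[`, TRUE, "egfr_involved"))
  res[, risk := risk_group(gap_class)]
  fwrite(res, out, sep = "\t")
  message("classify: ", nrow(res), " samples -> ", out)
  invisible(res)
}

.cli_survive <- function(opts) {
  clin_p <- .opt(opts, "clinical") %||% .fail("E_ARGS",
                                              "survive needs --clinical")
  cls_p <- .opt(opts, "classes") %||% .fail("E_ARGS",
                                            "survive needs --classes")
  out <- .opt(opts, "out") %||% .fail("E_ARGS", "survive needs --out FILE")
  clin <- fread(clin_p, sep = "\t")
  cls <- fread(cls_p, sep = "\t")
  cls[, id := as.character(id)]
  clin[, id := as.character(id)]
  dt <- merge(clin, cls[, .(id, gap_class, risk)], by = "id", all.x = TRUE)
  dt[is.na(gap_class), `:=`(gap_class = "NO_AMP",
                            risk = risk_group("NO_AMP"))]
  if (!nrow(dt)) .fail("E_INPUT", "no overlap between clinical and classes")
  filt <- apply_inclusion_filter(dt)
  inc <- filt$included
  km_of <- function(col) {
    lv <- unique(inc[[col]])
    setNames(lapply(lv, function(g) {
      d <- inc[get(col) == g]
      list(n = nrow(d), median = km_median(km_fit(d$os_months, d$event)))
    }), lv)
  }
  lr <- function(col) {
    if (length(unique(inc[[col]])) < 2)
      return(list(chisq = NA, df = 0, p = NA))
    t <- logrank_test(inc$os_months, inc$event, inc[[col]])
    list(chisq = t$chisq, df = t$df, p = t$p)
  }
  rep <- list(included_n = nrow(inc),
              excluded_n = nrow(filt$excluded),
              km_by_class = km_of("gap_class"),
              km_by_risk = km_of("risk"),
              logrank_class = lr("gap_class"),
              logrank_risk = lr("risk"))
  jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  message("survive: n=", nrow(inc), " -> ", out)
  invisible(rep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `simulate` (synthetic cohort to a directory), `call`
#' (amplicons + SEG files from paired probe TSVs), `classify` (GAP classes
#' from an amplicon table or an external SEG file, the latter using the
#' 7p11.2-band EGFR fallback), `survive` (KM/log-rank report from clinical +
#' class tables), `reproduce-paper`/`report` (bundled-cohort report).
#' Common flags: `--config FILE` (flat key=value, overridden by explicit
#' flags), `--seed`, `--annotation DIR` (expects cytoBand.txt and
#' optionally genes.bed), `--theta`, `--min-probes`, `--out`,
#' `--log-level`.
#'
#' @param args character vector of CLI arguments (e.g. `commandArgs(
#'   trailingOnly = TRUE)`).
#' @return stage-dependent value, invisibly.
#' @export
gap_cli <- function(args) {
  opts <- .parse_args(args)
  if (!is.null(opts$config)) {
    cfg <- .read_flat_config(opts$config)
    for (k in names(cfg)) {
      k2 <- gsub("-", "_", k)
      if (is.null(opts[[k2]])) opts[[k2]] <- cfg[[k]]
    }
  }
  if (!is.null(opts$log_level) && identical(opts$log_level, "quiet")) {
    return(suppressMessages(gap_cli_dispatch(opts)))
  }
  gap_cli_dispatch(opts)
}

gap_cli_dispatch <- function(opts) {
  cmd <- opts$positional[1]
  if (is.null(cmd) || is.na(cmd))
    .fail("E_ARGS", "usage: gap_cli <simulate|call|classify|survive|",
          "report|reproduce-paper> [--flags]")
  switch(cmd,
         simulate = .cli_simulate(opts),
         call = .cli_call(opts),
         classify = .cli_classify(opts),
         survive = .cli_survive(opts),
         report = ,
         `reproduce-paper` = {
           out <- .opt(opts, "out")
           rep <- reproduce_paper(out)
           if (is.null(out)) {
             cc <- unlist(rep$class_counts)
             message("classes: ", paste(names(cc), cc, sep = "=",
                                        collapse = " "))
             message("included n=", rep$included_n)
           }
           invisible(rep)
         },
         .fail("E_ARGS", "unknown subcommand: ", cmd))
}
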