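# Bundled 80-patient reference cohort: per-tumor amplification profiles
# (arm sets, band labels, EGFR involvement) and the clinical table (age,
# Karnofsky, surgery, chemotherapy, overall survival, vital status),
# transcribed from the source study's printed tables. Profile IDs are a
# subset of the clinical roster; 45 tumors carry amplification and 35 do
# not.

#' Load the bundled reference amplification profiles
#'
#' @return named list of 80 `gap_profile`s keyed by tumor id.
#' @export
load_series1_profiles <- function() {
  path <- system.file("extdata", "series1_profiles.tsv",
                      package = "gapstrat", mustWork = TRUE)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  profs <- lapply(seq_len(nrow(dt)), function(i) {
    arms <- strsplit(dt$arms[i], ",", fixed = TRUE)[[1]]
    bands <- strsplit(dt$bands[i], ",", fixed = TRUE)[[1]]
    gap_profile(dt$tumor_id[i], arms = arms, bands = bands,
                egfr_involved = dt$egfr_involved[i] == "1")
  })
  setNames(profs, dt$tumor_id)
}

#' Load the bundled reference clinical table
#'
#' Adds the analysis groupings used throughout: `age_group` (<=30, 31-45,
#' 46-60, 61-75, >75), `karnofsky_group` (>70 vs <=70), `surgery` (T =
#' complete resection, P = partial, B = biopsy only) and `chemo_category`
#' (Stupp-containing regimens vs other regimens vs none; "ND" becomes
#' missing).
#'
#' @return data.table of 80 records.
#' @export
load_series1_clinical <- function() {
  path <- system.file("extdata", "series1_clinical.tsv",
                      package = "gapstrat", mustWork = TRUE)
  dt <- fread(path, sep = "\t", header = TRUE, na.strings = c("NA", ""))
  dt[, age_group := cut(age, breaks = c(-Inf, 30, 45, 60, 75, Inf),
                        labels = c("<=30", "31-45", "46-60", "61-75", ">75"))]
  dt[, karnofsky_group := factor(ifelse(is.na(karnofsky), NA,
                                        ifelse(karnofsky > 70, ">70",
                                               "<=70")),
                                 levels = c(">70", "<=70"))]
  dt[, surgery := factor(surgery, levels = c("T", "P", "B"))]
  dt[, chemo_category := factor(fcase(
    chemotherapy %chin% c("Stupp", "Stupp/Sequential"), "Stupp",
    chemotherapy %chin% c("Sequential", "PCV", "BCNU+TMZ"), "Other",
    chemotherapy == "-", "None",
    default = NA), levels = c("Stupp", "Other", "None"))]
  dt[]
}

#' Join profiles with clinical data
#'
#' @param profiles named list of `gap_profile`s.
#' @param clinical clinical data.table with an `id` column.
#' @return clinical table with `gap_class` and `risk` columns added.
#' @export
join_profiles_clinical <- function(profiles, clinical) {
  cls <- vapply(profiles, classify_gap, "")
  dt <- copy(as.data.table(clinical))
  dt[, gap_class := factor(unname(cls[id]), levels = gap_classes())]
  if (anyNA(dt$gap_class))
    stop("clinical ids without profile: ",
         paste(dt$id[is.na(dt$gap_class)], collapse = ", "))
  dt[, risk := factor(risk_group(as.character(gap_class)),
                      levels = c("FAVORABLE", "UNFAVORABLE"))]
  dt[]
}

#' Reproduce the published stratification on the bundled cohort
#'
#' Runs the whole downstream pipeline on the bundled reference fixtures:
#' five-class frequency table, EGFR involvement count, survival inclusion
#' filter, Kaplan-Meier medians per GAP class and per risk group, five-group
#' and two-group log-rank tests, and the forward stepwise Cox model over
#' age group, Karnofsky group, surgery, chemotherapy category and risk
#' group.
#'
#' @param out optional path for a machine-readable JSON report.
#' @return report list (invisibly when `out` is given).
#' @export
reproduce_paper <- function(out = NULL) {
  profiles <- load_series1_profiles()
  clinical <- load_series1_clinical()
  joined <- join_profiles_clinical(profiles, clinical)

  freq <- cohort_frequency_table(profiles)
  egfr_n <- sum(vapply(profiles, `[[`, TRUE, "egfr_involved"))

  filt <- apply_inclusion_filter(joined)
  inc <- filt$included

  med_by <- function(split_col) {
    lv <- levels(inc[[split_col]])
    setNames(lapply(lv, function(g) {
      d <- inc[get(split_col) == g]
      if (!nrow(d)) return(list(n = 0L, median = NA_real_))
      fit <- km_fit(d$os_months, d$event)
      list(n = nrow(d), median = km_median(fit),
           range = range(d$os_months))
    }), lv)
  }
  class_km <- med_by("gap_class")
  risk_km <- med_by("risk")

  lr5 <- logrank_test(inc$os_months, inc$event, inc$gap_class)
  lr2 <- logrank_test(inc$os_months, inc$event, inc$risk)

  sw <- stepwise_cox(inc, c("age_group", "karnofsky_group", "surgery",
                            "chemo_category", "risk"))

  report <- list(
    cohort = list(n = length(profiles), amplified = sum(freq$n) -
                    freq[class == "NO_AMP"]$n, egfr_involved = egfr_n),
    class_counts = setNames(as.list(freq$n), freq$class),
    included_n = nrow(inc),
    excluded = filt$excluded[, .(id, os_months, event, reason)],
    km_median_by_class = lapply(class_km, `[[`, "median"),
    km_n_by_class = lapply(class_km, `[[`, "n"),
    km_median_by_risk = lapply(risk_km, `[[`, "median"),
    km_n_by_risk = lapply(risk_km, `[[`, "n"),
    logrank_5group = list(chisq = lr5$chisq, df = lr5$df, p = lr5$p),
    logrank_2group = list(chisq = lr2$chisq, df = lr2$df, p = lr2$p),
    stepwise = list(selected = sw$selected,
                    gate_p = as.list(sw$gate),
                    hr = as.list(sw$fit$hr),
                    ci_lo = as.list(sw$fit$ci_lo),
                    ci_hi = as.list(sw$fit$ci_hi),
                    p = as.list(sw$fit$p)))
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows", na = "null")
    return(invisible(report))
  }
  report
}
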