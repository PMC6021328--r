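# Per-tumor amplification profiles, the five GAP classes and the two
# prognostic risk groups, plus cohort frequency tables.
#
# A "chromosomal region" is a chromosome arm: several amplified bands on one
# arm count as one region, while amplicons on both arms of one chromosome
# count as two.

#' Construct an amplification profile
#'
#' @param tumor_id tumor identifier.
#' @param arms character vector of amplified arms (e.g. `c("7p","12q")`).
#' @param bands character vector of amplified band labels.
#' @param genes character vector of amplified gene symbols.
#' @param egfr_involved logical; when `NA` it is derived from `genes`
#'   (EGFR present) or, lacking gene data, from band `7p11.2`.
#' @return a `gap_profile` list with `n_regions = length(unique(arms))`.
#' @export
gap_profile <- function(tumor_id, arms = character(), bands = character(),
                        genes = character(), egfr_involved = NA) {
  arms <- sort(unique(arms[nzchar(arms)]))
  bands <- sort(unique(bands[nzchar(bands)]))
  genes <- sort(unique(genes[nzchar(genes)]))
  if (is.na(egfr_involved)) {
    egfr_involved <- if (length(genes)) "EGFR" %in% genes
    else "7p11.2" %in% bands
  }
  if (egfr_involved && length(arms) && !("7p" %in% arms))
    stop("profile ", tumor_id, ": EGFR involvement without arm 7p")
  structure(list(tumor_id = tumor_id, arms = arms, bands = bands,
                 genes = genes, egfr_involved = isTRUE(egfr_involved),
                 n_regions = length(arms)),
            class = "gap_profile")
}

#' Build a profile from one tumor's called amplicons
#'
#' Arms are the union of each amplicon's arm(s); EGFR involvement means some
#' amplicon's gene list contains EGFR, falling back to overlap with band
#' 7p11.2 when the input carries no gene annotation (e.g. external SEG
#' files).
#'
#' @param amplicons amplicon table from [call_amplicons()] (or a SEG-derived
#'   table annotated with arm/bands; `genes` may be absent or empty).
#' @param tumor_id tumor identifier.
#' @return a `gap_profile`.
#' @export
build_profile <- function(amplicons, tumor_id) {
  if (is.null(amplicons) || !nrow(amplicons))
    return(gap_profile(tumor_id, egfr_involved = FALSE))
  amp <- as.data.table(amplicons)
  split_col <- function(col)
    unique(unlist(strsplit(if (col %in% names(amp)) amp[[col]] else
      character(), ",", fixed = TRUE)))
  genes <- split_col("genes")
  have_genes <- length(genes) > 0
  egfr <- if (have_genes) "EGFR" %in% genes
  else "7p11.2" %in% split_col("bands")
  gap_profile(tumor_id, arms = split_col("arm"), bands = split_col("bands"),
              genes = genes, egfr_involved = egfr)
}

#' Assign the five-level GAP class
#'
#' No amplified region: `NO_AMP`. One region: `EGFR_ONLY` when EGFR is
#' involved, else `NON_EGFR_SINGLE`. Two or more regions: `MULTI_WITH_EGFR`
#' or `MULTI_WITHOUT_EGFR` by EGFR involvement. Total over all profiles.
#'
#' @param profile a `gap_profile`.
#' @return one of [gap_classes()].
#' @export
classify_gap <- function(profile) {
  stopifnot(inherits(profile, "gap_profile"))
  n <- profile$n_regions; e <- profile$egfr_involved
  if (n == 0) "NO_AMP"
  else if (n == 1) if (e) "EGFR_ONLY" else "NON_EGFR_SINGLE"
  else if (e) "MULTI_WITH_EGFR" else "MULTI_WITHOUT_EGFR"
}

#' Map a GAP class to its prognostic risk group
#'
#' `FAVORABLE` pools no-amplification with every EGFR-involved class;
#' `UNFAVORABLE` pools amplification (single or multiple regions) that does
#' not involve EGFR.
#'
#' @param class GAP class label(s) (vectorized).
#' @return `"FAVORABLE"` or `"UNFAVORABLE"`.
#' @export
risk_group <- function(class) {
  stopifnot(all(class %in% gap_classes()))
  ifelse(class %in% c("NO_AMP", "EGFR_ONLY", "MULTI_WITH_EGFR"),
         "FAVORABLE", "UNFAVORABLE")
}

#' Cohort class-frequency table
#'
#' @param profiles list of `gap_profile`s, one per tumor.
#' @return data.table with class, n, pct (of the cohort); counts sum to the
#'   cohort size. Duplicate tumor ids are an error.
#' @export
cohort_frequency_table <- function(profiles) {
  ids <- vapply(profiles, `[[`, "", "tumor_id")
  if (anyDuplicated(ids))
    stop("duplicate tumor id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cls <- factor(vapply(profiles, classify_gap, ""), levels = gap_classes())
  tab <- as.data.table(table(class = cls))
  setnames(tab, "N", "n")
  tab[, pct := if (length(ids)) 100 * n / length(ids) else 0]
  tab[]
}

#' Per-gene amplification frequency among amplified tumors
#'
#' Counts, for each gene, the tumors whose profile includes it, as a
#' percentage of tumors carrying any amplification.
#'
#' @param profiles list of `gap_profile`s.
#' @return data.table gene, n, pct (of amplified tumors), sorted by n.
#' @export
gene_frequency_table <- function(profiles) {
  ids <- vapply(profiles, `[[`, "", "tumor_id")
  if (anyDuplicated(ids)) stop("duplicate tumor id(s)")
  amped <- Filter(function(p) p$n_regions > 0, profiles)
  n_amp <- length(amped)
  genes <- unlist(lapply(amped, `[[`, "genes"))
  if (!length(genes))
    return(data.table(gene = character(), n = integer(), pct = numeric()))
  tab <- as.data.table(table(gene = genes))
  setnames(tab, "N", "n")
  tab[, pct := 100 * n / n_amp]
  setorder(tab, -n, gene)
  tab[]
}
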