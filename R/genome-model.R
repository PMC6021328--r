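# Genome coordinate system: cytoband map, gene catalog, arm assignment and
# interval queries. Coordinates are 0-based half-open; chromosome names are
# stored without the "chr" prefix ("1".."22", "X", "Y").

.known_chroms <- c(as.character(1:22), "X", "Y")

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix and validates against the assembly's
#' chromosome list (1-22, X, Y).
#'
#' @param chrom character vector of chromosome names.
#' @param strict error on unknown chromosomes (default `TRUE`); otherwise
#'   unknown entries become `NA`.
#' @return character vector of bare chromosome names.
#' @export
normalize_chrom <- function(chrom, strict = TRUE) {
  out <- sub("^chr", "", as.character(chrom))
  bad <- !(out %in% .known_chroms)
  if (any(bad)) {
    if (strict) stop("unknown chromosome(s): ",
                     paste(unique(chrom[bad]), collapse = ", "))
    out[bad] <- NA_character_
  }
  out
}

#' Construct a genomic interval
#'
#' @param chrom chromosome name (with or without `"chr"` prefix).
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @return a `genomic_interval` list.
#' @export
genomic_interval <- function(chrom, start, end) {
  chrom <- normalize_chrom(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)) || any(start < 0))
    stop("interval coordinates must be finite and non-negative")
  if (any(start >= end)) stop("interval requires start < end")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' Read a UCSC-style cytoband file
#'
#' Parses the cytoBand.txt dialect (tab-separated: chrom, start, end, band
#' name, Giemsa stain; no header; 0-based half-open). Lines on chromosomes
#' outside 1-22/X/Y are skipped with a warning. Band names must begin with
#' `p` or `q`, which determines the arm.
#'
#' @param path path to the cytoband file.
#' @return a `cytoband_map`: list with `bands` (data.table: chrom, start,
#'   end, band, stain, arm), `chroms` (chrom, length) and `arms` (chrom, arm,
#'   start, end, the p/q extents).
#' @export
read_cytobands <- function(path) {
  if (!file.exists(path)) stop("cytoband file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("cytoband file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("malformed cytoband line ", which(nf < 4)[1], ": expected >=4 ",
         "tab-separated fields, got ", nf[nf < 4][1])
  raw_chrom <- vapply(fields, `[`, "", 1L)
  chrom <- normalize_chrom(raw_chrom, strict = FALSE)
  if (anyNA(chrom)) {
    warning("skipping ", sum(is.na(chrom)), " cytoband line(s) on unknown ",
            "chromosome(s): ",
            paste(unique(raw_chrom[is.na(chrom)]), collapse = ", "))
    fields <- fields[!is.na(chrom)]; chrom <- chrom[!is.na(chrom)]
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  band <- vapply(fields, `[`, "", 4L)
  stain <- vapply(fields, function(f) if (length(f) >= 5) f[5] else "", "")
  bad <- which(!is.finite(start) | !is.finite(end) | start >= end)
  if (length(bad))
    stop("malformed cytoband line ", bad[1], ": bad coordinates")
  bad <- which(!grepl("^[pq]", band))
  if (length(bad))
    stop("malformed cytoband line ", bad[1], ": band name must start p/q")
  bands <- data.table(chrom = chrom, start = start, end = end, band = band,
                      stain = stain, arm = substr(band, 1, 1))
  setkey(bands, chrom, start)
  # validate tiling: bands cover each chromosome without gap or overlap
  chk <- bands[, {
    if (any(start[-1] != end[-.N]))
      stop("cytoband map: bands on chromosome ", chrom[1],
           " do not tile (gap or overlap)")
    if (start[1] != 0) stop("cytoband map: chromosome ", chrom[1],
                            " does not start at 0")
    p <- which(arm == "p"); q <- which(arm == "q")
    if (length(p) && length(q) && max(p) > min(q))
      stop("cytoband map: interleaved p/q bands on chromosome ", chrom[1])
    .(length = end[.N])
  }, by = chrom]
  arms <- bands[, .(start = min(start), end = max(end)),
                by = .(chrom, arm)]
  structure(list(bands = bands, chroms = chk, arms = arms),
            class = "cytoband_map")
}

#' Write a cytoband map back to cytoBand.txt dialect
#'
#' Round-trip inverse of [read_cytobands()]: `chr` prefixes are restored.
#'
#' @param map a `cytoband_map`.
#' @param path output path.
#' @export
write_cytobands <- function(map, path) {
  stopifnot(inherits(map, "cytoband_map"))
  b <- copy(map$bands)[, .(chrom = paste0("chr", chrom),
                           start = as.integer(start), end = as.integer(end),
                           band, stain)]
  fwrite(b, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED6 gene catalog
#'
#' Tab-separated chrom, start, end, symbol, score, strand (strand stored but
#' ignored by overlap logic). Each gene is annotated with the cytoband
#' containing its midpoint when a map is supplied. Symbols must be unique.
#'
#' @param path BED6 file path.
#' @param map optional `cytoband_map` used to attach band labels.
#' @return data.table: chrom, start, end, gene, strand, band.
#' @export
read_gene_catalog <- function(path, map = NULL) {
  if (!file.exists(path)) stop("gene catalog not found: ", path)
  bed <- fread(path, header = FALSE, sep = "\t")
  if (ncol(bed) < 4) stop("gene catalog must be BED with >=4 columns")
  setnames(bed, 1:4, c("chrom", "start", "end", "gene"))
  bed[, strand := if (ncol(bed) >= 6) bed[[6]] else "+"]
  bed <- bed[, .(chrom = normalize_chrom(chrom), start = as.numeric(start),
                 end = as.numeric(end), gene = as.character(gene), strand)]
  if (anyDuplicated(bed$gene))
    stop("gene catalog: duplicate symbol(s): ",
         paste(unique(bed$gene[duplicated(bed$gene)]), collapse = ", "))
  if (any(bed$start >= bed$end)) stop("gene catalog: start >= end")
  bed[, band := NA_character_]
  if (!is.null(map)) {
    mid <- (bed$start + bed$end) / 2
    for (i in seq_len(nrow(bed))) {
      hit <- map$bands[chrom == bed$chrom[i] & start <= mid[i] & end > mid[i]]
      if (nrow(hit)) bed$band[i] <- paste0(hit$chrom[1], hit$band[1])
    }
  }
  setkey(bed, chrom, start)
  bed[]
}

.arm_boundary <- function(map, chr) {
  a <- map$arms[chrom == chr]
  if (!nrow(a)) stop("unknown chromosome: ", chr)
  p <- a[arm == "p"]
  if (nrow(p)) p$end[1] else a[arm == "q"]$start[1]
}

#' Chromosome arm(s) of an interval
#'
#' Returns the arm (e.g. `"7p"`) containing the interval midpoint; an
#' interval spanning the p/q boundary returns both arms. Downstream region
#' counting treats each arm as a separate chromosomal region.
#'
#' @param chrom,start,end interval (0-based half-open).
#' @param map a `cytoband_map`.
#' @return character vector of one or two arm labels.
#' @export
arm_of <- function(chrom, start, end, map) {
  chrom <- normalize_chrom(chrom)
  stopifnot(length(chrom) == 1, start < end)
  b <- .arm_boundary(map, chrom)
  if (start < b && end > b) return(paste0(chrom, c("p", "q")))
  mid <- (start + end) / 2
  paste0(chrom, if (mid < b) "p" else "q")
}

#' Cytobands overlapping an interval
#'
#' @inheritParams arm_of
#' @return band labels (e.g. `"7p11.2"`) in genomic order; empty if none.
#' @export
bands_overlapping <- function(chrom, start, end, map) {
  chrom <- normalize_chrom(chrom)
  stopifnot(length(chrom) == 1, start < end)
  if (!chrom %in% map$chroms$chrom) stop("unknown chromosome: ", chrom)
  ch <- chrom; s <- start; e <- end
  hit <- map$bands[chrom == ch & start < e & end > s][order(start)]
  if (!nrow(hit)) character() else paste0(hit$chrom, hit$band)
}

#' Genes overlapping an interval
#'
#' Overlap (not containment) against the catalog; strand is ignored.
#'
#' @inheritParams arm_of
#' @param catalog a gene catalog from [read_gene_catalog()].
#' @return gene symbols in genomic order; empty if none.
#' @export
genes_overlapping <- function(chrom, start, end, catalog) {
  chrom <- normalize_chrom(chrom)
  stopifnot(length(chrom) == 1, start < end)
  ch <- chrom; s <- start; e <- end
  hit <- catalog[chrom == ch & start < e & end > s][order(start)]
  hit$gene
}

#' Packaged synthetic hg19 annotation
#'
#' Loads the bundled approximate-hg19 cytoband map and gene catalog
#' (synthetic fixtures: anchor bands and the 38 recurrently amplified genes
#' sit at approximately real coordinates; filler bands tile the rest).
#'
#' @return list with `map` and `genes`.
#' @export
default_annotation <- function() {
  map <- read_cytobands(system.file("extdata", "cytoBand.hg19.synthetic.txt",
                                    package = "gapstrat", mustWork = TRUE))
  genes <- read_gene_catalog(system.file("extdata",
                                         "genes.hg19.synthetic.bed",
                                         package = "gapstrat",
                                         mustWork = TRUE), map)
  list(map = map, genes = genes)
}
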