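# Shared fixtures and independent oracles built in code at test time.

library(data.table)

# tiny two-chromosome cytoband map written to a temp file
tiny_cytoband_file <- function(path = tempfile(fileext = ".txt")) {
  writeLines(c(
    "chr7\t0\t2800000\tp22.3\tgneg",
    "chr7\t2800000\t50000000\tp12.1\tgpos50",
    "chr7\t50000000\t60000000\tp11.2\tgneg",
    "chr7\t60000000\t70000000\tq11.21\tgneg",
    "chr7\t70000000\t159138663\tq36\tgpos50",
    "chr16\t0\t36600000\tp11\tgneg",
    "chr16\t36600000\t56700000\tq12.1\tgneg",
    "chr16\t56700000\t90354753\tq24\tgpos50"), path)
  path
}

tiny_map <- function() read_cytobands(tiny_cytoband_file())

tiny_gene_file <- function(path = tempfile(fileext = ".bed")) {
  writeLines(c(
    "chr7\t55000000\t55300000\tEGFR\t0\t+",
    "chr7\t55400000\t55500000\tLANCL2\t0\t-"), path)
  path
}

# probe track on one chromosome with given values, 50 kb spacing
make_track <- function(values, chrom = "7", spacing = 5e4) {
  data.table::data.table(chrom = chrom,
                         pos = seq(25000, by = spacing,
                                   length.out = length(values)),
                         value = as.numeric(values))
}

# brute-force two-group log-rank oracle: builds the 2x2 table at every
# distinct event time and accumulates hypergeometric moments directly.
logrank_oracle_2g <- function(times, events, group) {
  g <- as.integer(as.factor(group))  # 1/2
  ut <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ut) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# exhaustive within-segment sum-of-squares minimizer for a fixed number of
# segments (1..3); returns segment end indices
sse_oracle_breaks <- function(x, n_seg) {
  n <- length(x)
  cs <- cumsum(x); css <- cumsum(x^2)
  sse <- function(i, j) { # x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    ss <- css[j] - if (i > 1) css[i - 1] else 0
    ss - s^2 / (j - i + 1)
  }
  if (n_seg == 1) return(n)
  if (n_seg == 2) {
    best <- Inf; bk <- NA
    for (k in 1:(n - 1)) {
      v <- sse(1, k) + sse(k + 1, n)
      if (v < best - 1e-12) { best <- v; bk <- k }
    }
    return(c(bk, n))
  }
  best <- Inf; bk <- c(NA, NA)
  for (k1 in 1:(n - 2)) for (k2 in (k1 + 1):(n - 1)) {
    v <- sse(1, k1) + sse(k1 + 1, k2) + sse(k2 + 1, n)
    if (v < best - 1e-12) { best <- v; bk <- c(k1, k2) }
  }
  c(bk, n)
}

# fast sim config for tests: sparser probe grid, smaller events kept >= 10
# probes at the sparser spacing
fast_sim_config <- function(...) {
  sim_config(probe_spacing = 2e5, event_length = 2.5e6, ...)
}
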