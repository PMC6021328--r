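test_that("germline masking removes CNV probes and demands matched grids", {
  tum <- make_track(rep(2, 50))
  nor <- make_track(rep(2, 50))
  expect_identical(as.data.frame(suppressMessages(
    germline_mask(tum, nor, 0.6)))[, c("chrom", "pos", "value")],
    as.data.frame(tum))
  # germline CNV at 3.2 units in both tracks, delta 0.6 -> probes removed
  nor2 <- copy(nor); nor2$value[10:15] <- 3.2
  tum2 <- copy(tum); tum2$value[10:15] <- 3.2
  m <- suppressMessages(germline_mask(tum2, nor2, 0.6))
  expect_equal(nrow(m), 44)
  expect_false(any(m$pos %in% tum$pos[10:15]))
  expect_equal(attr(m, "n_masked"), 6L)
  nor3 <- copy(nor); nor3$pos[5] <- nor3$pos[5] + 1
  expect_error(germline_mask(tum, nor3, 0.6), "probe 5")
})

test_that("running-median smoothing: identity, spikes, truncated edges", {
  const <- make_track(rep(3.3, 21))
  expect_equal(smooth_track(const, 5)$value, rep(3.3, 21))
  spike <- make_track(c(rep(2, 10), 9, rep(2, 10)))
  expect_equal(smooth_track(spike, 5)$value, rep(2, 21))
  noisy <- make_track(runif(21, 1, 3))
  expect_equal(smooth_track(noisy, 1)$value, noisy$value)
})

test_that("segmentation: flat tracks, noiseless steps, probe partition", {
  flat <- rbind(make_track(rep(2, 40), "7"), make_track(rep(2, 30), "8"))
  seg <- segment_track(flat, 5, 5)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$num_probes, c(40L, 30L))
  step <- make_track(c(rep(2, 20), rep(6.2, 12), rep(2, 20)))
  seg <- segment_track(step, 5, 5)
  expect_equal(nrow(seg), 3)
  expect_equal(seg$seg_mean, c(2, 6.2, 2))
  expect_equal(seg$num_probes, c(20L, 12L, 20L))
  expect_equal(sum(seg$num_probes), 52L)
})

test_that("binary segmentation agrees with the exhaustive SSE oracle", {
  set.seed(11)
  for (rep_i in 1:25) {
    n_seg <- sample(1:3, 1)
    n <- sample(60:200, 1)
    repeat {
      cuts <- sort(sample(10:(n - 10), n_seg - 1))
      if (n_seg < 3 || diff(cuts) >= 10) break
    }
    means <- 2 + 3 * sample(0:3, n_seg)  # well-separated step means
    lab <- findInterval(seq_len(n), c(1, cuts + 1))
    x <- pmax(0.01, means[lab] + rnorm(n, 0, 0.3))
    seg <- segment_track(make_track(x), 5, 5)
    expect_lte(nrow(seg), 3)
    found_ends <- cumsum(seg$num_probes)
    oracle_ends <- sse_oracle_breaks(x, nrow(seg))
    expect_equal(found_ends, oracle_ends, info = paste("rep", rep_i))
  }
})

test_that("amplicon calling: threshold, polyploidy exclusion, annotation", {
  ann <- default_annotation()
  cfg <- caller_config()
  expect_equal(nrow(call_amplicons(data.table::data.table(), cfg, ann)), 0)
  segs <- data.table::data.table(
    chrom = c("7", "7", "4"),
    start = c(0, 54e6, 1e6), end = c(54e6, 56e6, 30e6),
    num_probes = c(1000L, 40L, 600L),
    seg_mean = c(2.0, 6.22, 3.54))  # diploid, amplified, tetraploid
  amp <- call_amplicons(segs, cfg, ann)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$arm, "7p")
  expect_true("EGFR" %in% strsplit(amp$genes, ",")[[1]])
  expect_true("7p11.2" %in% strsplit(amp$bands, ",")[[1]])
  expect_false(amp$whole_chrom_suspect)
  # min-probes gate
  segs$num_probes[2] <- 3L
  expect_equal(nrow(call_amplicons(segs, cfg, ann)), 0)
})

test_that("amplicons on opposite arms are never merged across centromere", {
  ann <- default_annotation()
  bnd <- ann$map$arms[chrom == "7" & arm == "p"]$end
  segs <- data.table::data.table(
    chrom = "7", start = c(bnd - 6e5, bnd + 1e5),
    end = c(bnd - 1e5, bnd + 6e5),
    num_probes = c(10L, 10L), seg_mean = c(6, 6))
  amp <- call_amplicons(segs, caller_config(), ann)
  expect_equal(nrow(amp), 2)
  expect_setequal(amp$arm, c("7p", "7q"))
  # same-arm neighbours inside the merge gap do merge, probe-weighted
  segs2 <- data.table::data.table(
    chrom = "7", start = c(54e6, 55.5e6), end = c(55e6, 56.5e6),
    num_probes = c(10L, 30L), seg_mean = c(6, 8))
  amp2 <- call_amplicons(segs2, caller_config(), ann)
  expect_equal(nrow(amp2), 1)
  expect_equal(amp2$seg_mean, (10 * 6 + 30 * 8) / 40)
  expect_equal(amp2$num_probes, 40L)
})

test_that("threshold monotonicity: stricter theta yields a subset", {
  ann <- default_annotation()
  cfg <- fast_sim_config(seed = 21)
  p <- simulate_pair(cfg, "MULTI_WITH_EGFR", 77, ann)
  seg <- call_sample(p$tumor, p$normal, caller_config(), ann)$segments
  a48 <- call_amplicons(seg, caller_config(theta = 4.8), ann)
  a60 <- call_amplicons(seg, caller_config(theta = 6.0), ann)
  key <- function(a) paste(a$chrom, a$start, a$end)
  # merged intervals can differ; require every strict amplicon to be
  # contained in some lenient amplicon
  for (i in seq_len(nrow(a60))) {
    covered <- any(a48$chrom == a60$chrom[i] & a48$start <= a60$start[i] &
                     a48$end >= a60$end[i])
    expect_true(covered)
  }
  expect_lte(nrow(a60), nrow(a48))
})

test_that("SEG files round-trip with the 1-based presentation convention", {
  segs <- data.table::data.table(chrom = "7", start = 1000, end = 5000,
                                 num_probes = 12L, seg_mean = 5.5)
  f <- tempfile(fileext = ".seg")
  write_seg(segs, "S1", f)
  lines <- readLines(f)
  expect_match(lines[1], "arbitrary copy-number units")
  expect_match(lines[3], "\t1001\t5000\t")  # 1-based inclusive on disk
  back <- read_seg(f)
  expect_equal(back$start, 1000)
  expect_equal(back$end, 5000)
  expect_equal(back$seg_mean, 5.5)
  expect_equal(back$sample_id, "S1")
})

test_that("germline CNVs never surface as amplicons at any copy number", {
  ann <- default_annotation()
  # a 20-copy germline event present in both tracks
  tum <- make_track(rep(2, 200)); nor <- make_track(rep(2, 200))
  v <- copies_to_value(20)
  tum$value[80:120] <- v; nor$value[80:120] <- v
  res <- call_sample(tum, nor, caller_config(), ann)
  expect_equal(nrow(res$amplicons), 0)
})
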