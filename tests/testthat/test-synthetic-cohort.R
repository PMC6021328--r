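test_that("copies_to_value anchors, monotonicity and domain", {
  expect_identical(copies_to_value(2), 2)
  expect_equal(copies_to_value(7), 4.8, tolerance = 1e-12)
  # tetraploid-equivalent gains stay below the amplification threshold
  expect_lt(copies_to_value(4), 4.8)
  # linear below diploid
  expect_equal(copies_to_value(c(0, 1, 1.5)), c(0, 1, 1.5))
  grid <- seq(0, 30, by = 0.25)
  expect_true(all(diff(copies_to_value(grid)) > 0))
  expect_error(copies_to_value(-1), ">= 0")
})

test_that("noiseless tracks reproduce planted values exactly", {
  ann <- default_annotation()
  cfg <- fast_sim_config(noise_sd = 0, polyploid_prob = 0, seed = 5)
  p <- simulate_pair(cfg, "EGFR_ONLY", 11, ann)
  ev <- p$events[somatic == TRUE]
  inside <- p$tumor[chrom == ev$chrom & pos >= ev$start & pos < ev$end]
  expect_true(nrow(inside) >= 10)
  expect_true(all(inside$value == copies_to_value(cfg$event_copies)))
  # germline sharing: germline deviations identical in both tracks,
  # somatic deviations only in the tumor
  germ <- p$events[somatic == FALSE]
  if (!is.null(germ) && nrow(germ)) {
    for (i in seq_len(nrow(germ))) {
      idx <- p$normal$chrom == germ$chrom[i] & p$normal$pos >= germ$start[i] &
        p$normal$pos < germ$end[i]
      expect_true(all(p$normal$value[idx] != 2))
      expect_true(all(p$normal$value[idx] == p$tumor$value[idx]))
    }
  }
  out <- p$normal[!(chrom == ev$chrom & pos >= ev$start & pos < ev$end)]
  expect_true(all(p$normal[chrom == ev$chrom & pos >= ev$start &
                             pos < ev$end]$value == 2))
})

test_that("NO_AMP tumors never exceed the threshold at sigma = 0", {
  cfg <- fast_sim_config(noise_sd = 0, polyploid_prob = 1, seed = 2)
  p <- simulate_pair(cfg, "NO_AMP", 3, default_annotation())
  expect_true(all(p$tumor$value < 4.8))
  expect_true(any(p$tumor$value >= 3))  # the polyploid gain is there
})

test_that("simulate_pair is deterministic given seed and config", {
  ann <- default_annotation()
  cfg <- fast_sim_config(seed = 1)
  a <- simulate_pair(cfg, "MULTI_WITHOUT_EGFR", 99, ann)
  b <- simulate_pair(cfg, "MULTI_WITHOUT_EGFR", 99, ann)
  expect_identical(a$tumor, b$tumor)
  expect_identical(a$events, b$events)
  expect_identical(a$clinical, b$clinical)
})

test_that("survival generator matches its configured medians", {
  cfg <- fast_sim_config(followup_range = c(Inf, Inf), seed = 1)
  set.seed(101)
  draws <- replicate(10000,
                     simulate_survival("NON_EGFR_SINGLE", cfg)$os_months)
  expect_lt(abs(median(draws) - 6) / 6, 0.10)
  evs <- replicate(200, simulate_survival("NO_AMP", cfg)$event)
  expect_true(all(evs == 1))  # infinite horizon: everything observed
  set.seed(7)
  s <- simulate_survival("NO_AMP", cfg)
  expect_gte(s$os_months, 1)
})

test_that("two-class survival separation is detectable by log-rank", {
  cfg <- fast_sim_config(followup_range = c(18, 84), seed = 1)
  set.seed(42)
  reject <- replicate(100, {
    a <- replicate(200, unlist(simulate_survival("EGFR_ONLY", cfg)))
    b <- replicate(200, unlist(simulate_survival("NON_EGFR_SINGLE", cfg)))
    d <- cbind(a, b)
    lr <- logrank_test(d["os_months", ], d["event", ],
                       rep(c("A", "B"), each = 200))
    lr$p < 0.01
  })
  expect_gte(mean(reject), 0.95)
})

test_that("simulate_cohort writes valid files and respects proportions", {
  cfg <- fast_sim_config(seed = 3)
  d <- file.path(tempdir(), "cohort0")
  co <- simulate_cohort(cfg, 0, dir = d)
  expect_equal(length(co$patients), 0)
  expect_true(file.exists(file.path(d, "clinical.tsv")))
  expect_error(sim_config(class_proportions = c(
    NO_AMP = 0.9, EGFR_ONLY = 0.2, NON_EGFR_SINGLE = 0.1,
    MULTI_WITH_EGFR = 0.1, MULTI_WITHOUT_EGFR = 0.1)), "sum to 1")
  co6 <- simulate_cohort(cfg, 6, keep_tracks = FALSE)
  expect_equal(length(co6$patients), 6)
  expect_true(all(co6$clinical$gap_class_true %in% gap_classes()))
  # truth table deterministic under a fixed seed
  co6b <- simulate_cohort(cfg, 6, keep_tracks = FALSE)
  expect_identical(co6$truth, co6b$truth)
})
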