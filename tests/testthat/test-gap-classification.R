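test_that("classify_gap implements the five-class rule exactly", {
  p <- function(arms, egfr) gap_profile("T", arms = arms,
                                        egfr_involved = egfr)
  expect_equal(classify_gap(p(character(), FALSE)), "NO_AMP")
  expect_equal(classify_gap(p("7p", TRUE)), "EGFR_ONLY")
  expect_equal(classify_gap(p("12q", FALSE)), "NON_EGFR_SINGLE")
  expect_equal(classify_gap(p(c("1q", "7p", "12q"), TRUE)),
               "MULTI_WITH_EGFR")
  expect_equal(classify_gap(p(c("4q", "12q"), FALSE)),
               "MULTI_WITHOUT_EGFR")
  # multiple bands on one arm are a single chromosomal region
  multi_band <- gap_profile("G46", arms = "12q",
                            bands = c("12q14.1", "12q15"),
                            egfr_involved = FALSE)
  expect_equal(multi_band$n_regions, 1)
  expect_equal(classify_gap(multi_band), "NON_EGFR_SINGLE")
})

test_that("build_profile aggregates amplicons and applies EGFR fallback", {
  expect_equal(build_profile(NULL, "T0")$n_regions, 0)
  amp <- data.table(chrom = c("7", "12"), start = c(54e6, 58e6),
                    end = c(56e6, 59e6), arm = c("7p", "12q"),
                    bands = c("7p11.2", "12q14.1"),
                    genes = c("EGFR,LANCL2", "CDK4"))
  pr <- build_profile(amp, "T1")
  expect_setequal(pr$arms, c("7p", "12q"))
  expect_true(pr$egfr_involved)
  expect_equal(pr$n_regions, 2)
  # no gene annotation: fall back to the 7p11.2 band
  amp2 <- copy(amp)[, genes := ""]
  expect_true(build_profile(amp2, "T2")$egfr_involved)
  amp3 <- copy(amp2)[, bands := c("7p12.1", "12q14.1")]
  expect_false(build_profile(amp3, "T3")$egfr_involved)
  # profile invariant: order of amplicons is irrelevant
  expect_equal(classify_gap(build_profile(amp[2:1], "T4")),
               classify_gap(pr))
})

test_that("risk_group pools favorable classes and is total", {
  expect_equal(risk_group("NO_AMP"), "FAVORABLE")
  expect_equal(risk_group("EGFR_ONLY"), "FAVORABLE")
  expect_equal(risk_group("MULTI_WITH_EGFR"), "FAVORABLE")
  expect_equal(risk_group("NON_EGFR_SINGLE"), "UNFAVORABLE")
  expect_equal(risk_group("MULTI_WITHOUT_EGFR"), "UNFAVORABLE")
  expect_error(risk_group("OTHER"))
})

test_that("classification partitions every generated profile", {
  set.seed(33)
  arms_pool <- c("1p", "1q", "4q", "7p", "7q", "11p", "12q", "17q")
  for (i in 1:50) {
    k <- sample(0:4, 1)
    arms <- sample(arms_pool, k)
    egfr <- "7p" %in% arms && runif(1) < 0.5
    cl <- classify_gap(gap_profile(paste0("T", i), arms = arms,
                                   egfr_involved = egfr))
    expect_true(cl %in% gap_classes())
    expect_true(risk_group(cl) %in% c("FAVORABLE", "UNFAVORABLE"))
  }
})

test_that("frequency tables count, sum and reject duplicates", {
  profs <- list(gap_profile("A", "7p", genes = c("EGFR", "LANCL2"),
                            egfr_involved = TRUE),
                gap_profile("B", "12q", genes = "CDK4",
                            egfr_involved = FALSE),
                gap_profile("C", egfr_involved = FALSE))
  tab <- cohort_frequency_table(profs)
  expect_equal(sum(tab$n), 3)
  expect_equal(tab[class == "EGFR_ONLY"]$n, 1)
  expect_equal(sum(tab$pct), 100)
  gf <- gene_frequency_table(profs)
  expect_equal(gf[gene == "EGFR"]$n, 1)
  expect_equal(gf[gene == "EGFR"]$pct, 50)  # 1 of 2 amplified tumors
  expect_error(cohort_frequency_table(c(profs, profs[1])), "duplicate")
  empty <- cohort_frequency_table(list())
  expect_equal(sum(empty$n), 0)
})

test_that("reference fixture reproduces the published class structure", {
  profs <- load_series1_profiles()
  expect_equal(length(profs), 80)
  tab <- cohort_frequency_table(profs)
  expect_equal(tab$n, c(35L, 17L, 10L, 13L, 5L))
  expect_equal(sum(vapply(profs, `[[`, TRUE, "egfr_involved")), 30)
  # group anchors called out in the source tables
  expect_equal(classify_gap(profs$G94), "EGFR_ONLY")
  expect_equal(classify_gap(profs$G46), "NON_EGFR_SINGLE")
  expect_equal(classify_gap(profs$G23), "MULTI_WITH_EGFR")
  expect_equal(classify_gap(profs$GBM13), "MULTI_WITHOUT_EGFR")
  expect_setequal(profs$G53$arms, c("7p", "7q"))
})
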