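sun_spec <- cohort_spec(c("sunitinib", "sutent"))

test_that("onset is event minus earliest full-precision start", {
  demo <- make_demo("1", event_dt = "20200301")
  drug <- make_drug("1")
  ther <- make_ther("1", "20200101")
  out <- compute_onset(demo, drug, ther, sun_spec)
  expect_equal(out$records$onset_days, 60L)
  expect_equal(nrow(out$excluded), 0L)

  # earliest of several linked starts wins; same-day onset is kept
  ther2 <- rbind(make_ther("1", "20200201"), make_ther("1", "20200301"))
  expect_equal(compute_onset(demo, drug, ther2, sun_spec)$records$onset_days,
               29L)
  demo0 <- make_demo("1", event_dt = "20200101")
  expect_equal(compute_onset(demo0, drug, ther, sun_spec)$records$onset_days,
               0L)
})

test_that("erroneous and undated onsets are excluded with reasons", {
  drug <- make_drug("1")
  ther <- make_ther("1", "20200101")
  # event precedes initiation
  neg <- compute_onset(make_demo("1", event_dt = "20191231"),
                       drug, ther, sun_spec)
  expect_equal(neg$excluded$reason, "negative")
  # year-month event precision is unknown time of onset
  ym <- compute_onset(make_demo("1", event_dt = "202003"),
                      drug, ther, sun_spec)
  expect_equal(ym$excluded$reason, "partial_date")
  # absent event / absent therapy start
  expect_equal(compute_onset(make_demo("1"), drug, ther,
                             sun_spec)$excluded$reason, "missing_event")
  expect_equal(compute_onset(make_demo("1", event_dt = "20200301"), drug,
                             make_ther(character(0), character(0)),
                             sun_spec)$excluded$reason, "missing_start")
  # partial start date only
  ps <- compute_onset(make_demo("1", event_dt = "20200301"), drug,
                      make_ther("1", "202001"), sun_spec)
  expect_equal(ps$excluded$reason, "partial_date")
})

test_that("therapy linkage prefers the cohort drug's sequence", {
  demo <- make_demo("1", event_dt = "20200301")
  drug <- rbind(make_drug("1", drug_seq = "2"),
                make_drug("1", drugname = "ASPIRIN", drug_seq = "1"))
  # seq 1 (aspirin) started much earlier; sunitinib is seq 2
  ther <- rbind(make_ther("1", "20190101", dsg_drug_seq = "1"),
                make_ther("1", "20200201", dsg_drug_seq = "2"))
  out <- compute_onset(demo, drug, ther, sun_spec)
  expect_equal(out$records$onset_days, 29L)
})

test_that("inclusion plus exclusions partition the cohort", {
  cfg <- generator_config(n_reports = 1500, seed = 21)
  sim <- generate_faers(cfg)
  demo <- data.table::rbindlist(lapply(sim$bundles, `[[`, "demo"))
  drug <- data.table::rbindlist(lapply(sim$bundles, `[[`, "drug"))
  ther <- data.table::rbindlist(lapply(sim$bundles, `[[`, "ther"))
  kept <- deduplicate_reports(demo)$kept
  cohort <- select_cohort(kept, drug, sun_spec)
  out <- compute_onset(kept, drug, ther, sun_spec, cohort = cohort)
  expect_equal(nrow(out$records) + nrow(out$excluded), length(cohort))
  expect_setequal(c(out$records$primaryid, out$excluded$primaryid), cohort)
  expect_true(all(out$records$onset_days >= 0))
})

test_that("shifting both dates by k days leaves onset unchanged", {
  demo <- make_demo(c("1", "2"), event_dt = c("20200301", "20200615"))
  drug <- make_drug(c("1", "2"))
  ther <- make_ther(c("1", "2"), c("20200101", "20200601"))
  base <- compute_onset(demo, drug, ther, sun_spec)$records$onset_days
  for (k in c(7, 100)) {
    shift <- function(x) format(as.Date(x, "%Y%m%d") + k, "%Y%m%d")
    demo_k <- make_demo(c("1", "2"),
                        event_dt = shift(c("20200301", "20200615")))
    ther_k <- make_ther(c("1", "2"), shift(c("20200101", "20200601")))
    expect_equal(compute_onset(demo_k, drug, ther_k,
                               sun_spec)$records$onset_days, base)
  }
})

test_that("onset summaries use interpolated quantiles and half-open bins", {
  s <- summarize_tto(c(10, 20, 30))
  expect_equal(s$median_days, 20)
  expect_equal(s$q1_days, 15)
  expect_equal(s$q3_days, 25)
  expect_equal(s$n, 3L)

  # all in the first month
  s1 <- summarize_tto(c(0, 5, 29))
  expect_equal(s1$bins$proportion[1], 1.0)
  # boundary day 30 falls in the second bin
  s2 <- summarize_tto(c(29, 30))
  expect_equal(s2$bins$count[1:2], c(1L, 1L))

  # singleton: quantiles equal the value
  s3 <- summarize_tto(51)
  expect_equal(c(s3$q1_days, s3$median_days, s3$q3_days), c(51, 51, 51))

  # permutation invariance, conservation, proportions sum to one
  set.seed(3)
  x <- sample(0:900, 400, replace = TRUE)
  sa <- summarize_tto(x)
  sb <- summarize_tto(sample(x))
  expect_equal(sa, sb)
  expect_equal(sum(sa$bins$count), sa$n)
  expect_equal(sum(sa$bins$proportion), 1, tolerance = 1e-9)

  # empty input yields the empty-summary marker
  s0 <- summarize_tto(integer(0))
  expect_equal(s0$n, 0L)
  expect_true(is.na(s0$median_days))
})
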