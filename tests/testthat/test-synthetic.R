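test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_reports = 500, seed = 77,
                          quarters = c("2020q1", "2020q2"))
  s1 <- generate_faers(cfg)
  s2 <- generate_faers(cfg)
  for (q in names(s1$bundles)) {
    for (tab in c("demo", "drug", "reac", "outc", "ther", "indi")) {
      expect_identical(as.data.frame(s1$bundles[[q]][[tab]]),
                       as.data.frame(s2$bundles[[q]][[tab]]))
    }
    expect_identical(s1$bundles[[q]]$deleted_caseids,
                     s2$bundles[[q]]$deleted_caseids)
  }
  expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))
  # a different seed actually changes the data
  s3 <- generate_faers(generator_config(n_reports = 500, seed = 78,
                                        quarters = c("2020q1", "2020q2")))
  expect_false(identical(as.data.frame(s1$bundles[[1]]$demo),
                         as.data.frame(s3$bundles[[1]]$demo)))
})

test_that("duplicates re-emit cases and dedup restores the case count", {
  cfg <- generator_config(n_reports = 1000, seed = 9, duplicate_frac = 0.1,
                          deletion_frac = 0)
  sim <- generate_faers(cfg)
  demo <- data.table::rbindlist(lapply(sim$bundles, `[[`, "demo"))
  expect_equal(nrow(demo), 1100L)
  expect_equal(attr(sim$truth, "n_duplicates"), 100L)
  dup_cases <- names(which(table(demo$caseid) == 2L))
  expect_length(dup_cases, 100L)
  # every revision carries a strictly later-or-equal FDA_DT and higher pid
  revs <- demo[demo$caseid %in% dup_cases]
  chk <- revs[, .(ok = partial_date_key(fda_dt)[2] >=
                    partial_date_key(fda_dt)[1] &&
                    as.numeric(primaryid[2]) > as.numeric(primaryid[1])),
              by = caseid]
  expect_true(all(chk$ok))
  kept <- deduplicate_reports(demo)$kept
  expect_equal(nrow(kept), 1000L)
  expect_equal(length(unique(kept$caseid)), 1000L)
})

test_that("deleted-case rosters list the configured fraction", {
  cfg <- generator_config(n_reports = 1000, seed = 10, deletion_frac = 0.05)
  sim <- generate_faers(cfg)
  deleted <- unique(unlist(lapply(sim$bundles, `[[`, "deleted_caseids")))
  expect_length(deleted, 50L)
  demo <- data.table::rbindlist(lapply(sim$bundles, `[[`, "demo"))
  kept <- apply_deletions(deduplicate_reports(demo)$kept, deleted)
  expect_equal(nrow(kept), 950L)
})

test_that("zero reports yield empty bundles and truth expectations", {
  sim <- generate_faers(generator_config(n_reports = 0, seed = 1))
  expect_length(sim$bundles, 0L)
  expect_true(all(sim$truth$expected_a == 0))
})

test_that("infeasible configurations fail validation", {
  expect_error(generator_config(drugs = data.frame(
    name = c("a", "b"), prevalence = c(0.6, 0.6))), "prevalence")
  expect_error(generator_config(planted = data.frame(
    drug = "sunitinib", pt = "Nonexistent", rr = 2)))
  expect_error(generator_config(planted = data.frame(
    drug = "sunitinib", pt = "Diarrhoea", rr = 50)), "exceeds 1")
})

test_that("expected tables follow the closed-form generative expectations", {
  cfg <- generator_config(
    n_reports = 50000, seed = 1, deletion_frac = 0, duplicate_frac = 0,
    drugs = data.frame(name = "sunitinib", prevalence = 0.5),
    pts = data.frame(pt = c("Target", "Common"),
                     soc = c("S1", "S2"),
                     baseline_prob = c(0.001, 0.05)),
    planted = data.frame(drug = "sunitinib", pt = "Target", rr = 10))
  tr_full <- generate_faers(cfg)$truth
  et <- expected_table(tr_full, "sunitinib", "Target")
  expect_equal(et$a, 50000 * 0.5 * 0.001 * 10)  # = 250
  expect_equal(et$a + et$b,
               sum(tr_full$expected_a[tr_full$drug == "sunitinib"]))

  # symmetric two-drug, two-PT null: expected ROR is exactly 1
  null_cfg <- generator_config(
    n_reports = 10000, seed = 2, deletion_frac = 0,
    drugs = data.frame(name = c("drugx", "drugy"),
                       prevalence = c(0.4, 0.4)),
    pts = data.frame(pt = c("P1", "P2"), soc = c("S1", "S2"),
                     baseline_prob = c(0.02, 0.02)),
    planted = data.frame(drug = character(0), pt = character(0),
                         rr = numeric(0)))
  tn <- generate_faers(null_cfg)$truth
  en <- expected_table(tn, "drugx", "P1")
  expect_equal((en$a * en$d) / (en$b * en$c), 1.0)
})

test_that("demographic draws track the configured marginals", {
  cfg <- generator_config(n_reports = 20000, seed = 4,
                          duplicate_frac = 0, deletion_frac = 0)
  sim <- generate_faers(cfg)
  demo <- data.table::rbindlist(lapply(sim$bundles, `[[`, "demo"))
  expect_equal(mean(demo$sex == "M"), 0.5935, tolerance = 0.03)
  yrs <- suppressWarnings(as.numeric(demo$age))
  expect_equal(mean(!is.na(yrs) & yrs >= 65), 0.3855, tolerance = 0.03)
  expect_equal(mean(demo$occr_country == "US"), 0.4887, tolerance = 0.03)
  expect_equal(mean(demo$occp_cod == "CN"), 0.3813, tolerance = 0.03)
})
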