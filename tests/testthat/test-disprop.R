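test_that("contingency cells count unique (report, term) pairs", {
  events <- data.table::data.table(
    primaryid = c("1", "1", "2", "3"),
    term = c("X", "Y", "X", "Z"))
  t1 <- build_contingency(events, cohort = "1", term = "X")
  expect_equal(unlist(t1[, c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_false(t1$degenerate)

  # cohort = everyone -> c = d = 0 -> degenerate
  t2 <- build_contingency(events, cohort = c("1", "2", "3"), term = "X")
  expect_equal(t2$c + t2$d, 0L)
  expect_true(t2$degenerate)

  # absent term -> a = c = 0 -> degenerate
  t3 <- build_contingency(events, cohort = "1", term = "Q")
  expect_equal(t3$a + t3$c, 0L)
  expect_true(t3$degenerate)

  # repeated pair counted once; term match is case-insensitive
  events2 <- rbind(events,
                   data.table::data.table(primaryid = "1", term = "x"))
  expect_equal(build_contingency(events2, "1", "X")$a, 1L)
})

test_that("marginal conservation holds across all tables at a level", {
  cfg <- generator_config(n_reports = 2000, seed = 13)
  sim <- generate_faers(cfg)
  reac <- data.table::rbindlist(lapply(sim$bundles, `[[`, "reac"))
  demo <- data.table::rbindlist(lapply(sim$bundles, `[[`, "demo"))
  kept <- deduplicate_reports(demo)$kept
  ev <- event_pairs(reac[reac$primaryid %in% kept$primaryid, ])
  cohort <- kept$primaryid[1:300]
  tabs <- contingency_tables(ev, cohort)
  cohort_pairs <- nrow(ev[ev$primaryid %in% cohort])
  expect_equal(sum(tabs$a), cohort_pairs)
  expect_true(all(tabs$a + tabs$b + tabs$c + tabs$d == nrow(ev)))
})

test_that("ROR, PRR/chi2, IC and EBGM match hand-computed values", {
  r <- compute_ror(10, 90, 100, 9900)
  expect_equal(r$ror, 11.0)
  expect_equal(r$ror_lo, 5.56, tolerance = 1e-3)
  expect_equal(r$ror_hi, 21.77, tolerance = 1e-3)
  expect_equal(compute_ror(5, 5, 5, 5)$ror, 1.0)

  p <- compute_prr(10, 90, 100, 9900)
  expect_equal(p$prr, 10.0)
  expect_equal(p$chi2, 74.45, tolerance = 1e-4)
  p0 <- compute_prr(1, 9, 10, 90)
  expect_equal(p0$prr, 1.0)
  expect_equal(p0$chi2, 0.0)

  ic <- compute_ic(10, 90, 100, 9900, mc_draws = 2000, seed = 1)
  expect_equal(ic$ic, log2(10 * 10100 / (110 * 100)))
  expect_equal(ic$ic, 3.199, tolerance = 1e-3)
  expect_equal(compute_ic(1, 9, 10, 90, mc_draws = 2000, seed = 1)$ic, 0)

  e <- compute_ebgm(10, 90, 100, 9900)
  expect_equal(e$ebgm, 9.1818, tolerance = 1e-4)
  expect_equal(compute_ebgm(1, 9, 10, 90)$ebgm, 1.0)
})

test_that("IC credible bound is seeded, reproducible, and below the point", {
  a <- c(10, 250); b <- c(90, 1000); cc <- c(100, 800); d <- c(9900, 50000)
  x1 <- compute_ic(a, b, cc, d, mc_draws = 5000, seed = 20240101)
  x2 <- compute_ic(a, b, cc, d, mc_draws = 5000, seed = 20240101)
  expect_identical(x1, x2)
  expect_true(all(x1$ic025 < x1$ic))
  # caller RNG state untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(compute_ic(10, 90, 100, 9900, mc_draws = 1000))
  expect_identical(runif(1), before)
})

test_that("all four estimators agree with an independent oracle", {
  tabs <- random_tables(1000, seed = 2024)
  r <- compute_ror(tabs$a, tabs$b, tabs$c, tabs$d)
  p <- compute_prr(tabs$a, tabs$b, tabs$c, tabs$d)
  ic <- compute_ic(tabs$a, tabs$b, tabs$c, tabs$d,
                   mc_draws = 1000, seed = 1)
  e <- compute_ebgm(tabs$a, tabs$b, tabs$c, tabs$d)
  for (i in seq_len(nrow(tabs))) {
    o <- oracle_stats(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(r$ror[i], o$ror, tolerance = 1e-9)
    expect_equal(r$ror_lo[i], o$ror_lo, tolerance = 1e-9)
    expect_equal(p$prr[i], o$prr, tolerance = 1e-9)
    expect_equal(p$chi2[i], o$chi2, tolerance = 1e-9)
    expect_equal(ic$ic[i], o$ic, tolerance = 1e-9)
    expect_equal(e$ebgm[i], o$ebgm, tolerance = 1e-9)
  }
})

test_that("EBGM equals 2^IC identically and orderings hold", {
  tabs <- random_tables(500, seed = 5)
  ic <- compute_ic(tabs$a, tabs$b, tabs$c, tabs$d, mc_draws = 1000)
  e <- compute_ebgm(tabs$a, tabs$b, tabs$c, tabs$d)
  p <- compute_prr(tabs$a, tabs$b, tabs$c, tabs$d)
  r <- compute_ror(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_equal(e$ebgm, 2^ic$ic, tolerance = 1e-9)
  up <- which(r$ror > 1)
  expect_true(all(r$ror[up] >= p$prr[up] - 1e-12))
  expect_true(all(p$prr[up] >= e$ebgm[up] - 1e-12))
  # independence tables (cells as products of margins): all three equal 1
  for (x in c(2L, 5L, 10L)) for (y in c(3L, 7L)) {
    tab <- c(x * y, x * (20 - y), (30 - x) * y, (30 - x) * (20 - y))
    expect_equal(compute_ror(tab[1], tab[2], tab[3], tab[4])$ror, 1.0)
    expect_equal(compute_prr(tab[1], tab[2], tab[3], tab[4])$prr, 1.0)
    expect_equal(compute_ebgm(tab[1], tab[2], tab[3], tab[4])$ebgm, 1.0)
  }
})

test_that("increasing a with b, c, d fixed strictly increases all four", {
  a_seq <- c(5, 10, 20, 40)
  vals <- lapply(a_seq, function(a) {
    c(ror = compute_ror(a, 500, 300, 50000)$ror,
      prr = compute_prr(a, 500, 300, 50000)$prr,
      ic = compute_ic(a, 500, 300, 50000, mc_draws = 1000)$ic,
      ebgm = compute_ebgm(a, 500, 300, 50000)$ebgm)
  })
  m <- do.call(rbind, vals)
  for (col in colnames(m)) expect_true(all(diff(m[, col]) > 0))
})

test_that("signal criteria apply the published thresholds", {
  row <- data.table::data.table(
    term = "Gastrointestinal disorders", a = 24452,
    ror = 2.27, ror_lo = 2.24, ror_hi = 2.30, prr = 2.04, chi2 = 1401.15,
    ic = 1.03, ic025 = 1.01, ebgm = 2.04, ebgm05 = 2.01)
  f <- evaluate_criteria(row)
  expect_true(f$ror_pos && f$prr_pos && f$bcpnn_pos && f$mgps_pos)
  expect_true(f$all_four)

  # N < 3 blocks ROR/PRR flags regardless of effect size
  small <- data.table::copy(row)[, a := 2]
  f2 <- evaluate_criteria(small)
  expect_false(f2$ror_pos)
  expect_false(f2$prr_pos)
  expect_false(f2$all_four)

  # IC025 = 0 fails the strict inequality
  zero <- data.table::copy(row)[, ic025 := 0]
  expect_false(evaluate_criteria(zero)$bcpnn_pos)

  # strict BCPNN additionally requires the PRR conditions
  weak_prr <- data.table::copy(row)[, prr := 1.5]
  expect_true(evaluate_criteria(weak_prr)$bcpnn_pos)
  expect_false(evaluate_criteria(weak_prr, bcpnn_strict = TRUE)$bcpnn_pos)

  # degenerate rows never flag
  deg <- data.table::copy(row)[, `:=`(degenerate = TRUE)]
  fd <- evaluate_criteria(deg)
  expect_false(any(unlist(fd[, c("ror_pos", "prr_pos", "bcpnn_pos",
                                 "mgps_pos", "all_four")])))
})

test_that("ranking filters to all-four signals with deterministic ties", {
  rows <- data.table::data.table(
    term = c("B", "A", "C", "D"),
    a = c(10L, 4L, 10L, 100L),
    ror = c(3, 9, 3, 5), ror_lo = 2, ror_hi = 9,
    prr = 3, chi2 = 100, ic = 1, ic025 = 0.5, ebgm = 3, ebgm05 = 2.5)
  rows <- evaluate_criteria(rows)
  rows$all_four[rows$term == "D"] <- FALSE   # a failed row never appears
  by_freq <- rank_signals(rows, by = "frequency")
  expect_equal(by_freq$term, c("B", "C", "A"))  # tie at a=10 -> term order
  by_ror <- rank_signals(rows, by = "ror")
  expect_equal(by_ror$term, c("A", "B", "C"))
  expect_false("D" %in% by_freq$term)
  # equal ror, unequal a: larger a first under ror ranking
  rows2 <- data.table::copy(rows)[term %in% c("B", "A")][, ror := 4]
  rows2$a <- c(10L, 4L)
  expect_equal(rank_signals(rows2, by = "ror")$term, c("B", "A"))
  expect_equal(nrow(rank_signals(rows, by = "ror", k = 2L)), 2L)
})

test_that("unexpected flag marks terms absent from the label list", {
  rows <- data.table::data.table(term = c("Thyroid atrophy", "Diarrhoea"))
  out <- flag_unexpected(rows, c("diarrhoea", "nausea"))
  expect_equal(out$unexpected, c(TRUE, FALSE))
  expect_warning(out2 <- flag_unexpected(rows, character(0)), "empty")
  expect_true(all(out2$unexpected))
})

test_that("degenerate tables are unscored unless continuity is requested", {
  events <- data.table::data.table(
    primaryid = c("1", "1", "2", "2", "3"),
    term = c("X", "Y", "Y", "Z", "Y"))
  sig <- signal_table(events, cohort = "1", mc_draws = 1000)
  xrow <- sig[sig$term == "X"]  # only the cohort reports X -> c = 0
  expect_true(xrow$degenerate)
  expect_true(is.na(xrow$ror))
  expect_false(xrow$all_four)
  sig2 <- signal_table(events, cohort = "1", mc_draws = 1000,
                       continuity = 0.5)
  xrow2 <- sig2[sig2$term == "X"]
  expect_false(xrow2$degenerate)
  expect_false(is.na(xrow2$ror))
})
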