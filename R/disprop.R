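# Disproportionality screening on 2x2 contingency tables.
#
# For one drug and one term the table is
#           term   other terms
#   drug      a        b
#   others    c        d
# where the counting unit is the unique (report, term) pair: a report
# contributes once per distinct PT, and once per distinct SOC at SOC level.
# The background is the whole curated database minus the cohort.

#' Unique (report, term) event pairs from reaction mentions
#'
#' @param reac REAC mentions (`primaryid`, `pt`) restricted to curated
#'   reports.
#' @param vocab optional [read_vocab()] table; required for `level = "SOC"`.
#' @param level `"PT"` or `"SOC"`.
#' @return data.table `(primaryid, term)`, unique pairs; PTs are trimmed, and
#'   matching is case-insensitive via an internal `term_key` column.
#' @export
event_pairs <- function(reac, vocab = NULL, level = c("PT", "SOC")) {
  level <- match.arg(level)
  reac <- data.table::as.data.table(reac)
  ev <- reac[, .(primaryid = primaryid, term = trimws(pt))]
  ev <- ev[nzchar(term)]
  if (level == "SOC") {
    if (is.null(vocab)) stop("SOC-level events need a vocabulary")
    ev[, term := map_pt_to_soc(term, vocab)]
  }
  ev[, term_key := tolower(term)]
  ev <- unique(ev, by = c("primaryid", "term_key"))
  ev[]
}

#' Build the 2x2 table for one term
#'
#' @param events unique (report, term) pairs over the full curated database
#'   at one level (see [event_pairs()]).
#' @param cohort character vector of cohort PRIMARYIDs.
#' @param term the target term.
#' @param level `"PT"` or `"SOC"` (annotation only).
#' @return one-row data.table `(term, level, a, b, c, d, degenerate)`.
#' @export
build_contingency <- function(events, cohort, term, level = "PT") {
  tabs <- contingency_tables(events, cohort, level = level)
  sel <- tolower(tabs$term) == tolower(term)
  hit <- tabs[sel]
  if (nrow(hit) == 0L) {
    drug_total <- length(intersect(unique(events$primaryid), cohort))
    n_total <- nrow(unique(data.table::as.data.table(events),
                           by = c("primaryid", "term")))
    hit <- data.table(term = term, level = level, a = 0L, b = drug_total,
                      c = 0L, d = n_total - drug_total, degenerate = TRUE)
  }
  hit[]
}

#' Build 2x2 tables for every term at a level
#'
#' Vectorised version of [build_contingency()]. A table is flagged
#' `degenerate` when any cell is zero (the estimators or the Woolf interval
#' would be undefined); statistics are skipped for degenerate tables unless a
#' continuity correction is applied downstream.
#'
#' @inheritParams build_contingency
#' @return data.table `(term, level, a, b, c, d, degenerate)`, one row per
#'   distinct term.
#' @export
contingency_tables <- function(events, cohort, level = "PT") {
  ev <- data.table::as.data.table(events)
  stopifnot(all(c("primaryid", "term") %in% names(ev)))
  if (!"term_key" %in% names(ev)) ev[, term_key := tolower(trimws(term))]
  ev <- unique(ev, by = c("primaryid", "term_key"))
  n_total <- nrow(ev)
  ev[, in_cohort := primaryid %chin% cohort]
  drug_total <- sum(ev$in_cohort)
  tabs <- ev[, .(term = term[1L], a = sum(in_cohort), term_total = .N),
             by = term_key]
  tabs[, `:=`(
    level = level,
    b = drug_total - a,
    c = term_total - a
  )]
  tabs[, d := n_total - a - b - c]
  tabs[, degenerate := a == 0L | b == 0L | c == 0L | d == 0L]
  data.table::setorder(tabs, term)
  tabs[, .(term, level, a, b, c, d, degenerate)]
}

#' @noRd
woolf_se <- function(a, b, c, d) sqrt(1 / a + 1 / b + 1 / c + 1 / d)

#' Reporting odds ratio with Woolf 95% CI
#'
#' `ROR = ad/bc`; `95% CI = exp(ln ROR -+ 1.96 * sqrt(1/a+1/b+1/c+1/d))`.
#'
#' @param a,b,c,d cell counts (vectorised).
#' @return data.table `(ror, ror_lo, ror_hi)`; `NA` where undefined
#'   (`b == 0` or `c == 0`, or a zero cell for the interval).
#' @export
compute_ror <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  ror <- (a * d) / (b * c)
  ror[b == 0 | c == 0] <- NA_real_
  s <- woolf_se(a, b, c, d)
  s[a == 0 | b == 0 | c == 0 | d == 0] <- NA_real_
  data.table(ror = ror,
             ror_lo = exp(log(ror) - 1.96 * s),
             ror_hi = exp(log(ror) + 1.96 * s))
}

#' Proportional reporting ratio with Pearson chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-squared statistic is the classical
#' Pearson statistic `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, no continuity
#' correction.
#'
#' @inheritParams compute_ror
#' @return data.table `(prr, chi2)`.
#' @export
compute_prr <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  prr <- (a / (a + b)) / (c / (c + d))
  prr[(a + b) == 0 | c == 0] <- NA_real_
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- n * (a * d - b * c)^2 / denom
  chi2[denom == 0] <- NA_real_
  data.table(prr = prr, chi2 = chi2)
}

#' BCPNN information component with Monte-Carlo credible lower bound
#'
#' The point estimate is the observed-over-expected reporting ratio on the
#' log2 scale, `IC = log2(a N / ((a+c)(a+b)))`. The lower bound `IC025` is
#' the 2.5% quantile of `log2(lambda / E)` where `lambda ~ Gamma(a + 1/2, 1)`
#' and `E = (a+b)(a+c)/N + 1/(2N)`, a seeded Monte-Carlo approximation to the
#' Bayesian credible interval of the BCPNN formulation.
#'
#' @inheritParams compute_ror
#' @param mc_draws Monte-Carlo draws per table (default 1e5).
#' @param seed RNG seed for the draws (caller RNG state is preserved).
#' @return data.table `(ic, ic025)`.
#' @export
compute_ic <- function(a, b, c, d, mc_draws = 1e5, seed = 20240101) {
  stopifnot(mc_draws >= 1000)
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  ic <- log2(a * n / ((a + c) * (a + b)))
  ic[(a + b) == 0 | (a + c) == 0] <- NA_real_
  e_count <- (a + b) * (a + c) / n + 0.5 / n
  ic025 <- rep(NA_real_, length(a))
  with_seed(seed, {
    for (i in seq_along(a)) {
      if (is.na(ic[i])) next
      lam <- rgamma(mc_draws, shape = a[i] + 0.5, rate = 1)
      ic025[i] <- log2(quantile(lam, 0.025, names = FALSE) / e_count[i])
    }
  })
  data.table(ic = ic, ic025 = ic025)
}

#' Empirical Bayes geometric mean (unshrunk) with Woolf-type lower bound
#'
#' As tabulated in common FAERS screens alongside the IC, the statistic is
#' the relative reporting ratio `EBGM = a N / ((a+c)(a+b))` (identically
#' `2^IC`), with `EBGM05 = exp(ln EBGM - 1.96 * sqrt(1/a+1/b+1/c+1/d))`.
#' Full gamma-Poisson-mixture shrinkage is deliberately not applied.
#'
#' @inheritParams compute_ror
#' @return data.table `(ebgm, ebgm05, ebgm95)`.
#' @export
compute_ebgm <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  ebgm <- a * n / ((a + c) * (a + b))
  ebgm[(a + b) == 0 | (a + c) == 0] <- NA_real_
  s <- woolf_se(a, b, c, d)
  s[a == 0 | b == 0 | c == 0 | d == 0] <- NA_real_
  data.table(ebgm = ebgm,
             ebgm05 = exp(log(ebgm) - 1.96 * s),
             ebgm95 = exp(log(ebgm) + 1.96 * s))
}

#' Apply the four signal criteria
#'
#' * ROR: CI lower bound > 1 and N >= 3 (N = a).
#' * PRR: PRR >= 2, chi-squared >= 4, N >= 3.
#' * BCPNN: IC025 > 0 (strict); with `bcpnn_strict` the PRR conditions are
#'   additionally required.
#' * MGPS: EBGM05 > 2 and N > 0.
#'
#' Degenerate rows get all flags `FALSE`.
#'
#' @param rows data.table with columns `a`, `ror_lo`, `prr`, `chi2`,
#'   `ic025`, `ebgm05` (and optionally `degenerate`).
#' @param bcpnn_strict require the PRR conditions for the BCPNN flag too.
#' @return `rows` with logical columns `ror_pos`, `prr_pos`, `bcpnn_pos`,
#'   `mgps_pos`, `all_four` added (by reference on a copy).
#' @export
evaluate_criteria <- function(rows, bcpnn_strict = FALSE) {
  rows <- data.table::as.data.table(data.table::copy(rows))
  deg <- if ("degenerate" %in% names(rows)) rows$degenerate else FALSE
  ok <- function(x) !is.na(x) & x
  rows[, ror_pos := ok(ror_lo > 1 & a >= 3) & !deg]
  rows[, prr_pos := ok(prr >= 2 & chi2 >= 4 & a >= 3) & !deg]
  bc <- ok(rows$ic025 > 0)
  if (bcpnn_strict) bc <- bc & rows$prr_pos
  rows[, bcpnn_pos := bc & !deg]
  rows[, mgps_pos := ok(ebgm05 > 2 & a > 0) & !deg]
  rows[, all_four := ror_pos & prr_pos & bcpnn_pos & mgps_pos]
  rows[]
}

#' Full signal table for one level
#'
#' Builds every contingency table, computes the four estimators with their
#' intervals, applies the criteria, and (at PT level, when a vocabulary is
#' given) annotates each PT with its SOC.
#'
#' @inheritParams build_contingency
#' @param vocab optional [read_vocab()] table.
#' @param mc_draws,seed passed to [compute_ic()].
#' @param continuity additive continuity correction (e.g. 0.5) applied to all
#'   four cells of tables with a zero cell; default 0 (such tables stay
#'   degenerate and unscored).
#' @param bcpnn_strict passed to [evaluate_criteria()].
#' @return data.table, one row per term: counts, `ror/ror_lo/ror_hi`,
#'   `prr/chi2`, `ic/ic025`, `ebgm/ebgm05/ebgm95`, criteria flags.
#' @export
signal_table <- function(events, cohort, level = "PT", vocab = NULL,
                         mc_draws = 1e5, seed = 20240101,
                         continuity = 0, bcpnn_strict = FALSE) {
  tabs <- contingency_tables(events, cohort, level = level)
  if (nrow(tabs) == 0L) return(tabs)
  a <- as.numeric(tabs$a); b <- as.numeric(tabs$b)
  c_ <- as.numeric(tabs$c); d <- as.numeric(tabs$d)
  if (continuity > 0) {
    zero <- tabs$degenerate
    a[zero] <- a[zero] + continuity; b[zero] <- b[zero] + continuity
    c_[zero] <- c_[zero] + continuity; d[zero] <- d[zero] + continuity
    # every corrected cell is now positive, so nothing stays degenerate
    data.table::set(tabs, j = "degenerate", value = FALSE)
  }
  stats <- cbind(compute_ror(a, b, c_, d), compute_prr(a, b, c_, d),
                 compute_ic(a, b, c_, d, mc_draws = mc_draws, seed = seed),
                 compute_ebgm(a, b, c_, d))
  out <- cbind(tabs, stats)
  deg <- out$degenerate
  num_cols <- c("ror", "ror_lo", "ror_hi", "prr", "chi2", "ic", "ic025",
                "ebgm", "ebgm05", "ebgm95")
  for (col in num_cols) out[deg == TRUE, (col) := NA_real_]
  out <- evaluate_criteria(out, bcpnn_strict = bcpnn_strict)
  if (level == "PT" && !is.null(vocab)) {
    out[, soc := map_pt_to_soc(term, vocab)]
    data.table::setcolorder(out, c("term", "soc"))
  }
  out[]
}

#' Rank signal rows the way published screens tabulate them
#'
#' Keeps only rows meeting all four criteria, sorts descending by report
#' count (`by = "frequency"`) or by ROR (`by = "ror"`), breaks ties by the
#' other key (descending) then term (ascending), and returns the top `k`.
#'
#' @param rows a [signal_table()] result.
#' @param by `"frequency"` or `"ror"`.
#' @param k how many rows to keep (default 50).
#' @return the ranked subset.
#' @export
rank_signals <- function(rows, by = c("frequency", "ror"), k = 50L) {
  by <- match.arg(by)
  rows <- data.table::as.data.table(rows)
  sel <- rows[all_four == TRUE]
  if (by == "frequency") {
    data.table::setorder(sel, -a, -ror, term)
  } else {
    data.table::setorder(sel, -ror, -a, term)
  }
  head(sel, k)
}

#' Flag terms absent from the drug label as unexpected
#'
#' @param rows a [signal_table()] result.
#' @param label_terms character vector of labelled PTs (case-insensitive);
#'   an empty set flags everything unexpected, with a warning.
#' @return `rows` with a logical `unexpected` column.
#' @export
flag_unexpected <- function(rows, label_terms) {
  rows <- data.table::as.data.table(data.table::copy(rows))
  label_terms <- tolower(trimws(as.character(label_terms)))
  label_terms <- label_terms[nzchar(label_terms)]
  if (length(label_terms) == 0L) {
    warning("empty label-term set: every term will be flagged unexpected")
  }
  rows[, unexpected := !(tolower(trimws(term)) %in% label_terms)]
  rows[]
}

#' Read a label-term file (one PT per line, UTF-8)
#' @param path file path.
#' @return character vector of PTs.
#' @export
read_label_terms <- function(path) {
  x <- trimws(read_lines_enc(path))
  x[nzchar(x)]
}
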