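# End-to-end driver: ingest -> curate -> signals -> time-to-onset ->
# descriptive outputs, with stage-count accounting and deterministic TSVs.

#' Pipeline configuration
#'
#' @param input_dirs character vector of quarter directories (one bundle
#'   each).
#' @param vocab_path PT -> SOC vocabulary TSV.
#' @param out_dir output directory for the TSV artifacts.
#' @param cohort a [cohort_spec()].
#' @param label_terms_path optional label PT list (one per line) for the
#'   unexpected-AE flag.
#' @param bcpnn_strict,continuity,mc_draws,seed,bin_edges tuning knobs passed
#'   through to the screening and onset stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dirs, vocab_path, out_dir,
                            cohort = cohort_spec(c("sunitinib", "sutent")),
                            label_terms_path = NULL,
                            bcpnn_strict = FALSE, continuity = 0,
                            mc_draws = 1e5, seed = 20240101,
                            bin_edges = default_bin_edges()) {
  stopifnot(length(input_dirs) >= 1L, inherits(cohort, "cohort_spec"),
            mc_draws >= 1000, continuity >= 0)
  structure(list(input_dirs = input_dirs, vocab_path = vocab_path,
                 out_dir = out_dir, cohort = cohort,
                 label_terms_path = label_terms_path,
                 bcpnn_strict = isTRUE(bcpnn_strict),
                 continuity = continuity, mc_draws = mc_draws,
                 seed = as.integer(seed), bin_edges = bin_edges),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys mirror the [pipeline_config()] arguments; `cohort` is a
#' mapping with `names`, and optional `role_codes` / `match_fields`.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  co <- y$cohort %||% list(names = c("sunitinib", "sutent"))
  pipeline_config(
    input_dirs = unlist(y$input_dirs),
    vocab_path = y$vocab_path,
    out_dir = y$out_dir,
    cohort = cohort_spec(unlist(co$names),
                         role_codes = unlist(co$role_codes) %||% "PS",
                         match_fields = unlist(co$match_fields) %||%
                           c("drugname", "prod_ai")),
    label_terms_path = y$label_terms_path,
    bcpnn_strict = y$bcpnn_strict %||% FALSE,
    continuity = y$continuity %||% 0,
    mc_draws = y$mc_draws %||% 1e5,
    seed = y$seed %||% 20240101,
    bin_edges = unlist(y$bin_edges) %||% default_bin_edges()
  )
}

#' @noRd
age_in_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  f <- data.table::fcase(
    age_cod == "MON", 1 / 12,
    age_cod == "WK", 1 / 52.18,
    age_cod == "DY", 1 / 365.25,
    age_cod == "HR", 1 / 8766,
    age_cod == "DEC", 10,
    default = 1  # YR and unspecified
  )
  a * f
}

#' Descriptive demographics of a cohort
#'
#' Tabulates sex, age bands (<18, 18-44, 45-64, >=65, unknown; ages
#' normalised to years from the AGE_COD unit first), serious outcomes (each
#' outcome code counted once per report), top-5 reporting countries,
#' reporter occupations, top-5 indications, and reports per FDA-receipt
#' year. Percentages use the total cohort-report denominator, rendered to
#' two decimals.
#'
#' @param demo cohort DEMO rows (deduplicated).
#' @param outc,indi outcome and indication mentions (filtered to the cohort
#'   internally).
#' @param denominator percentage denominator (default `nrow(demo)`).
#' @return data.table `(section, category, count, pct)`.
#' @export
summarize_demographics <- function(demo, outc = NULL, indi = NULL,
                                   denominator = nrow(demo)) {
  demo <- data.table::as.data.table(demo)
  n <- nrow(demo)
  rows <- list(data.table(section = "totals", category = "cohort_reports",
                          count = n, pct = pct2(n, denominator)))

  add_section <- function(section, counts) {
    if (length(counts) == 0L) {
      return(data.table(section = character(0), category = character(0),
                        count = integer(0), pct = numeric(0)))
    }
    data.table(section = section, category = names(counts),
               count = as.integer(counts),
               pct = pct2(as.integer(counts), denominator))
  }

  sex <- toupper(demo$sex)
  sex[!sex %in% c("M", "F")] <- "UNK"
  rows <- c(rows, list(add_section("sex", table(factor(
    sex, levels = c("M", "F", "UNK"))))))

  yrs <- age_in_years(demo$age, toupper(demo$age_cod))
  band <- cut(yrs, breaks = c(-Inf, 18, 45, 65, Inf), right = FALSE,
              labels = c("<18", "18-44", "45-64", ">=65"))
  band <- as.character(band)
  band[is.na(band)] <- "unknown"
  rows <- c(rows, list(add_section("age_band", table(factor(
    band, levels = c("<18", "18-44", "45-64", ">=65", "unknown"))))))

  if (!is.null(outc)) {
    oc <- data.table::as.data.table(outc)[primaryid %chin% demo$primaryid]
    oc <- unique(oc, by = c("primaryid", "outc_cod"))
    rows <- c(rows, list(add_section("outcome", table(factor(
      oc$outc_cod, levels = FAERS_OUTCOME_CODES)))))
  }

  ctry <- demo$occr_country
  ctry <- ctry[!is.na(ctry) & nzchar(ctry)]
  top_c <- sort(table(ctry), decreasing = TRUE)
  rows <- c(rows, list(add_section("country_top5", head(top_c, 5))))

  occ <- toupper(demo$occp_cod)
  occ[!occ %in% FAERS_OCCP_CODES] <- "missing"
  rows <- c(rows, list(add_section("reporter", table(factor(
    occ, levels = c(FAERS_OCCP_CODES, "missing"))))))

  if (!is.null(indi)) {
    ind <- data.table::as.data.table(indi)[primaryid %chin% demo$primaryid]
    ind <- unique(ind, by = c("primaryid", "indi_pt"))
    top_i <- sort(table(ind$indi_pt), decreasing = TRUE)
    rows <- c(rows, list(add_section("indication_top5", head(top_i, 5))))
  }

  yr <- parse_partial_date(demo$fda_dt)$year
  yr_tab <- table(yr)
  rows <- c(rows, list(add_section("reports_per_year", yr_tab)))

  data.table::rbindlist(rows)
}

#' @noRd
round_signal_columns <- function(dt) {
  dt <- data.table::copy(dt)
  num_cols <- intersect(c("ror", "ror_lo", "ror_hi", "prr", "chi2", "ic",
                          "ic025", "ebgm", "ebgm05", "ebgm95"), names(dt))
  for (col in num_cols) {
    dt[, (paste0(col, "_full")) := get(col)]
    dt[, (col) := round(get(col), 2)]
  }
  dt
}

#' Run the full pipeline
#'
#' Ingests every quarter, deduplicates, applies deleted-case rosters,
#' selects the cohort, computes PT- and SOC-level signal tables with the
#' frequency and ROR rankings, time-to-onset summaries, and descriptive
#' demographics, and writes deterministic TSV artifacts plus a run log with
#' stage-by-stage row accounting.
#'
#' @param config a [pipeline_config()].
#' @param verbose log progress to stderr.
#' @return invisibly, a list with all in-memory results (`status`, `curation`,
#'   `signals_pt`, `signals_soc`, `ranked_frequency`, `ranked_ror`, `tto`,
#'   `descriptive`, ...). `status` is `"ok"`, or `"warning"` when the cohort
#'   is empty (descriptive outputs only).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    log_msg(msg, verbose = verbose)
  }
  say("faersig pipeline | seed=%d | %d quarter dir(s)",
      config$seed, length(config$input_dirs))

  bundles <- lapply(config$input_dirs, parse_quarter)
  demo <- data.table::rbindlist(lapply(bundles, `[[`, "demo"))
  drug <- data.table::rbindlist(lapply(bundles, `[[`, "drug"))
  reac <- data.table::rbindlist(lapply(bundles, `[[`, "reac"))
  outc <- data.table::rbindlist(lapply(bundles, `[[`, "outc"))
  ther <- data.table::rbindlist(lapply(bundles, `[[`, "ther"))
  indi <- data.table::rbindlist(lapply(bundles, `[[`, "indi"))
  deleted <- unique(unlist(lapply(bundles, `[[`, "deleted_caseids")))
  parse_report <- data.table::rbindlist(
    lapply(bundles, `[[`, "parse_report"))[
      , lapply(.SD, sum), by = table]
  say("parsed: %d demo rows, %d drug rows, %d reac rows; %d dropped",
      nrow(demo), nrow(drug), nrow(reac), sum(parse_report$rows_dropped))

  dd <- deduplicate_reports(demo)
  say("dedup: %d raw -> %d distinct cases (%d duplicates removed)",
      nrow(demo), nrow(dd$kept), nrow(demo) - nrow(dd$kept))
  kept <- apply_deletions(dd$kept, deleted)
  say("deletions: %d removed (%d roster ids unmatched), %d cases remain",
      attr(kept, "n_removed"), attr(kept, "n_unmatched"), nrow(kept))

  cohort <- tryCatch(select_cohort(kept, drug, config$cohort),
                     warning = function(w) character(0))
  say("cohort: %d reports", length(cohort))

  curation <- data.table(
    caseids_in = length(unique(demo$caseid)),
    duplicates_removed = nrow(demo) - nrow(dd$kept),
    deletions_applied = attr(kept, "n_removed"),
    cohort_size = length(cohort)
  )
  write_table(curation, file.path(config$out_dir, "curation_report.tsv"))
  write_table(parse_report, file.path(config$out_dir, "parse_report.tsv"))

  demo_cohort <- kept[primaryid %chin% cohort]
  descriptive <- summarize_demographics(demo_cohort, outc, indi)
  write_table(descriptive,
              file.path(config$out_dir, "descriptive_summary.tsv"))

  out <- list(status = "ok", curation = curation,
              parse_report = parse_report, descriptive = descriptive,
              cohort = cohort, demo_kept = kept)

  if (length(cohort) == 0L) {
    say("empty cohort: descriptive outputs only")
    out$status <- "warning"
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
    warning("empty cohort; signal and onset stages skipped")
    return(invisible(out))
  }

  vocab <- read_vocab(config$vocab_path)
  reac_kept <- reac[primaryid %chin% kept$primaryid]
  ev_pt <- event_pairs(reac_kept, level = "PT")
  ev_soc <- event_pairs(reac_kept, vocab = vocab, level = "SOC")

  sig_pt <- signal_table(ev_pt, cohort, level = "PT", vocab = vocab,
                         mc_draws = config$mc_draws, seed = config$seed,
                         continuity = config$continuity,
                         bcpnn_strict = config$bcpnn_strict)
  sig_soc <- signal_table(ev_soc, cohort, level = "SOC",
                          mc_draws = config$mc_draws, seed = config$seed,
                          continuity = config$continuity,
                          bcpnn_strict = config$bcpnn_strict)
  if (!is.null(config$label_terms_path)) {
    label_terms <- read_label_terms(config$label_terms_path)
    sig_pt <- flag_unexpected(sig_pt, label_terms)
  }
  say("signals: %d PTs (%d all-four), %d SOCs (%d all-four)",
      nrow(sig_pt), sum(sig_pt$all_four), nrow(sig_soc),
      sum(sig_soc$all_four))

  write_table(round_signal_columns(sig_pt),
              file.path(config$out_dir, "signals_pt.tsv"))
  write_table(round_signal_columns(sig_soc),
              file.path(config$out_dir, "signals_soc.tsv"))
  ranked_f <- rank_signals(sig_pt, by = "frequency")
  ranked_r <- rank_signals(sig_pt, by = "ror")
  write_table(round_signal_columns(ranked_f),
              file.path(config$out_dir, "ranked_by_frequency.tsv"))
  write_table(round_signal_columns(ranked_r),
              file.path(config$out_dir, "ranked_by_ror.tsv"))

  onset <- compute_onset(demo_cohort, drug, ther, config$cohort,
                         cohort = cohort)
  tto <- summarize_tto(onset$records, bin_edges = config$bin_edges)
  say("onset: %d usable, %d excluded (%s)",
      nrow(onset$records), nrow(onset$excluded),
      paste(sprintf("%s=%d", names(table(onset$excluded$reason)),
                    table(onset$excluded$reason)), collapse = ", "))
  write_table(data.table(n = tto$n, mean_days = tto$mean_days,
                         median_days = tto$median_days,
                         q1_days = tto$q1_days, q3_days = tto$q3_days),
              file.path(config$out_dir, "tto_summary.tsv"))
  write_table(tto$bins, file.path(config$out_dir, "tto_bins.tsv"))

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  out <- c(out, list(signals_pt = sig_pt, signals_soc = sig_soc,
                     ranked_frequency = ranked_f, ranked_ror = ranked_r,
                     onset = onset, tto = tto))
  invisible(out)
}

#' Simulate bundles to disk for the CLI and examples
#'
#' Generates a synthetic multi-quarter dataset and writes each quarter in the
#' FAERS ASCII dialect under `dir/<quarter_id>/`, plus the ground-truth table
#' as `truth.tsv`.
#'
#' @param config a [generator_config()].
#' @param dir output directory.
#' @return invisibly, the vector of quarter directories.
#' @export
simulate_to_dir <- function(config, dir) {
  sim <- generate_faers(config)
  dirs <- vapply(sim$bundles, function(b) {
    d <- file.path(dir, b$quarter_id)
    write_quarter(b, d)
    d
  }, character(1))
  write_table(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dirs)
}
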