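# Time to onset: days from therapy initiation to adverse-event occurrence.
# Only full-precision (8-digit) dates qualify; records whose event precedes
# initiation are treated as erroneous and excluded. Same-day onset (0 days)
# is kept: only strictly negative differences are erroneous.

#' Compute onset days for a cohort
#'
#' For each cohort report: onset = event date minus the earliest eligible
#' full-precision therapy start date. Eligible THER rows are those whose
#' `dsg_drug_seq` matches a cohort-drug DRUG row's `drug_seq` for the same
#' report; when sequence linkage is unavailable (either side missing), every
#' THER row of the report is eligible.
#'
#' Exclusion reasons: `missing_event` (no event date), `missing_start` (no
#' therapy row / start date), `partial_date` (event or all candidate starts
#' below day precision), `negative` (event precedes initiation).
#'
#' @param demo cohort DEMO rows (deduplicated; needs `primaryid`,
#'   `event_dt`).
#' @param drug DRUG mentions for the curated database.
#' @param ther THER mentions.
#' @param spec the [cohort_spec()] identifying the cohort drug rows.
#' @param cohort character vector of cohort PRIMARYIDs (defaults to every id
#'   in `demo`).
#' @return list with `records` (data.table `primaryid`, `onset_days`) and
#'   `excluded` (data.table `primaryid`, `reason`); the two partition the
#'   cohort.
#' @export
compute_onset <- function(demo, drug, ther, spec,
                          cohort = unique(demo$primaryid)) {
  demo <- data.table::as.data.table(demo)
  ther <- data.table::as.data.table(ther)
  demo <- demo[primaryid %chin% cohort]

  ev <- parse_partial_date(demo$event_dt)
  event_date <- full_date(demo$event_dt)
  event_present <- !is.na(ev$precision)
  event_full <- !is.na(ev$precision) & ev$precision == "YMD"

  # candidate start dates per report
  matched <- drug_rows_matching(drug, spec)
  has_seq <- "drug_seq" %in% names(matched) && "dsg_drug_seq" %in% names(ther)
  ther_c <- ther[primaryid %chin% cohort]
  if (has_seq) {
    seq_ok <- !is.na(matched$drug_seq) & nzchar(matched$drug_seq)
    keys <- unique(matched[seq_ok, .(primaryid, drug_seq)])
    linked <- ther_c[!is.na(dsg_drug_seq) & nzchar(dsg_drug_seq)][
      keys, on = c(primaryid = "primaryid", dsg_drug_seq = "drug_seq"),
      nomatch = NULL]
    # reports with no sequence-linked row fall back to all their THER rows
    unlinked_ids <- setdiff(unique(ther_c$primaryid), unique(linked$primaryid))
    cand <- rbind(linked, ther_c[primaryid %chin% unlinked_ids],
                  fill = TRUE)
  } else {
    cand <- ther_c
  }
  if (nrow(cand)) {
    sp <- parse_partial_date(cand$start_dt)
    cand[, `:=`(start_date = full_date(start_dt),
                start_present = !is.na(sp$precision),
                start_full = !is.na(sp$precision) & sp$precision == "YMD")]
    starts <- cand[, .(
      any_start = any(start_present),
      start = if (any(start_full)) min(start_date[start_full]) else
        as.Date(NA)
    ), by = primaryid]
  } else {
    starts <- data.table(primaryid = character(0), any_start = logical(0),
                         start = as.Date(character(0)))
  }

  res <- data.table(primaryid = demo$primaryid,
                    event_present = event_present,
                    event_full = event_full,
                    event_date = event_date)
  res <- starts[res, on = "primaryid"]
  res[is.na(any_start), any_start := FALSE]

  res[, reason := data.table::fcase(
    !event_present, "missing_event",
    !any_start, "missing_start",
    !event_full | is.na(start), "partial_date",
    as.integer(event_date - start) < 0L, "negative",
    default = NA_character_
  )]
  res[, onset_days := data.table::fifelse(
    is.na(reason), as.integer(event_date - start), NA_integer_)]

  list(
    records = res[is.na(reason), .(primaryid, onset_days)],
    excluded = res[!is.na(reason), .(primaryid, reason)]
  )
}

#' @noRd
default_bin_edges <- function() c(0, 30, 60, 90, 120, 150, 180, 360, Inf)

#' @noRd
bin_labels <- function(edges) {
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  ifelse(is.infinite(hi), paste0(">=", lo),
         paste0(lo, "-", hi - 1))
}

#' Summarise onset times
#'
#' Median and quartiles use linear interpolation between order statistics
#' (R's default quantile type 7). Bins are half-open `[lo, hi)` on day
#' counts; the defaults are 30-day months up to 180 days, then 180--359, then
#' ">= 360" ("after one year" under the 30-day-month convention).
#'
#' @param onset_days integer vector of onset days (>= 0), or the `records`
#'   table from [compute_onset()].
#' @param bin_edges increasing numeric vector of bin edges starting at 0 and
#'   ending at `Inf`.
#' @return a `tto_summary` list: `n`, `mean_days`, `median_days`, `q1_days`,
#'   `q3_days`, and `bins` (data.table `label`, `count`, `proportion`).
#'   Empty input yields `n = 0` with `NA` summaries and zero-count bins.
#' @export
summarize_tto <- function(onset_days, bin_edges = default_bin_edges()) {
  if (is.data.frame(onset_days)) onset_days <- onset_days$onset_days
  onset_days <- as.numeric(onset_days)
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges),
            is.infinite(bin_edges[length(bin_edges)]))
  stopifnot(all(onset_days >= 0, na.rm = TRUE))
  onset_days <- onset_days[!is.na(onset_days)]
  n <- length(onset_days)
  labels <- bin_labels(bin_edges)
  if (n == 0L) {
    bins <- data.table(label = labels, count = 0L, proportion = NA_real_)
    out <- list(n = 0L, mean_days = NA_real_, median_days = NA_real_,
                q1_days = NA_real_, q3_days = NA_real_, bins = bins)
    return(structure(out, class = "tto_summary"))
  }
  q <- quantile(onset_days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  idx <- findInterval(onset_days, bin_edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(labels))
  bins <- data.table(label = labels, count = counts,
                     proportion = counts / n)
  structure(list(n = n, mean_days = mean(onset_days), median_days = q[2],
                 q1_days = q[1], q3_days = q[3], bins = bins),
            class = "tto_summary")
}

#' @export
print.tto_summary <- function(x, ...) {
  cat("<tto_summary> n =", x$n, "\n")
  if (x$n > 0) {
    cat(sprintf("  mean %.1f d, median %.1f d (IQR %.1f-%.1f)\n",
                x$mean_days, x$median_days, x$q1_days, x$q3_days))
    for (i in seq_len(nrow(x$bins))) {
      cat(sprintf("  %-8s %6d  %6.2f%%\n", x$bins$label[i],
                  x$bins$count[i], 100 * x$bins$proportion[i]))
    }
  }
  invisible(x)
}
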