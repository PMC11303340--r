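# Case-level curation: the FDA-recommended dedup rule, deleted-case removal,
# primary-suspect cohort selection, and PT -> SOC vocabulary lookup.

#' Deduplicate DEMO records by CASEID
#'
#' FAERS distributes every revision of a case; the FDA-recommended rule keeps,
#' per CASEID, the record with the highest FDA_DT, breaking ties by the
#' highest PRIMARYID. PRIMARYID comparison is numeric when the id parses as a
#' number (FAERS practice), else lexicographic. FDA_DT ordering uses the
#' (year, month-or-0, day-or-0) key, so a partial date sorts before any fuller
#' date in the same month.
#'
#' @param demo data.table of DEMO records (`primaryid`, `caseid`, `fda_dt`
#'   required).
#' @return list with `kept` (one row per distinct CASEID, original columns)
#'   and `decisions` (`caseid`, `kept_primaryid`, `discarded_primaryids`
#'   semicolon-joined, `n_discarded`).
#' @export
deduplicate_reports <- function(demo) {
  demo <- data.table::as.data.table(demo)
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  if (nrow(demo) == 0L) {
    return(list(kept = demo,
                decisions = data.table(caseid = character(0),
                                       kept_primaryid = character(0),
                                       discarded_primaryids = character(0),
                                       n_discarded = integer(0))))
  }
  work <- data.table::copy(demo)
  work[, fda_key := partial_date_key(fda_dt)]
  work[, pid_num := suppressWarnings(as.numeric(primaryid))]
  data.table::setorder(work, caseid, fda_key, pid_num, primaryid,
                       na.last = FALSE)
  work[, keep_flag := seq_len(.N) == .N, by = caseid]
  decisions <- work[, .(
    kept_primaryid = primaryid[.N],
    discarded_primaryids = paste(primaryid[-.N], collapse = ";"),
    n_discarded = .N - 1L
  ), by = caseid]
  kept <- work[keep_flag == TRUE]
  kept[, c("fda_key", "pid_num", "keep_flag") := NULL]
  list(kept = kept[], decisions = decisions[])
}

#' Remove cases listed on the deleted-case rosters
#'
#' Applied after deduplication, mirroring the published order of operations.
#' Deleted CASEIDs absent from the data are counted, not errors.
#'
#' @param kept deduplicated DEMO data.table.
#' @param deleted character vector: union of all quarters' deleted CASEIDs.
#' @return the surviving rows (order preserved) with attributes `n_removed`
#'   and `n_unmatched` (roster ids not present in `kept`).
#' @export
apply_deletions <- function(kept, deleted) {
  kept <- data.table::as.data.table(kept)
  deleted <- unique(as.character(deleted))
  out <- kept[!caseid %chin% deleted]
  attr(out, "n_removed") <- nrow(kept) - nrow(out)
  attr(out, "n_unmatched") <- length(setdiff(deleted, kept$caseid))
  out
}

#' Normalise a drug name for matching
#'
#' Case-folds, strips trademark glyphs and surrounding whitespace, collapses
#' internal whitespace runs.
#'
#' @param raw character vector.
#' @return normalised character vector.
#' @export
#' @examples
#' normalize_drug_name("  SUTENT® ")  # "sutent"
normalize_drug_name <- function(raw) {
  x <- tolower(as.character(raw))
  x <- gsub("[®™©]", "", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' @noRd
match_key <- function(x) {
  # additionally map punctuation to spaces so "sunitinib-malate" tokenises
  x <- normalize_drug_name(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Cohort specification for drug-name matching
#'
#' @param names drug names (generic and brand), matched as whole tokens after
#'   normalisation, so `"sunitinib"` matches `"SUNITINIB MALATE"` but not
#'   `"nilotinib"`.
#' @param role_codes FAERS role codes that qualify (default `"PS"`, primary
#'   suspect).
#' @param match_fields which DRUG columns to match against.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(names, role_codes = "PS",
                        match_fields = c("drugname", "prod_ai")) {
  names <- normalize_drug_name(names)
  stopifnot(length(names) > 0L, all(nzchar(names)),
            length(role_codes) > 0L,
            all(role_codes %in% FAERS_ROLE_CODES),
            all(match_fields %in% c("drugname", "prod_ai")))
  structure(list(names = names, role_codes = role_codes,
                 match_fields = match_fields),
            class = "cohort_spec")
}

#' @noRd
drug_rows_matching <- function(drug, spec) {
  drug <- data.table::as.data.table(drug)
  if (nrow(drug) == 0L) return(drug)
  hit <- drug$role_cod %in% spec$role_codes
  name_hit <- rep(FALSE, nrow(drug))
  # match_key output is [a-z0-9 ] only, so the keys are regex-safe as-is
  pats <- paste0("(^| )", match_key(spec$names), "( |$)")
  for (field in spec$match_fields) {
    if (!field %in% names(drug)) next
    keyed <- match_key(drug[[field]])
    for (p in pats) name_hit <- name_hit | grepl(p, keyed)
  }
  drug[hit & name_hit]
}

#' Select the primary-suspect cohort
#'
#' A curated report enters the cohort when at least one of its DRUG rows has a
#' qualifying role code and a whole-token name match on DRUGNAME or PROD_AI.
#'
#' @param demo_kept deduplicated, deletion-filtered DEMO table.
#' @param drug DRUG mentions (all quarters).
#' @param spec a [cohort_spec()].
#' @return sorted character vector of cohort PRIMARYIDs (subset of
#'   `demo_kept$primaryid`).
#' @export
select_cohort <- function(demo_kept, drug, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  demo_kept <- data.table::as.data.table(demo_kept)
  hits <- drug_rows_matching(drug, spec)
  ids <- sort(intersect(unique(hits$primaryid), demo_kept$primaryid))
  if (length(ids) == 0L) warning("cohort selection matched no reports")
  ids
}

#' Read a PT -> SOC vocabulary table
#'
#' Two-column TSV with header `pt`, `soc` (a stand-in for the licensed MedDRA
#' hierarchy, which cannot be redistributed; a small synthetic vocabulary
#' ships with the package for examples and tests).
#'
#' @param path TSV file path.
#' @return a `vocab_table`: data.table keyed on the case-folded PT.
#' @export
read_vocab <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", encoding = "UTF-8")
  if (!all(c("pt", "soc") %in% names(dt))) {
    stop("vocabulary file must have columns 'pt' and 'soc'")
  }
  dt <- dt[, .(pt = trimws(pt), soc = trimws(soc))]
  if (any(!nzchar(dt$soc))) stop("vocabulary has empty SOC values")
  dt[, pt_key := tolower(pt)]
  dt <- unique(dt, by = "pt_key")
  data.table::setkey(dt, pt_key)
  structure(dt, class = c("vocab_table", class(dt)))
}

#' Map preferred terms to their system organ class
#'
#' Case-insensitive exact lookup; misses return the sentinel `"UNMAPPED"`
#' (count available via the `"n_unmapped"` attribute).
#'
#' @param pt character vector of PTs.
#' @param vocab a [read_vocab()] table.
#' @return character vector of SOC names.
#' @export
map_pt_to_soc <- function(pt, vocab) {
  key <- tolower(trimws(pt))
  soc <- vocab[data.table::data.table(pt_key = key), on = "pt_key", soc]
  miss <- is.na(soc)
  soc[miss] <- "UNMAPPED"
  attr(soc, "n_unmapped") <- sum(miss)
  soc
}
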