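# Quarterly FAERS ASCII ingestion. Tables are "$"-delimited with a header
# line; the post-2012 column names are the default dialect and can be remapped
# (e.g. for legacy LAERS extracts where PRIMARYID was called ISR).

FAERS_ROLE_CODES <- c("PS", "SS", "C", "I")
FAERS_OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
FAERS_OCCP_CODES <- c("CN", "MD", "PH", "HP", "LW", "OT")

#' FAERS file dialect
#'
#' Describes how the quarterly ASCII files are laid out: field delimiter,
#' encoding, per-table file-name patterns and the mapping from the package's
#' internal column names to the column names found in the files. The default
#' is the layout FDA has distributed since 2012Q4 ("$"-delimited, PRIMARYID
#' keyed). Legacy layouts can be accommodated by overriding column names,
#' e.g. `faers_dialect(columns = list(demo = c(primaryid = "isr")))`.
#'
#' @param sep single-character field delimiter (default `"$"`).
#' @param encoding `"UTF-8"` (with automatic Latin-1 fallback per file).
#' @param columns optional named list of per-table named character vectors
#'   overriding file column names; names are `demo`, `drug`, `reac`, `outc`,
#'   `ther`, `indi`.
#' @return a `faers_dialect` list.
#' @export
faers_dialect <- function(sep = "$", encoding = "UTF-8", columns = NULL) {
  stopifnot(nchar(sep) == 1L)
  base <- list(
    demo = list(
      pattern = "^demo.*\\.txt$",
      columns = c(primaryid = "primaryid", caseid = "caseid", fda_dt = "fda_dt",
                  event_dt = "event_dt", age = "age", age_cod = "age_cod",
                  sex = "sex", occr_country = "occr_country",
                  occp_cod = "occp_cod"),
      required = c("primaryid", "caseid", "fda_dt")
    ),
    drug = list(
      pattern = "^drug.*\\.txt$",
      columns = c(primaryid = "primaryid", drug_seq = "drug_seq",
                  role_cod = "role_cod", drugname = "drugname",
                  prod_ai = "prod_ai"),
      required = c("primaryid", "role_cod", "drugname")
    ),
    reac = list(
      pattern = "^reac.*\\.txt$",
      columns = c(primaryid = "primaryid", pt = "pt"),
      required = c("primaryid", "pt")
    ),
    outc = list(
      pattern = "^outc.*\\.txt$",
      columns = c(primaryid = "primaryid", outc_cod = "outc_cod"),
      required = c("primaryid", "outc_cod")
    ),
    ther = list(
      pattern = "^ther.*\\.txt$",
      columns = c(primaryid = "primaryid", dsg_drug_seq = "dsg_drug_seq",
                  start_dt = "start_dt"),
      required = c("primaryid", "start_dt")
    ),
    indi = list(
      pattern = "^indi.*\\.txt$",
      columns = c(primaryid = "primaryid", indi_pt = "indi_pt"),
      required = c("primaryid", "indi_pt")
    )
  )
  if (!is.null(columns)) {
    for (tab in names(columns)) {
      if (!tab %in% names(base)) stop("unknown table in dialect override: ", tab)
      ov <- columns[[tab]]
      base[[tab]]$columns[names(ov)] <- unname(ov)
    }
  }
  structure(list(sep = sep, encoding = encoding, tables = base),
            class = "faers_dialect")
}

#' Read text lines with UTF-8 / Latin-1 fallback
#' @noRd
read_lines_enc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!all(validUTF8(lines))) {
    lines <- iconv(lines, from = "latin1", to = "UTF-8")
  }
  lines
}

#' Split delimited lines into a data.table, accounting for dropped rows
#' @noRd
split_delim <- function(lines, sep, ncol) {
  # append a sentinel so trailing empty fields survive strsplit
  parts <- strsplit(paste0(lines, sep, "\001"), sep, fixed = TRUE)
  nf <- lengths(parts) - 1L
  keep <- nf == ncol
  rows <- parts[keep]
  cols <- if (length(rows)) {
    data.table::transpose(lapply(rows, function(p) p[seq_len(ncol)]))
  } else {
    rep(list(character(0)), ncol)
  }
  list(cols = cols, kept = keep)
}

#' @noRd
read_faers_table <- function(path, table_name, dialect) {
  spec <- dialect$tables[[table_name]]
  lines <- tryCatch(read_lines_enc(path),
                    error = function(e) stop("unreadable file: ", path,
                                             " (", conditionMessage(e), ")"))
  if (length(lines) == 0L) stop("unreadable file (empty): ", path)
  header <- tolower(strsplit(lines[1L], dialect$sep, fixed = TRUE)[[1L]])
  header <- trimws(header)
  wanted <- tolower(spec$columns)
  idx <- match(wanted, header)
  missing_req <- names(spec$columns)[is.na(idx) &
                                       names(spec$columns) %in% spec$required]
  if (length(missing_req)) {
    stop("file ", basename(path), " lacks required column(s): ",
         paste(spec$columns[missing_req], collapse = ", "))
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  sp <- split_delim(body, dialect$sep, length(header))
  dt <- data.table::setDT(setNames(
    lapply(seq_along(spec$columns), function(i) {
      if (is.na(idx[i])) rep(NA_character_, sum(sp$kept))
      else trimws(sp$cols[[idx[i]]])
    }),
    names(spec$columns)
  ))
  rows_in <- length(body)
  dropped_shape <- rows_in - nrow(dt)

  # vocabulary / integrity validation, row-wise
  bad <- rep(FALSE, nrow(dt))
  if (table_name == "demo") {
    bad <- bad | !nzchar(dt$primaryid) | !nzchar(dt$caseid)
    bad <- bad | is.na(partial_date_key(dt$fda_dt))
  } else if (table_name == "drug") {
    bad <- bad | !nzchar(dt$primaryid) | !(dt$role_cod %in% FAERS_ROLE_CODES)
  } else if (table_name == "reac") {
    bad <- bad | !nzchar(dt$primaryid) | !nzchar(dt$pt)
  } else if (table_name == "outc") {
    bad <- bad | !nzchar(dt$primaryid) | !(dt$outc_cod %in% FAERS_OUTCOME_CODES)
  } else if (table_name == "ther") {
    bad <- bad | !nzchar(dt$primaryid)
  } else if (table_name == "indi") {
    bad <- bad | !nzchar(dt$primaryid) | !nzchar(dt$indi_pt)
  }
  list(
    data = dt[!bad],
    report = data.table(
      table = table_name, rows_in = rows_in,
      rows_kept = nrow(dt) - sum(bad),
      rows_dropped = dropped_shape + sum(bad)
    )
  )
}

#' @noRd
parse_quarter_id <- function(x) {
  x <- tolower(x)
  m <- regmatches(x, regexpr("(19|20)[0-9]{2}q[1-4]", x))
  if (length(m) != 1L) {
    # two-digit file-name form, e.g. DEMO20Q1.txt -> 2020q1
    m2 <- regmatches(x, regexpr("[0-9]{2}q[1-4]", x))
    if (length(m2) != 1L) return(NA_character_)
    m <- paste0("20", m2)
  }
  yr <- as.integer(substr(m, 1, 4))
  if (yr < 1968L || yr > 2100L) return(NA_character_)
  m
}

#' Read one FAERS quarterly bundle
#'
#' Expects a directory holding the "$"-delimited tables
#' `DEMO*.txt`, `DRUG*.txt`, `REAC*.txt` (required in spirit: DEMO is fatal if
#' absent, the others default to empty tables) plus optional `OUTC*`, `THER*`,
#' `INDI*` and a deleted-case roster (any file whose name contains "delet",
#' one CASEID per line — distributed with every packet since 2019Q1).
#'
#' Rows with the wrong number of fields, or failing the FAERS vocabulary
#' (role codes PS/SS/C/I, outcome codes, empty PTs, demo rows without
#' PRIMARYID/CASEID/parseable FDA_DT) are dropped and counted in the parse
#' report. Non-DEMO rows whose PRIMARYID is absent from DEMO are retained and
#' flagged `orphan` — deduplication operates on DEMO and joins later, so
#' dropping them here would silently change counts.
#'
#' @param path directory containing the quarter's files.
#' @param quarter_id optional `"YYYYqQ"` string; inferred from the DEMO file
#'   name when omitted.
#' @param dialect a [faers_dialect()].
#' @return a `faers_bundle`: list with `quarter_id`, data.tables `demo`,
#'   `drug`, `reac`, `outc`, `ther`, `indi`, character `deleted_caseids`,
#'   and `parse_report` (rows in/kept/dropped per table).
#' @export
parse_quarter <- function(path, quarter_id = NULL, dialect = faers_dialect()) {
  if (!dir.exists(path)) stop("quarter directory not found: ", path)
  files <- list.files(path, full.names = TRUE)
  fnames <- tolower(basename(files))

  find_one <- function(pattern) {
    hit <- files[grepl(pattern, fnames)]
    if (length(hit) > 1L) hit <- hit[1L]
    if (length(hit)) hit else NULL
  }

  demo_file <- find_one(dialect$tables$demo$pattern)
  if (is.null(demo_file)) stop("missing DEMO table in ", path)

  if (is.null(quarter_id)) {
    quarter_id <- parse_quarter_id(basename(demo_file))
    if (is.na(quarter_id)) quarter_id <- "unknown"
  } else {
    stopifnot(!is.na(parse_quarter_id(quarter_id)))
  }

  tables <- list()
  reports <- list()
  for (tab in names(dialect$tables)) {
    f <- find_one(dialect$tables[[tab]]$pattern)
    if (is.null(f)) {
      if (tab == "demo") stop("missing DEMO table in ", path)
      empty <- data.table::setDT(setNames(
        rep(list(character(0)), length(dialect$tables[[tab]]$columns)),
        names(dialect$tables[[tab]]$columns)))
      tables[[tab]] <- empty
      reports[[tab]] <- data.table(table = tab, rows_in = 0L,
                                   rows_kept = 0L, rows_dropped = 0L)
    } else {
      res <- read_faers_table(f, tab, dialect)
      tables[[tab]] <- res$data
      reports[[tab]] <- res$report
    }
  }

  del_file <- files[grepl("delet", fnames) & !grepl("\\.pdf$", fnames)]
  deleted <- character(0)
  if (length(del_file)) {
    deleted <- unique(trimws(unlist(lapply(del_file, read_lines_enc))))
    deleted <- deleted[nzchar(deleted)]
  }

  demo_ids <- tables$demo$primaryid
  for (tab in setdiff(names(tables), "demo")) {
    if (nrow(tables[[tab]])) {
      tables[[tab]][, orphan := !(primaryid %chin% demo_ids)]
    } else {
      tables[[tab]][, orphan := logical(0)]
    }
  }

  structure(
    c(list(quarter_id = quarter_id), tables,
      list(deleted_caseids = deleted,
           parse_report = data.table::rbindlist(reports))),
    class = "faers_bundle"
  )
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("<faers_bundle> quarter", x$quarter_id, "\n")
  for (tab in c("demo", "drug", "reac", "outc", "ther", "indi")) {
    cat(sprintf("  %-4s %6d rows\n", tab, nrow(x[[tab]])))
  }
  cat("  deleted caseids:", length(x$deleted_caseids), "\n")
  dropped <- sum(x$parse_report$rows_dropped)
  if (dropped > 0) cat("  rows dropped at parse:", dropped, "\n")
  invisible(x)
}

#' Write a record table as TSV
#'
#' Header plus one line per record. Embedded tabs/newlines in character
#' fields are replaced by a single space (counted and reported via the
#' `"sanitized"` attribute) so the file always round-trips.
#'
#' @param rows a data.frame/data.table.
#' @param path output file.
#' @return invisibly, the number of data rows written.
#' @export
write_table <- function(rows, path) {
  dt <- data.table::as.data.table(rows)
  n_sanitized <- 0L
  for (col in names(dt)) {
    if (is.character(dt[[col]])) {
      hits <- grepl("[\t\r\n]", dt[[col]])
      if (any(hits)) {
        n_sanitized <- n_sanitized + sum(hits)
        data.table::set(dt, j = col,
                        value = gsub("[\t\r\n]+", " ", dt[[col]]))
      }
    }
  }
  ok <- tryCatch({
    data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "")
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  out <- nrow(dt)
  attr(out, "sanitized") <- n_sanitized
  invisible(out)
}

#' Write one bundle back to disk in the quarterly ASCII dialect
#'
#' Emits `DEMOyyQq.txt` etc. (plus `DELETEDyyQq.txt` when the bundle carries
#' deleted CASEIDs) so that generator output feeds [parse_quarter()]
#' unchanged.
#'
#' @param bundle a `faers_bundle`.
#' @param dir output directory (created if needed).
#' @param dialect a [faers_dialect()].
#' @return invisibly, `dir`.
#' @export
write_quarter <- function(bundle, dir, dialect = faers_dialect()) {
  stopifnot(inherits(bundle, "faers_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  qid <- bundle$quarter_id
  suffix <- paste0(substr(qid, 3, 4), "Q", substr(qid, 6, 6))
  for (tab in names(dialect$tables)) {
    dt <- data.table::as.data.table(bundle[[tab]])
    cols <- names(dialect$tables[[tab]]$columns)
    present <- intersect(cols, names(dt))
    out <- dt[, present, with = FALSE]
    for (miss in setdiff(cols, present)) out[, (miss) := ""]
    data.table::setcolorder(out, cols)
    file <- file.path(dir, paste0(toupper(tab), suffix, ".txt"))
    for (col in names(out)) {
      v <- out[[col]]
      v[is.na(v)] <- ""
      data.table::set(out, j = col,
                      value = gsub("[$\t\r\n]+", " ", as.character(v)))
    }
    lines <- c(paste(unname(dialect$tables[[tab]]$columns),
                     collapse = dialect$sep),
               do.call(paste, c(as.list(out), sep = dialect$sep)))
    writeLines(lines, file)
  }
  if (length(bundle$deleted_caseids)) {
    writeLines(bundle$deleted_caseids,
               file.path(dir, paste0("DELETED", suffix, ".txt")))
  }
  invisible(dir)
}
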