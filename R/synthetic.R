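# Deterministic synthetic FAERS generator. Emulates the structures the
# curation and screening stages must handle: multi-quarter bundles, revised
# cases (same CASEID, later FDA_DT, higher PRIMARYID), deleted-case rosters,
# PS/SS/C role codes, multiple PTs per report, partial dates, demographic
# marginals, and planted drug-PT relative reporting rates with closed-form
# expected contingency tables.

#' Default PT panel for the generator (PT, SOC, baseline probability)
#' @noRd
default_pt_panel <- function() {
  data.table(
    pt = c("Diarrhoea", "Nausea", "Fatigue", "Asthenia", "Decreased appetite",
           "Hypertension", "Dysgeusia", "Stomatitis", "Hypothyroidism",
           "Palmar-plantar erythrodysaesthesia syndrome", "Yellow skin",
           "Thrombocytopenia", "Headache", "Dizziness", "Rash", "Pyrexia",
           "Vomiting", "Dyspnoea", "Oedema peripheral", "Insomnia"),
    soc = c("Gastrointestinal disorders", "Gastrointestinal disorders",
            "General disorders and administration site conditions",
            "General disorders and administration site conditions",
            "Metabolism and nutrition disorders", "Vascular disorders",
            "Nervous system disorders", "Gastrointestinal disorders",
            "Endocrine disorders", "Skin and subcutaneous tissue disorders",
            "Skin and subcutaneous tissue disorders",
            "Blood and lymphatic system disorders",
            "Nervous system disorders", "Nervous system disorders",
            "Skin and subcutaneous tissue disorders",
            "General disorders and administration site conditions",
            "Gastrointestinal disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "General disorders and administration site conditions",
            "Psychiatric disorders"),
    baseline_prob = c(0.060, 0.055, 0.070, 0.030, 0.020,
                      0.030, 0.005, 0.006, 0.004,
                      0.002, 0.001, 0.010, 0.050, 0.040, 0.050, 0.035,
                      0.045, 0.030, 0.020, 0.025)
  )
}

#' Default demographic marginals
#'
#' Sex, age-band, country and reporter proportions follow the published
#' descriptive profile of sunitinib spontaneous reports (male 59.35%,
#' age >= 65 38.55%, United States 48.87%, consumer reporters 38.13%, ...);
#' outcome codes are drawn independently per report.
#' @noRd
default_demo_marginals <- function() {
  list(
    sex = c(M = 0.5935, F = 0.3185, UNK = 0.0880),
    age_band = c("<18" = 0.0016, "18-44" = 0.0478, "45-64" = 0.3239,
                 ">=65" = 0.3855, UNK = 0.2412),
    country = c(US = 0.4887, JP = 0.0551, CN = 0.0516, AR = 0.0510,
                IN = 0.0395, OTHER = 0.3141),
    reporter = c(CN = 0.3813, MD = 0.3093, HP = 0.1709, PH = 0.1054,
                 LW = 0.0001, MISSING = 0.0330),
    outcome = c(DE = 0.2892, HO = 0.2838, DS = 0.0100, LT = 0.0301,
                OT = 0.3579)
  )
}

#' Generator configuration
#'
#' The defaults are the package's reference study conditions: a sunitinib-like
#' focal drug at 5% prevalence over eight quarters, a 20-PT panel, planted
#' relative reporting rates on five of its hallmark adverse events,
#' demographic marginals matching the published descriptive profile, and a
#' log-normal onset distribution with median 51 days and IQR approximately
#' 16--170 days (`meanlog = log(51)`,
#' `sdlog = (log(170) - log(16)) / (2 * 0.6745)`).
#'
#' @param n_reports number of distinct cases to simulate.
#' @param quarters character vector of `"YYYYqQ"` ids.
#' @param drugs data.frame with columns `name`, `prevalence` and optionally
#'   `brand`, `prod_ai`. Prevalences must sum to < 1; the remaining mass is
#'   split over five background comparator drugs.
#' @param pts data.frame with columns `pt`, `soc`, `baseline_prob`.
#' @param planted data.frame with columns `drug`, `pt`, `rr` (relative
#'   reporting rate multiplier applied when the drug is the report's primary
#'   suspect).
#' @param duplicate_frac fraction of cases re-emitted in a later quarter with
#'   a higher FDA_DT and PRIMARYID (case revisions).
#' @param deletion_frac fraction of cases listed on the final quarter's
#'   deleted-case roster.
#' @param demo_marginals list of categorical distributions (see defaults).
#' @param onset_lognormal `c(meanlog, sdlog)` of the onset-day distribution.
#' @param partial_date_frac fraction of event dates degraded to year-month
#'   precision or blanked entirely (half each).
#' @param start_missing_frac fraction of reports lacking a therapy start
#'   date.
#' @param seed integer RNG seed; generation is fully deterministic given the
#'   config.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(
    n_reports = 20000L,
    quarters = c("2020q1", "2020q2", "2020q3", "2020q4",
                 "2021q1", "2021q2", "2021q3", "2021q4"),
    drugs = data.frame(name = "sunitinib", prevalence = 0.05,
                       brand = "Sutent", prod_ai = "SUNITINIB MALATE"),
    pts = default_pt_panel(),
    planted = data.frame(
      drug = "sunitinib",
      pt = c("Diarrhoea", "Dysgeusia", "Hypothyroidism",
             "Palmar-plantar erythrodysaesthesia syndrome", "Yellow skin"),
      rr = c(2.8, 9.2, 8.8, 25, 60)),
    duplicate_frac = 0.10,
    deletion_frac = 0.02,
    demo_marginals = default_demo_marginals(),
    onset_lognormal = c(meanlog = log(51),
                        sdlog = (log(170) - log(16)) / (2 * 0.6745)),
    partial_date_frac = 0.25,
    start_missing_frac = 0.30,
    seed = 20240101L) {
  drugs <- data.table::as.data.table(drugs)
  pts <- data.table::as.data.table(pts)
  planted <- data.table::as.data.table(planted)
  stopifnot(n_reports >= 0,
            length(quarters) >= 1L,
            !anyNA(vapply(quarters, parse_quarter_id, character(1))),
            nrow(drugs) >= 1L, nrow(pts) >= 2L,
            all(drugs$prevalence > 0), all(drugs$prevalence < 1),
            all(pts$baseline_prob > 0), all(pts$baseline_prob < 1),
            duplicate_frac >= 0, duplicate_frac <= 1,
            deletion_frac >= 0, deletion_frac <= 1,
            partial_date_frac >= 0, partial_date_frac <= 1,
            start_missing_frac >= 0, start_missing_frac <= 1)
  if (sum(drugs$prevalence) >= 1) {
    stop("drug prevalences must sum to < 1 ",
         "(the remainder is background-comparator mass)")
  }
  if (nrow(planted)) {
    stopifnot(all(planted$rr > 0),
              all(planted$drug %in% drugs$name),
              all(planted$pt %in% pts$pt))
    bad <- planted[pts, on = "pt", nomatch = NULL][rr * baseline_prob > 1]
    if (nrow(bad)) stop("planted rr * baseline exceeds 1 for: ",
                        paste(bad$pt, collapse = ", "))
  }
  structure(list(
    n_reports = as.integer(n_reports), quarters = quarters, drugs = drugs,
    pts = pts, planted = planted, duplicate_frac = duplicate_frac,
    deletion_frac = deletion_frac, demo_marginals = demo_marginals,
    onset_lognormal = onset_lognormal, partial_date_frac = partial_date_frac,
    start_missing_frac = start_missing_frac, seed = as.integer(seed)
  ), class = "generator_config")
}

#' @noRd
quarter_start_date <- function(qid) {
  yr <- as.integer(substr(qid, 1, 4))
  q <- as.integer(substr(qid, 6, 6))
  as.Date(sprintf("%d-%02d-01", yr, (q - 1) * 3 + 1))
}

#' @noRd
sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Full drug panel: configured drugs plus background comparators
#' @noRd
drug_panel <- function(config) {
  drugs <- data.table::copy(config$drugs)
  if (!"brand" %in% names(drugs)) drugs[, brand := NA_character_]
  if (!"prod_ai" %in% names(drugs)) drugs[, prod_ai := NA_character_]
  rest <- 1 - sum(drugs$prevalence)
  bg <- data.table(
    name = paste0("comparatol-", 1:5),
    prevalence = rest / 5,
    brand = NA_character_,
    prod_ai = NA_character_
  )
  rbind(drugs, bg, fill = TRUE)
}

#' Generate synthetic FAERS bundles with ground truth
#'
#' @param config a [generator_config()].
#' @return list with `bundles` (list of `faers_bundle`, one per quarter) and
#'   `truth` (data.table of every drug-PT pair: `drug`, `pt`, `soc`,
#'   `prevalence`, `baseline`, `rr`, `expected_a` after curation). The truth
#'   table carries attributes `n_cases`, `n_duplicates`, `deleted_caseids`,
#'   and `config`.
#' @export
generate_faers <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_reports
  panel <- drug_panel(config)
  pts <- config$pts

  # rr matrix: drugs x pts
  rrm <- matrix(1, nrow = nrow(panel), ncol = nrow(pts),
                dimnames = list(panel$name, pts$pt))
  if (nrow(config$planted)) {
    for (i in seq_len(nrow(config$planted))) {
      rrm[config$planted$drug[i], config$planted$pt[i]] <-
        config$planted$rr[i]
    }
  }

  truth <- data.table::CJ(drug = panel$name, pt = pts$pt, sorted = FALSE)
  truth <- truth[panel[, .(drug = name, prevalence)], on = "drug"]
  truth <- truth[pts[, .(pt, soc, baseline = baseline_prob)], on = "pt"]
  truth[, rr := rrm[cbind(drug, pt)]]
  n_deleted <- floor(config$deletion_frac * n)
  truth[, expected_a := (n - n_deleted) * prevalence * baseline * rr]

  if (n == 0L) {
    data.table::setattr(truth, "n_cases", 0L)
    data.table::setattr(truth, "n_duplicates", 0L)
    data.table::setattr(truth, "deleted_caseids", character(0))
    data.table::setattr(truth, "config", config)
    return(list(bundles = list(), truth = truth))
  }

  res <- with_seed(config$seed, {
    caseid <- as.character(10000000L + seq_len(n))
    primaryid <- paste0(caseid, "1")
    qidx <- sample.int(length(config$quarters), n, replace = TRUE)
    qid <- config$quarters[qidx]
    qstart <- quarter_start_date(qid)
    fda <- qstart + sample.int(89, n, replace = TRUE) - 1L

    # drug assignment (one primary suspect per report)
    didx <- sample.int(nrow(panel), n, replace = TRUE,
                       prob = panel$prevalence)
    dname <- panel$name[didx]
    brand <- panel$brand[didx]
    use_brand <- !is.na(brand) & runif(n) < 0.5
    drugname <- toupper(data.table::fifelse(use_brand, brand, dname))
    prod_ai <- panel$prod_ai[didx]
    prod_ai[is.na(prod_ai)] <- toupper(dname[is.na(prod_ai)])

    # reactions: per-PT Bernoulli at baseline * rr(drug, pt)
    probs <- rrm[didx, , drop = FALSE] *
      matrix(pts$baseline_prob, nrow = n, ncol = nrow(pts), byrow = TRUE)
    hits <- matrix(runif(n * nrow(pts)), n) < probs
    hit_idx <- which(hits, arr.ind = TRUE)
    reac <- data.table(primaryid = primaryid[hit_idx[, 1]],
                       pt = pts$pt[hit_idx[, 2]],
                       quarter_id = qid[hit_idx[, 1]])

    # dates: start <= event <= fda
    onset <- round(rlnorm(n, config$onset_lognormal[[1]],
                          config$onset_lognormal[[2]]))
    lag <- sample.int(90, n, replace = TRUE) - 1L
    event <- fda - lag
    start <- event - onset
    event_dt <- format_faers_date(event)
    u <- runif(n)
    part <- u < config$partial_date_frac / 2
    miss <- u >= config$partial_date_frac / 2 & u < config$partial_date_frac
    event_dt[part] <- substr(event_dt[part], 1, 6)
    event_dt[miss] <- ""
    start_dt <- format_faers_date(start)
    start_dt[runif(n) < config$start_missing_frac] <- ""

    # demographics
    m <- config$demo_marginals
    sex <- sample_cat(n, m$sex)
    sex[sex == "UNK"] <- ""
    band <- sample_cat(n, m$age_band)
    age <- data.table::fcase(
      band == "<18", sample.int(17, n, replace = TRUE),
      band == "18-44", sample.int(27, n, replace = TRUE) + 17L,
      band == "45-64", sample.int(20, n, replace = TRUE) + 44L,
      band == ">=65", sample.int(26, n, replace = TRUE) + 64L,
      default = NA_integer_)
    age_chr <- as.character(age)
    age_chr[is.na(age)] <- ""
    age_cod <- data.table::fifelse(is.na(age), "", "YR")
    country <- sample_cat(n, m$country)
    country[country == "OTHER"] <-
      sample(c("FR", "DE", "GB", "CA", "BR", "IT", "ES"),
             sum(country == "OTHER"), replace = TRUE)
    occp <- sample_cat(n, m$reporter)
    occp[occp == "MISSING"] <- ""

    demo <- data.table(
      primaryid = primaryid, caseid = caseid,
      fda_dt = format_faers_date(fda), event_dt = event_dt,
      age = age_chr, age_cod = age_cod, sex = sex,
      occr_country = country, occp_cod = occp, quarter_id = qid
    )
    drug <- data.table(primaryid = primaryid, drug_seq = "1",
                       role_cod = "PS", drugname = drugname,
                       prod_ai = prod_ai, quarter_id = qid)
    ther <- data.table(primaryid = primaryid, dsg_drug_seq = "1",
                       start_dt = start_dt, quarter_id = qid)

    # outcomes: independent Bernoulli per code
    outc_list <- lapply(names(m$outcome), function(code) {
      sel <- runif(n) < m$outcome[[code]]
      data.table(primaryid = primaryid[sel], outc_cod = code,
                 quarter_id = qid[sel])
    })
    outc <- data.table::rbindlist(outc_list)

    # indications: focal drug gets oncology indications, background generic
    indis <- c("Metastatic renal cell carcinoma" = 0.2049,
               "Renal cell carcinoma" = 0.1907,
               "Renal cancer" = 0.1210,
               "Gastrointestinal stromal tumour" = 0.0777,
               "Renal cancer metastatic" = 0.0382)
    focal <- dname %in% config$drugs$name
    ind <- rep("", n)
    ind[focal] <- sample(c(names(indis), ""), sum(focal), replace = TRUE,
                         prob = c(indis, 1 - sum(indis)))
    ind[!focal] <- data.table::fifelse(
      runif(sum(!focal)) < 0.6, "Product used for unknown indication", "")
    has_ind <- nzchar(ind)
    indi <- data.table(primaryid = primaryid[has_ind], indi_pt = ind[has_ind],
                       quarter_id = qid[has_ind])

    # case revisions: re-emit in a later quarter with higher FDA_DT and
    # a higher PRIMARYID (same CASEID, identical clinical content)
    n_dup <- floor(config$duplicate_frac * n)
    dup_sel <- sort(sample.int(n, n_dup))
    nq <- length(config$quarters)
    dup_qidx <- pmin(qidx[dup_sel] + 1L, nq)
    dup_qid <- config$quarters[dup_qidx]
    dup_fda <- pmax(fda[dup_sel] + sample.int(150, n_dup, replace = TRUE),
                    quarter_start_date(dup_qid))
    dup_pid <- paste0(caseid[dup_sel], "2")
    remap <- function(dt, rows_idx_col = "primaryid") {
      sel <- dt[[rows_idx_col]] %chin% primaryid[dup_sel]
      out <- dt[sel]
      map <- setNames(dup_pid, primaryid[dup_sel])
      qmap <- setNames(dup_qid, primaryid[dup_sel])
      out[, quarter_id := qmap[primaryid]]
      out[, primaryid := map[primaryid]]
      out
    }
    dup_demo <- demo[dup_sel]
    dup_demo[, `:=`(primaryid = dup_pid,
                    fda_dt = format_faers_date(dup_fda),
                    quarter_id = dup_qid)]
    demo <- rbind(demo, dup_demo)
    drug <- rbind(drug, remap(drug))
    reac <- rbind(reac, remap(reac))
    ther <- rbind(ther, remap(ther))
    outc <- rbind(outc, remap(outc))
    indi <- rbind(indi, remap(indi))

    # deletions: listed on the final quarter's roster
    del_sel <- sample.int(n, n_deleted)
    deleted_caseids <- caseid[del_sel]

    list(demo = demo, drug = drug, reac = reac, outc = outc, ther = ther,
         indi = indi, deleted_caseids = deleted_caseids,
         n_duplicates = n_dup)
  })

  last_q <- config$quarters[length(config$quarters)]
  bundles <- lapply(config$quarters, function(q) {
    tabs <- lapply(res[c("demo", "drug", "reac", "outc", "ther", "indi")],
                   function(dt) {
                     out <- dt[quarter_id == q]
                     out[, quarter_id := NULL]
                     out[]
                   })
    structure(
      c(list(quarter_id = q), tabs,
        list(deleted_caseids = if (q == last_q) res$deleted_caseids
             else character(0),
             parse_report = data.table(
               table = names(tabs),
               rows_in = vapply(tabs, nrow, integer(1)),
               rows_kept = vapply(tabs, nrow, integer(1)),
               rows_dropped = 0L))),
      class = "faers_bundle")
  })
  names(bundles) <- config$quarters

  data.table::setattr(truth, "n_cases", n)
  data.table::setattr(truth, "n_duplicates", res$n_duplicates)
  data.table::setattr(truth, "deleted_caseids", res$deleted_caseids)
  data.table::setattr(truth, "config", config)
  list(bundles = bundles, truth = truth)
}

#' Expected contingency table under the generative model
#'
#' Closed-form expectation of the post-curation (report, PT) pair counts for
#' one drug-PT pair: `a = n_eff * prev * base * rr` with
#' `n_eff = n - floor(deletion_frac * n)`; margins follow by summing the
#' independent per-PT Bernoulli rates over the panel.
#'
#' @param truth the truth table from [generate_faers()].
#' @param drug,pt the pair of interest.
#' @return one-row data.table `(term, level, a, b, c, d)` of expectations
#'   (non-integer).
#' @export
expected_table <- function(truth, drug, pt) {
  tr <- data.table::as.data.table(truth)
  sel_d <- tr$drug == drug
  sel_p <- tr$pt == pt
  row <- tr[sel_d & sel_p]
  if (nrow(row) != 1L) stop("unknown drug-PT pair: ", drug, " / ", pt)
  a <- row$expected_a
  drug_total <- sum(tr$expected_a[sel_d])
  term_total <- sum(tr$expected_a[sel_p])
  n_total <- sum(tr$expected_a)
  data.table(term = pt, level = "PT", a = a, b = drug_total - a,
             c = term_total - a, d = n_total - drug_total - term_total + a)
}
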