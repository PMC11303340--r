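# Shared builders for the test suite. Everything is constructed in code;
# no fixture files beyond the package's bundled synthetic vocabulary.

make_demo <- function(primaryid, caseid = primaryid, fda_dt = "20200101",
                      event_dt = "", age = "", age_cod = "", sex = "",
                      occr_country = "", occp_cod = "") {
  data.table::data.table(
    primaryid = as.character(primaryid), caseid = as.character(caseid),
    fda_dt = fda_dt, event_dt = event_dt, age = as.character(age),
    age_cod = age_cod, sex = sex, occr_country = occr_country,
    occp_cod = occp_cod
  )
}

make_drug <- function(primaryid, role_cod = "PS", drugname = "SUNITINIB",
                      prod_ai = "", drug_seq = "1") {
  data.table::data.table(
    primaryid = as.character(primaryid), drug_seq = drug_seq,
    role_cod = role_cod, drugname = drugname, prod_ai = prod_ai
  )
}

make_ther <- function(primaryid, start_dt, dsg_drug_seq = "1") {
  data.table::data.table(primaryid = as.character(primaryid),
                         dsg_drug_seq = dsg_drug_seq, start_dt = start_dt)
}

# Write a quarter directory from raw "$"-delimited lines.
write_quarter_files <- function(dir, demo = NULL, drug = NULL, reac = NULL,
                                outc = NULL, ther = NULL, indi = NULL,
                                deleted = NULL, suffix = "20Q1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(name, lines) {
    if (!is.null(lines)) {
      writeLines(lines, file.path(dir, paste0(name, suffix, ".txt")))
    }
  }
  w("DEMO", demo); w("DRUG", drug); w("REAC", reac)
  w("OUTC", outc); w("THER", ther); w("INDI", indi)
  if (!is.null(deleted)) {
    writeLines(deleted, file.path(dir, paste0("DELETED", suffix, ".txt")))
  }
  dir
}

demo_header <- "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occr_country$occp_cod"
drug_header <- "primaryid$drug_seq$role_cod$drugname$prod_ai"
reac_header <- "primaryid$pt"

bundled_vocab <- function() {
  read_vocab(system.file("extdata", "synthetic_vocab.tsv",
                         package = "faersig"))
}

# Independent scalar oracles, recomputing each estimator from first
# principles (kept deliberately separate from the package implementation).
oracle_stats <- function(a, b, c, d) {
  n <- a + b + c + d
  expected <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  observed <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  list(
    ror = (a / b) / (c / d),
    ror_lo = exp(log((a * d) / (b * c)) -
                   1.96 * sqrt(1 / a + 1 / b + 1 / c + 1 / d)),
    ror_hi = exp(log((a * d) / (b * c)) +
                   1.96 * sqrt(1 / a + 1 / b + 1 / c + 1 / d)),
    prr = (a / (a + b)) / (c / (c + d)),
    chi2 = sum((observed - expected)^2 / expected),
    ic = log2((a / n) / (((a + b) / n) * ((a + c) / n))),
    ebgm = (a / n) / (((a + b) / n) * ((a + c) / n))
  )
}

random_tables <- function(n_tables, seed = 1, max_cell = 5000L) {
  set.seed(seed)
  data.table::data.table(
    a = sample.int(max_cell, n_tables, replace = TRUE),
    b = sample.int(max_cell, n_tables, replace = TRUE),
    c = sample.int(max_cell, n_tables, replace = TRUE),
    d = sample.int(max_cell, n_tables, replace = TRUE)
  )
}
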