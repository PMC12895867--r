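# Ingestion of FAERS quarterly ASCII archives. The distribution is a set of
# `$`-delimited tables (DEMO, DRUG, REAC, OUTC, THER, INDI) keyed by
# PRIMARYID (modern, 2012Q4 onward) or ISR (legacy). Legacy tables are
# remapped onto the modern key names at assembly so downstream code sees a
# single schema.

FAERS_TABLES <- c("DEMO", "DRUG", "REAC", "OUTC", "THER", "INDI")

# Age-unit conversion factors to years (365.25-day-year conventions).
AGE_UNIT_TO_YEARS <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.14,
                       DY = 1 / 365.25, HR = 1 / 8766)

REPORTER_CODES <- c(MD = "physician", PH = "pharmacist",
                    OT = "other_health_professional", LW = "lawyer",
                    CN = "consumer")

#' Parse one FAERS-dialect ASCII table
#'
#' Reads a `$`-delimited table whose first line names the columns. Data
#' lines whose field count differs from the header are recorded in the
#' attached rejects log and skipped — never silently dropped.
#'
#' @param stream a file path, or a character vector of lines (a single
#'   string with embedded newlines is split)
#' @param table_name one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`,
#'   `"THER"`, `"INDI"`
#' @param dialect `"modern"` (PRIMARYID-keyed) or `"legacy"` (ISR-keyed)
#' @param quarter_label optional label such as `"2019Q3"` carried through
#' @return object of class `faers_table`: list with `table_name`, `dialect`,
#'   `quarter_label`, `rows` (data.table, all-character, upper-cased column
#'   names, whitespace-trimmed values) and `rejects`
#' @export
parse_ascii_table <- function(stream, table_name, dialect = c("modern", "legacy"),
                              quarter_label = NA_character_) {
  dialect <- match.arg(dialect)
  table_name <- toupper(table_name)
  stopifnot(table_name %in% FAERS_TABLES)

  if (length(stream) == 1L && !grepl("\n", stream) && file.exists(stream)) {
    lines <- readLines(stream, warn = FALSE)
  } else {
    lines <- unlist(strsplit(stream, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (length(lines) == 0L) stop("empty stream: no header line in ", table_name)

  header <- toupper(trimws(strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]))
  key_col <- if (dialect == "modern") "PRIMARYID" else "ISR"
  if (!key_col %in% header) {
    stop(sprintf("header of %s (%s dialect) is missing required key column %s",
                 table_name, dialect, key_col))
  }

  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  rejects <- empty_rejects()
  rows <- data.table::as.data.table(
    setNames(rep(list(character(0)), length(header)), header))

  if (length(body)) {
    nfield <- lengths(strsplit(body, "$", fixed = TRUE))
    # a trailing empty field is dropped by strsplit; tolerate it
    trailing <- endsWith(body, "$")
    nfield <- nfield + as.integer(trailing)
    ok <- nfield == length(header)
    if (any(!ok)) {
      rejects <- add_rejects(rejects, table_name,
                             key = sub("\\$.*$", "", body[!ok]),
                             reason = "field_count_mismatch",
                             detail = sprintf("%d fields, header has %d",
                                              nfield[!ok], length(header)))
    }
    if (any(ok)) {
      parts <- data.table::tstrsplit(body[ok], "$", fixed = TRUE)
      length(parts) <- length(header)
      parts <- lapply(parts, function(p) {
        p <- trimws(as.character(p %||% NA_character_))
        p[is.na(p)] <- ""
        p
      })
      rows <- data.table::as.data.table(setNames(parts, header))
    }
  }

  missing_key <- !nzchar(rows[[key_col]])
  if (any(missing_key)) {
    rejects <- add_rejects(rejects, table_name, key = "",
                           reason = "empty_report_key")
    rows <- rows[!missing_key]
  }

  structure(list(table_name = table_name, dialect = dialect,
                 quarter_label = quarter_label, rows = rows,
                 rejects = rejects),
            class = "faers_table")
}

#' Read a directory tree of FAERS quarterly ASCII files
#'
#' Expects files named like `DEMO19Q3.txt` (any case, optionally inside
#' per-quarter subdirectories). Dialect is detected per file from the
#' header key column.
#'
#' @param dir root directory of the archive
#' @return list of `faers_table` objects
#' @export
read_faers_archive <- function(dir) {
  files <- list.files(dir, pattern = "\\.(txt|TXT)$", recursive = TRUE,
                      full.names = TRUE)
  pat <- paste0("^(", paste(FAERS_TABLES, collapse = "|"), ")")
  keep <- grepl(pat, toupper(basename(files)))
  files <- sort(files[keep])
  if (length(files) == 0L) stop("no FAERS table files found under ", dir)
  lapply(files, function(f) {
    base <- toupper(tools::file_path_sans_ext(basename(f)))
    tab <- regmatches(base, regexpr(pat, base))
    qlab <- sub(paste0("^", tab), "", base)
    qlab <- if (grepl("^[0-9]{2}Q[1-4]$", qlab)) {
      yy <- as.integer(substr(qlab, 1, 2))
      sprintf("%04dQ%s", ifelse(yy < 50, 2000 + yy, 1900 + yy),
              substr(qlab, 4, 4))
    } else NA_character_
    first <- toupper(readLines(f, n = 1L, warn = FALSE))
    dialect <- if (grepl("(^|\\$)ISR(\\$|$)", trimws(first))) "legacy" else "modern"
    parse_ascii_table(f, tab, dialect, qlab)
  })
}

# Internal: map legacy column names onto the modern schema.
normalize_dialect <- function(tab) {
  rows <- data.table::copy(tab$rows)
  if (tab$dialect == "legacy") {
    ren <- c(ISR = "PRIMARYID", CASE = "CASEID", GNDR_COD = "SEX",
             OCC_COD = "OCCP_COD")
    for (old in names(ren)) {
      if (old %in% names(rows) && !(ren[[old]] %in% names(rows))) {
        data.table::setnames(rows, old, ren[[old]])
      }
    }
  }
  rows
}

# Internal: route string -> route class.
classify_route <- function(route) {
  r <- toupper(trimws(route))
  out <- rep("other", length(r))
  out[!nzchar(r)] <- "unspecified"
  out[startsWith(r, "INTRAVENOUS")] <- "intravenous"
  out[startsWith(r, "INTRAVITREAL") | startsWith(r, "OPHTHALMIC") |
        startsWith(r, "INTRAOCULAR")] <- "intraocular"
  out
}

# Internal: AGE + AGE_COD -> years; implausible values dropped to NA.
age_to_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(age_cod))
  cod[!nzchar(cod)] <- "YR"
  fac <- AGE_UNIT_TO_YEARS[cod]
  yrs <- a * as.numeric(fac)
  yrs[!is.finite(yrs) | yrs < 0 | yrs >= 150] <- NA_real_
  yrs
}

get_col <- function(rows, col) {
  if (col %in% names(rows)) rows[[col]] else rep("", nrow(rows))
}

#' Assemble joined safety reports from parsed FAERS tables
#'
#' One report per DEMO row; DRUG/REAC/OUTC/THER/INDI rows are attached by
#' the report key. Child rows whose key matches no DEMO row go to the
#' rejects log. Ages are converted to years from AGE/AGE_COD, reporter
#' qualification decoded from OCCP_COD, drug routes classified, and
#' reaction PTs upper-cased.
#'
#' @param record_sets list of `faers_table` objects (at least one DEMO)
#' @return object of class `faers_reports`: list of data.tables `demo`,
#'   `drug`, `reac`, `outc`, `ther`, `indi` plus a `rejects` log. `demo`
#'   carries one row per report with `primaryid`, `caseid`, `fda_dt`,
#'   `event_dt`, `sex`, `age_years`, `reporter_qualification`, `country`,
#'   `fatal` and `outcome_codes`.
#' @export
assemble_reports <- function(record_sets) {
  if (inherits(record_sets, "faers_table")) record_sets <- list(record_sets)
  by_tab <- split(record_sets, vapply(record_sets, `[[`, "", "table_name"))
  if (is.null(by_tab$DEMO)) stop("assemble_reports requires at least one DEMO table")

  rejects <- data.table::rbindlist(
    c(list(empty_rejects()), lapply(record_sets, `[[`, "rejects")))

  stack <- function(tabs) {
    if (is.null(tabs)) return(data.table::data.table(PRIMARYID = character()))
    data.table::rbindlist(lapply(tabs, normalize_dialect), fill = TRUE)
  }

  demo_raw <- stack(by_tab$DEMO)
  sex <- toupper(get_col(demo_raw, "SEX"))
  sex[!sex %in% c("F", "M")] <- "unknown"
  occ <- toupper(trimws(get_col(demo_raw, "OCCP_COD")))
  qual <- unname(REPORTER_CODES[occ])
  qual[is.na(qual)] <- "unknown"
  country <- get_col(demo_raw, "REPORTER_COUNTRY")
  alt <- get_col(demo_raw, "OCCR_COUNTRY")
  country <- ifelse(nzchar(country), country, alt)

  demo <- data.table::data.table(
    primaryid = demo_raw$PRIMARYID,
    caseid = get_col(demo_raw, "CASEID"),
    fda_dt = get_col(demo_raw, "FDA_DT"),
    event_dt = get_col(demo_raw, "EVENT_DT"),
    sex = sex,
    age_years = age_to_years(get_col(demo_raw, "AGE"),
                             get_col(demo_raw, "AGE_COD")),
    reporter_qualification = qual,
    country = toupper(trimws(country))
  )
  known <- unique(demo$primaryid)

  attach_child <- function(tabs, name, keep) {
    raw <- stack(tabs)
    out <- data.table::data.table(primaryid = raw$PRIMARYID)
    for (col in names(keep)) out[[col]] <- trimws(get_col(raw, keep[[col]]))
    orphan <- !out$primaryid %in% known & nzchar(out$primaryid)
    if (any(orphan)) {
      rejects <<- add_rejects(rejects, name, out$primaryid[orphan],
                              "orphan_key", "no matching DEMO row")
    }
    out[!orphan & nzchar(out$primaryid)]
  }

  drug <- attach_child(by_tab$DRUG, "DRUG",
                       c(drug_seq = "DRUG_SEQ", role_code = "ROLE_COD",
                         drugname = "DRUGNAME", prod_ai = "PROD_AI",
                         route = "ROUTE"))
  drug[, role_code := toupper(role_code)]
  drug[!role_code %in% c("PS", "SS", "C", "I"), role_code := ""]
  drug[, route_class := classify_route(route)]

  reac <- attach_child(by_tab$REAC, "REAC", c(pt = "PT"))
  reac[, pt := toupper(pt)]
  reac <- unique(reac[nzchar(pt)])

  outc <- attach_child(by_tab$OUTC, "OUTC", c(outc_cod = "OUTC_COD"))
  outc[, outc_cod := toupper(outc_cod)]
  outc <- unique(outc[outc_cod %in% c("DE", "LT", "HO", "DS", "CA", "RI", "OT")])

  ther <- attach_child(by_tab$THER, "THER",
                       c(drug_seq = "DSG_DRUG_SEQ", start_dt = "START_DT"))
  if (!any(nzchar(ther$drug_seq))) {
    # legacy name for the therapy/drug sequence link
    ther2 <- attach_child(by_tab$THER, "THER",
                          c(drug_seq = "DRUG_SEQ", start_dt = "START_DT"))
    if (any(nzchar(ther2$drug_seq))) ther <- ther2
  }

  indi <- attach_child(by_tab$INDI, "INDI",
                       c(drug_seq = "INDI_DRUG_SEQ", indi_pt = "INDI_PT"))
  indi[, indi_pt := toupper(indi_pt)]

  fatal_ids <- unique(outc$primaryid[outc$outc_cod == "DE"])
  demo[, fatal := primaryid %in% fatal_ids]
  codes <- outc[, .(outcome_codes = paste(sort(unique(outc_cod)),
                                          collapse = ",")), by = primaryid]
  demo <- merge(demo, codes, by = "primaryid", all.x = TRUE, sort = FALSE)
  demo[is.na(outcome_codes), outcome_codes := ""]

  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 ther = ther, indi = indi, rejects = rejects,
                 deduplicated = FALSE),
            class = "faers_reports")
}

#' @export
print.faers_reports <- function(x, ...) {
  cat(sprintf(paste0("<faers_reports> %d reports (%s), %d drug rows, ",
                     "%d reaction rows, %d rejects\n"),
              nrow(x$demo),
              if (x$deduplicated) "deduplicated" else "raw",
              nrow(x$drug), nrow(x$reac), nrow(x$rejects)))
  invisible(x)
}

#' Collapse duplicate case versions to one report per case
#'
#' FAERS distributes successive versions of the same case across quarters.
#' Following the FDA-recommended rule, only the most recent version is
#' kept: per CASEID the report with the latest FDA_DT survives, ties broken
#' by the numerically largest PRIMARYID. Reports with an empty CASEID are
#' kept as their own singletons and flagged in the rejects log. Output is
#' sorted by caseid; the input object is not modified.
#'
#' @param reports `faers_reports` object
#' @return deduplicated `faers_reports`
#' @export
deduplicate <- function(reports) {
  stopifnot(inherits(reports, "faers_reports"))
  demo <- data.table::copy(reports$demo)
  rejects <- data.table::copy(reports$rejects)

  blank <- !nzchar(demo$caseid)
  if (any(blank)) {
    rejects <- add_rejects(rejects, "DEMO", demo$primaryid[blank],
                           "empty_caseid", "kept as singleton")
  }
  demo[, `:=`(.fda_key = partial_date_key(fda_dt),
              .pid_key = suppressWarnings(as.numeric(primaryid)))]
  demo[is.na(.pid_key), .pid_key := 0]

  keyed <- demo[nzchar(caseid)]
  data.table::setorder(keyed, caseid, -.fda_key, -.pid_key)
  survivors <- keyed[!duplicated(caseid)]
  out_demo <- rbind(survivors, demo[blank])
  data.table::setorder(out_demo, caseid, primaryid)
  out_demo[, c(".fda_key", ".pid_key") := NULL]

  keep <- out_demo$primaryid
  out <- list(
    demo = out_demo,
    drug = reports$drug[primaryid %in% keep],
    reac = reports$reac[primaryid %in% keep],
    outc = reports$outc[primaryid %in% keep],
    ther = reports$ther[primaryid %in% keep],
    indi = reports$indi[primaryid %in% keep],
    rejects = rejects,
    deduplicated = TRUE
  )
  structure(out, class = "faers_reports")
}

#' Serialize reports to interchange TSV tables
#'
#' Writes one parent table (a row per report) plus child tables for drugs
#' and reactions, with a stable column order.
#'
#' @param reports `faers_reports` object
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_reports_tsv <- function(reports, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(reports$demo[, .(primaryid, caseid, fda_dt, event_dt,
                                      sex, age_years, reporter_qualification,
                                      country, fatal, outcome_codes)],
                     file.path(dir, "reports.tsv"), sep = "\t")
  data.table::fwrite(reports$drug[, .(primaryid, drug_seq, role_code,
                                      drugname, prod_ai, route, route_class)],
                     file.path(dir, "drugs.tsv"), sep = "\t")
  data.table::fwrite(reports$reac[, .(primaryid, pt)],
                     file.path(dir, "reactions.tsv"), sep = "\t")
  invisible(dir)
}
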