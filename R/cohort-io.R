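#' Read raw hospitalization records from a delimited file
#'
#' One input row per admission. Diagnosis codes are normalized to their
#' 3-character ICD-10 categories ([normalizeCode()]) and deduplicated within
#' the row; unparseable codes are dropped, and rows left with no parseable
#' code, an unparseable date, or an unrecognized sex are dropped and counted
#' in the attached parse report.
#'
#' @param path path to a CSV/TSV file.
#' @param schema named character vector mapping the roles `id`, `date`,
#'   `age`, `sex`, `codes` to column names in the file.
#' @param code_sep delimiter separating codes inside the codes cell
#'   (default `";"`).
#' @param sep field separator; `"auto"` lets `data.table::fread` detect it.
#' @return data.frame of admission records with columns `patient_id`,
#'   `admission_date` (Date), `age`, `sex` and a list-column `codes`; the
#'   parse report (named list of dropped-row counts) is attached as
#'   attribute `"parse_report"`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("patient_id,admission_date,age,sex,codes",
#'              "P1,2010-03-04,45,F,I10;E11.9"), f)
#' recs <- readRecords(f)
#' recs$codes[[1]]  # "E11" "I10"
#' @export
readRecords <- function(path,
                        schema = c(id = "patient_id", date = "admission_date",
                                   age = "age", sex = "sex", codes = "codes"),
                        code_sep = ";", sep = "auto") {
  stopifnot(file.exists(path))
  need <- c("id", "date", "age", "sex", "codes")
  if (!all(need %in% names(schema)))
    stop("schema must name the columns for: ", paste(need, collapse = ", "))
  dt <- data.table::fread(path, sep = sep, colClasses = "character",
                          data.table = FALSE, showProgress = FALSE)
  missing_cols <- setdiff(unname(schema[need]), names(dt))
  if (length(missing_cols))
    stop("input file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))

  id <- as.character(dt[[schema[["id"]]]])
  date <- as.Date(dt[[schema[["date"]]]])
  age <- suppressWarnings(as.integer(dt[[schema[["age"]]]]))
  sex <- normalizeSex(dt[[schema[["sex"]]]])
  codes <- strsplit(as.character(dt[[schema[["codes"]]]]), code_sep,
                    fixed = TRUE)
  codes <- lapply(codes, function(x) {
    x <- normalizeCode(x[nzchar(trimws(x))], strict = FALSE)
    sort(unique(x[!is.na(x)]))
  })

  bad_date <- is.na(date)
  bad_age <- is.na(age)
  bad_sex <- is.na(sex)
  no_code <- lengths(codes) == 0L
  keep <- !(bad_date | bad_age | bad_sex | no_code)

  out <- data.frame(patient_id = id[keep], age = age[keep], sex = sex[keep],
                    stringsAsFactors = FALSE)
  out$admission_date <- date[keep]
  out$codes <- I(codes[keep])
  attr(out, "parse_report") <- list(
    rows_read = nrow(dt),
    rows_kept = sum(keep),
    dropped_no_code = sum(no_code & !bad_date & !bad_age & !bad_sex),
    dropped_bad_date = sum(bad_date),
    dropped_bad_age = sum(bad_age & !bad_date),
    dropped_bad_sex = sum(bad_sex & !bad_date & !bad_age)
  )
  out
}

normalizeSex <- function(x) {
  s <- tolower(substr(trimws(as.character(x)), 1L, 1L))
  out <- rep(NA_character_, length(s))
  out[s %in% c("f", "2", "w")] <- "female"
  out[s %in% c("m", "1")] <- "male"
  out
}

#' Select the baseline (first) record of each patient
#'
#' Keeps, per patient, the admission with the earliest date. When a patient
#' has several admissions on that earliest date, their code sets are merged
#' into one baseline record (a snapshot of all diagnoses at baseline), which
#' makes the result invariant to input row order.
#'
#' @param records admission records as returned by [readRecords()].
#' @return records with exactly one row per `patient_id`, sorted by id.
#' @export
selectBaseline <- function(records) {
  if (nrow(records) == 0L) return(records)
  first_date <- tapply(records$admission_date, records$patient_id, min)
  ids <- sort(unique(records$patient_id))
  keep <- records$admission_date ==
    as.Date(first_date[records$patient_id], origin = "1970-01-01")
  r <- records[keep, , drop = FALSE]
  r <- r[order(r$patient_id, r$age, r$sex), , drop = FALSE]
  idx <- split(seq_len(nrow(r)), r$patient_id)[ids]
  out <- r[vapply(idx, `[`, integer(1), 1L), , drop = FALSE]
  out$codes <- I(lapply(idx, function(i)
    sort(unique(unlist(r$codes[i], use.names = FALSE)))))
  rownames(out) <- NULL
  pr <- attr(records, "parse_report")
  if (!is.null(pr)) attr(out, "parse_report") <- pr
  out
}

#' Apply the inclusion/exclusion filters and form an analysis cohort
#'
#' Removes diagnosis codes outside ICD-10 chapters 1-14 from every record,
#' then excludes records left with no in-scope code and records whose age
#' falls outside the (inclusive) middle-age window.
#'
#' @param records baseline records from [selectBaseline()].
#' @param age_min,age_max inclusive age bounds (defaults 40 and 59).
#' @param label cohort name.
#' @return A [Cohort-class]; exclusion counts by reason are available via
#'   [cohortReport()].
#' @export
applyFilters <- function(records, age_min = 40L, age_max = 59L,
                         label = "cohort") {
  codes <- lapply(records$codes, function(x) {
    ch <- icdChapter(x)
    x[!is.na(ch) & ch >= 1L & ch <= 14L]
  })
  codes_removed <- sum(lengths(records$codes)) - sum(lengths(codes))
  age_ok <- records$age >= age_min & records$age <= age_max
  has_code <- lengths(codes) > 0L
  keep <- age_ok & has_code
  report <- attr(records, "parse_report")
  if (is.null(report)) report <- list()
  report$codes_removed_chapter <- codes_removed
  report$excluded_age <- sum(!age_ok)
  report$excluded_no_inscope_code <- sum(age_ok & !has_code)
  Cohort(records[keep, c("patient_id", "age", "sex"), drop = FALSE],
         codes[keep], label = label, report = report)
}

#' Stratify a cohort by sex
#'
#' @param cohort a [Cohort-class].
#' @return named list with `male` and `female` cohorts partitioning the
#'   input; labels are suffixed accordingly.
#' @export
stratifyBySex <- function(cohort) {
  p <- patientData(cohort)
  out <- lapply(c(male = "male", female = "female"), function(s) {
    sel <- p$sex == s
    Cohort(p[sel, , drop = FALSE], diseaseCodes(cohort)[sel],
           label = paste(objectLabel(cohort), s, sep = "_"),
           report = cohortReport(cohort))
  })
  out
}

#' Write / read a cohort in the canonical CSV form
#'
#' One row per patient: `patient_id`, `age`, `sex`, and the sorted code set
#' pipe-joined in `codes`; rows sorted by `patient_id`.
#'
#' @param cohort a [Cohort-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCohortCSV <- function(cohort, path) {
  p <- patientData(cohort)
  df <- data.frame(
    patient_id = p$patient_id, age = p$age, sex = p$sex,
    codes = vapply(diseaseCodes(cohort), paste, character(1), collapse = "|"),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$patient_id), , drop = FALSE]
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writeCohortCSV
#' @param label cohort name for the object read back.
#' @export
readCohortCSV <- function(path, label = "cohort") {
  df <- data.table::fread(path, colClasses = list(character = "patient_id"),
                          data.table = FALSE, showProgress = FALSE)
  codes <- strsplit(as.character(df$codes), "|", fixed = TRUE)
  Cohort(df[, c("patient_id", "age", "sex")], codes, label = label)
}

#' Write a cohort's parse/filter report as JSON
#'
#' @param cohort a [Cohort-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeCohortReport <- function(cohort, path) {
  rep <- cohortReport(cohort)
  rep$n_inpatients <- nInpatients(cohort)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
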