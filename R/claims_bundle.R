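#' Assemble and validate a claims bundle
#'
#' A claims bundle holds the four flat tables of a simplified claims
#' database, keyed by `patient_id`:
#'
#' * `enrollment`: `patient_id`, `birth_ym` (Date, month resolution stored at
#'   the imputed day 15), `sex` (`"male"`/`"female"`), `obs_start`, `obs_end`.
#' * `prescriptions`: `patient_id`, `rx_date`, `atc_code`, `days_supply`
#'   (1-90 days, the range dispensable per prescription in Japan),
#'   `fdc_flag` (fixed-dose combination product).
#' * `diagnoses`: `patient_id`, `dx_date`, `icd10_code`, `suspected_flag`
#'   (tentative/rule-out diagnosis; such rows are ignored when deriving
#'   comorbidity covariates).
#' * `visits`: `patient_id`, `visit_date`; one row per outpatient claim.
#'
#' Construction enforces the referential and window invariants: every claim
#' belongs to an enrolled patient, all claim dates lie inside that patient's
#' observation window, `obs_start <= obs_end`, and no patient reaches age 75
#' while under observation (employee health insurance covers ages < 75).
#'
#' @param enrollment,prescriptions,diagnoses,visits data frames with the
#'   columns listed above. Date columns must be `Date`.
#' @return an object of class `claims_bundle` (a named list of the four
#'   validated data frames).
#' @seealso [read_claims_bundle()], [write_claims_bundle()]
#' @export
claims_bundle <- function(enrollment, prescriptions, diagnoses, visits) {
  enrollment    <- check_columns(enrollment, "enrollment",
                                 c("patient_id", "birth_ym", "sex", "obs_start", "obs_end"))
  prescriptions <- check_columns(prescriptions, "prescriptions",
                                 c("patient_id", "rx_date", "atc_code", "days_supply", "fdc_flag"))
  diagnoses     <- check_columns(diagnoses, "diagnoses",
                                 c("patient_id", "dx_date", "icd10_code", "suspected_flag"))
  visits        <- check_columns(visits, "visits", c("patient_id", "visit_date"))

  enrollment$patient_id <- as.character(enrollment$patient_id)
  if (anyDuplicated(enrollment$patient_id)) {
    stop("enrollment: duplicated patient_id: ",
         paste(utils::head(unique(enrollment$patient_id[duplicated(enrollment$patient_id)]), 5L),
               collapse = ", "))
  }
  bad_sex <- !enrollment$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop("enrollment: sex must be 'male' or 'female'; offending rows: ",
         row_list(which(bad_sex)))
  }
  for (col in c("birth_ym", "obs_start", "obs_end")) {
    enrollment[[col]] <- as.Date(enrollment[[col]])
  }
  bad_win <- enrollment$obs_start > enrollment$obs_end
  if (any(bad_win)) {
    stop("enrollment: obs_start after obs_end; offending rows: ", row_list(which(bad_win)))
  }
  age_end <- as.numeric(enrollment$obs_end - enrollment$birth_ym) / 365.25
  if (any(age_end >= 75)) {
    stop("enrollment: patient reaches age 75 during observation; offending rows: ",
         row_list(which(age_end >= 75)))
  }

  prescriptions$patient_id <- as.character(prescriptions$patient_id)
  prescriptions$rx_date <- as.Date(prescriptions$rx_date)
  prescriptions$atc_code <- as.character(prescriptions$atc_code)
  prescriptions$days_supply <- as.integer(prescriptions$days_supply)
  prescriptions$fdc_flag <- as_flag(prescriptions$fdc_flag, "prescriptions$fdc_flag")
  bad_atc <- is.na(prescriptions$atc_code) | !nzchar(prescriptions$atc_code)
  if (any(bad_atc)) {
    stop("prescriptions: empty atc_code; offending rows: ", row_list(which(bad_atc)))
  }
  bad_supply <- is.na(prescriptions$days_supply) |
    prescriptions$days_supply < 1L | prescriptions$days_supply > 90L
  if (any(bad_supply)) {
    stop("prescriptions: days_supply must be an integer in 1-90; offending rows: ",
         row_list(which(bad_supply)))
  }

  diagnoses$patient_id <- as.character(diagnoses$patient_id)
  diagnoses$dx_date <- as.Date(diagnoses$dx_date)
  diagnoses$icd10_code <- normalize_icd10(diagnoses$icd10_code)
  diagnoses$suspected_flag <- as_flag(diagnoses$suspected_flag, "diagnoses$suspected_flag")
  bad_icd <- !grepl("^[A-Z][0-9]", diagnoses$icd10_code)
  if (any(bad_icd)) {
    stop("diagnoses: icd10_code must match the ICD-10 pattern (letter + digits); ",
         "offending rows: ", row_list(which(bad_icd)))
  }

  visits$patient_id <- as.character(visits$patient_id)
  visits$visit_date <- as.Date(visits$visit_date)

  check_claims_in_window(prescriptions, "rx_date", enrollment, "prescriptions")
  check_claims_in_window(diagnoses, "dx_date", enrollment, "diagnoses")
  check_claims_in_window(visits, "visit_date", enrollment, "visits")

  structure(list(enrollment = enrollment,
                 prescriptions = prescriptions,
                 diagnoses = diagnoses,
                 visits = visits),
            class = "claims_bundle")
}

check_columns <- function(x, name, cols) {
  if (!is.data.frame(x)) stop(name, " must be a data frame")
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop(name, ": missing column(s): ", paste(missing, collapse = ", "))
  }
  x <- as.data.frame(x)[cols]
  rownames(x) <- NULL
  x
}

row_list <- function(idx, max = 5L) {
  shown <- utils::head(idx, max)
  txt <- paste(shown, collapse = ", ")
  if (length(idx) > max) txt <- paste0(txt, ", ... (", length(idx), " total)")
  txt
}

as_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1) | is.na(x))) return(x == 1)
  if (is.character(x)) {
    lx <- toupper(trimws(x))
    mapped <- rep(NA, length(x))
    mapped[lx %in% c("TRUE", "T", "1", "YES")] <- TRUE
    mapped[lx %in% c("FALSE", "F", "0", "NO")] <- FALSE
    if (!anyNA(mapped[!is.na(x)])) return(mapped)
  }
  stop(what, ": cannot interpret as logical flag")
}

# uppercase, dots stripped; matching is by code prefix throughout
normalize_icd10 <- function(codes) {
  gsub(".", "", toupper(as.character(codes)), fixed = TRUE)
}

check_claims_in_window <- function(tbl, date_col, enrollment, name) {
  if (nrow(tbl) == 0L) return(invisible(NULL))
  idx <- match(tbl$patient_id, enrollment$patient_id)
  orphan <- is.na(idx)
  if (any(orphan)) {
    stop(name, ": patient_id not present in enrollment; offending rows: ",
         row_list(which(orphan)))
  }
  d <- as.Date(tbl[[date_col]])
  if (anyNA(d)) {
    stop(name, ": missing ", date_col, "; offending rows: ", row_list(which(is.na(d))))
  }
  outside <- d < enrollment$obs_start[idx] | d > enrollment$obs_end[idx]
  if (any(outside)) {
    stop(name, ": ", date_col, " outside the patient's observation window; ",
         "offending rows: ", row_list(which(outside)))
  }
  invisible(NULL)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  cat(sprintf("  enrollment:    %6d patients\n", nrow(x$enrollment)))
  cat(sprintf("  prescriptions: %6d claims\n", nrow(x$prescriptions)))
  cat(sprintf("  diagnoses:     %6d claims\n", nrow(x$diagnoses)))
  cat(sprintf("  visits:        %6d claims\n", nrow(x$visits)))
  if (nrow(x$enrollment)) {
    cat(sprintf("  observation:   %s .. %s\n",
                min(x$enrollment$obs_start), max(x$enrollment$obs_end)))
  }
  invisible(x)
}

#' Read a claims bundle from delimited text files
#'
#' Expects four CSV files (`enrollment.csv`, `prescriptions.csv`,
#' `diagnoses.csv`, `visits.csv`) in `dir`, with the column schemas
#' documented in [claims_bundle()]. All date columns are 6- or 8-digit
#' strings and go through [parse_claim_date()], so year-month dates receive
#' the imputed day 15.
#'
#' @param dir directory containing the four files.
#' @param sep field delimiter (default comma).
#' @param quiet suppress the per-table row-count message.
#' @return a validated `claims_bundle`.
#' @export
read_claims_bundle <- function(dir, sep = ",", quiet = FALSE) {
  paths <- file.path(dir, paste0(c("enrollment", "prescriptions", "diagnoses", "visits"), ".csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("claims table file(s) not found: ", paste(missing, collapse = ", "))
  }
  read1 <- function(p) utils::read.table(p, header = TRUE, sep = sep,
                                         colClasses = "character",
                                         stringsAsFactors = FALSE)
  enr <- read1(paths[1]); rx <- read1(paths[2]); dx <- read1(paths[3]); vis <- read1(paths[4])

  enr <- check_columns(enr, "enrollment.csv",
                       c("patient_id", "birth_ym", "sex", "obs_start", "obs_end"))
  enr$birth_ym  <- parse_claim_date(enr$birth_ym)
  enr$obs_start <- parse_claim_date(enr$obs_start)
  enr$obs_end   <- parse_claim_date(enr$obs_end)

  rx <- check_columns(rx, "prescriptions.csv",
                      c("patient_id", "rx_date", "atc_code", "days_supply", "fdc_flag"))
  rx$rx_date <- parse_claim_date(rx$rx_date)
  rx$days_supply <- as.integer(rx$days_supply)

  dx <- check_columns(dx, "diagnoses.csv",
                      c("patient_id", "dx_date", "icd10_code", "suspected_flag"))
  dx$dx_date <- parse_claim_date(dx$dx_date)

  vis <- check_columns(vis, "visits.csv", c("patient_id", "visit_date"))
  vis$visit_date <- parse_claim_date(vis$visit_date)

  bundle <- claims_bundle(enr, rx, dx, vis)
  if (!quiet) {
    message(sprintf("read claims bundle: %d patients, %d prescriptions, %d diagnoses, %d visits",
                    nrow(bundle$enrollment), nrow(bundle$prescriptions),
                    nrow(bundle$diagnoses), nrow(bundle$visits)))
  }
  bundle
}

#' Write a claims bundle to delimited text files
#'
#' Writes the four tables as CSV under `dir`, with claim dates as 8-digit
#' strings and `birth_ym` as a 6-digit year-month string.
#' `read_claims_bundle()` on the output reproduces the bundle field for
#' field.
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claims_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  enr <- bundle$enrollment
  enr$birth_ym  <- format_claim_ym(enr$birth_ym)
  enr$obs_start <- format_claim_date(enr$obs_start)
  enr$obs_end   <- format_claim_date(enr$obs_end)
  rx <- bundle$prescriptions
  rx$rx_date <- format_claim_date(rx$rx_date)
  rx$fdc_flag <- as.integer(rx$fdc_flag)
  dx <- bundle$diagnoses
  dx$dx_date <- format_claim_date(dx$dx_date)
  dx$suspected_flag <- as.integer(dx$suspected_flag)
  vis <- bundle$visits
  vis$visit_date <- format_claim_date(vis$visit_date)
  utils::write.csv(enr, file.path(dir, "enrollment.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(rx,  file.path(dir, "prescriptions.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(dx,  file.path(dir, "diagnoses.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(vis, file.path(dir, "visits.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' ATC class tests used throughout the pipeline
#'
#' In the coding scheme used here, `A10` is the antidiabetic class and
#' `A10P` the SGLT2-inhibitor subclass; membership is by code prefix.
#'
#' @param atc_code character vector of ATC codes.
#' @return logical vector.
#' @export
is_sglt2i <- function(atc_code) startsWith(as.character(atc_code), "A10P")

#' @rdname is_sglt2i
#' @export
is_antidiabetic <- function(atc_code) startsWith(as.character(atc_code), "A10")
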