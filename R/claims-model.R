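#' Oral 5-ASA product labels
#'
#' The four interchangeable oral mesalamine (5-aminosalicylic acid) products
#' marketed in Canada: delayed-release tablets and generics
#' (`ASACOL_OR_GENERIC`), controlled-release capsules (`PENTASA`),
#' enteric-coated tablets (`SALOFALK`), and the once-daily multi-matrix
#' formulation (`MEZAVANT`). Additional products can be introduced through a
#' custom drug code map.
#'
#' @return character vector of the four product labels.
#' @export
asa_products <- function() {
  c("ASACOL_OR_GENERIC", "PENTASA", "SALOFALK", "MEZAVANT")
}

#' Drug class labels
#'
#' Classes a dispensing claim can map to: the study drug class (`FIVE_ASA`),
#' corticosteroids (used as prior/concurrent exposure covariates),
#' comorbidity-marker medications (used for comorbidity flags and the chronic
#' disease score), and everything else (`OTHER`).
#'
#' @return character vector of class labels.
#' @export
drug_classes <- function() {
  c("FIVE_ASA", "CORTICOSTEROID", "COMORBIDITY_MARKER", "OTHER")
}

#' Default drug code map
#'
#' Maps raw drug codes to a product label, a drug class, an optional
#' comorbidity indicator, and an optional chronic-disease-score class. This
#' is the map the synthetic claims generator emits codes from; analyses of
#' real claims should supply their own map (see [read_code_map()]).
#'
#' @return data.frame with columns `drug_code`, `product`, `drug_class`,
#'   `comorbidity`, `cds_class` (the last two `NA` where not applicable).
#' @export
default_code_map <- function() {
  data.frame(
    drug_code = c("ASA-400", "PEN-500", "SAL-500", "MEZ-1200",
                  "COR-PRED", "MRK-HTN", "MRK-CARD", "MRK-RESP", "MRK-DIAB"),
    product = c("ASACOL_OR_GENERIC", "PENTASA", "SALOFALK", "MEZAVANT",
                rep("OTHER", 5)),
    drug_class = c(rep("FIVE_ASA", 4), "CORTICOSTEROID",
                   rep("COMORBIDITY_MARKER", 4)),
    comorbidity = c(rep(NA, 5), "hypertension", "heart_disease",
                    "respiratory_illness", "diabetes"),
    cds_class = c(rep(NA, 4), "corticosteroid", "hypertension",
                  "heart_disease", "respiratory_illness", "diabetes"),
    stringsAsFactors = FALSE
  )
}

#' Read a drug code map from YAML
#'
#' The YAML layout is a top-level `codes` mapping from raw drug code to a
#' record with fields `product`, `drug_class`, and optionally `comorbidity`
#' and `cds_class`:
#' ```yaml
#' codes:
#'   ASA-400: {product: ASACOL_OR_GENERIC, drug_class: FIVE_ASA}
#'   MRK-HTN: {drug_class: COMORBIDITY_MARKER, comorbidity: hypertension}
#' ```
#'
#' @param path path to the YAML file.
#' @return data.frame in the layout of [default_code_map()].
#' @export
read_code_map <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$codes)) stop("code map YAML must have a top-level 'codes' map")
  rows <- lapply(names(y$codes), function(code) {
    e <- y$codes[[code]]
    data.frame(
      drug_code = code,
      product = if (is.null(e$product)) "OTHER" else e$product,
      drug_class = if (is.null(e$drug_class)) "OTHER" else e$drug_class,
      comorbidity = if (is.null(e$comorbidity)) NA_character_ else e$comorbidity,
      cds_class = if (is.null(e$cds_class)) NA_character_ else e$cds_class,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, rows)
  validate_code_map(map)
  map
}

validate_code_map <- function(map) {
  check_columns(map, c("drug_code", "product", "drug_class"), "code map")
  bad_class <- setdiff(unique(map$drug_class), drug_classes())
  if (length(bad_class) > 0) {
    stop("unknown drug_class in code map: ", paste(bad_class, collapse = ", "))
  }
  is_asa <- map$drug_class == "FIVE_ASA"
  if (any(is_asa & !(map$product %in% asa_products()))) {
    stop("every FIVE_ASA code must map to one of the 5-ASA products")
  }
  if (any(!is_asa & map$product %in% asa_products())) {
    stop("5-ASA product labels are reserved for drug_class FIVE_ASA")
  }
  invisible(map)
}

read_delim_file <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, sep = sep, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8",
                  encoding = "UTF-8")
}

# Shared row-validity handling: `bad` is a logical vector, `why` a message
# per row. Under "error" policy the first offending line (1-based, counting
# the header as line 1) aborts; under "skip" offenders are dropped with a
# warning.
handle_bad_rows <- function(df, bad, why, on_bad) {
  if (!any(bad)) return(df)
  lines <- which(bad) + 1L
  msg <- sprintf("line %d: %s", lines, why[bad])
  if (on_bad == "error") {
    stop("invalid row(s):\n", paste(msg, collapse = "\n"), call. = FALSE)
  }
  warning(sprintf("skipped %d invalid row(s): %s", sum(bad),
                  paste(msg, collapse = "; ")), call. = FALSE)
  df[!bad, , drop = FALSE]
}

#' Read pharmacy dispensing claims
#'
#' Reads a delimited file with columns `patient_id`, `dispense_date`
#' (ISO 8601), `drug_code`, `quantity`, `days_supply` (an optional
#' `product_label` column is carried through if present), maps each code to
#' a product and drug class, and returns rows sorted by patient then date.
#'
#' @param path file path.
#' @param code_map drug code map (see [default_code_map()]); codes not in the
#'   map get product/class `OTHER`.
#' @param sep field delimiter; comma by default, `"\t"` accepted.
#' @param on_bad `"error"` (default) to fail on the first malformed row,
#'   `"skip"` to drop malformed rows with a warning. Malformed means an
#'   unparseable date or a non-positive `quantity`/`days_supply`.
#' @return data.frame of dispensing claims with derived `product` and
#'   `drug_class` columns, sorted by (`patient_id`, `dispense_date`).
#' @export
read_dispensing_claims <- function(path, code_map = default_code_map(),
                                   sep = ",", on_bad = c("error", "skip")) {
  on_bad <- match.arg(on_bad)
  raw <- read_delim_file(path, sep)
  check_columns(raw, c("patient_id", "dispense_date", "drug_code",
                       "quantity", "days_supply"), "dispensing claims")
  raw$dispense_date <- parse_iso_date(raw$dispense_date)
  raw$quantity <- suppressWarnings(as.numeric(raw$quantity))
  raw$days_supply <- suppressWarnings(as.numeric(raw$days_supply))
  bad_date <- is.na(raw$dispense_date)
  bad_qty <- is.na(raw$quantity) | raw$quantity < 1
  bad_ds <- is.na(raw$days_supply) | raw$days_supply < 1
  why <- rep("", nrow(raw))
  why[bad_ds] <- "days_supply must be a positive integer"
  why[bad_qty] <- "quantity must be a positive count"
  why[bad_date] <- "unparseable dispense_date (expected YYYY-MM-DD)"
  raw <- handle_bad_rows(raw, bad_date | bad_qty | bad_ds, why, on_bad)
  raw$quantity <- as.integer(raw$quantity)
  raw$days_supply <- as.integer(raw$days_supply)
  idx <- match(raw$drug_code, code_map$drug_code)
  raw$product <- ifelse(is.na(idx), "OTHER", code_map$product[idx])
  raw$drug_class <- ifelse(is.na(idx), "OTHER", code_map$drug_class[idx])
  raw <- raw[order(raw$patient_id, raw$dispense_date, raw$drug_code), ,
             drop = FALSE]
  rownames(raw) <- NULL
  raw
}

#' Read medical claims
#'
#' Columns: `patient_id`, `service_date` (ISO 8601), `icd9_code` (three
#' digits optionally followed by a decimal point and one or two digits).
#'
#' @inheritParams read_dispensing_claims
#' @return data.frame sorted by (`patient_id`, `service_date`).
#' @export
read_medical_claims <- function(path, sep = ",", on_bad = c("error", "skip")) {
  on_bad <- match.arg(on_bad)
  raw <- read_delim_file(path, sep)
  check_columns(raw, c("patient_id", "service_date", "icd9_code"),
                "medical claims")
  raw$service_date <- parse_iso_date(raw$service_date)
  bad_date <- is.na(raw$service_date)
  bad_code <- !grepl("^[0-9]{3}(\\.[0-9]{1,2})?$", raw$icd9_code)
  why <- rep("", nrow(raw))
  why[bad_code] <- "icd9_code must be 3 digits with optional .d or .dd"
  why[bad_date] <- "unparseable service_date (expected YYYY-MM-DD)"
  raw <- handle_bad_rows(raw, bad_date | bad_code, why, on_bad)
  raw <- raw[order(raw$patient_id, raw$service_date), , drop = FALSE]
  rownames(raw) <- NULL
  raw
}

#' Read drug-plan eligibility periods
#'
#' Columns: `patient_id`, `start_date`, `end_date` (ISO 8601,
#' `start_date <= end_date`; both ends inclusive).
#'
#' @inheritParams read_dispensing_claims
#' @return data.frame sorted by (`patient_id`, `start_date`).
#' @export
read_eligibility <- function(path, sep = ",", on_bad = c("error", "skip")) {
  on_bad <- match.arg(on_bad)
  raw <- read_delim_file(path, sep)
  check_columns(raw, c("patient_id", "start_date", "end_date"), "eligibility")
  raw$start_date <- parse_iso_date(raw$start_date)
  raw$end_date <- parse_iso_date(raw$end_date)
  bad_date <- is.na(raw$start_date) | is.na(raw$end_date)
  bad_order <- !bad_date & raw$start_date > raw$end_date
  why <- rep("", nrow(raw))
  why[bad_order] <- "start_date must not exceed end_date"
  why[bad_date] <- "unparseable date (expected YYYY-MM-DD)"
  raw <- handle_bad_rows(raw, bad_date | bad_order, why, on_bad)
  raw <- raw[order(raw$patient_id, raw$start_date), , drop = FALSE]
  rownames(raw) <- NULL
  raw
}

#' Read patient demographics
#'
#' Optional companion file with columns `patient_id`, `sex`
#' (`MALE`/`FEMALE`), `birth_year`, and optionally `region`.
#'
#' @inheritParams read_dispensing_claims
#' @return data.frame of one row per patient.
#' @export
read_patients <- function(path, sep = ",") {
  raw <- read_delim_file(path, sep)
  check_columns(raw, c("patient_id", "sex", "birth_year"), "patients")
  bad_sex <- !(raw$sex %in% c("MALE", "FEMALE"))
  if (any(bad_sex)) {
    stop("invalid sex value(s) on line(s): ",
         paste(which(bad_sex) + 1L, collapse = ", "))
  }
  raw$birth_year <- as.integer(raw$birth_year)
  raw[order(raw$patient_id), , drop = FALSE]
}

#' Write and read a cohort table
#'
#' Round-trip safe delimited output for cohort members: reading back a
#' written table reproduces every field exactly (dates as ISO 8601 text,
#' patient ids byte-for-byte including non-ASCII).
#'
#' @param members cohort member data.frame (see [build_cohort()]).
#' @param path output path.
#' @param sep field delimiter.
#' @return `write_cohort_table()` returns `path` invisibly;
#'   `read_cohort_table()` returns the member data.frame.
#' @export
write_cohort_table <- function(members, path, sep = ",") {
  out <- members
  for (col in c("index_date", "window_start", "window_end")) {
    if (col %in% names(out)) out[[col]] <- format(out[[col]], "%Y-%m-%d")
  }
  write_delim_file(out, path, sep)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path, sep = ",") {
  raw <- read_delim_file(path, sep)
  check_columns(raw, c("patient_id", "index_date", "index_product",
                       "window_start", "window_end"), "cohort table")
  for (col in c("index_date", "window_start", "window_end")) {
    raw[[col]] <- parse_iso_date(raw[[col]])
  }
  if ("age_at_index" %in% names(raw)) {
    raw$age_at_index <- as.integer(raw$age_at_index)
  }
  raw
}

# Delimited writer used for all outputs: UTF-8, no row names, no quoting
# surprises (quotes only where needed).
write_delim_file <- function(df, path, sep = ",") {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, row.names = FALSE, qmethod = "double",
                     na = "")
  invisible(path)
}
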