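#' @keywords internal
"_PACKAGE"

# Canonical column set of a household survey table, with type and range
# metadata used by the validator. `required_for` marks fields that feed one
# of the five performance indicators (missing values there drop the record).
household_schema <- function() {
  data.frame(
    field = c("household_id", "village_id", "region", "mae",
              "household_type", "land_ha", "livestock_tlu",
              "crop_diversity", "livestock_diversity", "market_orientation",
              "food_availability", "food_insecure_months", "hdds_good",
              "hdds_lean", "farm_income", "offfarm_income", "ghg_emissions",
              "female_share", "male_share"),
    type = c("character", "character", "character", "numeric", "character",
             rep("numeric", 14)),
    min = c(NA, NA, NA, 0, NA, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, NA, 0, 0),
    max = c(NA, NA, NA, Inf, NA, Inf, Inf, Inf, Inf, 1, Inf, 12, 12, 12,
            Inf, Inf, NA, 1, 1),
    integer = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                FALSE),
    required_for_indicators = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                                FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                                TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

household_types <- function() {
  c("couple", "single_woman", "single_man",
    "married_woman_absent_spouse", "married_man_absent_spouse")
}

#' Read a household survey table
#'
#' Reads a RHoMIS-style household table from CSV or XLSX. Columns are mapped
#' to the canonical schema (see `column_map`), numeric fields are parsed,
#' and missing values are preserved as `NA`. No validation beyond parsing is
#' performed here; see [validate_households()].
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by extension), `"csv"` or `"xlsx"`. XLSX support
#'   requires the readxl package.
#' @param column_map Optional named character vector mapping canonical field
#'   names to the file's column names, e.g.
#'   `c(land_ha = "landcultivated")`. Unmapped fields use their canonical
#'   names.
#' @return A data.frame with one row per household, in file order.
#' @export
read_household_table <- function(path, format = c("auto", "csv", "xlsx"),
                                 column_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the readxl package", call. = FALSE)
      }
      as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
    }
  )

  schema <- household_schema()
  wanted <- schema$field
  src <- stats::setNames(wanted, wanted)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), wanted)
    if (length(bad)) stop("column_map names unknown: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    src[names(column_map)] <- column_map
  }
  missing_cols <- src[!(src %in% names(raw))]
  if (length(missing_cols)) {
    stop("input table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  out <- raw[, src, drop = FALSE]
  names(out) <- wanted
  for (i in seq_len(nrow(schema))) {
    f <- schema$field[i]
    out[[f]] <- if (schema$type[i] == "numeric") {
      suppressWarnings(as.numeric(out[[f]]))
    } else {
      as.character(out[[f]])
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a household survey table
#'
#' CSV writer that round-trips with [read_household_table()]: for a table
#' that passes validation, `read(write(x))` equals `x` field for field.
#'
#' @param records Household table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_household_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a household table and drop unusable records
#'
#' Applies the schema's range and type rules, checks household-id
#' uniqueness and the village-to-region mapping, and drops (with a logged
#' reason) any record whose indicator-required fields are missing or
#' invalid. Negative greenhouse-gas totals are flagged with a warning but
#' kept, as the score only changes sign.
#'
#' @param records Table from [read_household_table()].
#' @param config A [pd_config()]; supplies the known household types.
#' @return A list with elements `records` (the clean table) and `report`
#'   (class `pd_validation`): a data.frame of per-field violations plus
#'   counts of dropped records and warnings.
#' @export
validate_households <- function(records, config = pd_config()) {
  schema <- household_schema()
  n0 <- nrow(records)
  errors <- list()
  warnings <- character()
  note <- function(id, field, violation) {
    errors[[length(errors) + 1]] <<- data.frame(
      household_id = id, field = field, violation = violation,
      stringsAsFactors = FALSE)
  }

  dup <- unique(records$household_id[duplicated(records$household_id)])
  if (length(dup)) {
    stop("duplicated household_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  vr <- unique(records[, c("village_id", "region")])
  multi <- unique(vr$village_id[duplicated(vr$village_id)])
  if (length(multi)) {
    stop("village mapped to more than one region: ",
         paste(multi, collapse = ", "), call. = FALSE)
  }

  drop <- logical(n0)
  tol <- 1e-6
  for (i in seq_len(n0)) {
    rec <- records[i, ]
    id <- rec$household_id
    for (j in seq_len(nrow(schema))) {
      f <- schema$field[j]
      v <- rec[[f]]
      req <- schema$required_for_indicators[j]
      if (is.na(v) || (schema$type[j] == "character" && !nzchar(v))) {
        if (req) { note(id, f, "missing required value"); drop[i] <- TRUE }
        next
      }
      if (schema$type[j] == "numeric") {
        lo <- schema$min[j]; hi <- schema$max[j]
        if (!is.na(lo) && v < lo || !is.na(hi) && v > hi) {
          note(id, f, sprintf("out of range [%s,%s]: %g",
                              format(lo), format(hi), v))
          if (req) drop[i] <- TRUE
        } else if (schema$integer[j] && abs(v - round(v)) > tol) {
          note(id, f, sprintf("not an integer: %g", v))
          if (req) drop[i] <- TRUE
        }
      }
    }
    if (!is.na(rec$household_type) &&
        !(rec$household_type %in% names(config$gender_weights))) {
      note(id, "household_type",
           paste0("unknown household type: ", rec$household_type))
      drop[i] <- TRUE
    }
    if (!is.na(rec$female_share) && !is.na(rec$male_share) &&
        rec$female_share + rec$male_share > 1 + tol) {
      note(id, "female_share", "female_share + male_share exceeds 1")
      drop[i] <- TRUE
    }
    if (!is.na(rec$ghg_emissions) && rec$ghg_emissions < 0) {
      warnings <- c(warnings,
                    sprintf("household %s: negative GHG emissions (%g)",
                            id, rec$ghg_emissions))
    }
  }

  n_drop <- sum(drop)
  if (n0 > 0 && n_drop > 0.5 * n0) {
    stop(sprintf("validation would drop %d of %d records; ",
                 n_drop, n0),
         "this signals a schema mismatch rather than bad records",
         call. = FALSE)
  }
  if (length(warnings)) warning(paste(warnings, collapse = "\n"),
                                call. = FALSE)

  report <- list(
    errors = if (length(errors)) do.call(rbind, errors) else
      data.frame(household_id = character(), field = character(),
                 violation = character(), stringsAsFactors = FALSE),
    n_input = n0,
    n_dropped = n_drop,
    dropped_ids = records$household_id[drop],
    warnings = warnings
  )
  class(report) <- "pd_validation"

  clean <- records[!drop, , drop = FALSE]
  rownames(clean) <- NULL
  list(records = clean, report = report)
}

#' @export
print.pd_validation <- function(x, ...) {
  cat("<pd_validation> ", x$n_input, " records read, ",
      x$n_dropped, " dropped, ", nrow(x$errors), " violation(s), ",
      length(x$warnings), " warning(s)\n", sep = "")
  if (nrow(x$errors)) print(utils::head(x$errors, 10))
  invisible(x)
}

#' Read a practice catalog
#'
#' The catalog links uncommon ("deviant") practices, identified during
#' qualitative follow-up visits, to the positive-deviant households where
#' they were observed.
#'
#' @param path CSV with columns `practice_code`, `positive_deviant_id`,
#'   `description`.
#' @return A data.frame with those three character columns.
#' @export
read_practice_catalog <- function(path) {
  cat_ <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("practice_code", "positive_deviant_id", "description")
  miss <- setdiff(need, names(cat_))
  if (length(miss)) stop("practice catalog lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (f in need) cat_[[f]] <- as.character(cat_[[f]])
  cat_[, need]
}
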