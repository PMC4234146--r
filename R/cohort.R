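#' wamindex: asset-based wealth indices and the WAMI SES index
#'
#' Household socioeconomic status (SES) measurement for multicountry child
#' health studies: indicator screening by Cronbach's alpha, tetrachoric-PCA
#' wealth scoring, random-forest asset selection, an adapted household-level
#' MPI, the composite WAMI index, and a validation framework against child
#' height-for-age Z-scores (HAZ).
#'
#' @keywords internal
#' @aliases wamindex-package
"_PACKAGE"

# ---------------------------------------------------------------------------
# Cohort container
# ---------------------------------------------------------------------------

#' Scalar fields every household record carries
#'
#' Asset indicators live in additional columns named by the indicator.
#' @keywords internal
#' @noRd
.cohort_core_fields <- c(
  "household_id", "site", "haz", "child_age_months", "child_sex",
  "maternal_education_years", "income_local", "currency",
  "people_per_room", "improved_water", "improved_sanitation",
  "any_child_died", "electricity", "natural_flooring", "solid_cooking_fuel"
)

#' Construct a household cohort
#'
#' A cohort is a tibble with one row per surveyed household: a site code,
#' the index child's height-for-age Z-score (`haz`), maternal education in
#' completed years, monthly income in local currency, improved water and
#' sanitation flags, the household-level MPI indicators (any child died,
#' electricity, natural flooring, solid cooking fuel), crowding
#' (`people_per_room`), and one 0/1 column per asset indicator.
#'
#' @param records data frame holding the core fields (see Details) and one
#'   column per asset named in `asset_names`.
#' @param asset_names character vector of asset indicator columns present in
#'   `records`; values must be 0, 1 or `NA`.
#' @param provenance character vector logging the data source and any
#'   filtering applied.
#' @return A tibble of class `wami_cohort` with attributes `asset_names` and
#'   `provenance`.
#' @export
new_cohort <- function(records, asset_names, provenance = character()) {
  records <- tibble::as_tibble(records)
  missing_core <- setdiff(.cohort_core_fields, names(records))
  if (length(missing_core) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_core, collapse = ", "), call. = FALSE)
  }
  missing_assets <- setdiff(asset_names, names(records))
  if (length(missing_assets) > 0) {
    stop("cohort is missing asset column(s): ",
         paste(missing_assets, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(records$household_id)) {
    dup <- records$household_id[duplicated(records$household_id)][1]
    stop("duplicate household_id: ", dup, call. = FALSE)
  }
  for (a in asset_names) {
    v <- records[[a]]
    if (!all(is.na(v) | v %in% c(0, 1))) {
      stop("asset indicator '", a, "' contains values other than 0/1/NA",
           call. = FALSE)
    }
  }
  if (any(!is.na(records$haz) & !is.finite(records$haz))) {
    stop("haz must be finite where present", call. = FALSE)
  }
  structure(records,
            asset_names = as.character(asset_names),
            provenance = provenance,
            class = c("wami_cohort", class(records)))
}

#' Asset indicator names of a cohort
#' @param cohort a `wami_cohort`.
#' @return Character vector of asset column names.
#' @export
asset_names <- function(cohort) attr(cohort, "asset_names")

#' @export
print.wami_cohort <- function(x, ...) {
  cat(sprintf("<wami_cohort> %d households, %d sites, %d asset indicators\n",
              nrow(x), length(unique(x$site)), length(asset_names(x))))
  NextMethod()
}

.append_provenance <- function(cohort, msg) {
  attr(cohort, "provenance") <- c(attr(cohort, "provenance"), msg)
  cohort
}

# ---------------------------------------------------------------------------
# Currency conversion
# ---------------------------------------------------------------------------

#' Construct a currency conversion table
#'
#' @param rates named numeric vector, ISO-4217 code -> USD per unit of local
#'   currency; all rates must be strictly positive.
#' @param date the date the exchange rates refer to (e.g. `"2010-01-01"`).
#' @return A `currency_table` object.
#' @examples
#' ct <- currency_table(c(USD = 1, BDT = 0.0145), date = "2010-01-01")
#' convert_income_usd(1000, "BDT", ct)
#' @export
currency_table <- function(rates, date = NA_character_) {
  rates <- unlist(rates)
  if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
    stop("rates must be a named vector of ISO-4217 codes", call. = FALSE)
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("exchange rates must be strictly positive", call. = FALSE)
  }
  structure(list(rates = rates, date = as.character(date)),
            class = "currency_table")
}

#' Convert local-currency income to USD
#'
#' @param income_local non-negative income amount(s) in local currency.
#' @param currency ISO-4217 code(s), recycled against `income_local`.
#' @param table a [currency_table()].
#' @return Income in USD.
#' @export
convert_income_usd <- function(income_local, currency, table) {
  stopifnot(inherits(table, "currency_table"))
  unknown <- setdiff(unique(currency), names(table$rates))
  if (length(unknown) > 0) {
    stop("unknown currency code(s): ", paste(unknown, collapse = ", "),
         "; known codes: ", paste(names(table$rates), collapse = ", "),
         call. = FALSE)
  }
  if (any(income_local < 0, na.rm = TRUE)) {
    stop("income_local must be non-negative", call. = FALSE)
  }
  unname(income_local * table$rates[currency])
}

#' Attach a USD income column to a cohort
#'
#' @param cohort a `wami_cohort`.
#' @param table a [currency_table()].
#' @return The cohort with an `income_usd` column.
#' @export
add_income_usd <- function(cohort, table) {
  cohort$income_usd <- convert_income_usd(cohort$income_local,
                                          cohort$currency, table)
  .append_provenance(cohort,
                     sprintf("income converted to USD (rates dated %s)",
                             table$date))
}

# ---------------------------------------------------------------------------
# Anthropometric filtering and stunting
# ---------------------------------------------------------------------------

#' Exclude households with missing or extreme HAZ
#'
#' Removes records with missing HAZ, then records with |HAZ| above
#' `haz_abs_limit` (default 6, the WHO biological-plausibility flagging
#' bound). Idempotent.
#'
#' @param cohort a `wami_cohort`.
#' @param haz_abs_limit positive Z-score bound; records with |HAZ| strictly
#'   above it are dropped.
#' @return A list with elements `cohort` (the filtered cohort) and
#'   `exclusions`, a list counting `missing_haz` and `extreme_haz` and
#'   recording the excluded `household_id`s.
#' @export
filter_anthropometry <- function(cohort, haz_abs_limit = 6) {
  stopifnot(inherits(cohort, "wami_cohort"), haz_abs_limit > 0)
  miss <- is.na(cohort$haz)
  extreme <- !miss & abs(cohort$haz) > haz_abs_limit
  keep <- !miss & !extreme
  log <- list(
    missing_haz = sum(miss),
    extreme_haz = sum(extreme),
    haz_abs_limit = haz_abs_limit,
    excluded_ids = cohort$household_id[!keep]
  )
  out <- cohort[keep, , drop = FALSE]
  out <- new_cohort(out, asset_names(cohort), attr(cohort, "provenance"))
  out <- .append_provenance(out, sprintf(
    "anthropometric filter |HAZ| <= %g: %d missing, %d extreme excluded",
    haz_abs_limit, log$missing_haz, log$extreme_haz))
  list(cohort = out, exclusions = log)
}

#' Classify stunting from a height-for-age Z-score
#'
#' Stunting is HAZ strictly below -2 (two standard deviations below the
#' growth-reference median); HAZ = -2 exactly is not stunted.
#'
#' @param haz numeric HAZ value(s); must be non-missing and finite.
#' @return Integer 0/1 vector.
#' @examples
#' is_stunted(c(-2.01, -2, 0.5))
#' @export
is_stunted <- function(haz) {
  if (any(is.na(haz)) || any(!is.finite(haz))) {
    stop("haz must be non-missing and finite", call. = FALSE)
  }
  as.integer(haz < -2)
}

# ---------------------------------------------------------------------------
# CSV + codebook I/O
# ---------------------------------------------------------------------------

#' Read a household cohort from CSV using a codebook
#'
#' The codebook (a YAML/JSON file or an equivalent list) maps the package's
#' canonical field names to the CSV's column names, names the asset
#' indicator columns, and supplies the 0/1 coding table for indicator cells
#' plus an optional currency table. Unparseable indicator cells are recorded
#' as missing with a warning.
#'
#' @param path path to a comma-separated UTF-8 file with a header row.
#' @param codebook path to a YAML or JSON codebook, or a list with elements
#'   `columns` (canonical name -> CSV column), `assets` (indicator name ->
#'   CSV column), optional `indicator_coding` (cell value -> 0/1) and
#'   optional `currency_table` (`rates`, `date`).
#' @return A `wami_cohort`; if the codebook carries a currency table an
#'   `income_usd` column is attached.
#' @export
read_cohort <- function(path, codebook) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cb <- .load_codebook(codebook)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")

  colmap <- unlist(cb$columns)
  required <- c("household_id", "site", "haz")
  miss_req <- setdiff(required, names(colmap))
  if (length(miss_req) > 0) {
    stop("codebook does not map required field(s): ",
         paste(miss_req, collapse = ", "), call. = FALSE)
  }
  wanted <- c(colmap, unlist(cb$assets))
  absent <- setdiff(unname(wanted), names(raw))
  if (length(absent) > 0) {
    stop("input is missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  coding <- .indicator_coding(cb)
  rec <- tibble::tibble(.rows = nrow(raw))
  numeric_fields <- c("haz", "child_age_months", "maternal_education_years",
                      "income_local", "people_per_room")
  binary_fields <- c("improved_water", "improved_sanitation",
                     "any_child_died", "electricity", "natural_flooring",
                     "solid_cooking_fuel", "child_sex")
  for (f in .cohort_core_fields) {
    if (!f %in% names(colmap)) {
      rec[[f]] <- if (f == "currency") NA_character_ else NA_real_
      next
    }
    v <- raw[[colmap[[f]]]]
    rec[[f]] <- if (f %in% numeric_fields) {
      suppressWarnings(as.numeric(v))
    } else if (f %in% binary_fields) {
      .decode_indicator(v, coding, colmap[[f]])
    } else {
      as.character(v)
    }
  }
  assets <- names(cb$assets)
  for (a in assets) {
    rec[[a]] <- .decode_indicator(raw[[cb$assets[[a]]]], coding, a)
  }
  cohort <- new_cohort(rec, assets,
                       provenance = sprintf("read from %s", path))
  if (!is.null(cb$currency_table)) {
    ct <- currency_table(cb$currency_table$rates,
                         date = cb$currency_table$date %||% NA_character_)
    cohort <- add_income_usd(cohort, ct)
  }
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_codebook <- function(codebook) {
  if (is.character(codebook) && length(codebook) == 1) {
    if (!file.exists(codebook)) {
      stop("codebook file not found: ", codebook, call. = FALSE)
    }
    if (grepl("\\.json$", codebook, ignore.case = TRUE)) {
      return(jsonlite::read_json(codebook, simplifyVector = FALSE))
    }
    return(yaml::read_yaml(codebook))
  }
  if (!is.list(codebook)) stop("codebook must be a path or a list",
                               call. = FALSE)
  codebook
}

.indicator_coding <- function(cb) {
  coding <- c("0" = 0, "1" = 1)
  if (!is.null(cb$indicator_coding)) {
    extra <- unlist(cb$indicator_coding)
    coding[names(extra)] <- as.numeric(extra)
  }
  coding
}

#' Decode raw indicator cells to 0/1/NA via the codebook coding table
#' @noRd
.decode_indicator <- function(v, coding, what) {
  key <- trimws(as.character(v))
  out <- unname(coding[key])
  bad <- !is.na(key) & nzchar(key) & is.na(out)
  if (any(bad)) {
    warning(sprintf("%d unparseable value(s) in '%s' recorded as missing",
                    sum(bad), what), call. = FALSE)
  }
  out
}

#' Write a cohort back to CSV
#'
#' Round-trips all typed fields; asset columns are written as 0/1.
#'
#' @param cohort a `wami_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an exclusion log as JSON
#' @param exclusions the `exclusions` element of [filter_anthropometry()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(exclusions, path) {
  jsonlite::write_json(exclusions, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
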