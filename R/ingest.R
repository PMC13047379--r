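# Ingest: parse raw Darwin-Core-style tables, apply the five quality-filter
# rules with a complete audit log, standardise countries to ISO 3166-1
# alpha-3, resolve holding countries from institution codes, and assign
# collecting periods.

.filter_rules <- c(
  "basis_of_record", "missing_origin", "unresolved_holding",
  "out_of_range_year", "missing_year", "absent_status", "zero_count",
  "invalid_country"
)

#' Period specification
#'
#' Ordered, non-overlapping, contiguous year bins. Each bin carries a label
#' and its arithmetic midpoint, the continuous predictor used by the trend
#' models.
#'
#' @param start_year,end_year Integer vectors of inclusive bin bounds.
#' @param labels Optional labels; default `"start-end"`.
#' @return Data frame of class `period_spec` with columns `label`,
#'   `start_year`, `end_year`, `midpoint`.
#' @export
#' @examples
#' default_periods()
#' assign_period(c(1929, 1930, 2020), default_periods())
period_spec <- function(start_year, end_year, labels = NULL) {
  stopifnot(length(start_year) == length(end_year), length(start_year) >= 1)
  ord <- order(start_year)
  start_year <- as.integer(start_year[ord]); end_year <- as.integer(end_year[ord])
  if (any(end_year < start_year)) stop("end_year must be >= start_year")
  if (length(start_year) > 1 &&
      any(start_year[-1] != end_year[-length(end_year)] + 1L))
    stop("periods must be contiguous and non-overlapping")
  if (is.null(labels)) labels <- paste0(start_year, "-", end_year)
  out <- data.frame(label = labels[ord], start_year = start_year,
                    end_year = end_year,
                    midpoint = (start_year + end_year) / 2,
                    stringsAsFactors = FALSE)
  class(out) <- c("period_spec", "data.frame")
  out
}

#' Default four collecting periods, 1900-2020
#'
#' Approximately 30-year bins (the last spans 31 years) with midpoints 1915,
#' 1945, 1975 and 2005.
#' @return A [period_spec()].
#' @export
default_periods <- function() {
  ps <- period_spec(c(1900L, 1930L, 1960L, 1990L),
                    c(1929L, 1959L, 1989L, 2020L))
  ps$midpoint <- c(1915, 1945, 1975, 2005)
  ps
}

#' Alternative temporal binnings for sensitivity analysis
#'
#' @param type `"decadal"` (twelve bins, the last spanning 2010-2020) or
#'   `"forty"` (three roughly 40-year bins).
#' @return A [period_spec()].
#' @export
alternative_periods <- function(type = c("decadal", "forty")) {
  type <- match.arg(type)
  if (type == "decadal") {
    starts <- seq(1900L, 2010L, by = 10L)
    ends <- c(seq(1909L, 2009L, by = 10L), 2020L)
    period_spec(starts, ends)
  } else {
    period_spec(c(1900L, 1940L, 1980L), c(1939L, 1979L, 2020L))
  }
}

#' Assign years to periods
#'
#' @param year Integer vector of years.
#' @param periods A [period_spec()].
#' @return Character vector of period labels.
#' @export
assign_period <- function(year, periods = default_periods()) {
  year <- as.integer(year)
  idx <- findInterval(year, periods$start_year)
  bad <- is.na(year) | idx == 0L | year > periods$end_year[pmax(idx, 1L)]
  if (any(bad))
    stop("year(s) outside configured periods: ",
         paste(unique(year[bad]), collapse = ", "))
  periods$label[idx]
}

.dwc_columns <- c(
  family = "family", basisOfRecord = "basisOfRecord", country = "country",
  countryCode = "countryCode", institutionCode = "institutionCode",
  ownerInstitutionCode = "ownerInstitutionCode", year = "year",
  eventDate = "eventDate", individualCount = "individualCount",
  occurrenceStatus = "occurrenceStatus"
)
.optional_dwc <- c("countryCode", "ownerInstitutionCode", "eventDate")

#' Parse a raw occurrence table
#'
#' Reads a delimited file (or accepts a data frame) and maps Darwin-Core-style
#' column names onto the canonical internal layout. No filtering is
#' performed; all fields are kept as character. Unmapped extra columns are
#' ignored. Missing non-optional mapped columns are a hard error naming the
#' column; missing optional columns (`countryCode`, `ownerInstitutionCode`,
#' `eventDate`) are filled with empty strings.
#'
#' @param path A file path, or a data frame already in memory.
#' @param column_mapping Named character vector mapping canonical names (see
#'   names of the default) to the column names present in the file.
#' @param delimiter Field delimiter; `","` by default, use `"\t"` for TSV.
#' @return Data frame of raw character rows with canonical column names.
#' @export
parse_occurrences <- function(path, column_mapping = .dwc_columns,
                              delimiter = ",") {
  raw <- if (is.data.frame(path)) path else
    utils::read.table(path, header = TRUE, sep = delimiter, quote = "\"",
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "",
                      na.strings = NULL)
  mapping <- .dwc_columns
  mapping[names(column_mapping)] <- column_mapping
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(mapping)) {
    src <- mapping[[canon]]
    if (src %in% names(raw)) {
      out[[canon]] <- as.character(raw[[src]])
    } else if (canon %in% .optional_dwc) {
      out[[canon]] <- rep("", nrow(raw))
    } else {
      stop("required column missing from input: ", src)
    }
  }
  out[is.na(out)] <- ""
  if (".defect" %in% names(raw)) out$.defect <- raw$.defect
  out
}

#' Standardise country values to ISO 3166-1 alpha-3
#'
#' Exact-match resolution (trimmed, case-insensitive) against a lookup table
#' of names and codes. Unresolved values return `NA` -- never a guess;
#' historical entities (USSR, Yugoslavia, ...) resolve only if the caller
#' supplies explicit override rows via [country_lookup()].
#'
#' @param value Character vector of raw country names or codes.
#' @param lookup Lookup table from [country_lookup()].
#' @return Character vector of ISO3 codes, `NA` where unresolved.
#' @export
standardize_country <- function(value, lookup = country_lookup()) {
  key <- tolower(trimws(as.character(value)))
  key[key == ""] <- NA
  lut <- stats::setNames(lookup$iso3, tolower(trimws(lookup$name)))
  unname(lut[key])
}

#' Resolve the holding country of a record
#'
#' `ownerInstitutionCode` takes precedence when present and resolvable in the
#' registry; otherwise `institutionCode` is used; otherwise `NA`.
#'
#' @param institution_code,owner_institution_code Character vectors.
#' @param registry Registry data frame (`institution_code`, `country_iso3`).
#' @return Character vector of ISO3 codes, `NA` where unresolved.
#' @export
resolve_holding_country <- function(institution_code, owner_institution_code,
                                    registry) {
  lut <- stats::setNames(registry$country_iso3,
                         toupper(trimws(registry$institution_code)))
  own <- unname(lut[toupper(trimws(as.character(owner_institution_code)))])
  ins <- unname(lut[toupper(trimws(as.character(institution_code)))])
  ifelse(!is.na(own), own, ins)
}

#' Filter raw occurrence rows into clean records, with a full audit log
#'
#' Applies the quality rules in a fixed order -- basis of record, missing
#' origin, unresolved holding institution, out-of-range year, missing year,
#' non-present occurrence status, zero count, invalid origin country -- and
#' attributes each removed row to the first rule it fails. Surviving records
#' carry resolved ISO3 origin and holding countries, an in-range year, and a
#' positive integer specimen count (missing or non-numeric counts are treated
#' as a single specimen). A four-digit year parsed from `eventDate` is used
#' only when the `year` column is empty.
#'
#' @param raw Raw rows from [parse_occurrences()].
#' @param registry Institution registry (`institution_code`, `country_iso3`).
#' @param lookup Country lookup from [country_lookup()].
#' @param year_range Inclusive retention window, default `c(1900, 2020)`.
#' @return List with `records` (data frame: `family`, `origin_country`,
#'   `holding_country`, `year`, `count`, `source_row`) and `log` (class
#'   `filter_log`: per-rule removal counts, `input_total`, `output_total`).
#' @export
filter_records <- function(raw, registry, lookup = country_lookup(),
                           year_range = c(1900L, 2020L)) {
  n <- nrow(raw)
  removed <- rep(NA_character_, n)
  mark <- function(cond, rule) {
    hit <- cond & is.na(removed)
    removed[hit] <<- rule
  }

  basis <- toupper(gsub("[^A-Za-z]", "", raw$basisOfRecord))
  mark(basis != "PRESERVEDSPECIMEN", "basis_of_record")

  origin_raw <- ifelse(nzchar(trimws(raw$countryCode)),
                       trimws(raw$countryCode), trimws(raw$country))
  mark(!nzchar(origin_raw), "missing_origin")

  holding <- resolve_holding_country(raw$institutionCode,
                                     raw$ownerInstitutionCode, registry)
  mark(is.na(holding), "unresolved_holding")

  year_col <- suppressWarnings(as.integer(trimws(raw$year)))
  ed_year <- suppressWarnings(as.integer(
    ifelse(grepl("^[0-9]{4}", raw$eventDate),
           substr(raw$eventDate, 1, 4), NA)))
  year_val <- ifelse(is.na(year_col), ed_year, year_col)
  mark(!is.na(year_val) &
         (year_val < year_range[1] | year_val > year_range[2]),
       "out_of_range_year")
  mark(is.na(year_val), "missing_year")

  status <- tolower(trimws(raw$occurrenceStatus))
  mark(nzchar(status) & status != "present", "absent_status")

  count_val <- suppressWarnings(as.numeric(trimws(raw$individualCount)))
  count_val[is.na(count_val)] <- 1      # missing => single specimen
  mark(count_val < 1, "zero_count")

  origin_iso <- standardize_country(origin_raw, lookup)
  mark(is.na(origin_iso), "invalid_country")

  keep <- is.na(removed)
  records <- data.frame(
    family = raw$family[keep],
    origin_country = origin_iso[keep],
    holding_country = holding[keep],
    year = year_val[keep],
    count = as.integer(round(count_val[keep])),
    source_row = which(keep),
    stringsAsFactors = FALSE
  )
  counts <- table(factor(removed, levels = .filter_rules))
  log <- structure(
    list(removed = stats::setNames(as.integer(counts), .filter_rules),
         input_total = n, output_total = nrow(records)),
    class = "filter_log")
  list(records = records, log = log)
}

#' @export
print.filter_log <- function(x, ...) {
  cat("Occurrence filter log\n")
  cat(sprintf("  input rows:  %d\n", x$input_total))
  cat(sprintf("  output rows: %d\n", x$output_total))
  for (r in names(x$removed))
    cat(sprintf("  removed [%s]: %d\n", r, x$removed[[r]]))
  invisible(x)
}

#' Serialise a filter log as JSON
#' @param log A `filter_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(log, path) {
  jsonlite::write_json(
    list(removed = as.list(log$removed), input_total = log$input_total,
         output_total = log$output_total),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
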