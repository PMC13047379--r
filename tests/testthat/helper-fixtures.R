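# Shared fixtures, all built in code.

fix_registry <- function() {
  data.frame(institution_code = c("AMNH", "NHMO", "NHMD", "ZMUC"),
             country_iso3 = c("USA", "NOR", "DNK", "DNK"),
             stringsAsFactors = FALSE)
}

raw_row <- function(family = "Canidae", basis = "PreservedSpecimen",
                    country = "", countryCode = "KEN",
                    institutionCode = "AMNH", ownerInstitutionCode = "",
                    year = "1950", eventDate = "", individualCount = "1",
                    occurrenceStatus = "present") {
  data.frame(family = family, basisOfRecord = basis, country = country,
             countryCode = countryCode, institutionCode = institutionCode,
             ownerInstitutionCode = ownerInstitutionCode, year = year,
             eventDate = eventDate, individualCount = individualCount,
             occurrenceStatus = occurrenceStatus, stringsAsFactors = FALSE)
}

# One row per defect class (in filter-rule order) plus one clean row.
nine_row_fixture <- function() {
  rbind(
    raw_row(basis = "FossilSpecimen"),                 # basis_of_record
    raw_row(countryCode = "", country = ""),           # missing_origin
    raw_row(institutionCode = "NOPE"),                 # unresolved_holding
    raw_row(year = "1899"),                            # out_of_range_year
    raw_row(year = "", eventDate = ""),                # missing_year
    raw_row(occurrenceStatus = "absent"),              # absent_status
    raw_row(individualCount = "0"),                    # zero_count
    raw_row(countryCode = "Narnia"),                   # invalid_country
    raw_row()                                          # clean
  )
}

# Six records over two periods for hand-traced aggregation checks:
#   KEN -> USA: counts 1, 1, 2  => weight 4
#   USA -> USA: count 5         => domestic ledger only
#   NOR -> DNK: count 3; DNK -> NOR: count 1
six_record_slice <- function() {
  data.frame(
    family = "Canidae",
    origin_country = c("KEN", "KEN", "KEN", "USA", "NOR", "DNK"),
    holding_country = c("USA", "USA", "USA", "USA", "DNK", "NOR"),
    year = c(1910, 1911, 1912, 1913, 1914, 1915),
    count = c(1, 1, 2, 5, 3, 1),
    source_row = 1:6,
    stringsAsFactors = FALSE)
}

small_synth <- function(seed = 42, n = 4000, ...) {
  synth_config(n_origin_countries = 30, n_holding_countries = 12,
               n_records = n, seed = seed, ...)
}

# Rebuild a raw table from filtered records (for idempotence checks): each
# record becomes a clean row whose institution maps to its holding country.
records_to_raw <- function(records, registry) {
  inst_of <- stats::setNames(registry$institution_code, registry$country_iso3)
  raw_row(family = records$family,
          countryCode = records$origin_country,
          institutionCode = unname(inst_of[records$holding_country]),
          year = as.character(records$year),
          individualCount = as.character(records$count))
}
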