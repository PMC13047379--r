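# Country code machinery: the ISO 3166-1 alpha-3 universe used throughout,
# a default ordering that puts plausible repository nations first, and the
# name -> code lookup used by standardize_country().

# Full ISO 3166-1 alpha-3 assignment set (249 codes).
.iso3_all <- c(
  "ABW", "AFG", "AGO", "AIA", "ALA", "ALB", "AND", "ARE", "ARG", "ARM",
  "ASM", "ATA", "ATF", "ATG", "AUS", "AUT", "AZE", "BDI", "BEL", "BEN",
  "BES", "BFA", "BGD", "BGR", "BHR", "BHS", "BIH", "BLM", "BLR", "BLZ",
  "BMU", "BOL", "BRA", "BRB", "BRN", "BTN", "BVT", "BWA", "CAF", "CAN",
  "CCK", "CHE", "CHL", "CHN", "CIV", "CMR", "COD", "COG", "COK", "COL",
  "COM", "CPV", "CRI", "CUB", "CUW", "CXR", "CYM", "CYP", "CZE", "DEU",
  "DJI", "DMA", "DNK", "DOM", "DZA", "ECU", "EGY", "ERI", "ESH", "ESP",
  "EST", "ETH", "FIN", "FJI", "FLK", "FRA", "FRO", "FSM", "GAB", "GBR",
  "GEO", "GGY", "GHA", "GIB", "GIN", "GLP", "GMB", "GNB", "GNQ", "GRC",
  "GRD", "GRL", "GTM", "GUF", "GUM", "GUY", "HKG", "HMD", "HND", "HRV",
  "HTI", "HUN", "IDN", "IMN", "IND", "IOT", "IRL", "IRN", "IRQ", "ISL",
  "ISR", "ITA", "JAM", "JEY", "JOR", "JPN", "KAZ", "KEN", "KGZ", "KHM",
  "KIR", "KNA", "KOR", "KWT", "LAO", "LBN", "LBR", "LBY", "LCA", "LIE",
  "LKA", "LSO", "LTU", "LUX", "LVA", "MAC", "MAF", "MAR", "MCO", "MDA",
  "MDG", "MDV", "MEX", "MHL", "MKD", "MLI", "MLT", "MMR", "MNE", "MNG",
  "MNP", "MOZ", "MRT", "MSR", "MTQ", "MUS", "MWI", "MYS", "MYT", "NAM",
  "NCL", "NER", "NFK", "NGA", "NIC", "NIU", "NLD", "NOR", "NPL", "NRU",
  "NZL", "OMN", "PAK", "PAN", "PCN", "PER", "PHL", "PLW", "PNG", "POL",
  "PRI", "PRK", "PRT", "PRY", "PSE", "PYF", "QAT", "REU", "ROU", "RUS",
  "RWA", "SAU", "SDN", "SEN", "SGP", "SGS", "SHN", "SJM", "SLB", "SLE",
  "SLV", "SMR", "SOM", "SPM", "SRB", "SSD", "STP", "SUR", "SVK", "SVN",
  "SWE", "SWZ", "SXM", "SYC", "SYR", "TCA", "TCD", "TGO", "THA", "TJK",
  "TKL", "TKM", "TLS", "TON", "TTO", "TUN", "TUR", "TUV", "TWN", "TZA",
  "UGA", "UKR", "UMI", "URY", "USA", "UZB", "VAT", "VCT", "VEN", "VGB",
  "VIR", "VNM", "VUT", "WLF", "WSM", "YEM", "ZAF", "ZMB", "ZWE"
)

# Countries that plausibly act as major specimen repositories; used as the
# head of the default holding-country pool so small synthetic worlds look
# like the GBIF-visible geography (US/Scandinavia/western Europe heavy).
.default_holders <- c(
  "USA", "NOR", "CAN", "DNK", "SWE", "FIN", "NLD", "JPN", "BEL", "DEU",
  "AUS", "GBR", "FRA", "MEX", "ESP", "CHE", "AUT", "ITA", "RUS", "ZAF",
  "BRA", "ARG", "NZL", "CHN", "IND", "POL", "CZE", "HUN", "PRT", "IRL",
  "ISR", "KOR", "COL", "CHL", "PER", "KEN", "EST", "LVA", "LTU", "UKR",
  "GRC", "TUR", "THA", "MYS"
)

.common_names <- c(
  "United States"            = "USA",
  "United States of America" = "USA",
  "Norway"                   = "NOR",
  "Canada"                   = "CAN",
  "Denmark"                  = "DNK",
  "Sweden"                   = "SWE",
  "Finland"                  = "FIN",
  "Netherlands"              = "NLD",
  "Japan"                    = "JPN",
  "Belgium"                  = "BEL",
  "Germany"                  = "DEU",
  "Australia"                = "AUS",
  "United Kingdom"           = "GBR",
  "France"                   = "FRA",
  "Mexico"                   = "MEX",
  "Spain"                    = "ESP",
  "Switzerland"              = "CHE",
  "Austria"                  = "AUT",
  "Italy"                    = "ITA",
  "Russia"                   = "RUS",
  "Russian Federation"       = "RUS",
  "South Africa"             = "ZAF",
  "Brazil"                   = "BRA",
  "Argentina"                = "ARG",
  "New Zealand"              = "NZL",
  "China"                    = "CHN",
  "India"                    = "IND",
  "Kenya"                    = "KEN",
  "Colombia"                 = "COL",
  "Ecuador"                  = "ECU",
  "Peru"                     = "PER",
  "Chile"                    = "CHL",
  "Bolivia"                  = "BOL",
  "Tanzania"                 = "TZA",
  "Uganda"                   = "UGA",
  "Ethiopia"                 = "ETH",
  "Nigeria"                  = "NGA",
  "Ghana"                    = "GHA",
  "Madagascar"               = "MDG",
  "Indonesia"                = "IDN",
  "Malaysia"                 = "MYS",
  "Thailand"                 = "THA",
  "Vietnam"                  = "VNM",
  "Viet Nam"                 = "VNM",
  "Philippines"              = "PHL",
  "Mongolia"                 = "MNG",
  "Turkey"                   = "TUR",
  "Greece"                   = "GRC",
  "Poland"                   = "POL",
  "Czechia"                  = "CZE",
  "Czech Republic"           = "CZE",
  "Hungary"                  = "HUN",
  "Portugal"                 = "PRT",
  "Ireland"                  = "IRL",
  "Iceland"                  = "ISL",
  "Greenland"                = "GRL",
  "Democratic Republic of the Congo" = "COD",
  "Republic of the Congo"    = "COG",
  "Congo, Democratic Republic of the" = "COD",
  "Ivory Coast"              = "CIV",
  "Cote d'Ivoire"            = "CIV",
  "South Korea"              = "KOR",
  "Republic of Korea"        = "KOR",
  "Iran"                     = "IRN",
  "Venezuela"                = "VEN",
  "Guyana"                   = "GUY",
  "Suriname"                 = "SUR",
  "Papua New Guinea"         = "PNG",
  "Namibia"                  = "NAM",
  "Botswana"                 = "BWA",
  "Zimbabwe"                 = "ZWE",
  "Zambia"                   = "ZMB",
  "Mozambique"               = "MOZ",
  "Egypt"                    = "EGY",
  "Morocco"                  = "MAR",
  "Ukraine"                  = "UKR",
  "Estonia"                  = "EST",
  "Latvia"                   = "LVA",
  "Lithuania"                = "LTU"
)

#' ISO 3166-1 alpha-3 country codes
#'
#' The full set of 249 alpha-3 codes used as the country universe, ordered so
#' that plausible repository nations come first. Synthetic-data pools take
#' prefixes of this vector, which makes a small holding pool resemble the real
#' geography of museum infrastructure.
#'
#' @param ordered If `TRUE` (default) repository-heavy ordering; if `FALSE`,
#'   alphabetical.
#' @return Character vector of alpha-3 codes.
#' @export
iso3_codes <- function(ordered = TRUE) {
  if (!ordered) return(.iso3_all)
  c(.default_holders, setdiff(.iso3_all, .default_holders))
}

#' Country-name lookup table
#'
#' Builds the lookup used by [standardize_country()]: identity rows for every
#' valid alpha-3 code, a set of common English country names, and optional
#' caller-supplied override rows (e.g. historical entities such as
#' `"USSR" -> "RUS"`). Matching is exact after trimming and case-folding;
#' there is deliberately no fuzzy matching, so anything absent from the table
#' fails standardisation and is logged rather than guessed.
#'
#' @param overrides Optional two-column data frame (`name`, `iso3`) appended
#'   to the built-in rows; later rows win on duplicated names.
#' @return A data frame with character columns `name` and `iso3`.
#' @export
#' @examples
#' lk <- country_lookup()
#' standardize_country(c("Kenya", "KEN", "Atlantis"), lk)
country_lookup <- function(overrides = NULL) {
  tbl <- rbind(
    data.frame(name = .iso3_all, iso3 = .iso3_all, stringsAsFactors = FALSE),
    data.frame(name = names(.common_names), iso3 = unname(.common_names),
               stringsAsFactors = FALSE)
  )
  if (!is.null(overrides)) {
    if (!all(c("name", "iso3") %in% names(overrides)))
      stop("`overrides` must have columns `name` and `iso3`")
    tbl <- rbind(tbl, overrides[, c("name", "iso3")])
  }
  tbl
}

is_iso3 <- function(x) x %in% .iso3_all
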