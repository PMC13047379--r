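# Synthetic occurrence-record generator. Emulates the statistical structure
# of GBIF-style preserved-specimen data: many origin countries feeding a
# concentrated set of holding countries, low bidirectional exchange, domestic
# retention (self-loops), a four-period temporal spread, and realistic
# contamination (missing dates, invalid codes, zero counts, non-specimen
# records). Every knob maps to a measurable property downstream, so the whole
# pipeline is testable without external downloads.

.defect_names <- c(
  "missing_year", "pre_1900_year", "invalid_country_code", "missing_origin",
  "missing_institution", "zero_count", "non_specimen_basis", "absent_status"
)

#' Configuration for the synthetic occurrence generator
#'
#' Defaults describe a world the size and shape of the real digitised record:
#' 178 origin countries, 44 holding countries, 312,456 raw rows of which
#' roughly 19% carry a defect (leaving ~253k clean records), holdings
#' concentration tuned to a Gini near 0.86, reciprocity near 0.08, and more
#' records in 1960-1989 than in other periods.
#'
#' @param n_origin_countries Number of countries specimens can originate from.
#' @param n_holding_countries Number of countries holding specimens.
#' @param n_records Total rows emitted (clean + defect rows).
#' @param concentration_alpha Symmetric Dirichlet parameter over
#'   holding-country shares. Small values concentrate holdings in few
#'   countries (high Gini); large values spread them evenly.
#' @param reciprocity_target Probability that a realised directed country
#'   pair (both countries holders) also receives reverse-direction records.
#'   `NA` disables the adjustment entirely, leaving pair directions exactly
#'   as drawn (useful for clean parameter-recovery experiments).
#' @param domestic_fraction Share of records collected and held in the same
#'   country (self-loops).
#' @param period_weights Four non-negative weights (sum 1) over the default
#'   collecting periods.
#' @param contamination_rates Named numeric vector of per-row defect
#'   probabilities for the eight defect classes (see `.defect_names`);
#'   defects are mutually exclusive per row.
#' @param families Character vector of family names.
#' @param family_weights Sampling weights for families (defaults follow the
#'   observed 37/16/47 Canidae/Felidae/Mustelidae split).
#' @param holders_in_origin_pool If `TRUE` (default) holding countries are a
#'   subset of the origin pool, mirroring the real 178-origin/44-holder
#'   asymmetry.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_origin_countries = 178,
                         n_holding_countries = 44,
                         n_records = 312456,
                         concentration_alpha = 0.1,
                         reciprocity_target = 0.08,
                         domestic_fraction = 0.3,
                         period_weights = c(0.20, 0.26, 0.31, 0.23),
                         contamination_rates = c(
                           missing_year = 0.080,
                           pre_1900_year = 0.030,
                           invalid_country_code = 0.015,
                           missing_origin = 0.030,
                           missing_institution = 0.020,
                           zero_count = 0.005,
                           non_specimen_basis = 0.005,
                           absent_status = 0.005
                         ),
                         families = c("Canidae", "Felidae", "Mustelidae"),
                         family_weights = c(0.373, 0.162, 0.465),
                         holders_in_origin_pool = TRUE,
                         seed = 1L) {
  rates <- numeric(length(.defect_names))
  names(rates) <- .defect_names
  if (length(contamination_rates)) {
    bad <- setdiff(names(contamination_rates), .defect_names)
    if (length(bad)) stop("unknown contamination class(es): ",
                          paste(bad, collapse = ", "))
    rates[names(contamination_rates)] <- contamination_rates
  }
  cfg <- list(
    n_origin_countries = as.integer(n_origin_countries),
    n_holding_countries = as.integer(n_holding_countries),
    n_records = as.integer(n_records),
    concentration_alpha = concentration_alpha,
    reciprocity_target = reciprocity_target,
    domestic_fraction = domestic_fraction,
    period_weights = period_weights,
    contamination_rates = rates,
    families = families,
    family_weights = family_weights / sum(family_weights),
    holders_in_origin_pool = isTRUE(holders_in_origin_pool),
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_records > 0, cfg$n_origin_countries >= 1,
            cfg$n_holding_countries >= 1, cfg$concentration_alpha > 0)
  if (!is.na(cfg$reciprocity_target) &&
      (cfg$reciprocity_target < 0 || cfg$reciprocity_target > 1))
    stop("reciprocity_target must be in [0, 1] or NA")
  if (cfg$domestic_fraction < 0 || cfg$domestic_fraction > 1)
    stop("domestic_fraction must be in [0, 1]")
  if (length(cfg$period_weights) != 4L || any(cfg$period_weights < 0))
    stop("period_weights must be 4 nonnegative reals")
  if (abs(sum(cfg$period_weights) - 1) > 1e-9)
    stop("period_weights must sum to 1")
  if (any(cfg$contamination_rates < 0) || any(cfg$contamination_rates > 1))
    stop("contamination rates must be in [0, 1]")
  if (sum(cfg$contamination_rates) > 1)
    stop("contamination rates must sum to at most 1")
  if (!length(cfg$families)) stop("at least one family required")
  if (length(cfg$family_weights) != length(cfg$families))
    stop("family_weights must match families")
  total_needed <- if (cfg$holders_in_origin_pool)
    max(cfg$n_origin_countries, cfg$n_holding_countries)
  else cfg$n_origin_countries + cfg$n_holding_countries
  if (total_needed > length(.iso3_all))
    stop("country pools exceed the ISO 3166-1 alpha-3 universe")
  if (cfg$holders_in_origin_pool &&
      cfg$n_origin_countries < cfg$n_holding_countries)
    stop("with holders_in_origin_pool, n_origin_countries must be >= n_holding_countries")
  invisible(cfg)
}

synth_pools <- function(cfg) {
  ord <- iso3_codes()
  holding <- ord[seq_len(cfg$n_holding_countries)]
  origin <- if (cfg$holders_in_origin_pool)
    ord[seq_len(cfg$n_origin_countries)]
  else ord[cfg$n_holding_countries + seq_len(cfg$n_origin_countries)]
  list(holding = holding, origin = origin)
}

#' Generate a synthetic institution registry
#'
#' Emulates a GRSciColl-style registry mapping institution codes to ISO3
#' countries. Every holding country is guaranteed at least one institution;
#' remaining institutions are distributed at random.
#'
#' @param n_institutions Number of institutions (must be >= number of
#'   countries).
#' @param holding_countries Character vector of ISO3 codes.
#' @param seed Integer seed.
#' @return Data frame with columns `institution_code`, `country_iso3`.
#' @export
generate_registry <- function(n_institutions, holding_countries, seed = 1L) {
  if (!length(holding_countries)) stop("holding_countries must be non-empty")
  if (n_institutions < length(holding_countries))
    stop("need at least one institution per holding country")
  if (!all(is_iso3(holding_countries)))
    stop("holding_countries must be valid ISO3 codes")
  set.seed(seed)
  codes <- sprintf("INST%04d", seq_len(n_institutions))
  extra <- n_institutions - length(holding_countries)
  countries <- c(holding_countries,
                 if (extra > 0) sample(holding_countries, extra, replace = TRUE))
  data.frame(institution_code = codes,
             country_iso3 = countries,
             stringsAsFactors = FALSE)
}

iso3_to_name <- function(code) {
  nm <- names(.common_names)[match(code, .common_names)]
  ifelse(is.na(nm), "", nm)
}

#' Generate a synthetic Darwin-Core-style occurrence table
#'
#' Clean rows follow a stated generative model: holding-country shares drawn
#' once from a symmetric Dirichlet, domestic rows with probability
#' `domestic_fraction`, non-domestic origins uniform over the origin pool
#' excluding the holding country, and directed-pair reciprocity adjusted to
#' `reciprocity_target` among pairs whose both countries are holders. Defect
#' rows are injected mutually exclusively per row so downstream filter-log
#' counts are exactly predictable.
#'
#' @param config A [synth_config()].
#' @param registry Optional registry from [generate_registry()]; generated
#'   automatically (3 institutions per holding country) when `NULL`.
#' @param debug If `TRUE`, a `.defect` provenance column is included in the
#'   output table.
#' @return Data frame with Darwin-Core-style columns (`family`,
#'   `basisOfRecord`, `country`, `countryCode`, `institutionCode`,
#'   `ownerInstitutionCode`, `year`, `eventDate`, `individualCount`,
#'   `occurrenceStatus`). Attributes: `defect_counts` (named vector including
#'   `none`), `shares` (the drawn Dirichlet shares), `reciprocity_report`,
#'   `registry`, and `config`.
#' @export
generate_occurrences <- function(config, registry = NULL, debug = FALSE) {
  cfg <- if (inherits(config, "synth_config")) config else
    do.call(synth_config, config)
  validate_synth_config(cfg)
  pools <- synth_pools(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_records

  if (is.null(registry)) {
    registry <- generate_registry(3L * cfg$n_holding_countries,
                                  pools$holding, seed = cfg$seed + 1L)
    set.seed(cfg$seed)  # registry generation must not perturb the main stream
  }
  if (!all(pools$holding %in% registry$country_iso3))
    stop("registry does not cover every holding country")

  # one Dirichlet draw of holding shares for the whole table
  shares <- stats::rgamma(cfg$n_holding_countries, shape = cfg$concentration_alpha)
  shares <- shares / sum(shares)
  names(shares) <- pools$holding

  holding_i <- sample(pools$holding, n, replace = TRUE, prob = shares)
  domestic_i <- stats::runif(n) < cfg$domestic_fraction
  origin_i <- holding_i
  nd <- which(!domestic_i)
  if (length(nd)) {
    n_origin <- length(pools$origin)
    pos <- match(holding_i[nd], pools$origin)      # NA if holder not in pool
    in_pool <- !is.na(pos)
    draw <- integer(length(nd))
    draw[in_pool] <- sample.int(n_origin - 1L, sum(in_pool), replace = TRUE)
    draw[in_pool] <- draw[in_pool] + (draw[in_pool] >= pos[in_pool])
    if (any(!in_pool))
      draw[!in_pool] <- sample.int(n_origin, sum(!in_pool), replace = TRUE)
    origin_i[nd] <- pools$origin[draw]
  }

  # defect labels first: reciprocity is adjusted on clean rows only, so the
  # measured (post-filter) network sees exactly the intended pair structure
  rates <- cfg$contamination_rates
  defect_i <- sample(c(.defect_names, "none"), n, replace = TRUE,
                     prob = c(rates, 1 - sum(rates)))

  recip_report <- list(n_reciprocable_pairs = 0L, n_nonreciprocable_pairs = 0L,
                       collisions_resolved = 0L, one_way_enforced = 0L,
                       mutual_singletons_stolen = 0L, mutual_unsatisfied = 0L)
  if (!is.na(cfg$reciprocity_target)) {
    adj <- adjust_reciprocity(origin_i, holding_i,
                              eligible = !domestic_i & defect_i == "none" &
                                origin_i %in% pools$holding,
                              target = cfg$reciprocity_target)
    origin_i <- adj$origin
    holding_i <- adj$holding
    recip_report <- adj$report
    # non-reciprocable pairs: realised clean international pairs whose origin
    # cannot hold (absent from the holder pool / registry)
    cl <- !domestic_i & defect_i == "none" & !(origin_i %in% pools$holding)
    recip_report$n_nonreciprocable_pairs <-
      length(unique(paste(origin_i[cl], holding_i[cl])))
  }

  # institutions: sample within each record's holding country
  inst_by_country <- split(registry$institution_code, registry$country_iso3)
  institution_i <- character(n)
  for (ctry in sort(unique(holding_i))) {
    rows <- which(holding_i == ctry)
    insts <- inst_by_country[[ctry]]
    institution_i[rows] <- if (length(insts) == 1L) insts else
      sample(insts, length(rows), replace = TRUE)
  }
  owner_i <- character(n)
  has_owner <- stats::runif(n) < 0.05
  owner_i[has_owner] <- institution_i[has_owner]

  periods <- default_periods()
  p_idx <- sample.int(4L, n, replace = TRUE, prob = cfg$period_weights)
  year_i <- periods$start_year[p_idx] +
    floor(stats::runif(n) * (periods$end_year[p_idx] - periods$start_year[p_idx] + 1L))

  family_i <- if (length(cfg$families) == 1L) rep(cfg$families, n) else
    sample(cfg$families, n, replace = TRUE, prob = cfg$family_weights)

  count_i <- rep(1L, n)
  multi <- stats::runif(n) < 0.10
  count_i[multi] <- 1L + sample.int(4L, sum(multi), replace = TRUE)
  count_chr <- as.character(count_i)
  count_chr[stats::runif(n) < 0.05] <- ""   # missing count => treated as 1

  year_chr <- as.character(year_i)
  event_chr <- rep("", n)
  has_ed <- stats::runif(n) < 0.4
  event_chr[has_ed] <- sprintf("%04d-%02d-%02d", year_i[has_ed],
                               sample.int(12L, sum(has_ed), replace = TRUE),
                               sample.int(28L, sum(has_ed), replace = TRUE))

  basis_i <- rep("PreservedSpecimen", n)
  status_i <- rep("present", n)
  country_code_chr <- origin_i
  country_chr <- iso3_to_name(origin_i)

  # defect injection (mutually exclusive per row)
  d <- defect_i == "missing_year"
  year_chr[d] <- ""; event_chr[d] <- ""
  d <- defect_i == "pre_1900_year"
  if (any(d)) {
    yy <- 1800L + sample.int(100L, sum(d), replace = TRUE) - 1L
    year_chr[d] <- as.character(yy); event_chr[d] <- ""
  }
  d <- defect_i == "invalid_country_code"
  if (any(d)) {
    country_code_chr[d] <- sample(c("XX?", "ZZZ99", "Congo?"), sum(d), TRUE)
    country_chr[d] <- "Atlantis"
  }
  d <- defect_i == "missing_origin"
  country_code_chr[d] <- ""; country_chr[d] <- ""
  d <- defect_i == "missing_institution"
  institution_i[d] <- ""; owner_i[d] <- ""
  d <- defect_i == "zero_count"
  count_chr[d] <- "0"
  d <- defect_i == "non_specimen_basis"
  if (any(d))
    basis_i[d] <- sample(c("HumanObservation", "FossilSpecimen",
                           "LivingSpecimen"), sum(d), TRUE)
  d <- defect_i == "absent_status"
  status_i[d] <- "absent"

  tbl <- data.frame(
    family = family_i,
    basisOfRecord = basis_i,
    country = country_chr,
    countryCode = country_code_chr,
    institutionCode = institution_i,
    ownerInstitutionCode = owner_i,
    year = year_chr,
    eventDate = event_chr,
    individualCount = count_chr,
    occurrenceStatus = status_i,
    stringsAsFactors = FALSE
  )
  if (debug) tbl$.defect <- defect_i

  counts <- table(factor(defect_i, levels = c(.defect_names, "none")))
  attr(tbl, "defect_counts") <- stats::setNames(as.integer(counts), names(counts))
  attr(tbl, "shares") <- shares
  attr(tbl, "reciprocity_report") <- recip_report
  attr(tbl, "registry") <- registry
  attr(tbl, "config") <- cfg
  tbl
}

# Rewrites directions of eligible international rows so that, per unordered
# country pair, both directions exist with probability `target` and exactly
# one direction otherwise. Singleton mutual pairs (one row, nothing to flip)
# are satisfied by re-routing a surplus row from the richest mutual pair.
adjust_reciprocity <- function(origin, holding, eligible, target) {
  report <- list(n_reciprocable_pairs = 0L, n_nonreciprocable_pairs = 0L,
                 collisions_resolved = 0L, one_way_enforced = 0L,
                 mutual_singletons_stolen = 0L, mutual_unsatisfied = 0L)
  idx <- which(eligible)
  if (!length(idx))
    return(list(origin = origin, holding = holding, report = report))
  o <- origin[idx]; h <- holding[idx]
  a <- pmin(o, h); b <- pmax(o, h)
  key <- paste(a, b, sep = "|")
  by_pair <- split(seq_along(idx), key)
  report$n_reciprocable_pairs <- length(by_pair)
  mutual <- stats::runif(length(by_pair)) < target
  names(mutual) <- names(by_pair)

  singletons <- character(0)   # keys of mutual pairs with a single row
  donors <- integer(0)         # local indices of surplus rows in mutual pairs
  for (k in names(by_pair)) {
    rows <- by_pair[[k]]
    ab <- strsplit(k, "|", fixed = TRUE)[[1]]
    fwd <- rows[o[rows] == ab[1]]   # direction a -> b
    bwd <- rows[o[rows] == ab[2]]
    if (mutual[[k]]) {
      if (length(rows) == 1L) {
        singletons <- c(singletons, k)
        next
      }
      if (length(fwd) == 0L) {
        flip <- bwd[1]
        o[flip] <- ab[1]; h[flip] <- ab[2]
        fwd <- flip; bwd <- bwd[-1]
      } else if (length(bwd) == 0L) {
        flip <- fwd[1]
        o[flip] <- ab[2]; h[flip] <- ab[1]
        bwd <- flip; fwd <- fwd[-1]
      }
      if (length(fwd) > 1L) donors <- c(donors, fwd[-1])
      if (length(bwd) > 1L) donors <- c(donors, bwd[-1])
    } else {
      if (length(fwd) && length(bwd)) {
        # collision: enforce one-way towards the majority direction
        if (length(fwd) >= length(bwd)) {
          o[bwd] <- ab[1]; h[bwd] <- ab[2]
          report$collisions_resolved <- report$collisions_resolved + length(bwd)
        } else {
          o[fwd] <- ab[2]; h[fwd] <- ab[1]
          report$collisions_resolved <- report$collisions_resolved + length(fwd)
        }
        report$one_way_enforced <- report$one_way_enforced + 1L
      }
    }
  }
  for (k in singletons) {
    rows <- by_pair[[k]]
    ab <- strsplit(k, "|", fixed = TRUE)[[1]]
    missing_dir <- if (o[rows[1]] == ab[1]) c(ab[2], ab[1]) else c(ab[1], ab[2])
    if (length(donors)) {
      don <- donors[1]; donors <- donors[-1]
      o[don] <- missing_dir[1]; h[don] <- missing_dir[2]
      report$mutual_singletons_stolen <- report$mutual_singletons_stolen + 1L
    } else {
      report$mutual_unsatisfied <- report$mutual_unsatisfied + 1L
    }
  }
  origin[idx] <- o
  holding[idx] <- h
  list(origin = origin, holding = holding, report = report)
}

#' Monte-Carlo reference Gini for Dirichlet share vectors
#'
#' Estimates the expected Gini coefficient of a symmetric
#' Dirichlet(`concentration_alpha`) share vector of length `n_holding`, the
#' quantity the synthetic generator's holdings Gini should recover. `sd` is
#' the Monte-Carlo spread of a single realisation (the relevant scale when
#' comparing one measured slice against the reference); `se` is the standard
#' error of the reported mean.
#'
#' @param concentration_alpha Positive Dirichlet parameter.
#' @param n_holding Number of holding countries.
#' @param n_reps Number of Monte-Carlo replicates (>= 1).
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, `se`, `n_reps`.
#' @export
reference_gini <- function(concentration_alpha, n_holding, n_reps = 400L,
                           seed = 1L) {
  stopifnot(concentration_alpha > 0, n_holding >= 1, n_reps >= 1)
  set.seed(seed)
  g <- vapply(seq_len(n_reps), function(i) {
    x <- stats::rgamma(n_holding, shape = concentration_alpha)
    gini(x / sum(x), variant = "include_zeros")
  }, numeric(1))
  list(mean = mean(g), sd = stats::sd(g),
       se = stats::sd(g) / sqrt(n_reps), n_reps = as.integer(n_reps))
}

#' Write synthetic tables to CSV
#'
#' @param table A table from [generate_occurrences()] (or any data frame).
#' @param path Output CSV path.
#' @param debug Keep the hidden `.defect` provenance column if present.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(table, path, debug = FALSE) {
  if (!debug) table$.defect <- NULL
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
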