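#' Published study inputs and worked-example arithmetic
#'
#' Small printed tables from the source study (per-species sighting and
#' incident totals, the 2017-2021 AIS vessel-hours total) shipped as CSV
#' under `extdata`, plus the arithmetic reproduced from them: per-species
#' shares of the sightings database and the annual mean of the vessel-hours
#' total.
#'
#' @name published
NULL

#' Per-species sighting totals from the study database
#'
#' @return data.frame: species, count (1985-2023 opportunistic sightings).
#' @export
published_sightings <- function() {
  utils::read.csv(system.file("extdata", "published_sightings.csv",
                              package = "whalerisk"),
                  stringsAsFactors = FALSE)
}

#' Per-species incident-report totals
#'
#' @return data.frame: species, count (2004-2019 incident reports; the
#'   remainder up to the 1,110 total is unidentified).
#' @export
published_incidents <- function() {
  utils::read.csv(system.file("extdata", "published_incidents.csv",
                              package = "whalerisk"),
                  stringsAsFactors = FALSE)
}

#' AIS vessel-activity totals
#'
#' @return list: `total_hours` (2017-2021), `n_years`.
#' @export
published_vessel_activity <- function() {
  df <- utils::read.csv(system.file("extdata", "published_vessel_hours.csv",
                                    package = "whalerisk"),
                        stringsAsFactors = FALSE)
  list(total_hours = df$total_hours[1], n_years = df$n_years[1])
}

#' Percentage shares of a count table
#'
#' @param counts named numeric vector or data.frame with `species`/`count`.
#' @return data.frame: species, count, share_pct (counts / total x 100).
#' @export
species_share <- function(counts) {
  if (is.data.frame(counts)) {
    df <- data.frame(species = counts$species, count = counts$count)
  } else {
    df <- data.frame(species = names(counts), count = as.numeric(counts))
  }
  if (any(df$count < 0)) stop("counts must be non-negative")
  df$share_pct <- 100 * df$count / sum(df$count)
  df
}

#' Annual mean from a multi-year total
#'
#' @param total total over the period.
#' @param n_years number of years.
#' @return total / n_years.
#' @export
annual_mean <- function(total, n_years) {
  if (n_years <= 0) stop("n_years must be positive")
  total / n_years
}
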