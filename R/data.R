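# fixture registry: expected count and value checksum (sum of values),
# validated on every load
fixture_catalog_ <- list(
  aircon_boeing720 = list(
    n = 213L, total = 19839,
    label = "Successive air-conditioning failure times, Boeing 720 fleet (hours)"),
  nyc_ozone_1973 = list(
    n = 116L, total = 4887,
    label = "Daily ozone levels, New York, May-September 1973 (ppb)"),
  wheaton_flood = list(
    n = 72L, total = 878.7,
    label = "Wheaton River flood-peak exceedances (m^3/s)"),
  covid_recovery_m60 = list(
    n = 50L, total = 919,
    label = "COVID-19 recovery times, males over 60 (days)")
)

#' Packaged lifetime datasets
#'
#' Loads one of the four positive-valued datasets shipped with the package
#' as one-value-per-line text under `inst/extdata`:
#' \describe{
#'   \item{`aircon_boeing720`}{213 successive failure times (hours) of the
#'     air-conditioning systems of a fleet of 13 Boeing 720 jet airplanes;}
#'   \item{`nyc_ozone_1973`}{116 daily ozone level measurements in New York,
#'     May-September 1973;}
#'   \item{`wheaton_flood`}{72 exceedances of flood peaks (m^3/s) of the
#'     Wheaton River near Carcross, Yukon Territory, Canada;}
#'   \item{`covid_recovery_m60`}{recovery times (days between first positive
#'     and first negative PCR test) of 50 male COVID-19 survivors over 60
#'     years old (anonymized Israeli Ministry of Health data).}
#' }
#' The loader validates the value count and a checksum on every call and
#' reads the file through the same plain-text reader as [read_sample()].
#'
#' @param name Dataset name (see above).
#' @return A tibble with a single numeric column `value` and attribute
#'   `label` carrying the provenance string.
#' @examples
#' nrow(gmoee_data("covid_recovery_m60"))
#' @export
gmoee_data <- function(name = c("aircon_boeing720", "nyc_ozone_1973",
                                "wheaton_flood", "covid_recovery_m60")) {
  name <- match.arg(name)
  meta <- fixture_catalog_[[name]]
  path <- system.file("extdata", paste0(name, ".txt"), package = "gmoee",
                      mustWork = TRUE)
  out <- read_sample(path)
  if (nrow(out) != meta$n) {
    abort(sprintf("fixture '%s': expected %d values, found %d.",
                  name, meta$n, nrow(out)))
  }
  if (abs(sum(out$value) - meta$total) > 1e-8) {
    abort(sprintf("fixture '%s': checksum mismatch.", name))
  }
  attr(out, "label") <- meta$label
  out
}

#' Read a univariate positive sample from disk
#'
#' Accepts one numeric value per line (plain text, `#` comments allowed) or a
#' single-column CSV with an optional header. Values are validated to be
#' strictly positive.
#'
#' @param path File path.
#' @return A tibble with one numeric column `value`.
#' @export
read_sample <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  # strip a single non-numeric header line (CSV-style)
  vals <- suppressWarnings(as.numeric(sub(",$", "", lines)))
  if (length(vals) && is.na(vals[1]) && !anyNA(vals[-1])) {
    vals <- vals[-1]
  }
  if (anyNA(vals)) abort(sprintf("non-numeric values in %s", path))
  tibble(value = sample_values(vals))
}

#' Generate a labeled synthetic GMO-EE sample
#'
#' Inverse-transform draws from the GMO-EE distribution (see [rgmoee()]),
#' reproducible for a fixed seed, returned in the same tabular shape as
#' [gmoee_data()] so synthetic and packaged samples are interchangeable in
#' the fitting pipeline.
#'
#' @param n Number of draws.
#' @param alpha,lambda,theta,beta GMO-EE parameters.
#' @param seed Optional integer seed (caller's RNG state is restored).
#' @return A tibble with column `value`, attribute `label = "synthetic"`.
#' @examples
#' gmoee_sample(5, 0.4, 0.8, 1, 0.5, seed = 1)
#' @export
gmoee_sample <- function(n, alpha, lambda, theta, beta, seed = NULL) {
  stopifnot(n >= 1)
  vals <- with_seed(seed, rgmoee(n, alpha, lambda, theta, beta))
  out <- tibble(value = vals)
  attr(out, "label") <- "synthetic"
  out
}
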