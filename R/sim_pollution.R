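#' Reference site means of ambient pollutants (ug m^-3)
#'
#' Two-year mean ambient concentrations of black carbon, PM2.5, PM10, NO2 and
#' O3 at the six monitored sites, as published for the field campaign. Used
#' as default parameters of [simulate_pollution_series()].
#'
#' @return Tibble with columns `site`, `bc`, `pm2.5`, `pm10`, `no2`, `o3`.
#' @export
reference_pollution_means <- function() {
  tibble(
    site = c("HGa", "HGb", "HKa", "HKb", "DM", "DW"),
    bc = c(1.9, 1.5, 1.3, 1.1, 0.9, 0.9),
    pm2.5 = c(14.1, 13.7, 13.0, 12.9, 12.1, 12.2),
    pm10 = c(22.7, 22.2, 21.3, 21.1, 19.8, 20.1),
    no2 = c(34.2, 28.9, 22.4, 20.7, 18.5, 16.8),
    o3 = c(42.9, 46.9, 49.9, 51.0, 52.1, 53.6)
  )
}

#' Reference per-site phylloplane BC load means and SDs (x1e8 particles/g)
#'
#' Published per-site mean +/- SD of the phylloplane BC load, in units of
#' 1e8 particles per gram of leaf. Used to parameterise simulations of site
#' comparisons and category fold changes.
#'
#' @return Tibble with `site`, `bc_category`, `mean_load`, `sd_load`.
#' @export
reference_bc_loads <- function() {
  tibble(
    site = c("HGa", "HGb", "HKa", "HKb", "DM", "DW"),
    bc_category = c("bcM", "bcM", "bcH", "bcH", "bcL", "bcL"),
    mean_load = c(1.9, 1.7, 4.1, 4.4, 0.6, 0.7),
    sd_load = c(2.4, 2.3, 3.8, 3.4, 0.7, 0.9)
  )
}

# peak day-of-year per pollutant: BC and NO2 peak in winter (mid January),
# particulates late winter/early spring, O3 in summer (anti-phased with NO2)
pollutant_phase_days <- c(bc = 15, `pm2.5` = 60, pm10 = 60, no2 = 15,
                          o3 = 15 + 182.625)

#' Simulate daily pollution time series with a seasonal cycle
#'
#' Per site and pollutant, generates `mean + amplitude * cos(2*pi*(day -
#' peak_day)/365.25) + noise`, truncated at zero. NO2 and O3 use anti-phased
#' seasonal components (winter vs summer peaks); BC peaks in winter and the
#' particulate fractions in late winter/early spring.
#'
#' @param site_means Tibble like [reference_pollution_means()] (`site` column
#'   plus one column per pollutant).
#' @param seasonal_amplitudes Named numeric amplitudes per pollutant
#'   (ug m^-3); defaults to 30% of the across-site mean level.
#' @param n_days Number of daily observations per site.
#' @param noise_sd Named (or scalar) Gaussian noise SD per pollutant;
#'   defaults to 20% of the across-site mean level.
#' @param seed Integer seed.
#' @return Long tibble: `site`, `day`, `pollutant`, `value`.
#' @examples
#' ps <- simulate_pollution_series(n_days = 30, seed = 1)
#' dplyr::count(ps, pollutant)
#' @export
simulate_pollution_series <- function(site_means = reference_pollution_means(),
                                      seasonal_amplitudes = NULL,
                                      n_days = 761L,
                                      noise_sd = NULL,
                                      seed = NULL) {
  site_means <- as_tibble(site_means)
  if (!"site" %in% names(site_means))
    abort("`site_means` needs a `site` column.")
  pollutants <- setdiff(names(site_means), "site")
  if (!length(pollutants)) abort("no pollutant columns in `site_means`.")
  if (any(as.matrix(site_means[pollutants]) < 0))
    abort("site means must be non-negative.")
  lvl <- vapply(site_means[pollutants], mean, numeric(1))
  if (is.null(seasonal_amplitudes)) seasonal_amplitudes <- 0.3 * lvl
  if (is.null(noise_sd)) noise_sd <- 0.2 * lvl
  if (length(noise_sd) == 1L && is.null(names(noise_sd)))
    noise_sd <- setNames(rep(noise_sd, length(pollutants)), pollutants)
  if (any(seasonal_amplitudes < 0) || any(noise_sd < 0))
    abort("amplitudes and noise SDs must be non-negative.")
  if (n_days < 1) abort("`n_days` must be >= 1.")

  phases <- pollutant_phase_days[pollutants]
  phases[is.na(phases)] <- 15 # unknown pollutants default to a winter peak
  days <- seq_len(n_days)
  with_seed(seed, {
    out <- purrr::map_dfr(seq_len(nrow(site_means)), function(i) {
      purrr::map_dfr(pollutants, function(p) {
        seasonal <- seasonal_amplitudes[[p]] *
          cos(2 * pi * (days - phases[[p]]) / 365.25)
        tibble(site = site_means$site[i], day = days, pollutant = p,
               value = pmax(0, site_means[[p]][i] + seasonal +
                              rnorm(n_days, 0, noise_sd[[p]])))
      })
    })
    out
  })
}
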