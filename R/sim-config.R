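#' Configuration for the synthetic herd simulator
#'
#' Defaults describe a multi-farm UK-like dairy system: founder cows born
#' 2006-2007, retained heifers through 2015 (three generations of pedigree),
#' a roughly 400-d calving interval, age at first calving near 25 months,
#' MilkBot-shaped lactation curves with farm- and cow-level parameter
#' variation, monthly milk recording, sparse farm-heterogeneous event
#' recording, seasonal weather, and an in-utero effect of -5 LRS points per
#' THI_max unit of mean trimester-3 exposure acting on a latent resilience
#' scale. The latent scale carries farm (SD 142), dam (SD 81) and residual
#' (SD 477) components, matching the magnitude of the random-effect structure
#' the scoring model is meant to recover, and is translated into survival
#' (lactations completed), yield deviation and calving-interval deviation so
#' the computed score - not a shortcut variable - carries the signal.
#'
#' @param n_farms Number of farms (each with its own weather station).
#' @param cows_per_farm Founder cows per farm.
#' @param founder_birth_years Calendar years founders are born in.
#' @param birth_window Inclusive birth-date window for retained heifers.
#' @param sim_end Last simulated date.
#' @param afc_mean,afc_sd Age at first calving, days.
#' @param ci_mean,ci_sd Calving interval, days.
#' @param lactation_params Distribution of the 4 curve parameters.
#' @param event_rates Daily hazards of true stressor events per category.
#' @param recording_completeness Probability a true event is recorded,
#'   per farm-year (farm-year thinning).
#' @param weather Seasonal sinusoid settings for temperature and dewpoint,
#'   plus optional injected missingness for one station-year.
#' @param injected_effects Named additive shifts on the latent daughter
#'   outcome, in score points per unit of the named window exposure
#'   (currently `mean_thi_t1`..`mean_thi_t3` supported).
#' @param injected_center Exposure values at which the injected effect is
#'   zero (centering, keeps the latent scale interpretable).
#' @param noise_sd Residual latent-outcome noise, points.
#' @param variance_components Farm- and dam-level latent SDs, points.
#' @param heifer_prob Probability a calving produces a retained heifer.
#' @param base_lactations Mean completed lactations for an average cow.
#' @param recording_interval Days between milk recordings.
#' @param milk_noise_sd Recording noise on daily yield, kg.
#' @param max_generation Pedigree depth (3 gives granddaughter pairs).
#' @param seed Integer random seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_farms = 8,
                       cows_per_farm = 40,
                       founder_birth_years = c(2006, 2007),
                       birth_window = as.Date(c("2006-01-01", "2015-12-31")),
                       sim_end = as.Date("2021-12-31"),
                       afc_mean = 760, afc_sd = 60,
                       ci_mean = 400, ci_sd = 45,
                       lactation_params = list(
                         scale_mean = 32, scale_sd_farm = 2.5,
                         scale_sd_cow = 3.5, ramp = 25, ramp_sd = 4,
                         offset = -5, offset_sd = 2,
                         decay = 0.0025, decay_sd = 5e-4),
                       event_rates = c(mastitis = 4e-4, lameness = 3e-4,
                                       antimicrobial = 5e-4,
                                       anti_inflammatory = 2e-4),
                       recording_completeness = 0.85,
                       weather = list(t_base = 13, t_amp = 8, t_phase = 200,
                                      t_sd = 3, dp_offset = 4, dp_sd = 1.5,
                                      missing_station = NULL,
                                      missing_year = NULL,
                                      missing_frac = 0),
                       injected_effects = c(mean_thi_t3 = -5),
                       injected_center = c(mean_thi_t3 = 55),
                       noise_sd = 477,
                       variance_components = c(farm = 142, dam = 81),
                       heifer_prob = 0.5,
                       base_lactations = 3,
                       recording_interval = 30,
                       milk_noise_sd = 1.5,
                       max_generation = 3,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_farms >= 1, cows_per_farm >= 1,
    all(event_rates >= 0 & event_rates <= 1),
    recording_completeness >= 0 && recording_completeness <= 1,
    heifer_prob >= 0 && heifer_prob <= 1,
    noise_sd >= 0, all(variance_components >= 0),
    afc_sd >= 0, ci_sd >= 0,
    birth_window[1] <= birth_window[2],
    all(names(injected_effects) %in% names(injected_center) |
          length(injected_effects) == 0))
  structure(cfg, class = "sim_config")
}
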