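#' Run the full analysis pipeline on a simulated herd
#'
#' simulate -> clean -> fit lactations -> THI exposure -> score -> features
#' -> model, in one call. Each stage is the package function a user would
#' call on real herd exports; the simulator only supplies the inputs. With
#' `out_dir` set, every intermediate table is written as CSV, so two runs
#' with the same configuration can be compared file by file.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory for CSV outputs.
#' @param mode `"daughter"` or `"granddaughter"` pairing.
#' @param candidates Candidate fixed effects for forward selection; the
#'   default tests the three trimester THI exposures, pregnancy number,
#'   centered mother LRS and season of birth.
#' @param run_model Set `FALSE` to stop after feature assembly.
#' @return List with all intermediate artifacts (`sim`, `cows`, `milk`,
#'   `fits`, `weather`, `farm_stations`, `lrs`, `pairs`, `features`,
#'   `selection`, `r2`, `cleaning_reports`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         mode = "daughter",
                         candidates = c("mean_thi_t1", "mean_thi_t2",
                                        "mean_thi_t3", "pregnancy",
                                        "mother_lrs_centered",
                                        "season_of_birth"),
                         run_model = TRUE) {
  sim <- simulate_herds(config)

  cc <- clean_cows(sim$cows, sim$calvings, config$birth_window)
  cm <- clean_milk(sim$milk, cc$cows, sim$calvings)
  cows <- cm$cows
  calvings <- sim$calvings[sim$calvings$cow_id %in% cows$cow_id, ,
                           drop = FALSE]

  fits <- fit_lactations(cm$milk)

  events <- match_treatments(sim$events, sim$products)
  herd_years <- filter_recording_herd_years(events, cows)

  qc <- qc_stations(sim$weather, "multi")
  ok_stations <- unique(qc$station_id[qc$retained])
  farm_stations <- match_nearest_station(
    sim$farms, sim$stations[sim$stations$station_id %in% ok_stations, ,
                            drop = FALSE])

  lrs <- compute_lrs_all(cows, calvings, fits, cm$milk)

  pairs <- match_pairs(cows, calvings,
                       generation_gap = if (mode == "daughter") 1 else 2)
  pair_year <- as.integer(format(pairs$calving_date, "%Y"))
  pair_farm <- cows$farm_id[match(pairs$offspring_id, cows$cow_id)]
  in_recording <- paste(pair_farm, pair_year) %in%
    paste(herd_years$farm_id, herd_years$year)
  pairs <- pairs[in_recording, , drop = FALSE]

  features <- build_features(pairs, cows, calvings, events, cm$milk,
                             sim$weather, farm_stations, lrs, fits, mode)

  selection <- NULL; r2 <- NULL
  if (run_model && nrow(features) > 20) {
    selection <- forward_select(features, candidates,
                                grouping = c("farm_id", "dam_id"))
    if (selection$fit$converged) r2 <- variance_explained(selection$fit)
  }

  out <- list(sim = sim, cows = cows, milk = cm$milk, fits = fits,
              events = events, herd_years = herd_years, weather = sim$weather,
              farm_stations = farm_stations, lrs = lrs, pairs = pairs,
              features = features, selection = selection, r2 = r2,
              cleaning_reports = list(cows = cc$report, milk = cm$report))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tab <- function(tab, nm)
      utils::write.csv(tab, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    write_tab(out$cows, "cows_clean")
    write_tab(out$fits, "lactations")
    write_tab(out$lrs, "lrs")
    write_tab(out$features, "features")
    write_tab(out$farm_stations, "farm_stations")
    write_tab(out$cleaning_reports$cows, "cleaning_report_cows")
    write_tab(out$cleaning_reports$milk, "cleaning_report_milk")
    if (!is.null(selection)) {
      write_tab(selection$trace, "selection_trace")
      write_tab(selection$fit$coefficients, "coefficients")
    }
  }
  out
}
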