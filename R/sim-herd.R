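#' Simulate daily weather for every station of a synthetic herd system
#'
#' One station per farm, placed across a UK-like latitude/longitude band.
#' Daily maximum temperature follows an annual sinusoid with Gaussian noise;
#' dewpoint sits a strictly positive spread below the maximum temperature, so
#' the physical constraint dewpoint <= t_max holds on every day. Optional
#' missingness can be injected into one station-year to exercise station QC.
#'
#' @param config A [sim_config()].
#' @return List with `stations` (station_id, lat, lon) and `weather`
#'   (station_id, date, t_max, dewpoint).
#' @export
simulate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  w <- config$weather
  start <- as.Date(paste0(min(config$founder_birth_years), "-01-01"))
  if (start > config$sim_end) stop("invalid date range")
  dates <- seq(start, config$sim_end, by = "day")

  stations <- dplyr::tibble(
    station_id = sprintf("ST%02d", seq_len(config$n_farms)),
    lat = seq(50.5, 54.5, length.out = config$n_farms) +
      stats::runif(config$n_farms, -0.1, 0.1),
    lon = seq(-4, -0.5, length.out = config$n_farms) +
      stats::runif(config$n_farms, -0.1, 0.1))

  doy <- as.integer(format(dates, "%j"))
  rows <- lapply(seq_len(config$n_farms), function(i) {
    t_max <- w$t_base + w$t_amp * cos(2 * pi * (doy - w$t_phase) / 365.25) +
      stats::rnorm(length(dates), 0, w$t_sd)
    spread <- pmax(0.2, stats::rnorm(length(dates), w$dp_offset, w$dp_sd))
    dplyr::tibble(station_id = stations$station_id[i], date = dates,
                  t_max = round(t_max, 2),
                  dewpoint = round(t_max - spread, 2))
  })
  weather <- dplyr::bind_rows(rows)

  if (!is.null(w$missing_station) && w$missing_frac > 0) {
    in_sy <- weather$station_id == w$missing_station &
      format(weather$date, "%Y") == as.character(w$missing_year)
    drop <- which(in_sy)
    drop <- sample(drop, ceiling(length(drop) * w$missing_frac))
    weather <- weather[-drop, , drop = FALSE]
  }
  list(stations = stations, weather = weather)
}

#' Reference product list for treatment-record matching
#'
#' A small synthetic product reference emulating a veterinary medicines
#' register: product name plus use category, including dry-cow preparations.
#'
#' @return Tibble `name`, `category`.
#' @export
default_products <- function() {
  dplyr::tibble(
    name = c("Betamox LA", "Synulox RTU", "Pen & Strep", "Tylan 200",
             "Excenel RTU", "Cobactan 2.5%", "Terramycin LA",
             "Metacam 20 mg/ml", "Ketofen 10%", "Finadyne Solution",
             "Rimadyl Cattle", "Cepravin Dry Cow", "Orbenin Dry Cow",
             "Ubro Red Dry Cow", "Bovilis BVD", "Rispoval 4",
             "Leptavoid-H", "Rotavec Corona"),
    category = c(rep("antimicrobial", 7), rep("anti_inflammatory", 4),
                 rep("antimicrobial", 3), rep("vaccine", 4)))
}

typo <- function(s) {
  ops <- sample(c("none", "drop", "swap", "case"), length(s), replace = TRUE,
                prob = c(0.45, 0.2, 0.2, 0.15))
  vapply(seq_along(s), function(i) {
    x <- s[i]
    n <- nchar(x)
    switch(ops[i],
           none = x,
           drop = if (n > 4) {
             k <- sample(n, 1); paste0(substr(x, 1, k - 1), substr(x, k + 1, n))
           } else x,
           swap = if (n > 4) {
             k <- sample(n - 1, 1)
             paste0(substr(x, 1, k - 1), substr(x, k + 1, k + 1),
                    substr(x, k, k), substr(x, k + 2, n))
           } else x,
           case = toupper(x))
  }, character(1))
}

#' Simulate a multi-farm herd with known ground truth
#'
#' Generates pedigree (founders, daughters, granddaughters), calving
#' histories, MilkBot-shaped milk recordings, stressor events with farm-year
#' recording thinning, free-text treatment records drawn from the product
#' list (with typos, to exercise fuzzy matching), seasonal weather, and a
#' latent resilience outcome per retained heifer: farm effect + dam effect +
#' injected in-utero effects (centered window exposures times the configured
#' points-per-unit) + residual noise. The latent value is translated into the
#' heifer's completed-lactation count, yield-scale deviation and
#' calving-interval deviation, so the lifetime resilience score computed
#' downstream carries the injected signal.
#'
#' @param config A [sim_config()].
#' @return List of class `herd_sim`: tables `cows`, `calvings`, `milk`,
#'   `events`, `weather`, `stations`, `farms`, `products`, and `truth`
#'   (per-cow latent outcome, exposures, pedigree, plus the injected effect
#'   sizes and variance components used).
#' @export
simulate_herds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  wx <- simulate_weather(config)
  set.seed(config$seed)
  lp <- config$lactation_params
  products <- default_products()

  farms <- dplyr::tibble(
    farm_id = sprintf("F%02d", seq_len(config$n_farms)),
    lat = wx$stations$lat + stats::runif(config$n_farms, -0.05, 0.05),
    lon = wx$stations$lon + stats::runif(config$n_farms, -0.05, 0.05),
    station_id = wx$stations$station_id,
    scale_mean = stats::rnorm(config$n_farms, lp$scale_mean, lp$scale_sd_farm),
    farm_eff = stats::rnorm(config$n_farms, 0,
                            config$variance_components["farm"]))

  weather <- add_thi(wx$weather)
  wx_by_station <- split(weather, weather$station_id)

  thi_window <- function(farm_i, birth_date, window) {
    conc <- birth_date - 283
    win <- trimester_dates(conc)
    k <- match(window, win$window)
    mean_thi(wx_by_station[[farms$station_id[farm_i]]],
             win$start[k], win$end[k])
  }

  cow_rows <- list(); truth_rows <- list()
  next_id <- 1L

  make_cow <- function(farm_i, birth_date, dam_id, dam_eff, generation,
                       latent) {
    id <- sprintf("C%05d", next_id)
    next_id <<- next_id + 1L
    afc <- round(min(1300, max(500,
                               stats::rnorm(1, config$afc_mean,
                                            config$afc_sd))))
    n_lact <- max(1, min(8, round(config$base_lactations + latent / 900 +
                                    stats::rnorm(1, 0, 0.7))))
    ci_dev <- -latent * 0.03
    intervals <- round(pmax(320, stats::rnorm(n_lact - 1, config$ci_mean,
                                              config$ci_sd) + ci_dev))
    calvings <- birth_date + cumsum(c(afc, intervals))
    calvings <- calvings[calvings <= config$sim_end - 120]
    if (length(calvings) == 0) calvings <- birth_date + afc
    n_lact <- length(calvings)
    dim_last <- round(max(20, stats::rnorm(1, 330, 80)))
    exit_date <- min(calvings[n_lact] + dim_last, config$sim_end)
    dim_last <- as.numeric(exit_date - calvings[n_lact])
    scale <- max(10, farms$scale_mean[farm_i] * (1 + 3e-4 * latent) +
                   stats::rnorm(1, 0, lp$scale_sd_cow))
    list(cow_id = id, farm_i = farm_i, birth_date = birth_date,
         dam_id = dam_id, exit_date = exit_date, calvings = calvings,
         dim_last = dim_last, generation = generation, latent = latent,
         params = c(scale = scale,
                    ramp = max(5, stats::rnorm(1, lp$ramp, lp$ramp_sd)),
                    offset = stats::rnorm(1, lp$offset, lp$offset_sd),
                    decay = max(5e-4, stats::rnorm(1, lp$decay,
                                                   lp$decay_sd))),
         own_eff = dam_eff)
  }

  # founders
  founder_dates <- as.Date(paste0(
    sample(config$founder_birth_years,
           config$n_farms * config$cows_per_farm, replace = TRUE),
    sprintf("-%02d-%02d",
            sample(12, config$n_farms * config$cows_per_farm, TRUE),
            sample(28, config$n_farms * config$cows_per_farm, TRUE))))
  cows <- list()
  for (f in seq_len(config$n_farms)) {
    for (c in seq_len(config$cows_per_farm)) {
      i <- (f - 1) * config$cows_per_farm + c
      own_eff <- stats::rnorm(1, 0, config$variance_components["dam"])
      latent <- farms$farm_eff[f] + own_eff +
        stats::rnorm(1, 0, config$noise_sd)
      cows[[length(cows) + 1]] <-
        make_cow(f, founder_dates[i], NA_character_, own_eff, 1L, latent)
    }
  }

  # descendants: each calving after the first may produce a retained heifer
  calving_flags <- list()
  gen <- 1L
  frontier <- cows
  while (gen < config$max_generation) {
    offspring <- list()
    for (cw in frontier) {
      keep <- stats::runif(length(cw$calvings)) < config$heifer_prob &
        cw$calvings >= config$birth_window[1] &
        cw$calvings <= config$birth_window[2]
      calving_flags[[length(calving_flags) + 1]] <-
        dplyr::tibble(cow_id = cw$cow_id, calving_date = cw$calvings,
                      heifer_retained = keep)
      for (j in which(keep)) {
        bd <- cw$calvings[j]
        inj <- 0
        expo <- c(mean_thi_t1 = NA_real_, mean_thi_t2 = NA_real_,
                  mean_thi_t3 = NA_real_)
        for (wname in c("mean_thi_t1", "mean_thi_t2", "mean_thi_t3")) {
          wlab <- toupper(sub("mean_thi_", "", wname))
          expo[wname] <- thi_window(cw$farm_i, bd, wlab)
        }
        for (e in names(config$injected_effects)) {
          if (!is.na(expo[e]))
            inj <- inj + config$injected_effects[[e]] *
              (expo[e] - config$injected_center[[e]])
        }
        own_eff <- stats::rnorm(1, 0, config$variance_components["dam"])
        latent <- farms$farm_eff[cw$farm_i] + cw$own_eff + inj +
          stats::rnorm(1, 0, config$noise_sd)
        nc <- make_cow(cw$farm_i, bd, cw$cow_id, own_eff, gen + 1L, latent)
        nc$exposures <- expo
        nc$injected <- unname(inj)
        offspring[[length(offspring) + 1]] <- nc
      }
    }
    cows <- c(cows, offspring)
    frontier <- offspring
    gen <- gen + 1L
  }
  for (cw in frontier) {
    calving_flags[[length(calving_flags) + 1]] <-
      dplyr::tibble(cow_id = cw$cow_id, calving_date = cw$calvings,
                    heifer_retained = FALSE)
  }

  cow_tab <- dplyr::bind_rows(lapply(cows, function(cw) dplyr::tibble(
    cow_id = cw$cow_id, farm_id = farms$farm_id[cw$farm_i],
    birth_date = cw$birth_date, dam_id = cw$dam_id,
    entry_date = cw$birth_date, exit_date = cw$exit_date)))
  calving_tab <- dplyr::bind_rows(lapply(cows, function(cw) dplyr::tibble(
    cow_id = cw$cow_id, calving_date = cw$calvings,
    parity = seq_along(cw$calvings))))
  flags_tab <- dplyr::bind_rows(calving_flags)
  calving_tab <- dplyr::left_join(calving_tab, flags_tab,
                                  by = c("cow_id", "calving_date"))
  calving_tab$heifer_retained[is.na(calving_tab$heifer_retained)] <- FALSE

  # milk recordings on the farm's recording grid
  milk_rows <- lapply(cows, function(cw) {
    grid_off <- (cw$farm_i * 7) %% config$recording_interval
    out <- list()
    for (j in seq_along(cw$calvings)) {
      start <- cw$calvings[j]
      end <- if (j < length(cw$calvings)) cw$calvings[j + 1] - 1 else
        cw$exit_date
      first_rec <- start + ((grid_off - as.numeric(start)) %%
                              config$recording_interval) + 5
      dates <- seq(first_rec, end, by = config$recording_interval)
      dates <- dates[dates >= start & dates <= end]
      if (length(dates) == 0) next
      dim <- as.numeric(dates - start)
      y <- milkbot_curve(dim, cw$params["scale"], cw$params["ramp"],
                         cw$params["offset"], cw$params["decay"]) +
        stats::rnorm(length(dim), 0, config$milk_noise_sd)
      out[[j]] <- dplyr::tibble(
        cow_id = cw$cow_id, date = dates,
        yield = round(pmax(0.5, y), 1),
        fat_pct = round(stats::rnorm(length(dim), 4.1, 0.5), 2),
        protein_pct = round(stats::rnorm(length(dim), 3.4, 0.25), 2),
        lactose_pct = round(stats::rnorm(length(dim), 4.5, 0.15), 2),
        scc = round(stats::rlnorm(length(dim), log(80), 0.9)))
    }
    dplyr::bind_rows(out)
  })
  milk_tab <- dplyr::bind_rows(milk_rows)

  # true stressor events, thinned by farm-year recording completeness
  ev_rows <- lapply(cows, function(cw) {
    days_active <- as.numeric(cw$exit_date - cw$calvings[1])
    if (days_active <= 0) return(NULL)
    out <- list()
    for (cat in names(config$event_rates)) {
      n <- stats::rpois(1, config$event_rates[[cat]] * days_active)
      if (n == 0) next
      dates <- cw$calvings[1] + sort(sample.int(days_active, n, TRUE))
      kind <- switch(cat, mastitis = "mastitis", lameness = "lameness",
                     "treatment")
      raw <- switch(
        cat,
        mastitis = rep("mastitis case", n),
        lameness = rep("lame - mobility score", n),
        antimicrobial = typo(sample(
          products$name[products$category == "antimicrobial"], n, TRUE)),
        anti_inflammatory = typo(sample(
          products$name[products$category == "anti_inflammatory"], n, TRUE)))
      out[[cat]] <- dplyr::tibble(cow_id = cw$cow_id, date = dates,
                                  raw_text = raw, kind = kind,
                                  true_category = cat)
    }
    dplyr::bind_rows(out)
  })
  events <- dplyr::bind_rows(ev_rows)
  if (nrow(events) == 0)
    events <- dplyr::tibble(cow_id = character(), date = as.Date(character()),
                            raw_text = character(), kind = character(),
                            true_category = character())
  if (nrow(events) > 0) {
    recorded <- stats::runif(nrow(events)) < config$recording_completeness
    events <- events[recorded, , drop = FALSE]
  }

  truth <- dplyr::bind_rows(lapply(cows, function(cw) dplyr::tibble(
    cow_id = cw$cow_id, farm_id = farms$farm_id[cw$farm_i],
    dam_id = cw$dam_id, generation = cw$generation, latent = cw$latent,
    injected = if (is.null(cw$injected)) NA_real_ else cw$injected,
    mean_thi_t1 = if (is.null(cw$exposures)) NA_real_ else
      cw$exposures[["mean_thi_t1"]],
    mean_thi_t2 = if (is.null(cw$exposures)) NA_real_ else
      cw$exposures[["mean_thi_t2"]],
    mean_thi_t3 = if (is.null(cw$exposures)) NA_real_ else
      cw$exposures[["mean_thi_t3"]],
    true_scale = cw$params[["scale"]],
    n_lactations = length(cw$calvings))))
  granddam <- cow_tab$dam_id[match(truth$dam_id, cow_tab$cow_id)]
  truth$granddam_id <- granddam

  structure(list(
    cows = cow_tab, calvings = calving_tab, milk = milk_tab,
    events = dplyr::as_tibble(events), weather = weather,
    stations = wx$stations, farms = farms[c("farm_id", "lat", "lon")],
    products = products,
    truth = list(cows = truth,
                 effects = config$injected_effects,
                 variance_components = c(config$variance_components,
                                         residual = config$noise_sd)),
    config = config), class = "herd_sim")
}

#' Write a simulated herd to a directory of CSV files
#'
#' @param sim A `herd_sim` from [simulate_herds()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_herd_csvs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(cows = sim$cows, calvings = sim$calvings, milk = sim$milk,
               events = sim$events,
               weather = sim$weather[c("station_id", "date", "t_max",
                                       "dewpoint")],
               stations = sim$stations, farms = sim$farms,
               products = sim$products, truth_cows = sim$truth$cows)
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read a herd CSV directory back into typed tables
#'
#' Inverse of [write_herd_csvs()]: parses the date columns so the tables can
#' flow straight into the cleaning and scoring functions.
#'
#' @param dir Directory holding the CSV set.
#' @return Named list of tibbles.
#' @export
read_herd_csvs <- function(dir) {
  rd <- function(nm, date_cols = character()) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) return(NULL)
    tab <- dplyr::as_tibble(utils::read.csv(p, stringsAsFactors = FALSE))
    for (col in intersect(date_cols, names(tab)))
      tab[[col]] <- as.Date(tab[[col]])
    tab
  }
  list(cows = rd("cows", c("birth_date", "entry_date", "exit_date")),
       calvings = rd("calvings", "calving_date"),
       milk = rd("milk", "date"),
       events = rd("events", "date"),
       weather = rd("weather", "date"),
       stations = rd("stations"),
       farms = rd("farms"),
       products = rd("products"),
       truth_cows = rd("truth_cows", character()))
}
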