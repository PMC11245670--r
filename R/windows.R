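#' Conception date of a pregnancy
#'
#' Commercial-herd mode estimates conception as 283 d (mean bovine gestation)
#' before the calving date; research-herd mode uses the recorded last
#' insemination before the pregnancy.
#'
#' @param calving_date Calving date ending the pregnancy.
#' @param mode `"estimated"` or `"insemination"`.
#' @param insemination_date Required in insemination mode; must precede the
#'   calving date.
#' @return Conception date.
#' @export
conception_date <- function(calving_date, mode = c("estimated", "insemination"),
                            insemination_date = NULL) {
  mode <- match.arg(mode)
  if (mode == "estimated") return(calving_date - 283)
  if (is.null(insemination_date))
    stop("insemination mode requires an insemination date")
  if (any(insemination_date >= calving_date))
    stop("insemination date must precede the calving date")
  insemination_date
}

#' Assign a day of pregnancy to its trimester window
#'
#' Days are counted from conception (day 0); the windows include 7 d of
#' preconception: trimester 1 spans days -7..94, trimester 2 days 95..189,
#' trimester 3 days 190..283. The three windows partition the 291-day span
#' with boundary days belonging to the window whose printed range contains
#' them.
#'
#' @param day Integer day(s) relative to conception, in \[-7, 283\].
#' @return Character vector of `"T1"`, `"T2"`, `"T3"`.
#' @export
assign_window <- function(day) {
  if (any(day < -7 | day > 283))
    stop("day of pregnancy outside [-7, 283]")
  ifelse(day <= 94, "T1", ifelse(day <= 189, "T2", "T3"))
}

#' Trimester window date ranges for one pregnancy
#'
#' @param conception Conception date.
#' @return Tibble `window`, `start`, `end` (closed date intervals).
#' @export
trimester_dates <- function(conception) {
  dplyr::tibble(window = c("T1", "T2", "T3"),
                start = conception + c(-7, 95, 190),
                end = conception + c(94, 189, 283))
}

#' Presence/absence of each stressor category within each trimester
#'
#' @param events Categorized events of one dam (`date`, `category`).
#' @param conception Conception date of the pregnancy.
#' @param categories Categories to flag.
#' @return Tibble, one row per window, logical column per category.
#' @export
summarize_events <- function(events, conception,
                             categories = c("mastitis", "lameness",
                                            "antimicrobial",
                                            "anti_inflammatory")) {
  win <- trimester_dates(conception)
  flags <- lapply(categories, function(cat) {
    d <- events$date[events$category == cat]
    vapply(seq_len(3), function(w)
      any(d >= win$start[w] & d <= win$end[w]), logical(1))
  })
  names(flags) <- categories
  dplyr::bind_cols(win["window"], dplyr::as_tibble(flags))
}

band <- function(x, breaks, labels) {
  if (length(x) == 0 || all(is.na(x))) return("missing")
  as.character(cut(x, breaks = breaks, labels = labels, right = TRUE))
}

#' Milk-quality category bands over a trimester window
#'
#' Summarises the dam's milk recordings dated inside the window (recording
#' date, not DIM, decides membership): minimum/median/maximum fat, protein
#' and yield, maximum fat:protein ratio and maximum SCC, each mapped to its
#' category band. Band convention: ">a-b" is the half-open interval (a, b],
#' so a value exactly on an upper edge belongs to the lower band; no
#' recording in the window gives `"missing"`.
#'
#' @param milk Milk recordings of the dam (`date`, `yield`, `fat_pct`,
#'   `protein_pct`, `scc`).
#' @param start,end Window bounds (closed).
#' @return One-row tibble of band labels.
#' @export
categorize_milk <- function(milk, start, end) {
  m <- milk[milk$date >= start & milk$date <= end, , drop = FALSE]
  fat_b <- function(x) band(x, c(0, 3, 5, Inf), c(">0-3%", ">3-5%", ">5%"))
  prot_b <- function(x) band(x, c(0, 3, 4, Inf), c(">0-3%", ">3-4%", ">4%"))
  fp_b <- function(x) band(x, c(0, 1, 1.2, 1.4, Inf),
                           c(">0-1", ">1-1.2", ">1.2-1.4", ">1.4"))
  scc_b <- function(x) band(x, c(0, 50, 100, 200, 400, Inf),
                            c(">0-50", ">50-100", ">100-200", ">200-400",
                              ">400"))
  yld_b <- function(x) band(x, c(0, 20, 30, 40, Inf),
                            c(">0-20", ">20-30", ">30-40", ">40"))
  s <- function(x) if (nrow(m) == 0) rep(NA_real_, 3) else
    c(min(x, na.rm = TRUE), stats::median(x, na.rm = TRUE),
      max(x, na.rm = TRUE))
  fat <- s(m$fat_pct); prot <- s(m$protein_pct); yld <- s(m$yield)
  dplyr::tibble(
    fat_min = fat_b(fat[1]), fat_med = fat_b(fat[2]), fat_max = fat_b(fat[3]),
    protein_min = prot_b(prot[1]), protein_med = prot_b(prot[2]),
    protein_max = prot_b(prot[3]),
    fat_protein_max = if (nrow(m) == 0) "missing" else
      fp_b(max(m$fat_pct / m$protein_pct, na.rm = TRUE)),
    scc_max = if (nrow(m) == 0) "missing" else
      scc_b(max(m$scc, na.rm = TRUE)),
    yield_min = yld_b(yld[1]), yield_med = yld_b(yld[2]),
    yield_max = yld_b(yld[3]))
}

#' Body-condition or locomotion category over a window
#'
#' Research-herd variant: the mean BCS in the window maps to under (<1.5),
#' normal (1.5-3.25, both edges inclusive) or over (>3.25); locomotion is
#' lame iff the maximum score in the window is >= 4.
#'
#' @param scores Numeric scores recorded inside the window.
#' @param kind `"bcs"` or `"locomotion"`.
#' @return Category string; `"missing"` when no scores fall in the window.
#' @export
categorize_condition <- function(scores, kind = c("bcs", "locomotion")) {
  kind <- match.arg(kind)
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) return("missing")
  if (kind == "bcs") {
    m <- mean(scores)
    if (m < 1.5) "under" else if (m > 3.25) "over" else "normal"
  } else {
    if (max(scores) >= 4) "lame" else "not_lame"
  }
}

#' Season of birth from a calendar date
#'
#' Meteorological seasons: spring is March-May, summer June-August, autumn
#' September-November, winter December-February.
#'
#' @param date Date vector.
#' @return Character vector of seasons.
#' @export
season_of_birth <- function(date) {
  m <- as.integer(format(date, "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[m]
}

#' Farm-level features at a calf's birth
#'
#' The herd 305-d yield context is the mean of all 305-d yields from
#' lactations starting within the 12 months before the calf's birth
#' (exclusive lower edge, lactations on the birth day itself excluded); the
#' parity structure is the mean parity across the farm's calvings in the
#' calf's birth year.
#'
#' @param birth_date Calf birth date.
#' @param lactation_starts Tibble of the farm's lactations: `start_date`,
#'   `yield_305`.
#' @param farm_calvings Tibble of the farm's calvings with `calving_date` and
#'   `parity`.
#' @return One-row tibble `mean_305d_yield`, `mean_parity` (NA when no
#'   qualifying records exist).
#' @export
farm_features <- function(birth_date, lactation_starts, farm_calvings) {
  in_lookback <- lactation_starts$start_date > (birth_date - 365) &
    lactation_starts$start_date < birth_date
  y <- lactation_starts$yield_305[in_lookback]
  y <- y[!is.na(y)]
  yr <- format(birth_date, "%Y")
  p <- farm_calvings$parity[format(farm_calvings$calving_date, "%Y") == yr]
  dplyr::tibble(
    mean_305d_yield = if (length(y)) mean(y) else NA_real_,
    mean_parity = if (length(p)) mean(p) else NA_real_)
}

#' Assemble the model feature table
#'
#' One row per retained offspring-ancestor pair: the offspring's LRS as the
#' outcome; per-trimester stressor presence flags, mean THI_max and
#' milk-quality bands for the ancestor's pregnancy; pregnancy number
#' collapsed to 2 / 3 / 4+; the mother's LRS centered on the dataset mean;
#' season of birth; and farm-level yield/parity context.
#'
#' @param pairs Pair table from [match_pairs()].
#' @param cows Cleaned cow table.
#' @param calvings Calving table.
#' @param events Categorized event table.
#' @param milk Cleaned milk table.
#' @param weather Enriched weather table (with `thi_max`).
#' @param farm_stations Farm-to-station map from [match_nearest_station()].
#' @param lrs LRS table from [compute_lrs_all()].
#' @param fits Lactation-fit table (for farm 305-d yield context).
#' @param mode `"daughter"` (ancestor = mother) or `"granddaughter"`
#'   (ancestor = granddam; the mother's LRS is additionally attached).
#' @return Tibble of feature rows; rows lacking an outcome are dropped and
#'   counted in the `"n_dropped"` attribute.
#' @export
build_features <- function(pairs, cows, calvings, events, milk, weather,
                           farm_stations, lrs, fits, mode = "daughter") {
  lrs_by_cow <- stats::setNames(lrs$lrs, lrs$cow_id)
  farm_of <- stats::setNames(cows$farm_id, cows$cow_id)
  dam_of <- stats::setNames(cows$dam_id, cows$cow_id)
  birth_of <- stats::setNames(cows$birth_date, cows$cow_id)

  cd <- lapply(split(calvings$calving_date, calvings$cow_id), sort)
  station_of <- stats::setNames(farm_stations$station_id,
                                farm_stations$farm_id)
  wx <- split(weather, weather$station_id)
  ev <- split(events, events$cow_id)
  mk <- split(milk, milk$cow_id)

  first_calv <- vapply(cd, function(d) as.numeric(d[1]), numeric(1))
  lact_starts <- dplyr::tibble(
    cow_id = fits$cow_id, lactation = fits$lactation,
    yield_305 = fits$yield_305)
  calv_idx <- dplyr::bind_rows(lapply(names(cd), function(id) dplyr::tibble(
    cow_id = id, lactation = seq_along(cd[[id]]),
    start_date = cd[[id]], calving_date = cd[[id]],
    parity = seq_along(cd[[id]]))))
  lact_starts <- dplyr::left_join(lact_starts, calv_idx,
                                  by = c("cow_id", "lactation"))
  lact_starts$farm_id <- farm_of[lact_starts$cow_id]
  calv_idx$farm_id <- farm_of[calv_idx$cow_id]

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    off <- pairs$offspring_id[i]
    anc <- pairs$ancestor_id[i]
    outcome <- lrs_by_cow[[off]]
    if (is.null(outcome) || is.na(outcome)) return(NULL)
    conc <- conception_date(pairs$calving_date[i], "estimated")
    win <- trimester_dates(conc)

    anc_ev <- ev[[anc]]
    flags <- summarize_events(
      if (is.null(anc_ev)) dplyr::tibble(date = as.Date(character()),
                                         category = character()) else anc_ev,
      conc)
    flag_cols <- as.list(stats::setNames(
      as.vector(t(as.matrix(flags[-1]))),
      paste(rep(names(flags)[-1], 3),
            rep(c("t1", "t2", "t3"), each = ncol(flags) - 1), sep = "_")))

    farm <- farm_of[[anc]]
    w <- wx[[station_of[[farm]]]]
    thi <- vapply(seq_len(3), function(k)
      mean_thi(w, win$start[k], win$end[k]), numeric(1))

    anc_mk <- mk[[anc]]
    if (is.null(anc_mk))
      anc_mk <- dplyr::tibble(date = as.Date(character()), yield = numeric(),
                              fat_pct = numeric(), protein_pct = numeric(),
                              scc = numeric())
    milk_cats <- lapply(seq_len(3), function(k)
      categorize_milk(anc_mk, win$start[k], win$end[k]))
    milk_cols <- unlist(lapply(seq_len(3), function(k)
      stats::setNames(as.list(milk_cats[[k]]),
                      paste0(names(milk_cats[[k]]), "_t", k))),
      recursive = FALSE)

    ff <- farm_features(birth_of[[off]],
                        lact_starts[lact_starts$farm_id == farm &
                                      !is.na(lact_starts$farm_id), ,
                                    drop = FALSE],
                        calv_idx[calv_idx$farm_id == farm &
                                   !is.na(calv_idx$farm_id), , drop = FALSE])

    mother <- if (mode == "daughter") anc else dam_of[[off]]
    mother_lrs <- if (!is.na(mother) && mother %in% names(lrs_by_cow))
      lrs_by_cow[[mother]] else NA_real_
    ancestor_lrs <- lrs_by_cow[[anc]]
    if (is.null(ancestor_lrs)) ancestor_lrs <- NA_real_

    dplyr::bind_cols(
      dplyr::tibble(
        offspring_id = off, ancestor_id = anc, dam_id = mother,
        farm_id = farm, outcome = outcome,
        pregnancy = as.character(min(pairs$pregnancy_index[i], 4)),
        mother_lrs = mother_lrs, ancestor_lrs = ancestor_lrs,
        season_of_birth = season_of_birth(birth_of[[off]]),
        mean_thi_t1 = thi[1], mean_thi_t2 = thi[2], mean_thi_t3 = thi[3]),
      dplyr::as_tibble(flag_cols), dplyr::as_tibble(milk_cols), ff)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out$pregnancy <- ifelse(out$pregnancy == "4", "4+", out$pregnancy)
    out$mother_lrs_centered <- out$mother_lrs -
      mean(out$mother_lrs, na.rm = TRUE)
  }
  attr(out, "n_dropped") <- nrow(pairs) - nrow(out)
  out
}
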