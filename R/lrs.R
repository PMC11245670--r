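#' Herd-average quantities entering the lifetime resilience score
#'
#' Computes, per grouping unit (farm, or farm x subherd for a research-herd
#' analysis), the mean calving interval over all selected cows and years, the
#' mean calving interval for each lactation transition j to j+1, and the
#' fitted lactation-curve parameters of every contributing cow-lactation,
#' from which the herd-average daily yield at any day of lactation j is the
#' across-cow mean of fitted curves (monthly recordings cannot supply daily
#' sums, so fitted curves stand in for daily milk on both sides of the yield
#' ratio). Cow-lactations without a converged fit do not contribute.
#'
#' @param cows Cleaned cow table; must contain the `group_cols`.
#' @param calvings Calving table (`cow_id`, `calving_date`).
#' @param fits Lactation-fit table from [fit_lactations()].
#' @param group_cols Character vector of grouping columns, default `"farm_id"`.
#' @return Object of class `herd_averages`: a named list of per-group
#'   summaries (`cint_mean`, `cint_by_j`, `params`) plus the group map.
#' @export
herd_averages <- function(cows, calvings, fits, group_cols = "farm_id") {
  key <- do.call(paste, c(cows[group_cols], sep = "/"))
  cow_group <- stats::setNames(key, cows$cow_id)

  ints <- calving_intervals(calvings)
  ints$group <- cow_group[ints$cow_id]
  fits <- fits[fits$converged, , drop = FALSE]
  fits$group <- cow_group[fits$cow_id]

  groups <- lapply(unique(key), function(g) {
    gi <- ints[!is.na(ints$group) & ints$group == g, , drop = FALSE]
    if (nrow(gi) == 0)
      stop("group '", g, "' has no calving intervals; cannot form herd averages")
    list(cint_mean = mean(gi$interval),
         cint_by_j = tapply(gi$interval, gi$transition, mean),
         params = fits[!is.na(fits$group) & fits$group == g, , drop = FALSE])
  })
  names(groups) <- unique(key)
  structure(list(groups = groups, cow_group = cow_group,
                 group_cols = group_cols),
            class = "herd_averages")
}

#' Calving intervals per cow and lactation transition
#'
#' @param calvings Calving table.
#' @return Tibble `cow_id`, `transition` (j, the lactation whose start opens
#'   the interval), `interval` (days between calving j and j+1).
#' @export
calving_intervals <- function(calvings) {
  cd <- lapply(split(calvings$calving_date, calvings$cow_id), sort)
  rows <- lapply(names(cd), function(id) {
    d <- cd[[id]]
    if (length(d) < 2) return(NULL)
    dplyr::tibble(cow_id = id, transition = seq_len(length(d) - 1),
                  interval = as.numeric(diff(d)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- dplyr::tibble(cow_id = character(), transition = integer(),
                         interval = numeric())
  out
}

#' Herd-average daily yield for lactation j at given days
#'
#' Mean across contributing cows of the fitted (floored) lactation curves.
#'
#' @param group One element of `herd_averages$groups`.
#' @param j Lactation number.
#' @param days Days in milk (>= 1).
#' @return Numeric vector of mean kg/day, `NA` if no cow contributes.
#' @keywords internal
my_mean_day <- function(group, j, days) {
  p <- group$params[group$params$lactation == j, , drop = FALSE]
  if (nrow(p) == 0) return(rep(NA_real_, length(days)))
  curves <- mapply(function(s, r, o, d) milkbot_curve(days, s, r, o, d),
                   p$scale, p$ramp, p$offset, p$decay)
  rowMeans(matrix(curves, nrow = length(days)))
}

#' Lifetime resilience score of one cow
#'
#' The score is a baseline equal to the herd mean calving interval, plus a
#' 300-point bonus per started lactation, plus one point per day the age at
#' first calving falls short of 730 d (minus one per day beyond), plus the
#' summed day deviations of the cow's calving intervals below their herd
#' transition means, plus, per lactation, the percentage by which the cow's
#' summed daily yield over days 1..max(305, DIM at lactation end) exceeds the
#' herd-average sum over the same days, minus a penalty of one point per DIM
#' short of 100 when the cow exits her final lactation before 100 DIM.
#'
#' @param cow_id Cow identifier (must appear in the herd-averages group map).
#' @param birth_date Birth date.
#' @param calving_dates Sorted calving dates (length >= 1).
#' @param fits_by_lact Named list of `lactation_fit` objects, names
#'   `"1"`, `"2"`, ... per lactation.
#' @param avgs A [herd_averages()] object.
#' @param dim_last DIM at the end of the final lactation (exit date minus
#'   last calving date, or a proxy when exit is unrecorded).
#' @return One-row tibble with `cow_id`, `lrs`, the six additive components
#'   (`baseline`, `lactation_bonus`, `afc_component`, `calving_interval`,
#'   `yield`, `early_exit_penalty`), `exit_lactation` and `afc`. `lrs` is
#'   `NA` when a lactation lacks a converged yield curve.
#' @export
compute_lrs <- function(cow_id, birth_date, calving_dates, fits_by_lact,
                        avgs, dim_last) {
  group <- avgs$groups[[avgs$cow_group[[cow_id]]]]
  L <- length(calving_dates)
  afc <- as.numeric(calving_dates[1] - birth_date)
  na_row <- function() dplyr::tibble(
    cow_id = cow_id, lrs = NA_real_, baseline = NA_real_,
    lactation_bonus = NA_real_, afc_component = NA_real_,
    calving_interval = NA_real_, yield = NA_real_,
    early_exit_penalty = NA_real_, exit_lactation = L, afc = afc)

  dim_end <- c(if (L > 1) as.numeric(diff(calving_dates)), dim_last)

  baseline <- group$cint_mean
  bonus <- 300 * L
  afc_comp <- 730 - afc

  cint_comp <- 0
  if (L > 1) {
    own <- as.numeric(diff(calving_dates))
    herd <- group$cint_by_j[as.character(seq_len(L - 1))]
    if (anyNA(herd)) return(na_row())
    cint_comp <- sum(herd - own)
  }

  yield_comp <- 0
  for (j in seq_len(L)) {
    fit <- fits_by_lact[[as.character(j)]]
    if (is.null(fit) || !isTRUE(fit$converged)) return(na_row())
    K <- max(305, dim_end[j])
    days <- seq_len(K)
    herd_daily <- my_mean_day(group, j, days)
    if (anyNA(herd_daily)) return(na_row())
    yield_comp <- yield_comp +
      (sum(predict_daily(fit, days)) / sum(herd_daily) - 1) * 100
  }

  exit_pen <- min(0, dim_last - 100)
  dplyr::tibble(
    cow_id = cow_id,
    lrs = baseline + bonus + afc_comp + cint_comp + yield_comp + exit_pen,
    baseline = baseline, lactation_bonus = bonus, afc_component = afc_comp,
    calving_interval = cint_comp, yield = yield_comp,
    early_exit_penalty = exit_pen, exit_lactation = L, afc = afc)
}

#' Lifetime resilience scores for a whole herd
#'
#' Computes [herd_averages()] internally, derives DIM at the end of each
#' cow's final lactation from her exit date (falling back to her last milk
#' recording date plus one day when exit is unrecorded, flagged in the
#' `exit_proxy` column), and scores every cow with at least one calving.
#'
#' @param cows Cleaned cow table.
#' @param calvings Calving table.
#' @param fits Lactation-fit table from [fit_lactations()].
#' @param milk Optional cleaned milk table, used only for the exit-date proxy.
#' @param group_cols Grouping columns for the herd averages.
#' @return Tibble of per-cow scores and components; `n_missing` attribute
#'   counts cows whose LRS could not be computed for lack of a converged
#'   lactation curve.
#' @export
compute_lrs_all <- function(cows, calvings, fits, milk = NULL,
                            group_cols = "farm_id") {
  avgs <- herd_averages(cows, calvings, fits, group_cols)
  cd <- lapply(split(calvings$calving_date, calvings$cow_id), sort)
  last_milk <- if (!is.null(milk))
    tapply(milk$date, milk$cow_id, max) else NULL

  fit_rows <- split(fits, fits$cow_id)
  rows <- lapply(seq_len(nrow(cows)), function(i) {
    id <- cows$cow_id[i]
    dates <- cd[[id]]
    if (is.null(dates)) return(NULL)
    proxy <- FALSE
    if (!is.na(cows$exit_date[i])) {
      dim_last <- as.numeric(cows$exit_date[i] - dates[length(dates)])
    } else if (!is.null(last_milk) && !is.na(last_milk[id])) {
      dim_last <- as.numeric(last_milk[id] - as.numeric(dates[length(dates)])) + 1
      proxy <- TRUE
    } else {
      return(NULL)
    }
    fb <- fit_rows[[id]]
    fits_by_lact <- if (is.null(fb)) list() else
      stats::setNames(lapply(seq_len(nrow(fb)),
                             function(r) fit_from_row(fb[r, ])),
                      as.character(fb$lactation))
    out <- compute_lrs(id, cows$birth_date[i], dates, fits_by_lact, avgs,
                       dim_last)
    out$exit_proxy <- proxy
    out
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_missing") <- sum(is.na(out$lrs))
  out
}
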