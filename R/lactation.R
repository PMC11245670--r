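#' MilkBot lactation curve
#'
#' Four-parameter nonlinear lactation curve
#' `yield(t) = scale * (1 - exp((offset - t) / ramp) / 2) * exp(-decay * t)`:
#' `scale` (kg) sets the overall magnitude, `ramp` (days) the steepness of the
#' early rise, `offset` (days) a time shift of that rise, and `decay` (1/day)
#' the exponential rate of late-lactation decline.
#'
#' @param t Days in milk (numeric vector).
#' @param scale,ramp,offset,decay Curve parameters.
#' @return Predicted daily yield in kg/day, floored at 0.
#' @export
milkbot_curve <- function(t, scale, ramp, offset, decay) {
  pmax(0, scale * (1 - exp((offset - t) / ramp) / 2) * exp(-decay * t))
}

#' Fit the lactation curve to one cow-lactation
#'
#' Bounded least squares on (DIM, yield) pairs with DIM in \[0, 305\] and
#' yield > 0. Start values are data driven (scale near 1.2x the maximum
#' yield, ramp 25 d, offset -5 d, decay 0.002/d); on failure up to three
#' jittered restarts are attempted before flagging non-convergence. Fewer
#' than four usable points never converges.
#'
#' @param dim Days in milk of each recording.
#' @param yield Daily yield (kg/day) of each recording.
#' @param n_starts Number of additional jittered starts tried on failure.
#' @return List of class `lactation_fit`: `params` (scale, ramp, offset,
#'   decay), `converged`, `yield_305` (kg; `NA` unless converged), `rss`,
#'   `n_obs`.
#' @export
fit_lactation <- function(dim, yield, n_starts = 3) {
  keep <- !is.na(dim) & !is.na(yield) & dim >= 0 & dim <= 305 & yield > 0
  dim <- dim[keep]; yield <- yield[keep]
  fail <- structure(list(params = c(scale = NA_real_, ramp = NA_real_,
                                    offset = NA_real_, decay = NA_real_),
                         converged = FALSE, yield_305 = NA_real_,
                         rss = NA_real_, n_obs = length(dim)),
                    class = "lactation_fit")
  if (length(dim) < 4 || length(unique(dim)) < 4) return(fail)

  base_start <- c(scale = 1.2 * max(yield), ramp = 25, offset = -5,
                  decay = 0.002)
  lower <- c(scale = 1e-6, ramp = 1, offset = -60, decay = 0)
  upper <- c(scale = 150, ramp = 150, offset = 60, decay = 0.05)
  resid_fn <- function(p)
    yield - p["scale"] * (1 - exp((p["offset"] - dim) / p["ramp"]) / 2) *
      exp(-p["decay"] * dim)
  starts <- c(list(base_start), lapply(seq_len(n_starts), function(i) {
    c(scale = unname(base_start["scale"]) * (0.7 + 0.3 * i),
      ramp = 10 + 15 * i, offset = -5 + 5 * (i - 2), decay = 0.001 * i)
  }))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = st, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit) && fit$info %in% 1:4 &&
        (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) return(fail)
  p <- best$par
  out <- structure(list(params = p[c("scale", "ramp", "offset", "decay")],
                        converged = TRUE, yield_305 = NA_real_,
                        rss = best$deviance, n_obs = length(dim)),
                   class = "lactation_fit")
  out$yield_305 <- yield_305(out)
  out
}

#' Predicted daily yield from a fitted lactation curve
#'
#' @param fit A `lactation_fit`.
#' @param day Day(s) in milk, >= 1.
#' @return Predicted kg/day (floored at 0); `NA` for non-converged fits.
#' @export
predict_daily <- function(fit, day) {
  stopifnot(all(day >= 1))
  if (!fit$converged) return(rep(NA_real_, length(day)))
  p <- fit$params
  milkbot_curve(day, p["scale"], p["ramp"], p["offset"], p["decay"])
}

#' 305-day milk yield of a fitted lactation
#'
#' Sum of the predicted daily yields over days 1..305.
#'
#' @param fit A `lactation_fit`.
#' @return Yield in kg, or `NA` for a non-converged fit.
#' @export
yield_305 <- function(fit) {
  if (!fit$converged) return(NA_real_)
  sum(predict_daily(fit, 1:305))
}

#' Fit lactation curves for every cow-lactation in a milk table
#'
#' @param milk Cleaned milk table with `cow_id`, `lactation`, `dim`, `yield`.
#' @return Tibble with one row per cow-lactation: parameters, `converged`,
#'   `yield_305`, `rss`, `n_obs`. The list of fit objects is attached as the
#'   `"fits"` attribute keyed by `"cow_id.lactation"`.
#' @export
fit_lactations <- function(milk) {
  grp <- split(milk, paste(milk$cow_id, milk$lactation, sep = "."))
  fits <- lapply(grp, function(g) fit_lactation(g$dim, g$yield))
  tab <- dplyr::bind_rows(lapply(names(fits), function(k) {
    f <- fits[[k]]
    g <- grp[[k]]
    dplyr::tibble(cow_id = g$cow_id[1], lactation = g$lactation[1],
                  scale = unname(f$params["scale"]),
                  ramp = unname(f$params["ramp"]),
                  offset = unname(f$params["offset"]),
                  decay = unname(f$params["decay"]),
                  converged = f$converged, yield_305 = f$yield_305,
                  rss = f$rss, n_obs = f$n_obs)
  }))
  tab <- dplyr::arrange(tab, .data$cow_id, .data$lactation)
  attr(tab, "fits") <- fits
  tab
}

fit_from_row <- function(row) {
  structure(list(params = c(scale = row$scale, ramp = row$ramp,
                            offset = row$offset, decay = row$decay),
                 converged = row$converged, yield_305 = row$yield_305,
                 rss = row$rss, n_obs = row$n_obs),
            class = "lactation_fit")
}
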