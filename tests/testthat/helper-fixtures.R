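# Independent oracles and small fixture builders used across the suite.

# Hand-coded dynamic-programming Levenshtein distance (oracle, kept
# independent of utils::adist used by the implementation).
lev_dist <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  na <- length(a); nb <- length(b)
  d <- matrix(0L, na + 1, nb + 1)
  d[, 1] <- 0:na; d[1, ] <- 0:nb
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    cost <- if (a[i] == b[j]) 0L else 1L
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
  }
  d[na + 1, nb + 1]
}

# Brute-force partial ratio: enumerate every same-length window of the
# longer string and maximise the normalised similarity.
brute_partial_ratio <- function(a, b) {
  a <- tolower(trimws(a)); b <- tolower(trimws(b))
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  m <- nchar(a); n <- nchar(b)
  if (m == 0) return(if (n == 0) 100 else 0)
  best <- Inf
  for (i in 1:(n - m + 1))
    best <- min(best, lev_dist(a, substr(b, i, i + m - 1)))
  100 * (1 - best / m)
}

# A lactation_fit whose curve is exactly constant at y kg/day for t >= 1.
const_fit <- function(y) {
  structure(list(params = c(scale = y, ramp = 0.1, offset = -5, decay = 0),
                 converged = TRUE, yield_305 = 305 * y, rss = 0, n_obs = 10),
            class = "lactation_fit")
}

fit_row <- function(cow_id, lactation, scale, ramp = 0.1, offset = -5,
                    decay = 0, converged = TRUE) {
  dplyr::tibble(cow_id = cow_id, lactation = lactation, scale = scale,
                ramp = ramp, offset = offset, decay = decay,
                converged = converged,
                yield_305 = if (converged) 305 * scale else NA_real_,
                rss = 0, n_obs = 10)
}

# A one-farm herd of constant-yield cows whose averages are exact:
# overall and per-transition mean calving interval 400 d, herd-average
# daily yield 30 kg in lactations 1 and 2. Includes the golden cow "T"
# (AFC 700, one 380-d interval, constant 33 kg/day) whose contributions
# are balanced by the helpers so the herd means stay exact.
golden_herd <- function() {
  birth <- as.Date("2008-01-01")
  cows <- dplyr::tibble(
    cow_id = c("T", "H1", "H2"), farm_id = "F01",
    birth_date = birth, dam_id = NA_character_, entry_date = birth,
    exit_date = as.Date(NA))
  calvings <- dplyr::tibble(
    cow_id = rep(c("T", "H1", "H2"), each = 2),
    calving_date = c(birth + 700, birth + 700 + 380,
                     birth + 730, birth + 730 + 400,
                     birth + 730, birth + 730 + 420))
  fits <- dplyr::bind_rows(
    fit_row("T", 1, 33), fit_row("T", 2, 33),
    fit_row("H1", 1, 28.5), fit_row("H1", 2, 28.5),
    fit_row("H2", 1, 28.5), fit_row("H2", 2, 28.5))
  list(cows = cows, calvings = calvings, fits = fits,
       avgs = herd_averages(cows, calvings, fits))
}

# Naive day-by-day, cow-by-cow reference scorer working from the raw
# tables; every mean and sum is recomputed with explicit loops and its own
# curve evaluation, independent of the production implementation.
ref_lrs <- function(cow_id, cows, calvings, fits, dim_last_by_cow) {
  curve <- function(t, s, r, o, d) pmax(0, s * (1 - exp((o - t) / r) / 2) *
                                          exp(-d * t))
  ints <- list(); trans <- list()
  for (id in unique(calvings$cow_id)) {
    d <- sort(calvings$calving_date[calvings$cow_id == id])
    if (length(d) >= 2) for (j in 1:(length(d) - 1)) {
      ints[[length(ints) + 1]] <- as.numeric(d[j + 1] - d[j])
      trans[[length(trans) + 1]] <- j
    }
  }
  ints <- unlist(ints); trans <- unlist(trans)
  cint_bar <- mean(ints)

  herd_day <- function(j, days) {
    rows <- fits[fits$lactation == j & fits$converged, ]
    vals <- matrix(NA_real_, nrow(rows), length(days))
    for (r in seq_len(nrow(rows)))
      vals[r, ] <- curve(days, rows$scale[r], rows$ramp[r], rows$offset[r],
                         rows$decay[r])
    colMeans(vals)
  }

  d <- sort(calvings$calving_date[calvings$cow_id == cow_id])
  L <- length(d)
  birth <- cows$birth_date[cows$cow_id == cow_id]
  afc <- as.numeric(d[1] - birth)
  dim_end <- c(if (L > 1) as.numeric(diff(d)), dim_last_by_cow[[cow_id]])
  total <- cint_bar + 300 * L + (730 - afc)
  if (L > 1) for (j in 1:(L - 1))
    total <- total + mean(ints[trans == j]) - as.numeric(d[j + 1] - d[j])
  for (j in 1:L) {
    K <- max(305, dim_end[j])
    row <- fits[fits$cow_id == cow_id & fits$lactation == j, ]
    own <- sum(curve(1:K, row$scale, row$ramp, row$offset, row$decay))
    total <- total + (own / sum(herd_day(j, 1:K)) - 1) * 100
  }
  total + min(0, dim_last_by_cow[[cow_id]] - 100)
}

# Tiny deterministic cow table builder for cleaning tests.
make_cow <- function(cow_id, farm = "F01", birth = as.Date("2008-06-01"),
                     entry = birth, dam = NA_character_, exit = as.Date(NA)) {
  dplyr::tibble(cow_id = cow_id, farm_id = farm, birth_date = birth,
                dam_id = dam, entry_date = entry, exit_date = exit)
}
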