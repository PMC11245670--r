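test_that("a herd-average cow scores baseline plus 300 per lactation", {
  g <- golden_herd()
  # one lactation at exact herd average: AFC 730, constant 30 kg/day,
  # exit at DIM >= 100 -> all deviation terms vanish
  avg1 <- compute_lrs("H1", as.Date("2008-01-01"),
                      as.Date("2008-01-01") + 730,
                      list("1" = const_fit(30)), g$avgs, dim_last = 305)
  expect_equal(avg1$lrs, g$avgs$groups[["F01"]]$cint_mean + 300)
  expect_equal(g$avgs$groups[["F01"]]$cint_mean, 400)

  # completing one more average lactation adds exactly 300 points
  avg2 <- compute_lrs("H1", as.Date("2008-01-01"),
                      as.Date("2008-01-01") + c(730, 730 + 400),
                      list("1" = const_fit(30), "2" = const_fit(30)),
                      g$avgs, dim_last = 305)
  expect_equal(avg2$lrs - avg1$lrs, 300)
  expect_equal(avg2$lactation_bonus, 600)
})

test_that("the hand-computed golden example scores 1,020 points", {
  g <- golden_herd()
  res <- compute_lrs("T", as.Date("2008-01-01"),
                     as.Date("2008-01-01") + c(700, 700 + 380),
                     list("1" = const_fit(33), "2" = const_fit(33)),
                     g$avgs, dim_last = 50)
  # 400 baseline + 600 bonus + 30 AFC + 20 interval + 20 yield - 50 exit
  expect_equal(res$lrs, 1020, tolerance = 1e-9)
  expect_equal(res$baseline, 400)
  expect_equal(res$lactation_bonus, 600)
  expect_equal(res$afc_component, 30)
  expect_equal(res$calving_interval, 20)
  expect_equal(res$yield, 20, tolerance = 1e-9)
  expect_equal(res$early_exit_penalty, -50)
  # the score is exactly the sum of its six components
  expect_equal(res$lrs, res$baseline + res$lactation_bonus +
                 res$afc_component + res$calving_interval + res$yield +
                 res$early_exit_penalty)
})

test_that("AFC component crosses zero at 730 d, one point per day", {
  g <- golden_herd()
  afc_comp <- vapply(seq(600, 900, 10), function(afc) {
    compute_lrs("H1", as.Date("2008-01-01"),
                as.Date("2008-01-01") + afc,
                list("1" = const_fit(30)), g$avgs,
                dim_last = 305)$afc_component
  }, numeric(1))
  expect_equal(afc_comp, 730 - seq(600, 900, 10))
  # translation property: shifting AFC by delta lowers the score by delta
  base <- compute_lrs("H1", as.Date("2008-01-01"),
                      as.Date("2008-01-01") + 700,
                      list("1" = const_fit(30)), g$avgs, dim_last = 305)$lrs
  shifted <- compute_lrs("H1", as.Date("2008-01-01"),
                         as.Date("2008-01-01") + 725,
                         list("1" = const_fit(30)), g$avgs,
                         dim_last = 305)$lrs
  expect_equal(base - shifted, 25)
})

test_that("the exit penalty activates strictly below 100 DIM", {
  g <- golden_herd()
  pen <- vapply(c(1, 50, 99, 100, 101, 305), function(d) {
    compute_lrs("H1", as.Date("2008-01-01"),
                as.Date("2008-01-01") + 730,
                list("1" = const_fit(30)), g$avgs, dim_last = d)$early_exit_penalty
  }, numeric(1))
  expect_equal(pen, c(-99, -50, -1, 0, 0, 0))
  expect_true(all(pen <= 0))
})

test_that("uniformly scaled yields leave the yield component unchanged at 0", {
  birth <- as.Date("2008-01-01")
  for (f in c(0.5, 1, 2.7)) {
    cows <- dplyr::tibble(cow_id = c("A", "B"), farm_id = "F01",
                          birth_date = birth, dam_id = NA_character_,
                          entry_date = birth, exit_date = birth + 1500)
    calvings <- dplyr::tibble(cow_id = rep(c("A", "B"), each = 2),
                              calving_date = birth + c(730, 1130, 730, 1130))
    fits <- dplyr::bind_rows(fit_row("A", 1, 30 * f), fit_row("B", 1, 30 * f))
    avgs <- herd_averages(cows, calvings, fits)
    res <- compute_lrs("A", birth, birth + 730,
                       list("1" = const_fit(30 * f)), avgs, dim_last = 305)
    expect_equal(res$yield, 0, tolerance = 1e-12)
  }
})

test_that("production scoring agrees with the naive reference on a herd", {
  set.seed(21)
  birth <- as.Date("2008-01-01")
  n <- 25
  ids <- sprintf("R%02d", 1:n)
  afc <- round(runif(n, 650, 850))
  nlact <- sample(1:3, n, TRUE)
  cows <- dplyr::tibble(cow_id = ids, farm_id = "F01", birth_date = birth,
                        dam_id = NA_character_, entry_date = birth,
                        exit_date = as.Date(NA))
  calvings <- list(); fits <- list(); dim_last <- list()
  for (i in 1:n) {
    dates <- birth + cumsum(c(afc[i], round(runif(nlact[i] - 1, 350, 450))))
    calvings[[i]] <- dplyr::tibble(cow_id = ids[i], calving_date = dates)
    for (j in seq_len(nlact[i]))
      fits[[length(fits) + 1]] <-
        fit_row(ids[i], j, scale = runif(1, 25, 40), ramp = runif(1, 15, 30),
                offset = runif(1, -10, 0), decay = runif(1, 1e-3, 4e-3))
    dim_last[[ids[i]]] <- round(runif(1, 30, 400))
    cows$exit_date[i] <- dates[length(dates)] + dim_last[[ids[i]]]
  }
  calvings <- dplyr::bind_rows(calvings)
  fits <- dplyr::bind_rows(fits)

  got <- compute_lrs_all(cows, calvings, fits)
  expect_equal(nrow(got), n)
  expect_equal(attr(got, "n_missing"), 0)
  for (id in sample(ids, 10)) {
    expect_equal(got$lrs[got$cow_id == id],
                 ref_lrs(id, cows, calvings, fits, dim_last),
                 tolerance = 1e-9, info = id)
  }
  # component identity holds for every cow
  expect_equal(got$lrs, got$baseline + got$lactation_bonus +
                 got$afc_component + got$calving_interval + got$yield +
                 got$early_exit_penalty)
})

test_that("missing yield curves give a missing, counted score", {
  g <- golden_herd()
  res <- compute_lrs("T", as.Date("2008-01-01"),
                     as.Date("2008-01-01") + c(700, 1080),
                     list("1" = const_fit(33)), g$avgs, dim_last = 50)
  expect_true(is.na(res$lrs))
})

test_that("herd averages match a direct group-by computation", {
  birth <- as.Date("2008-01-01")
  cows <- dplyr::tibble(cow_id = c("A", "B", "C"), farm_id = c("F1", "F1", "F2"),
                        birth_date = birth, dam_id = NA_character_,
                        entry_date = birth, exit_date = as.Date(NA))
  calvings <- dplyr::tibble(
    cow_id = c("A", "A", "A", "B", "B", "C", "C"),
    calving_date = birth + c(700, 1080, 1500, 730, 1150, 720, 1100))
  fits <- dplyr::bind_rows(fit_row("A", 1, 30), fit_row("B", 1, 32),
                           fit_row("C", 1, 28))
  avgs <- herd_averages(cows, calvings, fits)
  # F1 intervals: A 380, 420; B 420 -> overall (380+420+420)/3
  expect_equal(avgs$groups[["F1"]]$cint_mean, mean(c(380, 420, 420)))
  expect_equal(unname(avgs$groups[["F1"]]$cint_by_j["1"]), mean(c(380, 420)))
  expect_equal(unname(avgs$groups[["F1"]]$cint_by_j["2"]), 420)
  expect_equal(avgs$groups[["F2"]]$cint_mean, 380)
  # a group without calving intervals is an error naming the group
  solo <- dplyr::tibble(cow_id = "Z", farm_id = "F9", birth_date = birth,
                        dam_id = NA_character_, entry_date = birth,
                        exit_date = as.Date(NA))
  expect_error(
    herd_averages(rbind(cows, solo),
                  rbind(calvings,
                        dplyr::tibble(cow_id = "Z", calving_date = birth + 700)),
                  fits),
    "F9")
})
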