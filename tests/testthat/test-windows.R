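test_that("trimester windows partition -7..283 into sizes 102/95/94", {
  days <- -7:283
  w <- assign_window(days)
  expect_equal(as.vector(table(w)[c("T1", "T2", "T3")]), c(102L, 95L, 94L))
  expect_equal(assign_window(-7), "T1")
  expect_equal(assign_window(94), "T1")
  expect_equal(assign_window(95), "T2")
  expect_equal(assign_window(189), "T2")
  expect_equal(assign_window(190), "T3")
  expect_equal(assign_window(283), "T3")
  expect_error(assign_window(284), "outside")
  expect_error(assign_window(-8), "outside")
  # window date ranges tile the same span with no overlap or gap
  win <- trimester_dates(as.Date("2010-01-01"))
  covered <- unlist(mapply(function(s, e) seq(s, e, by = "day"),
                           win$start, win$end))
  expect_equal(length(covered), 291)
  expect_equal(length(unique(covered)), 291)
})

test_that("conception dates follow the estimated and insemination modes", {
  expect_equal(conception_date(as.Date("2010-10-11")), as.Date("2010-01-01"))
  # round trip
  calv <- as.Date("2012-05-20")
  expect_equal(conception_date(calv) + 283, calv)
  ins <- as.Date("2011-08-01")
  expect_equal(conception_date(calv, "insemination", ins), ins)
  expect_error(conception_date(calv, "insemination", calv + 1), "precede")
  expect_error(conception_date(calv, "insemination"), "requires")
})

test_that("event presence flags match a brute-force day scan", {
  conc <- as.Date("2011-03-15")
  ev <- dplyr::tibble(date = conc + c(100, 250),
                      category = c("mastitis", "lameness"))
  flags <- summarize_events(ev, conc)
  expect_equal(flags$mastitis, c(FALSE, TRUE, FALSE))  # day 100 is in T2
  expect_equal(flags$lameness, c(FALSE, FALSE, TRUE))
  expect_false(any(flags$antimicrobial))

  set.seed(9)
  for (rep in 1:20) {
    n <- sample(0:6, 1)
    ev <- dplyr::tibble(
      date = conc + sample(-7:283, n, TRUE),
      category = sample(c("mastitis", "lameness", "antimicrobial",
                          "anti_inflammatory"), n, TRUE))
    flags <- summarize_events(ev, conc)
    for (cat in c("mastitis", "lameness", "antimicrobial",
                  "anti_inflammatory")) {
      rel_days <- as.numeric(ev$date[ev$category == cat] - conc)
      truth <- vapply(c("T1", "T2", "T3"), function(w)
        any(assign_window(rel_days) == w), logical(1))
      expect_equal(unname(flags[[cat]]), unname(truth))
    }
  }
})

test_that("milk-quality bands follow the (a, b] half-open convention", {
  win <- c(as.Date("2011-01-01"), as.Date("2011-03-31"))
  mk <- function(fat = 4, prot = 3.4, yield = 28, scc = 80, n = 3)
    dplyr::tibble(date = seq(win[1], win[2], length.out = n),
                  yield = yield, fat_pct = fat, protein_pct = prot, scc = scc)
  # fat max exactly 3.0 belongs to the lower band
  expect_equal(categorize_milk(mk(fat = 3), win[1], win[2])$fat_max, ">0-3%")
  expect_equal(categorize_milk(mk(fat = 3.01), win[1], win[2])$fat_max, ">3-5%")
  expect_equal(categorize_milk(mk(scc = 400), win[1], win[2])$scc_max,
               ">200-400")
  expect_equal(categorize_milk(mk(scc = 401), win[1], win[2])$scc_max, ">400")
  expect_equal(categorize_milk(mk(yield = 20), win[1], win[2])$yield_max,
               ">0-20")
  cat <- categorize_milk(mk(fat = 4.2, prot = 3.5), win[1], win[2])
  expect_equal(cat$fat_protein_max, ">1-1.2")
  # no recording inside the window -> every band is "missing"
  none <- categorize_milk(mk(), win[2] + 10, win[2] + 50)
  expect_true(all(unlist(none) == "missing"))
  # min/median/max summarised before banding
  spread <- dplyr::tibble(date = win[1] + c(10, 40, 70),
                          yield = c(15, 25, 45), fat_pct = c(2.5, 4, 5.5),
                          protein_pct = c(2.9, 3.3, 4.2), scc = c(40, 90, 450))
  got <- categorize_milk(spread, win[1], win[2])
  expect_equal(got$yield_min, ">0-20")
  expect_equal(got$yield_med, ">20-30")
  expect_equal(got$yield_max, ">40")
  expect_equal(got$fat_min, ">0-3%")
  expect_equal(got$fat_med, ">3-5%")
  expect_equal(got$fat_max, ">5%")
  expect_equal(got$protein_min, ">0-3%")
  expect_equal(got$protein_max, ">4%")
  expect_equal(got$scc_max, ">400")
})

test_that("condition scores band on window mean (BCS) and max (locomotion)", {
  expect_equal(categorize_condition(c(4, 2, 1), "locomotion"), "lame")
  expect_equal(categorize_condition(c(3, 3, 2), "locomotion"), "not_lame")
  expect_equal(categorize_condition(numeric(), "locomotion"), "missing")
  expect_equal(categorize_condition(1.5, "bcs"), "normal")
  expect_equal(categorize_condition(3.25, "bcs"), "normal")
  expect_equal(categorize_condition(c(1, 1.4), "bcs"), "under")
  expect_equal(categorize_condition(3.3, "bcs"), "over")
})

test_that("season of birth maps months to meteorological seasons", {
  expect_equal(season_of_birth(as.Date("2010-06-01")), "summer")
  expect_equal(season_of_birth(as.Date("2010-12-01")), "winter")
  expect_equal(season_of_birth(as.Date("2012-02-29")), "winter")
  expect_equal(season_of_birth(as.Date("2010-03-01")), "spring")
  expect_equal(season_of_birth(as.Date("2010-11-30")), "autumn")
})

test_that("farm features use a 12-month lookback and birth-year parity", {
  birth <- as.Date("2012-06-01")
  lacts <- dplyr::tibble(
    start_date = birth - c(30, 200, 364, 365, 400),
    yield_305 = c(8000, 9000, 10000, 11000, 12000))
  calv <- dplyr::tibble(
    calving_date = as.Date(c("2012-01-10", "2012-07-01", "2011-06-01")),
    parity = c(2, 4, 9))
  got <- farm_features(birth, lacts, calv)
  # lactations exactly 365 and 400 d old fall outside the lookback
  expect_equal(got$mean_305d_yield, mean(c(8000, 9000, 10000)))
  expect_equal(got$mean_parity, 3)

  single <- farm_features(birth, lacts[1, ], calv)
  expect_equal(single$mean_305d_yield, 8000)
  empty <- farm_features(birth, lacts[5, ], calv[3, ])
  expect_true(is.na(empty$mean_305d_yield))
  expect_true(is.na(empty$mean_parity))
})

test_that("assembled feature rows center mother LRS and collapse parity", {
  cfg <- sim_config(n_farms = 2, cows_per_farm = 10, seed = 5)
  res <- suppressWarnings(run_pipeline(cfg, run_model = FALSE))
  f <- res$features
  expect_gt(nrow(f), 5)
  expect_equal(mean(f$mother_lrs_centered, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_true(all(f$pregnancy %in% c("2", "3", "4+")))
  expect_true(all(f$pregnancy[f$pregnancy == "4+"] == "4+"))
  expect_true(all(!is.na(f$outcome)))
  # accounting: rows equal retained pairs minus drops
  expect_equal(nrow(f), nrow(res$pairs) - attr(f, "n_dropped"))
  # categorical milk bands are exhaustive (band or missing)
  expect_true(all(f$fat_max_t1 %in% c(">0-3%", ">3-5%", ">5%", "missing")))
})

test_that("granddaughter pairing mode attaches the grandmaternal pregnancy", {
  cfg <- sim_config(n_farms = 2, cows_per_farm = 12, seed = 14)
  res <- suppressWarnings(run_pipeline(cfg, mode = "granddaughter",
                                       run_model = FALSE))
  f <- res$features
  expect_gt(nrow(f), 0)
  # ancestor is the granddam: two pedigree steps above the offspring
  cows <- res$cows
  mother <- cows$dam_id[match(f$offspring_id, cows$cow_id)]
  granddam <- cows$dam_id[match(mother, cows$cow_id)]
  expect_equal(f$ancestor_id, granddam)
  # both the mother LRS proxy and the granddam LRS are carried
  expect_true(all(c("mother_lrs", "ancestor_lrs") %in% names(f)))
})
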