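# Simulate a balanced farm/dam/calf hierarchy with known components.
sim_features <- function(n_farms = 10, dams_per_farm = 10, calves_per_dam = 2,
                         beta_thi = 0, sd_farm = 0, sd_dam = 0, sd_e = 100,
                         intercept = 1500, seed = 1) {
  set.seed(seed)
  n <- n_farms * dams_per_farm * calves_per_dam
  farm <- rep(sprintf("F%02d", 1:n_farms), each = dams_per_farm * calves_per_dam)
  dam <- rep(sprintf("D%04d", 1:(n_farms * dams_per_farm)),
             each = calves_per_dam)
  thi <- rnorm(n, 55, 3)
  noise1 <- rnorm(n); noise2 <- rnorm(n)
  f_eff <- rnorm(n_farms, 0, sd_farm)[as.integer(factor(farm))]
  d_eff <- rnorm(n_farms * dams_per_farm, 0, sd_dam)[as.integer(factor(dam))]
  dplyr::tibble(
    farm_id = farm, dam_id = dam, mean_thi_t3 = thi,
    noise1 = noise1, noise2 = noise2,
    outcome = intercept + beta_thi * thi + f_eff + d_eff + rnorm(n, 0, sd_e))
}

test_that("null variance components are estimated near zero and flagged", {
  d <- sim_features(dams_per_farm = 5, calves_per_dam = 4,
                    sd_farm = 0, sd_dam = 0, sd_e = 50, seed = 2)
  fit <- fit_lmm(d, "mean_thi_t3")
  expect_true(fit$converged)
  expect_lt(fit$varcomp[["farm_id"]], 10)   # < 20% of the residual SD
  expect_lt(fit$varcomp[["dam_id"]], 10)
  expect_true(all(fit$varcomp >= 0))
})

test_that("with zero variance components estimates reduce to OLS", {
  d <- sim_features(sd_farm = 0, sd_dam = 0, sd_e = 50, seed = 3)
  fit <- fit_lmm(d, "mean_thi_t3")
  ols <- lm(outcome ~ mean_thi_t3, data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 0.02)
})

test_that("a known fixed effect is recovered with its uncertainty", {
  d <- sim_features(n_farms = 20, dams_per_farm = 25, beta_thi = -5,
                    sd_farm = 142, sd_dam = 81, sd_e = 477, seed = 4)
  fit <- fit_lmm(d, "mean_thi_t3")
  est <- fit$coefficients[fit$coefficients$term == "mean_thi_t3", ]
  expect_lt(est$estimate, 0)
  expect_true(est$lci <= -5 && -5 <= est$uci)
})

test_that("joint Wald tests cover multi-level categorical terms", {
  d <- sim_features(seed = 5, sd_e = 50)
  d$preg <- sample(c("2", "3", "4+"), nrow(d), TRUE)
  d$outcome <- d$outcome + ifelse(d$preg == "4+", -80, 0)
  fit <- fit_lmm(d, "preg")
  w <- wald_term(fit, "preg")
  expect_equal(w$df, 2)
  expect_lt(w$p, 0.01)
  # a term absent from the model has no test
  expect_true(is.na(wald_term(fit, "ghost")$p))
})

test_that("forward selection enters the strong predictor first", {
  sel_first <- vapply(1:10, function(s) {
    d <- sim_features(beta_thi = -8, sd_farm = 30, sd_dam = 30, sd_e = 100,
                      seed = 100 + s)
    sel <- forward_select(d, c("noise1", "mean_thi_t3", "noise2"),
                          max_steps = 1)
    if (length(sel$selected)) sel$selected[1] else NA_character_
  }, character(1))
  expect_gte(mean(sel_first == "mean_thi_t3", na.rm = TRUE), 0.9)
})

test_that("selection respects subgroups, traces decisions deterministically", {
  d <- sim_features(seed = 6, sd_e = 50)
  # yield_min/med/max are one subgroup: correlated copies of one signal
  sig <- rnorm(nrow(d))
  d$yield_min <- sig + rnorm(nrow(d), 0, 0.2)
  d$yield_med <- sig + rnorm(nrow(d), 0, 0.2)
  d$yield_max <- sig + rnorm(nrow(d), 0, 0.2)
  d$outcome <- d$outcome + 40 * sig
  sel <- forward_select(
    d, c("yield_min", "yield_med", "yield_max"),
    groups = list(yield = c("yield_min", "yield_med", "yield_max")))
  expect_equal(length(intersect(sel$selected,
                                c("yield_min", "yield_med", "yield_max"))), 1)
  sel2 <- forward_select(
    d, c("yield_min", "yield_med", "yield_max"),
    groups = list(yield = c("yield_min", "yield_med", "yield_max")))
  expect_identical(sel$trace, sel2$trace)
  expect_true(all(c("step", "candidate", "p", "decision") %in%
                    names(sel$trace)))
})

test_that("empty candidate lists return the intercept-plus-random model", {
  d <- sim_features(seed = 7)
  sel <- forward_select(d, character())
  expect_equal(sel$selected, character())
  expect_true(sel$fit$converged)
  expect_equal(sel$fit$coefficients$term, "(Intercept)")
})

test_that("polynomial terms enter only when supported by the data", {
  d <- sim_features(seed = 8, sd_e = 30)
  x <- d$mean_thi_t3 - 55
  d$outcome <- d$outcome - 8 * x + 3 * x^2
  d$xc <- x
  sel <- forward_select(d, "xc", poly_degree = 3)
  expect_true("xc" %in% sel$selected)
  expect_true("I(xc^2)" %in% sel$selected)
  # degree stops growing once unsupported
  expect_false("I(xc^3)" %in% sel$selected)
})

test_that("variance explained is coherent and recovers known shares", {
  d0 <- sim_features(seed = 9)
  f0 <- fit_lmm(d0, "mean_thi_t3")
  r0 <- variance_explained(f0)
  expect_lt(r0[["marginal"]], 0.02)          # no true fixed effect
  expect_gte(r0[["conditional"]], r0[["marginal"]])

  # known shares: var(fixed) = 25*9 = 225, farm 100^2, dam 0, resid 100^2;
  # the farm-variance estimate carries Monte-Carlo error of order
  # sqrt(2/(n_farms - 1)), hence the loose tolerances
  d1 <- sim_features(n_farms = 40, dams_per_farm = 15, beta_thi = -5,
                     sd_farm = 100, sd_dam = 0, sd_e = 100, seed = 10)
  f1 <- fit_lmm(d1, "mean_thi_t3")
  r1 <- variance_explained(f1)
  tot <- 225 + 100^2 + 100^2
  expect_equal(r1[["marginal"]], 225 / tot, tolerance = 0.35)
  expect_equal(r1[["conditional"]], (225 + 100^2) / tot, tolerance = 0.3)
})

test_that("group cross-validation predicts held-out farms from fixed effects", {
  d <- sim_features(n_farms = 6, dams_per_farm = 8, beta_thi = -5,
                    sd_farm = 50, sd_dam = 30, sd_e = 100, seed = 11)
  cv <- loocv_by_group(d, "mean_thi_t3")
  expect_equal(nrow(cv$fold_rmse), 6)           # fold count = group count
  expect_equal(nrow(cv$predictions), nrow(d))
  expect_true(is.finite(cv$pooled_rmse))
  # null data: pooled RMSE close to the total outcome SD
  dn <- sim_features(n_farms = 6, dams_per_farm = 10, sd_e = 100, seed = 12)
  cvn <- loocv_by_group(dn, character())
  expect_equal(cvn$pooled_rmse, sd(dn$outcome), tolerance = 0.1)
  expect_error(loocv_by_group(d[d$farm_id == "F01", ], "mean_thi_t3"),
               "at least 2")
})

test_that("spearman correlations match a manual rank computation", {
  d <- dplyr::tibble(a = c(3, 1, 4, 1, 5, 9, 2, 6),
                     b = c(2, 7, 1, 8, 2, 8, 1, 8))
  d$rev <- -d$a
  d$same <- d$a
  d$const <- 1
  m <- spearman_matrix(d)
  expect_equal(m["a", "same"], 1)
  expect_equal(m["a", "rev"], -1)
  # manual oracle: Pearson correlation of the ranks
  expect_equal(m["a", "b"],
               cor(rank(d$a), rank(d$b)), tolerance = 1e-12)
  expect_true("const" %in% attr(m, "constant_columns"))
  expect_error(spearman_matrix(d[1:2, ]), "3 rows")
})
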