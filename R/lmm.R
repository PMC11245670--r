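#' Fit a hierarchical linear mixed model by maximum likelihood
#'
#' Outcome on fixed effects with random intercepts at farm and dam level
#' (3-level: calf within dam within farm) or dam level only (2-level).
#' Fitting is by maximum likelihood, so nested fixed structures are
#' comparable during selection. Aliased fixed-effect columns are dropped by
#' the underlying fitter with a warning; a singular fit reports the affected
#' variance component as 0 and is flagged.
#'
#' @param features Feature table (one row per calf).
#' @param fixed Character vector of fixed-effect terms (model-formula
#'   syntax); empty gives the intercept-only model.
#' @param grouping Random-intercept grouping columns, e.g.
#'   `c("farm_id", "dam_id")` or `"dam_id"`.
#' @param outcome Name of the outcome column.
#' @return List of class `lmm_fit`: `model` (the merMod), `coefficients`
#'   (tibble with estimates, Wald 95% CIs and P-values), `varcomp` (named SD
#'   vector including `residual`), `logLik`, `aic`, `singular`, `converged`,
#'   `fixed`, `grouping`, `outcome`, `data`.
#' @export
fit_lmm <- function(features, fixed = character(), grouping = c("farm_id",
                                                                "dam_id"),
                    outcome = "outcome") {
  rhs <- paste(c(if (length(fixed)) fixed else "1",
                 paste0("(1 | ", grouping, ")")), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = features, REML = FALSE))),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(converged = FALSE, fixed = fixed,
                          grouping = grouping, outcome = outcome),
                     class = "lmm_fit"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sds <- stats::setNames(vc$sdcor, ifelse(vc$grp == "Residual", "residual",
                                          vc$grp))
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- b / se
  coefs <- dplyr::tibble(
    term = names(b), estimate = unname(b), se = unname(se),
    lci = unname(b - 1.96 * se), uci = unname(b + 1.96 * se),
    p = unname(2 * stats::pnorm(-abs(z))))
  structure(list(
    model = fit, coefficients = coefs, varcomp = sds,
    logLik = as.numeric(stats::logLik(fit)), aic = stats::AIC(fit),
    singular = lme4::isSingular(fit), converged = TRUE,
    fixed = fixed, grouping = grouping, outcome = outcome,
    data = features), class = "lmm_fit")
}

#' Joint Wald test of one model term
#'
#' Quadratic-form Wald chi-square across all fitted coefficients belonging to
#' the term (one df per coefficient), so multi-level categorical candidates
#' are tested jointly rather than per level.
#'
#' @param fit An `lmm_fit`.
#' @param term The term as given in `fixed`.
#' @return List `statistic`, `df`, `p` (`p = NA` if the term has no
#'   estimable coefficients).
#' @export
wald_term <- function(fit, term) {
  asg <- attr(stats::model.matrix(fit$model), "assign")
  labs <- attr(stats::terms(fit$model), "term.labels")
  k <- match(term, labs)
  idx <- which(asg == k)
  if (is.na(k) || length(idx) == 0)
    return(list(statistic = NA_real_, df = 0L, p = NA_real_))
  b <- lme4::fixef(fit$model)[idx]
  V <- as.matrix(stats::vcov(fit$model))[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  list(statistic = stat, df = length(idx),
       p = stats::pchisq(stat, length(idx), lower.tail = FALSE))
}

#' Forward stepwise selection with Wald entry tests
#'
#' At each step every remaining candidate is added in turn to the current
#' model, its joint Wald P recomputed against the grown model, and the
#' candidate with the smallest P below the entry threshold enters. Candidates
#' may be grouped (e.g. the minimum/median/maximum summaries of one milk
#' variable): at most one member of a group enters, the one with the lowest P
#' on the step where the group first becomes significant. After main-effect
#' entry, polynomial terms (squares then cubes of selected continuous
#' predictors) and declared interactions are tested; an interaction enters
#' only if significant and the AIC decreases. Ties in P are broken by
#' declaration order. The full trace of every decision is returned.
#'
#' @param features Feature table.
#' @param candidates Character vector of candidate terms, in declaration
#'   order.
#' @param groups Optional named list mapping a subgroup name to the member
#'   terms that are mutually exclusive.
#' @param interactions Optional character vector of candidate interaction
#'   terms (tested against the final main-effects model).
#' @param grouping Random-effect structure, as in [fit_lmm()].
#' @param outcome Outcome column.
#' @param threshold Wald entry threshold (default 0.05).
#' @param poly_degree Maximum polynomial degree tested for selected
#'   continuous predictors (default 3).
#' @param max_steps Cap on main-effect entry steps (Inf = run to exhaustion).
#' @return List: `fit` (final `lmm_fit`), `selected`, `trace` (tibble of
#'   step, candidate, P, decision).
#' @export
forward_select <- function(features, candidates, groups = list(),
                           interactions = character(),
                           grouping = c("farm_id", "dam_id"),
                           outcome = "outcome", threshold = 0.05,
                           poly_degree = 3, max_steps = Inf) {
  selected <- character()
  remaining <- candidates
  trace <- list()
  note <- function(step, cand, p, decision)
    trace[[length(trace) + 1]] <<- dplyr::tibble(
      step = step, candidate = cand, p = p, decision = decision)
  group_of <- function(term) {
    hit <- vapply(groups, function(g) term %in% g, logical(1))
    if (any(hit)) names(groups)[which(hit)[1]] else NA_character_
  }

  step <- 0L
  while (length(remaining) > 0 && step < max_steps) {
    step <- step + 1L
    ps <- vapply(remaining, function(cand) {
      f <- fit_lmm(features, c(selected, cand), grouping, outcome)
      if (!f$converged) return(NA_real_)
      wald_term(f, cand)$p
    }, numeric(1))
    ok <- !is.na(ps) & ps < threshold
    if (!any(ok)) {
      for (i in seq_along(remaining))
        note(step, remaining[i], ps[i], "not entered")
      break
    }
    best <- which(ok)[which.min(ps[ok])]
    entered <- remaining[best]
    for (i in seq_along(remaining))
      note(step, remaining[i], ps[i],
           if (i == best) "entered" else "candidate")
    selected <- c(selected, entered)
    g <- group_of(entered)
    drop <- remaining == entered
    if (!is.na(g)) drop <- drop | remaining %in% groups[[g]]
    remaining <- remaining[!drop]
  }

  # polynomial terms for selected continuous predictors
  numeric_sel <- selected[vapply(selected, function(s)
    s %in% names(features) && is.numeric(features[[s]]), logical(1))]
  for (v in if (poly_degree >= 2) numeric_sel else character()) {
    for (d in 2:poly_degree) {
      term <- sprintf("I(%s^%d)", v, d)
      f <- fit_lmm(features, c(selected, term), grouping, outcome)
      p <- if (f$converged) wald_term(f, term)$p else NA_real_
      if (!is.na(p) && p < threshold) {
        selected <- c(selected, term)
        note(step, term, p, "entered (polynomial)")
      } else {
        note(step, term, p, "not entered (polynomial)")
        break
      }
    }
  }

  base_fit <- fit_lmm(features, selected, grouping, outcome)
  for (term in interactions) {
    f <- fit_lmm(features, c(selected, term), grouping, outcome)
    p <- if (f$converged) wald_term(f, term)$p else NA_real_
    if (!is.na(p) && p < threshold && f$aic < base_fit$aic) {
      selected <- c(selected, term)
      base_fit <- f
      note(step, term, p, "entered (interaction, AIC improved)")
    } else {
      note(step, term, p, "not entered (interaction)")
    }
  }

  list(fit = fit_lmm(features, selected, grouping, outcome),
       selected = selected,
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         dplyr::tibble(step = integer(), candidate = character(),
                       p = numeric(), decision = character()))
}

#' Marginal and conditional variance explained of a mixed model
#'
#' Marginal: variance of the fixed-effect predictions over the total
#' (fixed + summed random-intercept variances + residual). Conditional: the
#' fixed plus non-residual random variances over the same total.
#'
#' @param fit An `lmm_fit`.
#' @return Named numeric vector `marginal`, `conditional`.
#' @export
variance_explained <- function(fit) {
  stopifnot(fit$converged)
  pred <- as.vector(stats::model.matrix(fit$model) %*% lme4::fixef(fit$model))
  var_f <- stats::var(pred)
  vcs <- fit$varcomp^2
  var_r <- sum(vcs[names(vcs) != "residual"])
  var_e <- vcs[["residual"]]
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Leave-one-group-out cross-validation of a selected model
#'
#' Refits the selected fixed structure on all but one farm (or trial group)
#' at a time and predicts the held-out rows from fixed effects only (the
#' random effect of an unseen group is its prior mean, 0).
#'
#' @param features Feature table.
#' @param fixed Selected fixed-effect terms.
#' @param group_col Column defining the folds (e.g. `"farm_id"`).
#' @param grouping Random-effect structure for the refits.
#' @param outcome Outcome column.
#' @return List: `predictions` (tibble of group, observed, predicted),
#'   `fold_rmse` (tibble of group, rmse, n), `pooled_rmse`; folds that fail
#'   to converge are flagged and excluded from pooled metrics.
#' @export
loocv_by_group <- function(features, fixed, group_col = "farm_id",
                           grouping = c("farm_id", "dam_id"),
                           outcome = "outcome") {
  groups <- unique(features[[group_col]])
  if (length(groups) < 2) stop("need at least 2 groups for cross-validation")
  preds <- list(); folds <- list()
  for (g in groups) {
    hold <- features[[group_col]] == g
    f <- fit_lmm(features[!hold, , drop = FALSE], fixed, grouping, outcome)
    if (!f$converged) {
      folds[[g]] <- dplyr::tibble(group = g, rmse = NA_real_,
                                  n = sum(hold), converged = FALSE)
      next
    }
    p <- stats::predict(f$model, newdata = features[hold, , drop = FALSE],
                        re.form = NA, allow.new.levels = TRUE)
    obs <- features[[outcome]][hold]
    preds[[g]] <- dplyr::tibble(group = g, observed = obs, predicted = p)
    folds[[g]] <- dplyr::tibble(group = g,
                                rmse = sqrt(mean((obs - p)^2)),
                                n = sum(hold), converged = TRUE)
  }
  preds <- dplyr::bind_rows(preds)
  list(predictions = preds,
       fold_rmse = dplyr::bind_rows(folds),
       pooled_rmse = if (nrow(preds))
         sqrt(mean((preds$observed - preds$predicted)^2)) else NA_real_)
}

#' Spearman rank-correlation matrix of numeric predictors
#'
#' Pairwise-complete rank correlations; constant columns give undefined
#' (`NA`) entries, flagged in the `"constant_columns"` attribute.
#'
#' @param features Feature table (non-numeric columns ignored).
#' @return Correlation matrix.
#' @export
spearman_matrix <- function(features) {
  num <- features[vapply(features, is.numeric, logical(1))]
  if (nrow(num) < 3) stop("need at least 3 rows")
  constant <- names(num)[vapply(num, function(x)
    length(unique(x[!is.na(x)])) <= 1, logical(1))]
  m <- suppressWarnings(stats::cor(as.matrix(num), method = "spearman",
                                   use = "pairwise.complete.obs"))
  structure(m, constant_columns = constant)
}
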