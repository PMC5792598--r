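#' Fit the climate mixed-effects model for a branch-year response
#'
#' Fits `Y = b0 + b1*X1 + b2*X2` with the two climate predictors as fixed
#' effects and, by default, a random intercept and random slopes for the same
#' terms grouped by treatment (independent random-effect variances), so each
#' treatment may express its own climate response around the population-level
#' one. Predictors are standardized (experimental-period mean/SD, pooled over
#' the rows supplied) unless `standardize = FALSE`. Estimation is by maximum
#' likelihood so that AIC comparisons across fixed-effect structures are
#' valid. If the random-slope fit fails to converge the model falls back to a
#' random intercept only and the fit is flagged.
#'
#' @param data branch-year data frame.
#' @param response column name of the response.
#' @param predictors character vector of two predictor column names.
#' @param group grouping column for the random effects (default `"treatment"`).
#' @param standardize standardize predictors before fitting (default TRUE).
#' @param random `"slopes"` (intercept + slopes, independent variances) or
#'   `"intercept"`.
#' @return object of class `lmem_fit`: list with `coefficients` (estimate,
#'   SE, Wald z p-value per fixed effect), `random_sd` (per random term),
#'   `aic`, `r2_marginal`, `r2_conditional`, `scaling` (per-predictor
#'   mean/SD used), `fallback` flag, and the underlying `lme4` `model`.
#' @export
fit_lmem <- function(data, response, predictors, group = "treatment",
                     standardize = TRUE, random = c("slopes", "intercept")) {
  random <- match.arg(random)
  stopifnot(length(predictors) == 2L)
  cols <- c(response, predictors, group)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  if (length(unique(d[[group]])) < 2L) stop("need at least two groups for random effects")
  names(d) <- c(".y", ".x1", ".x2", ".g")
  scaling <- NULL
  if (standardize) {
    s1 <- standardize_series(d$.x1)
    s2 <- standardize_series(d$.x2)
    d$.x1 <- s1$z; d$.x2 <- s2$z
    scaling <- data.frame(predictor = predictors,
                          mean = c(s1$mean, s2$mean), sd = c(s1$sd, s2$sd))
  }
  form <- if (random == "slopes") {
    .y ~ .x1 + .x2 + (1 + .x1 + .x2 || .g)
  } else {
    .y ~ .x1 + .x2 + (1 | .g)
  }
  fallback <- FALSE
  # singular fits are tolerated (three treatment groups make boundary
  # estimates of a random-effect variance routine); only a hard failure
  # triggers the random-intercept-only fallback
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = d, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))),
    error = function(e) e
  )
  if (inherits(fit, "error") && random == "slopes") {
    fallback <- TRUE
    fit <- lme4::lmer(.y ~ .x1 + .x2 + (1 | .g), data = d, REML = FALSE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
  } else if (inherits(fit, "error")) {
    stop("mixed model failed to fit: ", conditionMessage(fit))
  }
  smr <- summary(fit)$coefficients
  est <- smr[, "Estimate"]; se <- smr[, "Std. Error"]
  coefs <- data.frame(
    term = c("(Intercept)", predictors),
    estimate = unname(est), se = unname(se),
    p_value = unname(2 * stats::pnorm(-abs(est / se)))
  )
  vc <- lme4::VarCorr(fit)
  rnd <- do.call(rbind, lapply(seq_along(vc), function(i) {
    data.frame(term = colnames(vc[[i]]), sd = attr(vc[[i]], "stddev"))
  }))
  rnd$term[rnd$term == ".x1"] <- predictors[1]
  rnd$term[rnd$term == ".x2"] <- predictors[2]
  rownames(rnd) <- NULL
  r2 <- r2_marginal_conditional(fit)
  structure(list(
    response = response, predictors = predictors,
    coefficients = coefs, random_sd = rnd,
    aic = stats::AIC(fit),
    r2_marginal = r2[["r2_marginal"]], r2_conditional = r2[["r2_conditional"]],
    scaling = scaling, fallback = fallback, n = nrow(d), model = fit
  ), class = "lmem_fit")
}

#' @export
print.lmem_fit <- function(x, ...) {
  cat(sprintf("mixed model: %s ~ %s + %s (random by group%s), n = %d\n",
              x$response, x$predictors[1], x$predictors[2],
              if (x$fallback) "; intercept-only fallback" else "", x$n))
  print(x$coefficients, digits = 3)
  cat(sprintf("AIC = %.1f, R2(marginal) = %.3f, R2(conditional) = %.3f\n",
              x$aic, x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Marginal and conditional R squared of a mixed model
#'
#' Variance-partition R squared for Gaussian mixed models: the marginal
#' version is the fixed-effect variance over the total (fixed + random +
#' residual), the conditional version adds the random-effect variance to the
#' numerator. The random-effect variance of each term is the average of
#' `z_i' Sigma z_i` over observations, which handles random slopes.
#'
#' @param fit an `lme4` model or an [fit_lmem()] object.
#' @return named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_marginal_conditional <- function(fit) {
  if (inherits(fit, "lmem_fit")) fit <- fit$model
  X <- stats::model.matrix(fit)
  var_fixed <- stats::var(as.vector(X %*% lme4::fixef(fit)))
  fr <- stats::model.frame(fit)
  vc <- lme4::VarCorr(fit)
  var_random <- 0
  for (i in seq_along(vc)) {
    sig <- as.matrix(vc[[i]])
    cn <- colnames(sig)
    Z <- vapply(cn, function(v) {
      if (v == "(Intercept)") rep(1, nrow(fr)) else fr[[v]]
    }, numeric(nrow(fr)))
    Z <- matrix(Z, nrow = nrow(fr))
    var_random <- var_random + mean(rowSums((Z %*% sig) * Z))
  }
  var_resid <- stats::sigma(fit)^2
  tot <- var_fixed + var_random + var_resid
  c(r2_marginal = var_fixed / tot,
    r2_conditional = (var_fixed + var_random) / tot)
}

#' AIC-ranked search over climate predictor pairs
#'
#' Fits the mixed model of [fit_lmem()] for every candidate pair of climate
#' predictors and ranks the fits by AIC. For each pair the model is also
#' compared (likelihood ratio) with its two nested single-predictor
#' submodels, and a collinearity note is raised when the two predictors
#' correlate with `|r| > collinearity_limit` (high-VPD day counts and
#' monsoon precipitation are strongly anti-correlated at the site).
#'
#' @inheritParams fit_lmem
#' @param candidates list of length-2 character vectors; by default all
#'   unordered pairs of the four seasonal predictors (two precipitation
#'   windows, two VPD-exceedance windows).
#' @param collinearity_limit absolute correlation that triggers a note.
#' @param lrt compute the nested likelihood-ratio comparisons (default TRUE;
#'   disable in large simulation loops).
#' @return data frame ranked by AIC, one row per candidate pair, with
#'   `delta_aic`, `r2_marginal`, `r2_conditional`, likelihood-ratio p-values
#'   for dropping each term, the predictor correlation, and a `collinear`
#'   flag; the fitted models are attached as attribute `fits`.
#' @export
model_search <- function(data, response,
                         candidates = NULL, group = "treatment",
                         collinearity_limit = 0.8, lrt = TRUE) {
  if (is.null(candidates)) {
    preds <- c("ppt_premonsoon", "ppt_monsoon", "vpd_days_dry", "vpd_days_monsoon")
    preds <- intersect(preds, names(data))
    if (length(preds) < 2L) stop("no default candidate predictors found in data")
    candidates <- utils::combn(preds, 2, simplify = FALSE)
  }
  if (length(candidates) == 1L && !is.list(candidates)) candidates <- list(candidates)
  fits <- lapply(candidates, function(pr) fit_lmem(data, response, pr, group = group))
  rows <- mapply(function(pr, f) {
    d <- data[stats::complete.cases(data[c(response, pr, group)]), , drop = FALSE]
    r <- stats::cor(d[[pr[1]]], d[[pr[2]]])
    # LRT against each single-predictor submodel (same ML criterion)
    lrt_p <- if (!lrt) c(NA_real_, NA_real_) else vapply(1:2, function(k) {
      sub <- tryCatch(
        lme4::lmer(stats::reformulate(c(pr[-k], sprintf("(1 + %s || %s)", pr[-k], group)),
                                      response),
                   data = d, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")),
        error = function(e) NULL)
      if (is.null(sub)) return(NA_real_)
      stats::anova(sub, f$model)[2, "Pr(>Chisq)"]
    }, numeric(1))
    data.frame(predictor1 = pr[1], predictor2 = pr[2],
               aic = f$aic, r2_marginal = f$r2_marginal,
               r2_conditional = f$r2_conditional,
               lrt_p_drop1 = lrt_p[1], lrt_p_drop2 = lrt_p[2],
               predictor_cor = r,
               collinear = abs(r) > collinearity_limit)
  }, candidates, fits, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  ord <- order(out$aic)
  out <- out[ord, , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  attr(out, "fits") <- fits[ord]
  if (any(out$collinear)) {
    message("collinear predictor pair(s) flagged (|r| > ", collinearity_limit, ")")
  }
  out
}

#' Bootstrap comparison of per-treatment climate slopes
#'
#' Resamples branches (with replacement, within treatment), refits the
#' per-treatment linear response `Y ~ X1 + X2` on each resample, and compares
#' the chosen coefficient between treatments: for each treatment pair the
#' percentile position of zero in the bootstrap difference distribution gives
#' a two-sided p-value. A hypothesized ordering of treatments is "confirmed"
#' when the point estimates are ordered accordingly and every adjacent pair
#' differs significantly at `1 - conf`.
#'
#' @param data branch-year data with columns `branch_id`, `treatment`, the
#'   response and the predictors.
#' @param response,predictors model columns (one or two predictors).
#' @param coef which predictor's coefficient to compare (default the first).
#' @param ordering optional character vector of treatment levels hypothesized
#'   in increasing order of the coefficient.
#' @param b bootstrap replicates per treatment.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return list with `slopes` (per treatment), `pairs` (data frame of
#'   pairwise differences, CIs, p-values), and `ordering_confirmed` (logical,
#'   `NA` when no ordering supplied).
#' @export
bootstrap_coef_between_treatments <- function(data, response, predictors,
                                              coef = predictors[1],
                                              ordering = NULL,
                                              b = 2000L, seed = NULL, conf = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(coef %in% predictors)
  cols <- c("branch_id", "treatment", response, predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  form <- stats::reformulate(predictors, response)
  fit_coef <- function(dd) {
    cf <- tryCatch(stats::coef(stats::lm(form, data = dd)), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(NA_real_)
    unname(cf[coef])
  }
  treatments <- unique(as.character(d$treatment))
  point <- vapply(treatments, function(tr) fit_coef(d[d$treatment == tr, ]), numeric(1))
  boots <- lapply(treatments, function(tr) {
    dt <- d[d$treatment == tr, , drop = FALSE]
    br <- unique(dt$branch_id)
    if (length(br) < 2L) stop("treatment ", tr, " has fewer than 2 branches")
    idx_by_branch <- split(seq_len(nrow(dt)), dt$branch_id)
    vapply(seq_len(b), function(i) {
      repeat {
        take <- sample(br, length(br), replace = TRUE)
        dd <- dt[unlist(idx_by_branch[take], use.names = FALSE), , drop = FALSE]
        v <- fit_coef(dd)
        if (!is.na(v)) return(v)
      }
    }, numeric(1))
  })
  names(boots) <- treatments
  pairs <- utils::combn(treatments, 2, simplify = FALSE)
  pair_rows <- lapply(pairs, function(pr) {
    diffs <- boots[[pr[2]]] - boots[[pr[1]]]
    qs <- stats::quantile(diffs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    p <- 2 * min((sum(diffs <= 0) + 1) / (b + 1), (sum(diffs >= 0) + 1) / (b + 1))
    data.frame(lower = pr[1], higher = pr[2],
               diff = point[pr[2]] - point[pr[1]],
               ci_lower = qs[1], ci_upper = qs[2],
               p_value = min(p, 1), significant = qs[1] > 0 | qs[2] < 0)
  })
  pair_df <- do.call(rbind, pair_rows)
  confirmed <- NA
  if (!is.null(ordering)) {
    stopifnot(all(ordering %in% treatments), length(ordering) == length(treatments))
    pts <- point[ordering]
    monotone <- all(diff(pts) > 0)
    adjacent_sig <- vapply(seq_len(length(ordering) - 1L), function(i) {
      a <- ordering[i]; b2 <- ordering[i + 1]
      row <- pair_df[(pair_df$lower == a & pair_df$higher == b2) |
                       (pair_df$lower == b2 & pair_df$higher == a), ]
      isTRUE(row$significant[1])
    }, logical(1))
    confirmed <- monotone && all(adjacent_sig)
  }
  list(slopes = point, pairs = pair_df, ordering_confirmed = confirmed)
}
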