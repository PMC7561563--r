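#' Fit a functional-group trajectory model
#'
#' Fits the per-group succession model: response ~ time * environment with a
#' landscape random intercept and a trap random intercept nested in landscape.
#' Species richness and abundance are modelled with a negative binomial
#' (NB2, variance = mu + mu^2/theta) error distribution to absorb aggregated
#' counts; gain and loss rates (`Gp`, `Lp`) with Gaussian errors. Time is
#' categorical: years 1..T for counts, intervals 1..T-1 for rates. All models
#' are fitted by maximum likelihood (Laplace approximation for the NB family)
#' so that likelihood-ratio tests between nested fits are valid.
#'
#' With only two landscapes the landscape variance component is weakly
#' identified and routinely collapses to zero. The fitter first attempts the
#' full random structure and falls back to landscape as a fixed effect (trap
#' intercept retained) when the landscape variance is degenerate or the fit
#' does not converge; the structure actually used is recorded in the result
#' and reported by `print()`.
#'
#' @param series a `group_series` (richness/abundance) or `turnover`
#'   (`Gp`/`Lp`) table. Records with undefined rates are dropped listwise.
#' @param sites a [site_table()] supplying environment and landscape per trap.
#' @param response one of `"richness"`, `"abundance"`, `"Gp"`, `"Lp"`.
#' @param random random-effect policy: `"auto"` (try full structure, fall
#'   back), `"landscape_random"` (force full structure), `"landscape_fixed"`
#'   (landscape fixed + trap intercept), `"none"` (fixed effects only).
#' @return an object of class `trajectory_fit` with components `model`
#'   (the glmmTMB fit), `data`, `response`, `family`, `random_structure`,
#'   `time_levels`. Methods: `print`, `summary`, `predict`, `residuals`,
#'   `logLik`, `plot`.
#' @seealso [interaction_lrt()], [within_time_contrasts()],
#'   [residual_time_diagnostics()]
#' @export
fit_trajectory <- function(series, sites,
                           response = c("richness", "abundance", "Gp", "Lp"),
                           random = c("auto", "landscape_random",
                                      "landscape_fixed", "none")) {
  response <- match.arg(response)
  random <- match.arg(random)
  if (!response %in% names(series))
    stop("response '", response, "' not found in the series")
  family <- if (response %in% c("richness", "abundance")) "nbinom2" else "gaussian"
  time_col <- if ("year" %in% names(series)) "year" else "t1"
  df <- data.frame(
    trap = series$trap,
    time = factor(series[[time_col]]),
    y = series[[response]]
  )
  df$environment <- factor(sites$environment[match(df$trap, sites$trap)],
                           levels = c("shaded", "exposed"))
  df$landscape <- factor(sites$landscape[match(df$trap, sites$trap)])
  if (anyNA(df$environment) || anyNA(df$landscape))
    stop("trap(s) missing from the site table: ",
         paste(utils::head(setdiff(df$trap, sites$trap), 5), collapse = ", "))
  df <- df[!is.na(df$y), ]
  if (nlevels(droplevels(df$time)) < 2) stop("need at least 2 time levels")
  if (nlevels(droplevels(df$environment)) < 2)
    stop("both environments must be present")
  df$time <- droplevels(df$time)

  if (family == "gaussian" && stats::var(df$y) < 1e-12) {
    # constant response: the mixed model is degenerate (zero residual
    # variance); an ordinary least-squares fit carries the same (flat)
    # mean structure
    model <- stats::lm(y ~ time * environment, data = df)
    message("constant response; returning a degenerate fixed-effects fit")
    return(structure(list(model = model, data = df, response = response,
                          family = family, random_structure = "none",
                          formula = y ~ time * environment,
                          time_levels = levels(df$time),
                          group = attr(series, "group")),
                     class = "trajectory_fit"))
  }
  order_try <- switch(random,
    auto = c("landscape_random", "landscape_fixed", "none"),
    landscape_random = "landscape_random",
    landscape_fixed = c("landscape_fixed", "none"),
    none = "none")
  try_ladder <- function(fam) {
    collapsed <- NULL
    for (nm in order_try) {
      m <- fit_traj_model(df, fam, nm)
      if (is.null(m)) next
      if (nm == "landscape_random" && random == "auto" &&
          !traj_ls_var_ok(m)) {
        collapsed <- list(model = m, used = nm) # keep as last resort
        next
      }
      return(list(model = m, used = nm))
    }
    collapsed
  }
  family_used <- family
  fit <- try_ladder(family)
  if (is.null(fit) && family == "nbinom2") {
    # dispersion at the boundary (theta -> Inf): the NB2 likelihood's
    # supremum is the Poisson one, so fit the limit explicitly
    fit <- try_ladder("poisson")
    if (!is.null(fit)) {
      family_used <- "poisson"
      message("NB dispersion at its Poisson boundary; fitted the ",
              "Poisson limit")
    }
  }
  if (is.null(fit))
    stop("trajectory model failed to converge for response '", response,
         "' even after random-effect fallback")
  if (random == "auto" && fit$used != "landscape_random")
    message("landscape random intercept degenerate; using structure '",
            fit$used, "'")
  structure(list(model = fit$model, data = df, response = response,
                 family = family, family_used = family_used,
                 random_structure = fit$used,
                 formula = traj_formula(fit$used),
                 time_levels = levels(df$time),
                 group = attr(series, "group")),
            class = "trajectory_fit")
}

traj_formula <- function(structure, interaction = TRUE) {
  fixed <- if (interaction) "y ~ time * environment" else "y ~ time + environment"
  rhs <- switch(structure,
    landscape_random = "+ (1 | landscape) + (1 | trap)",
    landscape_fixed = "+ landscape + (1 | trap)",
    none = "")
  stats::as.formula(paste(fixed, rhs), env = globalenv())
}

# fit one candidate structure; NULL unless cleanly converged
fit_traj_model <- function(df, family, structure, interaction = TRUE) {
  fam <- switch(family,
                nbinom2 = glmmTMB::nbinom2(),
                poisson = stats::poisson(),
                gaussian = stats::gaussian())
  m <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(traj_formula(structure, interaction),
                                      data = df, family = fam, REML = FALSE)),
    error = function(e) NULL)
  ok <- !is.null(m) && isTRUE(m$sdr$pdHess) && all(is.finite(m$fit$par)) &&
    is.finite(stats::logLik(m))
  if (ok) {
    v <- tryCatch(stats::vcov(m)$cond, error = function(e) NULL)
    ok <- !is.null(v) && all(is.finite(diag(v)))
  }
  if (ok) m else NULL
}

traj_ls_var_ok <- function(m) {
  vc <- glmmTMB::VarCorr(m)$cond
  if (!"landscape" %in% names(vc)) return(TRUE)
  as.numeric(vc$landscape) > 1e-6
}

model_beta <- function(fit) {
  if (inherits(fit$model, "glmmTMB")) glmmTMB::fixef(fit$model)$cond
  else stats::coef(fit$model)
}

model_vcov <- function(fit) {
  if (inherits(fit$model, "glmmTMB")) stats::vcov(fit$model)$cond
  else suppressWarnings(stats::vcov(fit$model)) # perfect-fit lm warns
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("Trajectory model:", x$response,
      if (!is.null(x$group)) paste0("(group ", x$group, ")"), "\n")
  cat("Family:", x$family, " |  random structure:", x$random_structure, "\n")
  cat("Fixed effects (link scale):\n")
  print(round(model_beta(x), 4))
  invisible(x)
}

#' @export
summary.trajectory_fit <- function(object, ...) summary(object$model)

#' @export
logLik.trajectory_fit <- function(object, ...) stats::logLik(object$model)

#' @export
residuals.trajectory_fit <- function(object, type = "pearson", ...) {
  stats::residuals(object$model, type = type)
}

cell_grid <- function(fit) {
  expand.grid(time = factor(fit$time_levels, levels = fit$time_levels),
              environment = factor(c("shaded", "exposed"),
                                   levels = c("shaded", "exposed")),
              KEEP.OUT.ATTRS = FALSE)
}

#' Cell predictions on the response scale
#'
#' Population-level predictions (random effects set to zero; for fits with a
#' fixed landscape term, averaged over landscapes) for every time x
#' environment combination, with Wald 95% confidence intervals back-
#' transformed from the link scale.
#'
#' @param object a `trajectory_fit`.
#' @param level confidence level.
#' @param ... unused.
#' @return data frame: time, environment, fit, se_link, lwr, upr.
#' @export
predict.trajectory_fit <- function(object, level = 0.95, ...) {
  grid <- cell_grid(object)
  beta <- model_beta(object)
  V <- model_vcov(object)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    if (object$random_structure == "landscape_fixed") {
      ls_lv <- levels(object$data$landscape)
      # population-level cell mean: average the linear predictor over
      # landscapes
      Ls <- lapply(ls_lv, function(l)
        fixed_design_row(object, grid$time[i], grid$environment[i], l))
      Reduce(`+`, Ls) / length(Ls)
    } else {
      fixed_design_row(object, grid$time[i], grid$environment[i])
    }
  })
  L <- do.call(rbind, rows)
  eta <- as.numeric(L %*% beta)
  se <- sqrt(pmax(0, rowSums((L %*% V) * L)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  inv <- if (object$family == "nbinom2") exp else identity
  out <- cell_grid(object)
  out$fit <- inv(eta)
  out$se_link <- se
  out$lwr <- inv(eta - z * se)
  out$upr <- inv(eta + z * se)
  out
}

fixed_design_row <- function(fit, time, environment, landscape = NULL) {
  nd <- data.frame(
    time = factor(time, levels = fit$time_levels),
    environment = factor(environment, levels = c("shaded", "exposed"))
  )
  ff <- y ~ time * environment
  if (fit$random_structure == "landscape_fixed") {
    ls_lv <- levels(fit$data$landscape)
    nd$landscape <- factor(if (is.null(landscape)) ls_lv[1] else landscape,
                           levels = ls_lv)
    ff <- y ~ time * environment + landscape
  }
  nd$y <- 0
  stats::model.matrix(ff, nd)
}

#' Likelihood-ratio test for the time x environment interaction
#'
#' Refits the model without the interaction term (same error family and
#' random structure) and compares by likelihood ratio:
#' chi2 = 2(logLik_full - logLik_reduced), clipped at zero, with df equal to
#' the difference in fixed-effect counts ((T-1)(E-1) for the factorial
#' design). A precomputed reduced fit may be supplied; it must nest in the
#' full fit.
#'
#' @param full a `trajectory_fit` containing the interaction.
#' @param reduced optional `trajectory_fit` without the interaction.
#' @return list with `chi2`, `df`, `p`, and the reduced model's log-likelihood.
#' @export
interaction_lrt <- function(full, reduced = NULL) {
  ll_full <- as.numeric(stats::logLik(full$model))
  k_full <- attr(stats::logLik(full$model), "df")
  if (is.null(reduced)) {
    # both halves of the comparison must share one random structure; walk
    # down the ladder until a structure fits both cleanly
    ladder <- unique(c(full$random_structure, "landscape_fixed", "none"))
    fam_used <- if (is.null(full$family_used)) full$family else full$family_used
    try_pair <- function(fam) {
      for (s in ladder) {
        red_m <- fit_traj_model(full$data, fam, s, interaction = FALSE)
        if (is.null(red_m)) next
        full_m <- if (s == full$random_structure && fam == fam_used)
                    full$model
                  else fit_traj_model(full$data, fam, s)
        if (is.null(full_m)) next
        if (s != full$random_structure || fam != fam_used)
          message("interaction test refitted both models (family ", fam,
                  ", structure '", s, "')")
        return(list(full = full_m, red = red_m))
      }
      NULL
    }
    pair <- try_pair(fam_used)
    # NB dispersion at its Poisson boundary in either half: use the limit
    if (is.null(pair) && fam_used == "nbinom2") pair <- try_pair("poisson")
    if (is.null(pair))
      stop("reduced model failed to converge under any random structure")
    ll_full <- as.numeric(stats::logLik(pair$full))
    k_full <- attr(stats::logLik(pair$full), "df")
    ll_red <- as.numeric(stats::logLik(pair$red))
    k_red <- attr(stats::logLik(pair$red), "df")
  } else {
    nf <- names(glmmTMB::fixef(full$model)$cond)
    nr <- names(glmmTMB::fixef(reduced$model)$cond)
    if (!all(nr %in% nf) || length(nr) >= length(nf))
      stop("reduced model does not nest in the full model")
    ll_red <- as.numeric(stats::logLik(reduced$model))
    k_red <- attr(stats::logLik(reduced$model), "df")
  }
  df <- k_full - k_red
  if (df <= 0) stop("models are not nested with positive df difference")
  chi2 <- max(0, 2 * (ll_full - ll_red))
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       logLik_full = ll_full, logLik_reduced = ll_red)
}

#' Exposed-vs-shaded Wald contrasts within each time level
#'
#' For every year (or interval) computes the exposed minus shaded difference
#' of linear predictors as a Wald z test from the fixed-effect covariance
#' matrix, unadjusted for multiplicity (optionally Bonferroni/Holm adjusted).
#' The contrast is built from model-matrix rows, so it is invariant to the
#' factor coding.
#'
#' @param fit a `trajectory_fit` with the full interaction.
#' @param adjust p-value adjustment passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return data frame: time, estimate (link scale), se, z, p.
#' @export
within_time_contrasts <- function(fit, adjust = "none") {
  beta <- model_beta(fit)
  V <- model_vcov(fit)
  res <- lapply(fit$time_levels, function(tl) {
    L <- fixed_design_row(fit, tl, "exposed") -
         fixed_design_row(fit, tl, "shaded")
    est <- as.numeric(L %*% beta)
    se <- sqrt(as.numeric(L %*% V %*% t(L)))
    c(estimate = est, se = se)
  })
  out <- data.frame(time = fit$time_levels, do.call(rbind, res))
  out$z <- out$estimate / out$se
  out$p <- stats::p.adjust(2 * stats::pnorm(-abs(out$z)), method = adjust)
  out
}

#' Specialist-vs-generalist early-succession model
#'
#' Tests whether host-tree specialists accumulate species or individuals
#' faster than generalists at the start of the succession. Fits a negative
#' binomial mixed model on years 1-2 only, with year, environment and
#' functional group (and all interactions) as fixed effects and a trap random
#' intercept (landscape handled per the usual fallback policy). Reports the
#' Wald test of the environment x year x group three-way interaction
#' (computed as a coding-invariant double difference of cell linear
#' predictors) and each group's predicted year-2 / year-1 fold change
#' (averaged over environments on the link scale).
#'
#' @param series_specialist,series_generalist `group_series` tables for the
#'   two host-affinity groups.
#' @param sites a [site_table()].
#' @param response `"richness"` or `"abundance"`.
#' @param years the two successional years to compare (default 1 and 2).
#' @return list with `three_way` (estimate, se, z, p), `fold_changes`
#'   (named numeric: specialist, generalist), and the underlying `model`.
#' @export
specialist_generalist_model <- function(series_specialist, series_generalist,
                                        sites,
                                        response = c("richness", "abundance"),
                                        years = c(1, 2)) {
  response <- match.arg(response)
  mk <- function(s, g) {
    d <- data.frame(trap = s$trap, year = s$year, y = s[[response]], group = g)
    d[d$year %in% years, ]
  }
  df <- rbind(mk(series_specialist, "specialist"),
              mk(series_generalist, "generalist"))
  df$group <- factor(df$group, levels = c("generalist", "specialist"))
  df$year <- factor(df$year, levels = years)
  df$environment <- factor(sites$environment[match(df$trap, sites$trap)],
                           levels = c("shaded", "exposed"))
  df$landscape <- factor(sites$landscape[match(df$trap, sites$trap)])
  for (v in c("group", "year", "environment"))
    if (nlevels(droplevels(df[[v]])) < 2)
      stop("both levels of '", v, "' must be present in years ",
           paste(years, collapse = "-"))
  fit1 <- function(form, fam) {
    m <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(form, data = df, family = fam,
                                        REML = FALSE)),
      error = function(e) NULL)
    if (is.null(m) || !isTRUE(m$sdr$pdHess) ||
        !is.finite(stats::logLik(m))) return(NULL)
    v <- tryCatch(stats::vcov(m)$cond, error = function(e) NULL)
    if (is.null(v) || !all(is.finite(diag(v)))) return(NULL)
    m
  }
  form_r <- y ~ year * environment * group + (1 | landscape) + (1 | trap)
  form_f <- y ~ year * environment * group + landscape + (1 | trap)
  model <- NULL
  for (fam in list(glmmTMB::nbinom2(), stats::poisson())) {
    m <- fit1(form_r, fam)
    if (!is.null(m) &&
        as.numeric(glmmTMB::VarCorr(m)$cond$landscape) > 1e-6) {
      model <- m; has_ls_fixed <- FALSE; break
    }
    collapsed <- m
    m <- fit1(form_f, fam)
    if (!is.null(m)) { model <- m; has_ls_fixed <- TRUE; break }
    if (!is.null(collapsed)) { # landscape variance ~0 but fit is sound
      model <- collapsed; has_ls_fixed <- FALSE; break
    }
  }
  if (is.null(model))
    stop("specialist/generalist model failed to converge")

  beta <- glmmTMB::fixef(model)$cond
  V <- stats::vcov(model)$cond
  ff <- if (has_ls_fixed) y ~ year * environment * group + landscape
        else y ~ year * environment * group
  row <- function(yr, env, grp) {
    nd <- data.frame(
      year = factor(yr, levels = years),
      environment = factor(env, levels = c("shaded", "exposed")),
      group = factor(grp, levels = c("generalist", "specialist")),
      y = 0)
    if (has_ls_fixed)
      nd$landscape <- factor(levels(df$landscape)[1],
                             levels = levels(df$landscape))
    stats::model.matrix(ff, nd)
  }
  # double difference: [growth(exposed) - growth(shaded)] specialist - generalist
  dd <- function(grp) {
    (row(years[2], "exposed", grp) - row(years[1], "exposed", grp)) -
      (row(years[2], "shaded", grp) - row(years[1], "shaded", grp))
  }
  L <- dd("specialist") - dd("generalist")
  est <- drop(L %*% beta)
  se <- sqrt(drop(L %*% V %*% t(L)))
  three_way <- data.frame(estimate = est, se = se, z = est / se,
                          p = 2 * stats::pnorm(-abs(est / se)))
  fold <- function(grp) {
    d_eta <- mean(vapply(c("shaded", "exposed"), function(env) {
      drop((row(years[2], env, grp) - row(years[1], env, grp)) %*% beta)
    }, 0))
    exp(d_eta)
  }
  list(three_way = three_way,
       fold_changes = c(specialist = fold("specialist"),
                        generalist = fold("generalist")),
       model = model)
}

#' Residual-versus-time diagnostics
#'
#' Temporal autocorrelation in repeated measurements on the same traps would
#' violate the model's independence assumption. This returns the Pearson
#' residuals ordered by time within each trap, each trap's lag-1 residual
#' autocorrelation, and a distribution summary, mirroring the residual-vs-time
#' inspection used to verify that the categorical time effect absorbs the
#' temporal structure.
#'
#' @param fit a `trajectory_fit` over at least 3 time points.
#' @return list with `residuals` (trap, time, residual), `lag1` (named vector
#'   of per-trap lag-1 correlations), and `mean_lag1`.
#' @export
residual_time_diagnostics <- function(fit) {
  if (length(fit$time_levels) < 3)
    stop("residual-vs-time diagnostics need at least 3 time points")
  df <- fit$data
  df$residual <- stats::residuals(fit$model, type = "pearson")
  df <- df[order(df$trap, as.integer(as.character(df$time))), ]
  # acf-style estimator (no within-trap re-centering: residuals are already
  # centred by the model, and re-centering short series biases the estimate
  # toward -1/(T-1))
  lag1 <- vapply(split(df$residual, df$trap), function(r) {
    if (length(r) < 3 || sum(r^2) == 0) return(NA_real_)
    n <- length(r)
    sum(r[-n] * r[-1]) / sum(r^2)
  }, 0)
  list(residuals = df[, c("trap", "time", "residual")],
       lag1 = lag1,
       mean_lag1 = mean(lag1, na.rm = TRUE))
}

#' Plot observed and predicted trajectories
#'
#' Predicted cell means with 95% confidence bars for each environment,
#' with the observed per-trap values as small jittered points.
#'
#' @param x a `trajectory_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trajectory_fit <- function(x, ...) {
  pr <- stats::predict(x)
  obs <- x$data
  tnum <- as.integer(factor(obs$time, levels = x$time_levels))
  off <- ifelse(obs$environment == "exposed", -0.12, 0.12)
  graphics::plot(tnum + off + stats::runif(length(tnum), -0.04, 0.04), obs$y,
                 pch = ifelse(obs$environment == "exposed", 1, 16),
                 col = "grey60", cex = 0.6, xaxt = "n",
                 xlab = if (x$response %in% c("Gp", "Lp")) "interval" else "year",
                 ylab = x$response, ...)
  graphics::axis(1, at = seq_along(x$time_levels), labels = x$time_levels)
  ptn <- as.integer(factor(pr$time, levels = x$time_levels))
  poff <- ifelse(pr$environment == "exposed", -0.12, 0.12)
  graphics::arrows(ptn + poff, pr$lwr, ptn + poff, pr$upr,
                   angle = 90, code = 3, length = 0.04)
  graphics::points(ptn + poff, pr$fit, cex = 1.6,
                   pch = ifelse(pr$environment == "exposed", 24, 21),
                   bg = ifelse(pr$environment == "exposed", "white", "grey40"))
  invisible(pr)
}
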