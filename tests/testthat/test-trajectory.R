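# simulate a balanced two-landscape NB count design with known cell means
sim_nb_series <- function(cell_means, n_per_env = 30, theta = 5, seed = 1) {
  set.seed(seed)
  T_ <- ncol(cell_means)
  sites <- site_table(
    trap = sprintf("t%03d", seq_len(2 * n_per_env)),
    environment = rep(c("exposed", "shaded"), each = n_per_env),
    landscape = rep(c("A", "B"), times = n_per_env)
  )
  df <- expand.grid(trap = sites$trap, year = seq_len(T_),
                    stringsAsFactors = FALSE)
  env <- sites$environment[match(df$trap, sites$trap)]
  mu <- cell_means[cbind(match(env, rownames(cell_means)), df$year)]
  df$richness <- stats::rnbinom(nrow(df), mu = mu, size = theta)
  df$abundance <- df$richness
  series <- structure(df, group = "all", class = c("group_series", "data.frame"))
  list(series = series, sites = sites)
}

test_that("NB trajectory fit recovers simulated cell means within 15%", {
  cm <- rbind(exposed = c(2, 8, 8, 8), shaded = c(2, 4, 6, 8))
  # average the recovered cell means over replicate simulations so the
  # check tests bias, not single-draw sampling noise
  prs <- lapply(1:5, function(r) {
    s <- sim_nb_series(cm, n_per_env = 30, theta = 5, seed = 42 + r)
    predict(quiet_fit(s$series, s$sites, "richness"))
  })
  pr <- prs[[1]]
  fit_avg <- rowMeans(sapply(prs, `[[`, "fit"))
  truth <- cm[cbind(match(as.character(pr$environment), rownames(cm)),
                    as.integer(as.character(pr$time)))]
  expect_true(all(abs(fit_avg - truth) / truth < 0.15))
  expect_true(all(pr$lwr <= pr$fit & pr$fit <= pr$upr))
  expect_true(all(pr$lwr > 0)) # count family: positive predictions
})

test_that("interaction LRT has df (T-1)(E-1) and detects a strong interaction", {
  cm <- rbind(exposed = c(2, 8, 8, 8), shaded = c(2, 4, 6, 8))
  s <- sim_nb_series(cm, n_per_env = 30, theta = 5, seed = 7)
  fit <- quiet_fit(s$series, s$sites, "richness")
  lrt <- interaction_lrt(fit)
  expect_equal(lrt$df, 3L)
  expect_lt(lrt$p, 0.01)
  expect_gte(lrt$chi2, 0)
})

test_that("null interaction LRT p-values are roughly uniform", {
  # identical means in every cell; moderate replicate count keeps the
  # Kolmogorov-Smirnov check affordable
  cm <- rbind(exposed = c(5, 5, 5, 5), shaded = c(5, 5, 5, 5))
  ps <- vapply(1:40, function(r) {
    s <- sim_nb_series(cm, n_per_env = 15, theta = 5, seed = 1000 + r)
    fit <- quiet_fit(s$series, s$sites, "richness", random = "none")
    interaction_lrt(fit)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(ps > 0.05), 0.7)
})

test_that("a constant Gaussian response gives flat predictions and null contrasts", {
  s <- sim_nb_series(rbind(exposed = c(2, 2, 2), shaded = c(2, 2, 2)),
                     n_per_env = 10, seed = 3)
  s$series$Gp <- 0.7
  s$series$t1 <- s$series$year
  to <- s$series[, c("trap", "t1", "Gp")]
  to$group <- "all"
  fit <- quiet_fit(to, s$sites, "Gp", random = "none")
  pr <- predict(fit)
  expect_equal(pr$fit, rep(0.7, nrow(pr)), tolerance = 1e-6)
  ct <- within_time_contrasts(fit)
  expect_equal(ct$estimate, rep(0, nrow(ct)), tolerance = 1e-6)
})

test_that("single-environment data violate the fit precondition", {
  cm <- rbind(exposed = c(2, 4, 6), shaded = c(2, 4, 6))
  s <- sim_nb_series(cm, n_per_env = 8, seed = 5)
  keep <- s$sites$environment == "exposed"
  sites1 <- site_table(s$sites$trap[keep], s$sites$environment[keep],
                       s$sites$landscape[keep])
  ser1 <- s$series[s$series$trap %in% sites1$trap, ]
  expect_error(quiet_fit(ser1, sites1, "richness"), "environment")
})

test_that("undefined turnover rates are excluded listwise from rate models", {
  set.seed(11)
  st <- simulate_study(sim_params(n_traps_per_env_per_landscape = 5), seed = 21)
  asp <- filter_aspen(st$community, st$traits)
  to <- turnover_rates(asp, st$traits, "specialist")
  fit <- quiet_fit(to, st$sites, "Gp", random = "none")
  expect_equal(nrow(fit$data), sum(!is.na(to$Gp)))
})

test_that("within-time contrasts localise a cell-mean difference", {
  # equal means at year 1 only; later years differ
  cm <- rbind(exposed = c(3, 9, 9), shaded = c(3, 3, 3))
  s <- sim_nb_series(cm, n_per_env = 40, theta = 10, seed = 13)
  fit <- quiet_fit(s$series, s$sites, "richness")
  ct <- within_time_contrasts(fit)
  expect_lt(abs(ct$estimate[ct$time == "1"]), 0.25)      # centred at 0
  expect_gt(ct$estimate[ct$time == "2"], log(2))         # ~log(3) off 0
  expect_true(all(ct$p > 0 & ct$p <= 1))
  expect_equal(ct$z, ct$estimate / ct$se)
})

test_that("contrasts agree with the multcomp reference on a glm fit", {
  skip_if_not_installed("multcomp")
  cm <- rbind(exposed = c(2, 8, 8, 8), shaded = c(2, 4, 6, 8))
  s <- sim_nb_series(cm, n_per_env = 20, theta = 5, seed = 17)
  fit <- quiet_fit(s$series, s$sites, "richness", random = "none")
  ct <- within_time_contrasts(fit)
  # the same Wald contrast, assembled independently through multcomp::glht
  beta <- glmmTMB::fixef(fit$model)$cond
  K <- matrix(0, 1, length(beta), dimnames = list(NULL, names(beta)))
  K[, "environmentexposed"] <- 1
  K[, "time3:environmentexposed"] <- 1
  g <- multcomp::glht(fit$model, linfct = K,
                      coef. = function(m) glmmTMB::fixef(m)$cond,
                      vcov. = function(m) stats::vcov(m)$cond)
  sg <- summary(g, test = multcomp::adjusted("none"))
  expect_equal(ct$estimate[ct$time == "3"],
               unname(sg$test$coefficients), tolerance = 1e-8)
  expect_equal(ct$se[ct$time == "3"], unname(sg$test$sigma),
               tolerance = 1e-8)
})

test_that("NB predictions approach a Poisson fit on equidispersed data", {
  set.seed(19)
  s <- sim_nb_series(rbind(exposed = c(4, 7, 5, 6), shaded = c(3, 5, 6, 4)),
                     n_per_env = 25, theta = 1e8, seed = 19) # Poisson limit
  fit <- quiet_fit(s$series, s$sites, "richness", random = "none")
  pois <- stats::glm(y ~ time * environment, data = fit$data,
                     family = stats::poisson())
  nd <- expand.grid(time = factor(1:4), environment = factor(
    c("shaded", "exposed"), levels = c("shaded", "exposed")))
  pp <- stats::predict(pois, nd, type = "response")
  pr <- predict(fit)
  expect_true(all(abs(pr$fit - pp) / pp < 0.02))
})

test_that("predictions are invariant to relabelling time levels", {
  cm <- rbind(exposed = c(2, 8, 6), shaded = c(2, 4, 5))
  s <- sim_nb_series(cm, n_per_env = 15, theta = 5, seed = 23)
  fit1 <- quiet_fit(s$series, s$sites, "richness", random = "none")
  s2 <- s
  s2$series$year <- c(10, 20, 30)[s2$series$year] # new labels, same order
  fit2 <- quiet_fit(s2$series, s2$sites, "richness", random = "none")
  expect_equal(predict(fit1)$fit, predict(fit2)$fit, tolerance = 1e-6)
})

test_that("three-way specialist/generalist model recovers fold changes", {
  set.seed(29)
  n <- 60
  sites <- site_table(sprintf("t%03d", 1:n),
                      rep(c("exposed", "shaded"), each = n / 2),
                      rep(c("A", "B"), n / 2))
  mk <- function(mult_exposed, mult_shaded, base) {
    df <- expand.grid(trap = sites$trap, year = 1:2, stringsAsFactors = FALSE)
    env <- sites$environment[match(df$trap, sites$trap)]
    mu <- ifelse(env == "exposed",
                 base * ifelse(df$year == 2, mult_exposed, 1),
                 base * ifelse(df$year == 2, mult_shaded, 1))
    df$abundance <- stats::rnbinom(nrow(df), mu = mu, size = 8)
    df$richness <- df$abundance
    structure(df, class = c("group_series", "data.frame"))
  }
  # specialists jump x8 at exposed sites, generalists x2; both x1.5 in shade
  sp <- mk(8, 1.5, base = 5)
  ge <- mk(2, 1.5, base = 5)
  m <- specialist_generalist_model(sp, ge, sites, "abundance")
  fc <- m$fold_changes
  true_fc <- c(specialist = sqrt(8 * 1.5), generalist = sqrt(2 * 1.5))
  expect_true(all(abs(fc - true_fc) / true_fc < 0.25))
  expect_lt(m$three_way$p, 0.05)
  expect_gt(m$three_way$estimate, 0)

  # identical dynamics: three-way estimate near zero, fold change ~ shared
  ge2 <- mk(2, 1.5, base = 5)
  m0 <- specialist_generalist_model(mk(2, 1.5, 5), ge2, sites, "abundance")
  expect_lt(abs(m0$three_way$z), 2.5)
})

test_that("residual diagnostics separate white noise from AR(1) errors", {
  n_trap <- 40; T_ <- 6
  sites <- site_table(sprintf("t%02d", 1:n_trap),
                      rep(c("exposed", "shaded"), each = n_trap / 2),
                      rep(c("A", "B"), n_trap / 2))
  mk_rates <- function(innov) {
    df <- expand.grid(trap = sites$trap, t1 = seq_len(T_),
                      stringsAsFactors = FALSE)
    df <- df[order(df$trap, df$t1), ]
    df$Gp <- 0.5 + as.numeric(innov)
    structure(df, class = c("turnover", "data.frame"))
  }
  set.seed(31)
  white <- rnorm(n_trap * T_, sd = 0.2)
  fitw <- quiet_fit(mk_rates(white), sites, "Gp", random = "none")
  dw <- residual_time_diagnostics(fitw)
  expect_lt(abs(dw$mean_lag1), 0.12)

  ar <- as.vector(replicate(n_trap,
    as.numeric(stats::arima.sim(list(ar = 0.8), T_, sd = 0.2))))
  fita <- quiet_fit(mk_rates(ar), sites, "Gp", random = "none")
  da <- residual_time_diagnostics(fita)
  expect_gt(da$mean_lag1, 0.3)

  # too few time points for the diagnostic
  short <- mk_rates(white)
  short <- structure(short[short$t1 <= 2, ],
                     class = c("turnover", "data.frame"))
  fs <- quiet_fit(short, sites, "Gp", random = "none")
  expect_error(residual_time_diagnostics(fs), "3 time points")
})
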