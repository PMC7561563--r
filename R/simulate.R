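#' Simulation parameters for a study-shaped succession dataset
#'
#' Defines the generative model used by [simulate_study()]: for each species
#' and trap, a latent first-arrival year is drawn from an environment-specific
#' colonization profile (probability of first presence in each successional
#' year; the remainder never arrives), presence then survives from year to
#' year with a constant annual persistence probability (geometric survival),
#' detection thins the latent presences independently per trap-year, and
#' detected presences receive a zero-truncated negative binomial count
#' (1 + NB with matched mean). Fungal diversity per trap is Poisson with an
#' environment-specific mean.
#'
#' The default preset mirrors the motivating field design: 15 traps per
#' environment per landscape in 2 landscapes (60 traps), 4 successional
#' years, and a species pool of 17 host-tree specialists and 167 generalists
#' split across trophic guilds in the proportions of the motivating study's
#' tallies (wood-feeders 22, fungivores 73, predators 75,
#' omnivores/saprophages 14), plus 30 non-host species that the filtering
#' step must remove. The exposed colonization profile is front-loaded (most
#' first arrivals by year 2) while the shaded profile is flat, encoding the
#' hypothesis that favourable exposed sites accumulate species early while
#' shaded sites accumulate gradually.
#'
#' @param n_traps_per_env_per_landscape traps per environment per landscape.
#' @param n_years number of successional years T.
#' @param pool data frame with columns `host_affinity`, `guild`, `n` giving
#'   the species pool composition.
#' @param n_non_aspen number of non-host species added to the raw data.
#' @param colonization named list (`exposed`, `shaded`) of first-arrival
#'   probability vectors of length T (sum <= 1). Each entry may itself be a
#'   named list per host affinity to give groups distinct dynamics; the
#'   default front-loads exposed arrivals (hardest for specialists, whose
#'   early surge at favourable sites is part of the emulated hypothesis)
#'   while shaded arrivals are flat.
#' @param persistence annual probability that an established species remains.
#' @param detection per trap-year detection probability of a present species.
#' @param mu negative binomial mean count for a detected species (shaded).
#' @param theta NB2 dispersion (variance = mu + mu^2/theta).
#' @param env_mu_mult multiplier on `mu` at exposed sites.
#' @param env_affinity_sd standard deviation (log scale) of the per-species
#'   environment affinity: each species receives one mean-one lognormal
#'   multiplier applied to its exposed-site count mean and reciprocally to
#'   its shaded-site mean, so some species lean sunny and some shady. This
#'   is what gives the community a compositional environment axis; 0
#'   disables it.
#' @param abund_sd standard deviation (log scale) of the per-species base
#'   abundance: species-specific mean-one lognormal multipliers on `mu`
#'   emulate the strongly right-skewed species abundance distribution of
#'   real assemblages (a few consistent dominants, many rarities); 0 makes
#'   all species equally common.
#' @param fungal_lambda named vector (`exposed`, `shaded`) of Poisson means
#'   for fungal diversity.
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(n_traps_per_env_per_landscape = 15,
                       n_years = 4,
                       pool = default_pool(),
                       n_non_aspen = 30,
                       colonization = default_colonization(),
                       persistence = 0.5,
                       detection = 0.8,
                       mu = 2.5,
                       theta = 1,
                       env_mu_mult = 2,
                       env_affinity_sd = 0.8,
                       abund_sd = 1.5,
                       fungal_lambda = c(exposed = 1.5, shaded = 2.5)) {
  p <- list(n_traps_per_env_per_landscape = n_traps_per_env_per_landscape,
            n_years = n_years, pool = pool, n_non_aspen = n_non_aspen,
            colonization = colonization, persistence = persistence,
            detection = detection, mu = mu, theta = theta,
            env_mu_mult = env_mu_mult, env_affinity_sd = env_affinity_sd,
            abund_sd = abund_sd, fungal_lambda = fungal_lambda)
  leaves <- function(x) if (is.list(x)) unlist(lapply(x, leaves),
                                                recursive = FALSE) else list(x)
  for (env in c("exposed", "shaded")) {
    prof <- colonization[[env]]
    if (is.null(prof)) stop("colonization profile missing for ", env)
    for (pr in leaves(prof)) {
      if (length(pr) != n_years)
        stop("colonization profiles must have length n_years = ", n_years)
      if (any(pr < 0) || any(pr > 1) || sum(pr) > 1 + 1e-12)
        stop("colonization profile entries must be probabilities summing to <= 1")
    }
  }
  for (v in c("persistence", "detection"))
    if (p[[v]] < 0 || p[[v]] > 1) stop(v, " must be a probability")
  if (theta <= 0) stop("theta must be > 0")
  if (mu <= 0 || env_mu_mult <= 0) stop("mu and env_mu_mult must be > 0")
  if (env_affinity_sd < 0) stop("env_affinity_sd must be >= 0")
  if (abund_sd < 0) stop("abund_sd must be >= 0")
  class(p) <- "sim_params"
  p
}

default_pool <- function() {
  data.frame(
    host_affinity = rep(c("specialist", "generalist"), each = 4),
    guild = rep(c("wood_feeder", "fungivore", "predator",
                  "omnivore_saprophage"), 2),
    n = c(4, 7, 4, 2,      # specialists: 17
          18, 66, 71, 12)  # generalists: 167
  )
}

#' Default colonization profiles of the study-shaped preset
#'
#' First-arrival probability per successional year, by environment, host
#' affinity and (for generalists) trophic guild. The exposed profiles are
#' front-loaded — hardest for the host-tree specialists and the wood-feeders,
#' which surge while the nutrient-rich cambium is fresh — while shaded
#' profiles are flat, with fungivores rising through time as fungi establish.
#'
#' @return nested list accepted by [sim_params()]'s `colonization` argument.
#' @export
default_colonization <- function() {
  list(
    exposed = list(
      specialist = c(0.08, 0.30, 0.04, 0.02),
      generalist = list(
        wood_feeder = c(0.20, 0.15, 0.02, 0.01),
        fungivore = c(0.10, 0.14, 0.05, 0.03),
        predator = c(0.10, 0.14, 0.04, 0.02),
        omnivore_saprophage = c(0.08, 0.08, 0.06, 0.04),
        unassigned = c(0.05, 0.05, 0.05, 0.05))),
    shaded = list(
      specialist = c(0.04, 0.05, 0.06, 0.06),
      generalist = list(
        wood_feeder = c(0.04, 0.04, 0.03, 0.03),
        fungivore = c(0.03, 0.05, 0.07, 0.08),
        predator = c(0.05, 0.05, 0.05, 0.05),
        omnivore_saprophage = c(0.06, 0.07, 0.05, 0.04),
        unassigned = c(0.05, 0.05, 0.05, 0.05)))
  )
}

profile_for <- function(params, env, affinity, guild = NULL) {
  prof <- params$colonization[[env]]
  if (!is.list(prof)) return(prof)
  out <- prof[[affinity]]
  if (is.null(out)) out <- prof[[1]]
  if (!is.list(out)) return(out)
  g <- if (!is.null(guild) && !is.null(out[[guild]])) out[[guild]] else out[[1]]
  g
}

#' Simulate a study-shaped succession dataset
#'
#' Draws one realisation of the colonization-extinction-detection model in
#' [sim_params()] and returns the three study tables plus the latent ground
#' truth. Reproducible: the same `seed` gives an identical study.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed (all random streams derive from it).
#' @return an object of class `simulated_study`: `community`
#'   ([community_matrix()] including non-host species), `traits`
#'   ([trait_table()]), `sites` ([site_table()]), and `ground_truth` (latent
#'   presence array, arrival years, parameters, seed).
#' @export
simulate_study <- function(params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  T_ <- params$n_years
  npl <- params$n_traps_per_env_per_landscape
  sites <- expand.grid(i = seq_len(npl),
                       environment = c("exposed", "shaded"),
                       landscape = c("A", "B"), stringsAsFactors = FALSE)
  sites$trap <- sprintf("trap%02d", seq_len(nrow(sites)))
  n_trap <- nrow(sites)

  pool <- params$pool
  sp <- data.frame(
    species = character(0), host_affinity = character(0), guild = character(0))
  k <- 0
  for (r in seq_len(nrow(pool))) {
    if (pool$n[r] == 0) next
    ids <- sprintf("sp%03d", k + seq_len(pool$n[r]))
    sp <- rbind(sp, data.frame(species = ids,
                               host_affinity = pool$host_affinity[r],
                               guild = pool$guild[r]))
    k <- k + pool$n[r]
  }
  if (params$n_non_aspen > 0) {
    ids <- sprintf("nx%03d", seq_len(params$n_non_aspen))
    sp <- rbind(sp, data.frame(species = ids, host_affinity = "non_aspen",
                               guild = "unassigned"))
  }
  n_sp <- nrow(sp)

  arrival <- matrix(NA_integer_, n_trap, n_sp,
                    dimnames = list(sites$trap, sp$species))
  latent <- array(FALSE, c(n_trap, T_, n_sp),
                  dimnames = list(sites$trap, as.character(seq_len(T_)),
                                  sp$species))
  counts <- array(0L, dim = dim(latent), dimnames = dimnames(latent))
  aff_of <- ifelse(sp$host_affinity == "non_aspen", "generalist",
                   sp$host_affinity)
  # per-species environment affinity: mean-one lognormal multiplier on the
  # exposed-site count mean (drawn once per species)
  env_aff <- exp(stats::rnorm(n_sp, 0, params$env_affinity_sd) -
                   params$env_affinity_sd^2 / 2)
  # per-species base commonness (species abundance distribution)
  base_mu <- params$mu * exp(stats::rnorm(n_sp, 0, params$abund_sd) -
                               params$abund_sd^2 / 2)
  guild_of <- sp$guild
  stratum <- paste(aff_of, guild_of)
  # vectorised over all (trap, species) pairs within each env x affinity x
  # guild stratum, which share one colonization profile
  for (env in c("exposed", "shaded")) {
    tr_idx <- which(sites$environment == env)
    if (!length(tr_idx)) next
    for (st in unique(stratum)) {
      sp_idx <- which(stratum == st)
      if (!length(sp_idx)) next
      prof <- profile_for(params, env, aff_of[sp_idx[1]],
                          guild_of[sp_idx[1]])
      np <- length(tr_idx) * length(sp_idx)
      a <- sample.int(T_ + 1L, np, replace = TRUE,
                      prob = c(prof, max(0, 1 - sum(prof))))
      dur <- if (params$persistence >= 1) rep(Inf, np)
             else 1L + stats::rgeom(np, prob = 1 - params$persistence)
      ii <- rep(tr_idx, times = length(sp_idx))
      jj <- rep(sp_idx, each = length(tr_idx))
      est <- a <= T_
      arrival[cbind(ii[est], jj[est])] <- a[est]
      # reciprocal affinity: a sun-leaning species is rarer in the shade,
      # so the compositional contrast is 2x the per-species log affinity
      m_sp <- if (env == "exposed")
                base_mu * params$env_mu_mult * env_aff
              else base_mu / env_aff
      for (y in seq_len(T_)) {
        pres <- a <= y & y <= a + dur - 1
        det <- pres & stats::runif(np) < params$detection
        latent[cbind(ii[pres], y, jj[pres])] <- TRUE
        if (any(det))
          counts[cbind(ii[det], y, jj[det])] <-
            1L + stats::rnbinom(sum(det),
                                mu = pmax(m_sp[jj[det]] - 1, 1e-8),
                                size = params$theta)
      }
    }
  }
  fung <- stats::rpois(n_trap, params$fungal_lambda[sites$environment])
  long_idx <- which(counts >= 0, arr.ind = TRUE) # full grid
  community <- community_matrix(
    trap = dimnames(counts)[[1]][long_idx[, 1]],
    year = as.integer(dimnames(counts)[[2]][long_idx[, 2]]),
    species = dimnames(counts)[[3]][long_idx[, 3]],
    count = counts[long_idx]
  )
  structure(list(
    community = community,
    traits = trait_table(sp$species, sp$host_affinity, sp$guild),
    sites = site_table(sites$trap, sites$environment, sites$landscape, fung),
    ground_truth = list(arrival = arrival, latent = latent,
                        env_affinity = stats::setNames(env_aff, sp$species),
                        params = params, seed = seed)
  ), class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated succession study (seed", x$ground_truth$seed, ")\n")
  print(x$community)
  cat("Species pool:", nrow(x$traits), "species (",
      sum(x$traits$host_affinity == "specialist"), "specialists,",
      sum(x$traits$host_affinity == "generalist"), "generalists,",
      sum(x$traits$host_affinity == "non_aspen"), "non-host )\n")
  invisible(x)
}

#' Export a simulated study to CSV files
#'
#' Writes `community.csv`, `traits.csv`, `sites.csv` and `ground_truth.json`
#' into a directory. With a fixed seed the exports are byte-identical across
#' runs.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @param sparse passed to [write_community()].
#' @export
export_study <- function(study, dir, sparse = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_community(study$community, file.path(dir, "community.csv"),
                  sparse = sparse)
  utils::write.csv(study$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$sites, file.path(dir, "sites.csv"),
                   row.names = FALSE, quote = FALSE)
  gt <- study$ground_truth
  jsonlite::write_json(
    list(seed = gt$seed,
         params = gt$params[setdiff(names(gt$params), "pool")],
         pool = gt$params$pool,
         arrival = as.data.frame(gt$arrival)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

# exact distribution of one species' *observed* presence history in one trap:
# enumerate arrival year x survival duration x per-year detection outcomes
history_distribution <- function(profile, persistence, detection, T_) {
  probs <- stats::setNames(numeric(2^T_),
                           apply(expand.grid(rep(list(0:1), T_)), 1,
                                 paste, collapse = ""))
  hist_key <- function(h) paste(as.integer(h), collapse = "")
  # P(survive exactly d years) = persistence^(d-1) (1 - persistence), d >= 1;
  # durations reaching past year T are pooled (right-censored)
  p_never <- max(0, 1 - sum(profile))
  probs[hist_key(rep(FALSE, T_))] <- 0 # filled below
  add <- function(key, p) probs[key] <<- probs[key] + p
  for (a in seq_len(T_)) {
    if (profile[a] <= 0) next
    max_d <- T_ - a + 1
    for (d in seq_len(max_d)) {
      p_d <- if (d < max_d) persistence^(d - 1) * (1 - persistence)
             else persistence^(d - 1) # censored tail
      yrs <- a:(a + d - 1)
      # enumerate detection outcomes over the latent years
      for (mask in 0:(2^d - 1)) {
        det <- as.logical(bitwAnd(mask, 2^(seq_len(d) - 1)))
        h <- rep(FALSE, T_)
        h[yrs[det]] <- TRUE
        add(hist_key(h),
            profile[a] * p_d *
              prod(ifelse(det, detection, 1 - detection)))
      }
    }
  }
  add(hist_key(rep(FALSE, T_)), p_never)
  stopifnot(abs(sum(probs) - 1) < 1e-9)
  probs
}

#' Expected turnover rates under the simulation model
#'
#' Computes the expected per-trap Gp and Lp for each environment and
#' interval implied by a [sim_params()] object. The distribution of one
#' species' observed presence history is obtained by exhaustive enumeration
#' over arrival year, geometric survival duration and per-year detection
#' outcomes; trap-level rates (ratios of sums across the species pool) are
#' then averaged over `n_mc` Monte Carlo traps whose species histories are
#' drawn from that exact distribution. Also returns the exact expected
#' per-trap G, L and richness components.
#'
#' @param params a [sim_params()] object.
#' @param n_mc Monte Carlo traps per environment (default 1e5).
#' @param seed seed for the Monte Carlo stream.
#' @return data frame: environment, t1, t2, E_G, E_L, E_S_t1, E_S_t2 (exact),
#'   Gp, Lp (Monte Carlo means of the per-trap rates), and `mc_se` columns.
#' @export
true_turnover <- function(params = sim_params(), n_mc = 1e5, seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  T_ <- params$n_years
  pool <- params$pool
  set.seed(seed)
  out <- list()
  strata <- pool[pool$n > 0, , drop = FALSE]
  for (env in c("exposed", "shaded")) {
    # distinct history distributions per (affinity, guild) stratum
    dists <- lapply(seq_len(nrow(strata)), function(r)
      history_distribution(
        profile_for(params, env, strata$host_affinity[r], strata$guild[r]),
        params$persistence, params$detection, T_))
    hmats <- lapply(dists, function(d)
      matrix(as.integer(unlist(strsplit(names(d), ""))),
             ncol = T_, byrow = TRUE))
    # exact per-interval expectations of the per-species indicators
    exact <- matrix(0, T_ - 1, 4,
                    dimnames = list(NULL, c("G", "L", "S1", "S2")))
    for (a in seq_len(nrow(strata))) {
      nsp <- strata$n[a]
      H <- hmats[[a]]; pr <- dists[[a]]
      for (t in seq_len(T_ - 1)) {
        prior <- as.integer(rowSums(H[, seq_len(t), drop = FALSE]) > 0)
        later <- as.integer(rowSums(H[, seq(t + 1, T_), drop = FALSE]) > 0)
        g_ind <- H[, t + 1] * (1 - prior)
        l_ind <- H[, t] * (1 - later)
        exact[t, ] <- exact[t, ] + nsp * c(sum(g_ind * pr), sum(l_ind * pr),
                                           sum(H[, t] * pr),
                                           sum(H[, t + 1] * pr))
      }
    }
    # Monte Carlo expectation of the per-trap ratio Gp = G / ((S1+S2)/2)
    gp <- matrix(NA_real_, n_mc, T_ - 1)
    lp <- matrix(NA_real_, n_mc, T_ - 1)
    Gs <- matrix(0L, n_mc, T_ - 1); Ls <- matrix(0L, n_mc, T_ - 1)
    S <- matrix(0L, n_mc, T_)
    for (a in seq_len(nrow(strata))) {
      nsp <- strata$n[a]
      H <- hmats[[a]]; pr <- dists[[a]]
      draw <- sample.int(nrow(H), n_mc * nsp, replace = TRUE, prob = pr)
      Hd <- H[draw, , drop = FALSE]
      grp <- rep(seq_len(n_mc), each = nsp)
      for (t in seq_len(T_))
        S[, t] <- S[, t] + tabulate(grp[Hd[, t] == 1], nbins = n_mc)
      for (t in seq_len(T_ - 1)) {
        prior <- as.integer(rowSums(Hd[, seq_len(t), drop = FALSE]) > 0)
        later <- as.integer(rowSums(Hd[, seq(t + 1, T_), drop = FALSE]) > 0)
        Gs[, t] <- Gs[, t] + tabulate(grp[Hd[, t + 1] == 1 & prior == 0],
                                      nbins = n_mc)
        Ls[, t] <- Ls[, t] + tabulate(grp[Hd[, t] == 1 & later == 0],
                                      nbins = n_mc)
      }
    }
    for (t in seq_len(T_ - 1)) {
      denom <- (S[, t] + S[, t + 1]) / 2
      ok <- denom > 0
      gp[ok, t] <- Gs[ok, t] / denom[ok]
      lp[ok, t] <- Ls[ok, t] / denom[ok]
    }
    mc_mean <- function(m) colMeans(m, na.rm = TRUE)
    mc_se <- function(m) apply(m, 2, function(v)
      stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
    out[[env]] <- data.frame(
      environment = env, t1 = seq_len(T_ - 1), t2 = seq(2, T_),
      E_G = exact[, "G"], E_L = exact[, "L"],
      E_S_t1 = exact[, "S1"], E_S_t2 = exact[, "S2"],
      Gp = mc_mean(gp), Lp = mc_mean(lp),
      Gp_mc_se = mc_se(gp), Lp_mc_se = mc_se(lp)
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
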