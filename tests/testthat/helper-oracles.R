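# Independent brute-force oracles and fixture builders. These deliberately
# re-derive results from first principles (explicit scans, explicit hat
# matrices) and share no code with the implementation paths they check.

# --- turnover -----------------------------------------------------------

# direct scan of the permanence rule, species by species
oracle_gains_losses <- function(history, t1) {
  T_ <- ncol(history)
  G <- 0L; L <- 0L
  for (s in seq_len(nrow(history))) {
    h <- history[s, ]
    if (h[t1 + 1] && !any(h[seq_len(t1)])) G <- G + 1L
    if (h[t1] && !any(h[seq(t1 + 1, T_)])) L <- L + 1L
  }
  c(G = G, L = L)
}

random_history <- function(n_species, n_years, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.1, 0.6)
  matrix(runif(n_species * n_years) < p, n_species, n_years)
}

# the worked 5-species example used throughout
worked_history <- function() {
  rbind(A = c(1, 1, 1, 1), B = c(0, 1, 1, 1), C = c(1, 0, 0, 0),
        D = c(1, 0, 1, 0), E = c(0, 0, 0, 1)) > 0
}

# --- small community fixtures ------------------------------------------

tiny_community <- function() {
  community_matrix(
    trap = c("t1", "t1", "t1"), year = c(1, 2, 2),
    species = c("spA", "spA", "spB"), count = c(2, 0, 5)
  )
}

random_community <- function(n_trap = 6, n_year = 4, n_sp = 20, seed = NULL,
                             p_zero = 0.6, lambda = 3) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(trap = sprintf("t%02d", seq_len(n_trap)),
                      year = seq_len(n_year),
                      species = sprintf("s%03d", seq_len(n_sp)),
                      stringsAsFactors = FALSE)
  grid$count <- ifelse(runif(nrow(grid)) < p_zero, 0L,
                       rpois(nrow(grid), lambda))
  community_matrix(grid$trap, grid$year, grid$species, grid$count)
}

random_traits <- function(species, seed = NULL,
                          p = c(specialist = 0.15, generalist = 0.65,
                                non_aspen = 0.20)) {
  if (!is.null(seed)) set.seed(seed)
  aff <- sample(names(p), length(species), replace = TRUE, prob = p)
  guild <- ifelse(aff == "non_aspen", "unassigned",
                  sample(c("wood_feeder", "fungivore", "predator",
                           "omnivore_saprophage"), length(species),
                         replace = TRUE))
  trait_table(species, aff, guild)
}

# --- ordination ---------------------------------------------------------

# explicit projection-matrix RDA: hat matrices built by solve(), eigenvalues
# from the eigen-decomposition of (HY)'(HY)
oracle_rda <- function(Y, data, terms, condition = NULL) {
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  hat <- function(M) M %*% solve(crossprod(M), t(M))
  mmat <- function(f) {
    m <- stats::model.matrix(f, data)[, -1, drop = FALSE]
    scale(m, center = TRUE, scale = FALSE)
  }
  if (!is.null(condition)) {
    Hz <- hat(mmat(condition))
    Yc <- Yc - Hz %*% Yc
    X <- (diag(n) - Hz) %*% mmat(terms)
  } else X <- mmat(terms)
  H <- hat(X)
  Yhat <- H %*% Yc
  ee <- eigen(crossprod(Yhat), symmetric = TRUE)
  total <- sum(Yc^2) / (n - 1)
  ev <- ee$values / (n - 1)
  keep <- ev > 1e-10 * total
  list(eig = ev[keep], vectors = ee$vectors[, keep, drop = FALSE],
       total = total, R2 = sum(Yhat^2) / sum(Yc^2))
}

# oracle type-II species scores (up to axis sign)
oracle_species_scores <- function(or, n) {
  const <- ((n - 1) * or$total)^(1 / 4)
  sweep(or$vectors, 2, sqrt(or$eig / or$total), "*") * const
}

random_ordination_data <- function(n = 40, n_sp = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data <- data.frame(
    year = factor(sample(1:4, n, replace = TRUE)),
    environment = factor(sample(c("shaded", "exposed"), n, replace = TRUE),
                         levels = c("shaded", "exposed")),
    landscape = factor(sample(c("A", "B"), n, replace = TRUE)),
    fungal_diversity = rpois(n, 2)
  )
  # guarantee all cells occupied so the factorial design has full rank
  cells <- expand.grid(year = levels(data$year),
                       environment = levels(data$environment))
  data$year[seq_len(nrow(cells))] <- cells$year
  data$environment[seq_len(nrow(cells))] <- cells$environment
  data$landscape[1:2] <- c("A", "B")
  Y <- matrix(rnorm(n * n_sp), n, n_sp,
              dimnames = list(NULL, sprintf("sp%02d", seq_len(n_sp))))
  list(Y = Y, data = data)
}

# --- misc ----------------------------------------------------------------

quiet_fit <- function(...) suppressMessages(fit_trajectory(...))
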