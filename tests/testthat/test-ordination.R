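test_that("Hellinger transformation follows its definition", {
  expect_equal(hellinger(rbind(c(1, 4, 4))), rbind(c(1 / 3, 2 / 3, 2 / 3)))
  expect_equal(hellinger(rbind(c(0, 0, 0))), rbind(c(0, 0, 0)))
  expect_error(hellinger(rbind(c(-1, 2))), "non-negative")
  set.seed(1)
  Y <- matrix(rpois(200, 2), 20, 10)
  H <- hellinger(Y)
  nz <- rowSums(Y) > 0
  expect_equal(sqrt(rowSums(H[nz, ]^2)), rep(1, sum(nz)), tolerance = 1e-12)
  expect_true(all(H >= 0 & H <= 1))
})

test_that("Hellinger agrees with the vegan reference on nonzero rows", {
  skip_if_not_installed("vegan")
  set.seed(2)
  Y <- matrix(rpois(300, 3) + 1, 30, 10)
  expect_equal(unname(hellinger(Y)),
               unname(as.matrix(vegan::decostand(Y, "hellinger"))),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("perfectly structured data give R2 = 1 on one axis", {
  n <- 10
  base <- rbind(c(1, 0, 2), c(0, 3, 1))
  Y <- base[rep(1:2, each = n / 2), ]
  data <- data.frame(environment = factor(rep(c("exposed", "shaded"),
                                              each = n / 2)))
  r <- partial_rda(Y, data, ~environment)
  expect_equal(r$R2, 1, tolerance = 1e-12)
  expect_equal(r$rank, 1L)
  expect_equal(sum(r$eig_unconstrained), 0, tolerance = 1e-12)
})

test_that("a saturated design explains everything", {
  set.seed(3)
  n <- 8
  Y <- matrix(rnorm(n * 5), n, 5)
  data <- data.frame(cell = factor(seq_len(n)))
  r <- partial_rda(Y, data, ~cell)
  expect_equal(r$R2, 1, tolerance = 1e-10)
})

test_that("partial RDA matches the projection-matrix oracle to 1e-8", {
  for (seed in 1:5) {
    rd <- random_ordination_data(n = 40, n_sp = 12, seed = seed)
    r <- partial_rda(rd$Y, rd$data, ~ year * environment, ~landscape)
    or <- oracle_rda(rd$Y, rd$data, ~ year * environment, ~landscape)
    expect_equal(r$eig, or$eig, tolerance = 1e-8)
    expect_equal(r$R2, or$R2, tolerance = 1e-8)
    expect_equal(r$total, or$total, tolerance = 1e-8)
    sc <- ordination_scores(r, scaling = 2)
    osc <- oracle_species_scores(or, nrow(rd$Y))
    expect_equal(abs(unname(as.matrix(sc$species))), abs(unname(osc)),
                 tolerance = 1e-8)
  }
})

test_that("partial RDA agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  rd <- random_ordination_data(n = 48, n_sp = 10, seed = 9)
  r <- partial_rda(rd$Y, rd$data, ~ year * environment, ~landscape)
  v <- vegan::rda(rd$Y ~ year * environment + Condition(landscape),
                  data = rd$data)
  expect_equal(unname(r$eig), unname(v$CCA$eig), tolerance = 1e-10)
  expect_equal(r$R2, v$CCA$tot.chi / (v$CCA$tot.chi + v$CA$tot.chi),
               tolerance = 1e-10)
})

test_that("eigenvalues decompose the conditioned total variance", {
  rd <- random_ordination_data(n = 36, n_sp = 8, seed = 13)
  r <- partial_rda(rd$Y, rd$data, ~ year + environment, ~landscape)
  expect_equal(sum(r$eig) + sum(r$eig_unconstrained), r$total,
               tolerance = 1e-8)
  expect_true(r$R2 >= 0 && r$R2 <= 1)
  expect_lte(r$rank, r$df_terms)
})

test_that("conditioning away the constraints leaves nothing to explain", {
  rd <- random_ordination_data(n = 30, n_sp = 6, seed = 17)
  r <- partial_rda(rd$Y, rd$data, ~ year + environment, ~ year + environment)
  expect_equal(r$R2, 0, tolerance = 1e-10)
})

test_that("first eigenvalue equals the between-group SS for one 2-level factor", {
  set.seed(19)
  n <- 24
  Y <- matrix(rnorm(n * 5), n, 5)
  g <- factor(rep(c("a", "b"), each = n / 2))
  r <- partial_rda(Y, data.frame(g = g), ~g)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  means <- apply(Yc, 2, function(col) tapply(col, g, mean))
  between <- sum((n / 2) * means^2) / (n - 1)
  expect_equal(r$eig[1], between, tolerance = 1e-10)
  expect_equal(r$rank, 1L)
})

test_that("aliased designs are rejected with the offending columns named", {
  set.seed(23)
  n <- 20
  data <- data.frame(a = factor(rep(c("x", "y"), each = n / 2)))
  data$b <- data$a # alias
  Y <- matrix(rnorm(n * 4), n, 4)
  expect_error(partial_rda(Y, data, ~ a + b), "aliased")
})

test_that("rank-2 structure puts the driving species first in type-II scores", {
  set.seed(29)
  n <- 40
  data <- data.frame(environment = factor(rep(c("shaded", "exposed"),
                                              each = n / 2),
                                          levels = c("shaded", "exposed")))
  Y <- matrix(rnorm(n * 8, sd = 0.05), n, 8,
              dimnames = list(NULL, sprintf("sp%d", 1:8)))
  Y[, 3] <- Y[, 3] + ifelse(data$environment == "exposed", 1, 0) # carrier
  r <- partial_rda(Y, data, ~environment)
  sc <- ordination_scores(r, scaling = 2, threshold = 0.2)
  expect_equal(which.max(abs(sc$species$RDA1)), 3L)
  expect_true("sp3" %in% sc$flagged)
  # the two environment centroids sit on opposite sides of the origin
  cents <- sc$centroids[grep("environment", rownames(sc$centroids)), "RDA1"]
  expect_lt(prod(cents), 0)
  expect_error(ordination_scores(r, scaling = 3), "scaling")
})

test_that("permutation tests are deterministic given a seed", {
  rd <- random_ordination_data(n = 32, n_sp = 8, seed = 31)
  t1 <- marginal_permutation_test(rd$Y, rd$data, ~ year * environment,
                                  ~landscape, term = "year:environment",
                                  n_perm = 99, seed = 42)
  t2 <- marginal_permutation_test(rd$Y, rd$data, ~ year * environment,
                                  ~landscape, term = "year:environment",
                                  n_perm = 99, seed = 42)
  expect_identical(t1$p, t2$p)
  expect_identical(t1$F, t2$F)
  expect_error(marginal_permutation_test(rd$Y, rd$data, ~year, NULL,
                                         term = "year", n_perm = 0), "n_perm")
})

test_that("permutation p-values are invariant to species column order", {
  rd <- random_ordination_data(n = 32, n_sp = 8, seed = 37)
  perm <- sample(ncol(rd$Y))
  t1 <- marginal_permutation_test(rd$Y, rd$data, ~ year + environment, NULL,
                                  term = "environment", n_perm = 49, seed = 5)
  t2 <- marginal_permutation_test(rd$Y[, perm], rd$data, ~ year + environment,
                                  NULL, term = "environment", n_perm = 49,
                                  seed = 5)
  expect_equal(t1$F, t2$F, tolerance = 1e-12)
  expect_identical(t1$p, t2$p)
})

test_that("a saturating group effect reaches the minimal p-value", {
  set.seed(41)
  n <- 24
  data <- data.frame(environment = factor(rep(c("shaded", "exposed"),
                                              each = n / 2)))
  Y <- matrix(rnorm(n * 6, sd = 0.01), n, 6)
  Y[data$environment == "exposed", ] <- Y[data$environment == "exposed", ] + 5
  ts <- marginal_permutation_test(Y, data, ~environment, NULL,
                                  term = "environment", n_perm = 199,
                                  seed = 7)
  expect_equal(ts$p, 1 / 200)
})

test_that("marginal pseudo-F matches vegan's margin test on the same data", {
  skip_if_not_installed("vegan")
  rd <- random_ordination_data(n = 40, n_sp = 9, seed = 43)
  ours <- marginal_permutation_test(rd$Y, rd$data, ~ year * environment,
                                    ~landscape, term = "year:environment",
                                    n_perm = 99, seed = 1)
  v <- vegan::rda(rd$Y ~ year * environment + Condition(landscape),
                  data = rd$data)
  va <- vegan::anova.cca(v, by = "margin", permutations = 99)
  expect_equal(ours$F, va["year:environment", "F"], tolerance = 1e-8)
  expect_equal(ours$df, va["year:environment", "Df"])
})
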