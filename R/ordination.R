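#' Hellinger transformation
#'
#' Square root of the row-relative abundance: entry (i, j) becomes
#' sqrt(y_ij / y_i+). Rows with zero total are mapped to zero rows. After the
#' transformation each nonzero row has unit Euclidean norm, which makes
#' Euclidean-distance ordination (RDA/PCA) appropriate for species count
#' data dominated by zeros.
#'
#' @param x non-negative numeric matrix, samples in rows, species in columns.
#' @return matrix of the same shape, entries in [0, 1].
#' @examples
#' hellinger(rbind(c(1, 4, 4))) # 1/3, 2/3, 2/3
#' @export
hellinger <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("Hellinger transformation requires non-negative input")
  rs <- rowSums(x)
  out <- sqrt(sweep(x, 1, ifelse(rs > 0, rs, 1), "/"))
  out[rs == 0, ] <- 0
  out
}

#' Flatten a community matrix to a sample-by-species table
#'
#' Each (trap, year) combination becomes one sample row; the accompanying
#' data frame carries the trap, year, environment, landscape and fungal
#' diversity of each row for use as ordination predictors.
#'
#' @param x a [community_matrix()].
#' @param sites a [site_table()].
#' @return list with `Y` (samples x species count matrix, rownames
#'   "trap.year") and `data` (aligned predictor data frame with `year` as a
#'   factor of successional years).
#' @export
community_to_samples <- function(x, sites) {
  d <- dim(x)
  # rows ordered year-within-trap
  tr <- rep(traps(x), each = d[2])
  yr <- rep(study_years(x), times = d[1])
  Y <- matrix(NA_real_, d[1] * d[2], d[3],
              dimnames = list(paste(tr, yr, sep = "."), species_ids(x)))
  for (i in seq_len(d[1])) Y[seq((i - 1) * d[2] + 1, i * d[2]), ] <- x[i, , ]
  idx <- match(tr, sites$trap)
  if (anyNA(idx)) stop("trap(s) missing from site table")
  list(Y = Y,
       data = data.frame(trap = tr, year = factor(yr),
                         environment = factor(sites$environment[idx],
                                              levels = c("shaded", "exposed")),
                         landscape = factor(sites$landscape[idx]),
                         fungal_diversity = sites$fungal_diversity[idx],
                         row.names = rownames(Y)))
}

# centered model matrix without intercept; attaches term assignment
design_matrix <- function(formula, data) {
  mm <- stats::model.matrix(formula, data)
  asg <- attr(mm, "assign")
  keep <- asg != 0
  X <- mm[, keep, drop = FALSE]
  structure(scale(X, center = TRUE, scale = FALSE),
            assign = asg[keep],
            term_labels = attr(stats::terms(formula, data = data),
                               "term.labels"))
}

# orthonormal basis of the column space (rank-revealing)
ortho_basis <- function(X) {
  if (is.null(X) || ncol(X) == 0) return(matrix(0, nrow(X), 0))
  q <- qr(X)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

project_out <- function(Y, Q) {
  if (ncol(Q) == 0) return(Y)
  Y - Q %*% (t(Q) %*% Y)
}

#' Partial redundancy analysis
#'
#' Constrained ordination of a (typically Hellinger-transformed) community
#' matrix on categorical/numeric predictors, optionally after removing the
#' effect of conditioning variables. The algorithm: (1) center Y columnwise;
#' (2) residualize Y and the term design on the conditioning design by linear
#' projection; (3) regress the residualized Y on the residualized terms; the
#' singular value decomposition of the fitted values gives the constrained
#' axes and eigenvalues, the residual matrix the unconstrained ones.
#' Eigenvalues are on the variance scale (divided by n - 1, as in standard
#' ordination software) and eigenvalues below 1e-10 x total are dropped as
#' numerically zero. R^2 is the constrained sum of squares over the total sum
#' of squares of the conditioned, centered response; the adjusted R^2 uses
#' the Ezekiel correction with the residual degrees of freedom after both
#' the conditioning and constraining designs.
#'
#' @param Y samples x species numeric matrix (use [hellinger()] first for
#'   count data).
#' @param data data frame of predictors aligned with the rows of `Y`.
#' @param terms one-sided formula of constraining terms, e.g.
#'   `~ year * environment`.
#' @param condition one-sided formula of conditioning terms (e.g.
#'   `~ landscape`) or `NULL`.
#' @return an object of class `prda`: eigenvalues (constrained and
#'   unconstrained), total variance, `R2`, `adjR2`, the SVD factors, row
#'   data and design bookkeeping. Methods: `print`, `summary`,
#'   [ordination_scores()], [anova_prda()] via [marginal_permutation_test()],
#'   `plot` (triplot).
#' @export
partial_rda <- function(Y, data, terms, condition = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (nrow(data) != n) stop("rows of Y and data are not aligned")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Z <- if (is.null(condition)) matrix(0, n, 0) else design_matrix(condition, data)
  Qz <- ortho_basis(Z)
  X <- design_matrix(terms, data)
  Yr <- project_out(Yc, Qz)
  Xr <- project_out(X, Qz)
  # columns wholly absorbed by the conditioning design carry no constraint
  absorbed <- sqrt(colSums(Xr^2)) <= 1e-8 * (sqrt(colSums(X^2)) + 1e-12)
  Xr <- Xr[, !absorbed, drop = FALSE]
  if (ncol(Xr) > 0) {
    qx <- qr(Xr)
    if (qx$rank < ncol(Xr)) {
      piv <- qx$pivot[seq(qx$rank + 1, ncol(Xr))]
      stop("rank-deficient constraining design; aliased column(s): ",
           paste(colnames(Xr)[piv], collapse = ", "))
    }
    Qx <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  } else {
    Qx <- matrix(0, n, 0)
  }
  Yhat <- Qx %*% (t(Qx) %*% Yr)
  Yres <- Yr - Yhat
  total <- sum(Yr^2) / (n - 1)
  sv <- svd(Yhat)
  ev <- sv$d^2 / (n - 1)
  keep <- ev > 1e-10 * total
  sv_res <- svd(Yres)
  ev_res <- sv_res$d^2 / (n - 1)
  keep_res <- ev_res > 1e-10 * total
  R2 <- sum(ev[keep]) / total
  df_total <- n - 1 - ncol(Qz)
  df_resid <- df_total - ncol(Qx)
  adjR2 <- if (df_resid > 0) 1 - (1 - R2) * df_total / df_resid else NA_real_
  structure(list(
    eig = ev[keep], eig_unconstrained = ev_res[keep_res],
    total = total, R2 = R2, adjR2 = adjR2,
    u = sv$u[, keep, drop = FALSE], d = sv$d[keep],
    v = sv$v[, keep, drop = FALSE],
    n = n, rank = sum(keep), df_terms = ncol(Qx), df_resid = df_resid,
    Yr = Yr, Yhat = Yhat, Qz = Qz, Qx = Qx,
    data = data, terms = terms, condition = condition,
    species = colnames(Y)
  ), class = "prda")
}

#' @export
print.prda <- function(x, ...) {
  cat("Partial RDA:", deparse(x$terms[[2]]),
      if (!is.null(x$condition)) paste("| Condition:",
                                       deparse(x$condition[[2]])), "\n")
  cat("Samples:", x$n, " | constrained axes:", x$rank, "\n")
  cat(sprintf("Total variance (conditioned): %.5f\n", x$total))
  cat(sprintf("Constrained R2 = %.4f  (adjusted %.4f)\n", x$R2, x$adjR2))
  cat("Constrained eigenvalues:\n")
  print(round(x$eig, 5))
  invisible(x)
}

#' @export
summary.prda <- function(object, ...) {
  prop <- object$eig / object$total
  data.frame(axis = paste0("RDA", seq_along(object$eig)),
             eigenvalue = object$eig,
             proportion = prop,
             cumulative = cumsum(prop))
}

#' Ordination scores with type-II (correlation) scaling
#'
#' Under scaling 2 the species scores are the species loadings scaled by
#' sqrt(eigenvalue / total variance), so angles between species arrows
#' approximate correlations; site scores are left unscaled by the
#' eigenvalues. Both are multiplied by the usual display constant
#' ((n - 1) x total)^(1/4). Scaling 1 (distance scaling) applies the
#' eigenvalue scaling to the sites instead. Factor-level centroids are the
#' means of the site scores per level of each factor in the constraining
#' design, so they do not depend on the dummy coding. Species whose absolute
#' score on either of the first two axes exceeds `threshold` are flagged for
#' labelling in triplots.
#'
#' @param rda a `prda` fit.
#' @param scaling 1 or 2 (default 2).
#' @param display site scores from fitted values (`"lc"`, default: the
#'   constrained display) or weighted averages of species (`"wa"`).
#' @param threshold absolute-score labelling threshold (default 0.2).
#' @return list with `sites`, `species`, `centroids` data frames (axis
#'   columns RDA1, RDA2, ...) and `flagged` species names.
#' @export
ordination_scores <- function(rda, scaling = 2, display = "lc",
                              threshold = 0.2) {
  if (!scaling %in% c(1, 2)) stop("scaling must be 1 or 2")
  k <- rda$rank
  lam_rel <- rda$eig / rda$total
  const <- ((rda$n - 1) * rda$total)^(1 / 4)
  sp_scale <- if (scaling == 2) sqrt(lam_rel) else rep(1, k)
  si_scale <- if (scaling == 1) sqrt(lam_rel) else rep(1, k)
  species <- sweep(rda$v, 2, sp_scale, "*") * const
  u_site <- if (display == "wa") {
    sweep(rda$Yr %*% rda$v, 2, rda$d, "/")
  } else rda$u
  sites <- sweep(u_site, 2, si_scale, "*") * const
  ax <- paste0("RDA", seq_len(k))
  dimnames(species) <- list(rda$species, ax)
  dimnames(sites) <- list(rownames(rda$data), ax)
  fac <- names(rda$data)[vapply(rda$data, is.factor, TRUE)]
  fac <- intersect(fac, all.vars(rda$terms))
  cents <- do.call(rbind, lapply(fac, function(f) {
    m <- apply(sites, 2, function(s) tapply(s, rda$data[[f]], mean))
    m <- matrix(m, ncol = k,
                dimnames = list(paste(f, levels(rda$data[[f]]), sep = "."), ax))
    m
  }))
  # interaction (cell) centroids when >1 factor is constrained
  if (length(fac) > 1) {
    cell <- interaction(rda$data[fac], sep = ".")
    cm <- apply(sites, 2, function(s) tapply(s, cell, mean))
    cm <- matrix(cm, ncol = k,
                 dimnames = list(paste0("cell.", levels(cell)), ax))
    cents <- rbind(cents, cm)
  }
  nax <- min(2, k)
  flagged <- rownames(species)[
    apply(abs(species[, seq_len(nax), drop = FALSE]) > threshold, 1, any)]
  list(sites = as.data.frame(sites), species = as.data.frame(species),
       centroids = as.data.frame(cents), flagged = flagged,
       scaling = scaling, threshold = threshold)
}

#' Marginal permutation test for one constraining term
#'
#' Tests the marginal contribution of `term` given all other constraining
#' terms (and the conditioning design): the marginal sum of squares is the
#' difference between the fitted sums of squares of the full constraining
#' design and of the design with the term's columns removed, and the
#' pseudo-F statistic is (SS_term / df_term) / (SS_resid / df_resid). The
#' null distribution is generated by Freedman-Lane permutation: residuals of
#' the reduced model (all other terms) are permuted as whole rows, added back
#' to the reduced-model fit, and the statistic recomputed; by default rows
#' are exchanged freely, or within the blocks of `within` (e.g. trap) for a
#' restricted, repeated-measures scheme. The p-value uses the +1
#' small-sample correction: (# permuted F >= observed F + 1) / (n_perm + 1).
#'
#' @inheritParams partial_rda
#' @param term character, one of the term labels of `terms`
#'   (e.g. `"year:environment"`).
#' @param n_perm number of permutations (study default 999; must be >= 1).
#' @param seed integer seed for the permutation stream.
#' @param within optional factor (length nrow(Y)) restricting permutations to
#'   exchanges within its levels.
#' @return an object of class `prda_test`: term, `F`, `df`, `df_resid`,
#'   `p`, `n_perm`, `seed`, and the permuted statistics.
#' @export
marginal_permutation_test <- function(Y, data, terms, condition = NULL,
                                      term, n_perm = 999, seed = NULL,
                                      within = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X <- design_matrix(terms, data)
  labels <- attr(X, "term_labels")
  if (!term %in% labels)
    stop("term '", term, "' not among: ", paste(labels, collapse = ", "))
  Z <- if (is.null(condition)) matrix(0, n, 0) else design_matrix(condition, data)
  Qz <- ortho_basis(Z)
  Yr <- project_out(scale(Y, center = TRUE, scale = FALSE), Qz)
  Xr <- project_out(X, Qz)
  term_id <- match(term, labels)
  Qfull <- ortho_basis(Xr)
  Qred <- ortho_basis(Xr[, attr(X, "assign") != term_id, drop = FALSE])
  df_term <- ncol(Qfull) - ncol(Qred)
  if (df_term < 1) stop("term '", term, "' is aliased with the other terms")
  df_resid <- n - 1 - ncol(Qz) - ncol(Qfull)
  ss <- function(Q, M) sum((t(Q) %*% M)^2)
  stat <- function(M) {
    ss_full <- ss(Qfull, M)
    ss_term <- ss_full - ss(Qred, M)
    (ss_term / df_term) / ((sum(M^2) - ss_full) / df_resid)
  }
  F_obs <- stat(Yr)
  fit_red <- Qred %*% (t(Qred) %*% Yr)
  E <- Yr - fit_red
  if (!is.null(seed)) set.seed(seed)
  perm_index <- function() {
    if (is.null(within)) return(sample.int(n))
    idx <- seq_len(n)
    for (lv in split(seq_len(n), within)) idx[lv] <- lv[sample.int(length(lv))]
    idx
  }
  F_perm <- vapply(seq_len(n_perm),
                   function(b) stat(fit_red + E[perm_index(), , drop = FALSE]),
                   0)
  p <- (sum(F_perm >= F_obs) + 1) / (n_perm + 1)
  structure(list(term = term, F = F_obs, df = df_term, df_resid = df_resid,
                 p = p, n_perm = n_perm, seed = seed, F_perm = F_perm),
            class = "prda_test")
}

#' @export
print.prda_test <- function(x, ...) {
  cat(sprintf(
    "Marginal permutation test, term '%s': F = %.3f, DF = %d, %d, P = %.4g (%d permutations)\n",
    x$term, x$F, x$df, x$df_resid, x$p, x$n_perm))
  invisible(x)
}

#' Triplot of a partial RDA
#'
#' Site points (open = exposed, filled = shaded when an `environment` factor
#' is present), species arrows for flagged species, and factor-level
#' centroids, on the first two constrained axes.
#'
#' @param x a `prda` fit.
#' @param scaling passed to [ordination_scores()].
#' @param threshold species-label threshold.
#' @param ... passed to [graphics::plot()].
#' @export
plot.prda <- function(x, scaling = 2, threshold = 0.2, ...) {
  if (x$rank < 2) stop("need at least 2 constrained axes to draw a triplot")
  sc <- ordination_scores(x, scaling = scaling, threshold = threshold)
  pr <- 100 * x$eig / x$total
  env <- x$data$environment
  pch <- if (!is.null(env)) ifelse(env == "exposed", 1, 16) else 16
  graphics::plot(sc$sites$RDA1, sc$sites$RDA2, pch = pch, col = "grey50",
                 cex = 0.7, asp = 1,
                 xlab = sprintf("RDA1 (%.1f%%)", pr[1]),
                 ylab = sprintf("RDA2 (%.1f%%)", pr[2]), ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey80")
  fl <- sc$species[sc$flagged, , drop = FALSE]
  if (nrow(fl)) {
    graphics::arrows(0, 0, fl$RDA1, fl$RDA2, length = 0.05, col = "tomato3")
    graphics::text(fl$RDA1 * 1.08, fl$RDA2 * 1.08, rownames(fl),
                   cex = 0.7, col = "tomato4")
  }
  cc <- sc$centroids[grep("^cell\\.", rownames(sc$centroids)), , drop = FALSE]
  if (!nrow(cc)) cc <- sc$centroids
  graphics::points(cc$RDA1, cc$RDA2, pch = 22, bg = "white", cex = 1.4)
  graphics::text(cc$RDA1, cc$RDA2, sub("^cell\\.", "", rownames(cc)),
                 cex = 0.6, pos = 3)
  invisible(sc)
}
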