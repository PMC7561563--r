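#' Ezekiel-adjusted R-squared
#'
#' Bias-corrected explained-variance proportion,
#' 1 - (1 - R2)(n - 1)/(n - m - 1), the adjustment that makes explained
#' fractions comparable across predictor sets with different degrees of
#' freedom in variance partitioning.
#'
#' @param R2 raw proportion of variance explained, in [0, 1].
#' @param n number of samples.
#' @param m number of predictor degrees of freedom (model df excluding the
#'   intercept).
#' @return adjusted R-squared (can be negative).
#' @export
adjusted_r2 <- function(R2, n, m) {
  if (any(R2 < 0 | R2 > 1)) stop("R2 must lie in [0, 1]")
  if (any(n <= m + 1)) stop("adjusted R2 undefined: need n > m + 1")
  1 - (1 - R2) * (n - 1) / (n - m - 1)
}

# raw constrained R2 of centered Y on a design formula (no conditioning);
# returns R2 and the design rank
rda_r2 <- function(Yc, formula, data) {
  X <- design_matrix(formula, data)
  Q <- ortho_basis(X)
  list(R2 = sum((t(Q) %*% Yc)^2) / sum(Yc^2), m = ncol(Q))
}

#' Three-set variance partitioning of a community matrix
#'
#' Partitions the variance of a (Hellinger-transformed) community matrix
#' explained by environment (E), year (Y) and fungal diversity (F) into
#' unique and shared adjusted-R-squared fractions. All seven non-empty
#' predictor subsets are fitted as unconditioned RDAs, each raw R-squared is
#' Ezekiel-adjusted for its design degrees of freedom, and the seven
#' elementary fractions (three unique, three pairwise-shared, one
#' triple-shared) are obtained by inclusion-exclusion, e.g. the unique E
#' fraction is adjR2(E+Y+F) - adjR2(Y+F). Individual shared fractions may be
#' negative; this is a documented property of adjusted-R-squared partitioning
#' and they are reported as computed (truncate only for display). Rows with
#' missing `fungal` are dropped with a warning.
#'
#' @param Y samples x species numeric matrix (Hellinger-transformed counts).
#' @param data data frame aligned with `Y`.
#' @param env,year,fungal one-sided formulas selecting the three predictor
#'   sets from `data`.
#' @return an object of class `varpart3`: `subsets` (raw and adjusted R2 and
#'   df for the 7 subsets), `fractions` (named: unique_E, unique_Y, unique_F,
#'   shared_EY, shared_YF, shared_EF, shared_EYF, residual), `n`.
#' @export
varpart3 <- function(Y, data, env = ~environment, year = ~year,
                     fungal = ~fungal_diversity) {
  Y <- as.matrix(Y)
  used <- unique(unlist(lapply(list(env, year, fungal), all.vars)))
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  if (!all(cc)) {
    warning(sum(!cc), " row(s) with missing predictor values dropped")
    Y <- Y[cc, , drop = FALSE]
    data <- data[cc, , drop = FALSE]
  }
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  join <- function(...) {
    fs <- list(...)
    rhs <- paste(vapply(fs, function(f) deparse(f[[2]]), ""), collapse = " + ")
    stats::as.formula(paste("~", rhs))
  }
  subsets <- list(
    E = env, Y = year, F = fungal,
    EY = join(env, year), EF = join(env, fungal), YF = join(year, fungal),
    EYF = join(env, year, fungal)
  )
  fits <- lapply(subsets, function(f) rda_r2(Yc, f, data))
  m_max <- max(vapply(fits, `[[`, 0, "m"))
  if (n <= m_max + 1)
    stop("too few samples (", n, ") for the largest predictor set (df ",
         m_max, ")")
  tab <- data.frame(
    subset = names(subsets),
    df = vapply(fits, `[[`, 0, "m"),
    R2 = vapply(fits, `[[`, 0, "R2")
  )
  tab$adjR2 <- adjusted_r2(tab$R2, n, tab$df)
  a <- stats::setNames(tab$adjR2, tab$subset)
  # region membership: which elementary fractions each subset union covers
  regions <- c("uE", "uY", "uF", "sEY", "sYF", "sEF", "sEYF")
  cover <- rbind(
    E   = c(1, 0, 0, 1, 0, 1, 1),
    Y   = c(0, 1, 0, 1, 1, 0, 1),
    F   = c(0, 0, 1, 0, 1, 1, 1),
    EY  = c(1, 1, 0, 1, 1, 1, 1),
    EF  = c(1, 0, 1, 1, 1, 1, 1),
    YF  = c(0, 1, 1, 1, 1, 1, 1),
    EYF = c(1, 1, 1, 1, 1, 1, 1)
  )
  colnames(cover) <- regions
  frac <- solve(cover, a[rownames(cover)])
  fractions <- c(unique_E = unname(frac["uE"]), unique_Y = unname(frac["uY"]),
                 unique_F = unname(frac["uF"]), shared_EY = unname(frac["sEY"]),
                 shared_YF = unname(frac["sYF"]), shared_EF = unname(frac["sEF"]),
                 shared_EYF = unname(frac["sEYF"]),
                 residual = unname(1 - a["EYF"]))
  structure(list(subsets = tab, fractions = fractions, n = n,
                 labels = c(E = deparse(env[[2]]), Y = deparse(year[[2]]),
                            F = deparse(fungal[[2]]))),
            class = "varpart3")
}

#' @export
print.varpart3 <- function(x, digits = 3, ...) {
  cat("Variance partitioning over {E = ", x$labels["E"], ", Y = ",
      x$labels["Y"], ", F = ", x$labels["F"], "}, n = ", x$n, "\n", sep = "")
  cat("Subset adjusted R2:\n")
  print(cbind(x$subsets[, c("subset", "df")],
              round(x$subsets[, c("R2", "adjR2")], digits)),
        row.names = FALSE)
  cat("Fractions (adjusted R2; shared fractions may be negative):\n")
  print(round(x$fractions, digits))
  invisible(x)
}

#' Venn-style display of a three-set variance partition
#'
#' Three fixed circles annotated with the unique and shared percentage
#' fractions (negative fractions are truncated at zero for display only, and
#' marked with "<0").
#'
#' @param x a `varpart3` object.
#' @param ... unused.
#' @export
plot.varpart3 <- function(x, ...) {
  f <- x$fractions
  pct <- function(v) if (v < 0) "<0" else sprintf("%.0f%%", 100 * v)
  th <- seq(0, 2 * pi, length.out = 120)
  centers <- rbind(c(-0.5, 0.3), c(0.5, 0.3), c(0, -0.55))
  graphics::plot(NA, xlim = c(-2, 2), ylim = c(-2, 1.7), asp = 1,
                 axes = FALSE, xlab = "", ylab = "")
  for (i in 1:3)
    graphics::lines(centers[i, 1] + cos(th), centers[i, 2] + sin(th))
  lab <- c(paste0("E = ", x$labels["E"]), paste0("Y = ", x$labels["Y"]),
           paste0("F = ", x$labels["F"]))
  graphics::text(c(-1.3, 1.3, 0), c(1.45, 1.45, -1.75), lab)
  graphics::text(-0.9, 0.4, pct(f["unique_E"]))
  graphics::text(0.9, 0.4, pct(f["unique_Y"]))
  graphics::text(0, -0.95, pct(f["unique_F"]))
  graphics::text(0, 0.55, pct(f["shared_EY"]))
  graphics::text(-0.55, -0.35, pct(f["shared_EF"]))
  graphics::text(0.55, -0.35, pct(f["shared_YF"]))
  graphics::text(0, -0.1, pct(f["shared_EYF"]))
  graphics::text(1.6, -1.5, paste0("residual ", pct(f["residual"])))
  invisible(x)
}
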