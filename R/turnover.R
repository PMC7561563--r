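#' Presence histories for one trap
#'
#' @param x a [community_matrix()].
#' @param trap a trap id in `x`.
#' @return logical matrix (species x years): `TRUE` where count > 0.
#' @export
presence_history <- function(x, trap) {
  if (!trap %in% traps(x)) stop("unknown trap: ", trap)
  t(x[trap, , , drop = TRUE] > 0)
}

#' Permanent species gains and losses over one interval
#'
#' A species counts as *gained* at year `t2` only if it was absent in all
#' study years before `t2`; it counts as *lost* at year `t1` only if it is
#' absent in all study years after `t1`. Temporary absences (a species that
#' disappears and later reappears) therefore contribute to neither count.
#' Permanence is assessed within the observation window only, so losses in
#' the final interval are right-censored by design.
#'
#' @param history logical matrix (species x years) of presences for one trap,
#'   as returned by [presence_history()].
#' @param interval integer pair `c(t1, t2)` with `t2 = t1 + 1`.
#' @return named integer vector `c(G = ..., L = ...)`.
#' @examples
#' h <- rbind(A = c(1, 1, 1, 1), B = c(0, 1, 1, 1), C = c(1, 0, 0, 0),
#'            D = c(1, 0, 1, 0), E = c(0, 0, 0, 1)) > 0
#' permanent_gains_losses(h, c(1, 2)) # G = 1 (B), L = 1 (C)
#' permanent_gains_losses(h, c(2, 3)) # G = 0, L = 0 (D merely reappears)
#' @export
permanent_gains_losses <- function(history, interval) {
  history <- as.matrix(history) > 0
  T_ <- ncol(history)
  t1 <- interval[1]; t2 <- interval[2]
  if (t2 != t1 + 1 || t1 < 1 || t2 > T_)
    stop("interval must be (t, t+1) within the study years 1..", T_)
  prior <- rowSums(history[, seq_len(t2 - 1), drop = FALSE]) > 0
  later <- rowSums(history[, seq(t1 + 1, T_), drop = FALSE]) > 0
  c(G = sum(history[, t2] & !prior),
    L = sum(history[, t1] & !later))
}

#' Permanent gain and loss rates per trap and interval
#'
#' For each trap and consecutive-year interval, computes endpoint richness
#' `S_t1`, `S_t2`, the permanent gain and loss counts `G`, `L` (see
#' [permanent_gains_losses()]), and the normalised rates
#' \deqn{G_p = G / \tfrac{1}{2}(S_{t1}+S_{t2}), \qquad
#'       L_p = L / \tfrac{1}{2}(S_{t1}+S_{t2}),}
#' the per-interval colonization and extinction rates relative to the mean
#' size of the existing community. When `S_t1 + S_t2 = 0` the rates are
#' undefined and reported as `NA` (such records are excluded from, not
#' imputed into, downstream model fits). Rates lie in [0, 2] when defined.
#'
#' @param x a [community_matrix()] (already aspen-filtered when used with
#'   host-affinity or guild groups).
#' @param traits a [trait_table()]; may be `NULL` when `group = "all"` and the
#'   matrix needs no subsetting.
#' @param group functional group selector, see [aggregate_group()].
#' @return a `turnover` data frame with one row per trap x interval:
#'   trap, t1, t2, group, S_t1, S_t2, G, L, Gp, Lp.
#' @export
turnover_rates <- function(x, traits = NULL, group = "all") {
  yrs <- study_years(x)
  if (length(yrs) < 2) stop("at least 2 study years are required (no intervals)")
  if (!is.null(traits)) {
    sel <- intersect(species_ids(x), group_species(traits, group))
    x <- structure(x[, , sel, drop = FALSE],
                   year_levels = attr(x, "year_levels"),
                   class = "community_matrix")
  } else if (group != "all") {
    stop("a trait table is required to select group '", group, "'")
  }
  pres <- x > 0
  rich <- apply(pres, c(1, 2), sum)
  recs <- vector("list", length(traps(x)))
  for (i in seq_along(traps(x))) {
    h <- t(pres[i, , , drop = TRUE])
    if (dim(x)[3] == 1L) h <- matrix(pres[i, , 1], nrow = 1)
    gl <- vapply(seq_len(length(yrs) - 1),
                 function(t) permanent_gains_losses(h, c(t, t + 1)),
                 c(G = 0, L = 0))
    s1 <- rich[i, seq_len(length(yrs) - 1)]
    s2 <- rich[i, seq(2, length(yrs))]
    denom <- (s1 + s2) / 2
    recs[[i]] <- data.frame(
      trap = traps(x)[i], t1 = seq_len(length(yrs) - 1),
      t2 = seq(2, length(yrs)), group = group,
      S_t1 = as.integer(s1), S_t2 = as.integer(s2),
      G = as.integer(gl["G", ]), L = as.integer(gl["L", ]),
      Gp = ifelse(denom > 0, gl["G", ] / denom, NA_real_),
      Lp = ifelse(denom > 0, gl["L", ] / denom, NA_real_)
    )
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  structure(out, class = c("turnover", "data.frame"))
}

#' @export
print.turnover <- function(x, ...) {
  cat("Permanent turnover rates:", length(unique(x$trap)), "traps,",
      length(unique(x$t1)), "intervals, group =", x$group[1], "\n")
  und <- sum(is.na(x$Gp))
  if (und) cat(und, "trap-interval(s) with undefined rates (empty community)\n")
  NextMethod()
}

#' Mean gain/loss rates per environment and interval
#'
#' @param object a `turnover` table.
#' @param sites a [site_table()] giving each trap's environment.
#' @param ... unused.
#' @return data frame of mean Gp and Lp (undefined records dropped) per
#'   environment x interval, with the number of defined records.
#' @export
summary.turnover <- function(object, sites = NULL, ...) {
  env <- if (is.null(sites)) rep("all", nrow(object))
         else sites$environment[match(object$trap, sites$trap)]
  ok <- !is.na(object$Gp)
  agg <- stats::aggregate(cbind(Gp, Lp) ~ env + t1,
                          data = cbind(object[ok, ], env = env[ok]), FUN = mean)
  n <- stats::aggregate(list(n = ok[ok]), by = list(env = env[ok], t1 = object$t1[ok]),
                        FUN = length)
  merge(agg, n, by = c("env", "t1"))
}

#' Write a turnover table to CSV
#'
#' Undefined rates are written as empty fields.
#' @param x a `turnover` table.
#' @param path output path.
#' @export
write_turnover <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
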