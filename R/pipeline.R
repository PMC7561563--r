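#' Run the full succession analysis pipeline
#'
#' Orchestrates the complete analysis from raw tables (or a fresh
#' simulation): host-affinity filtering, per-group turnover rates, trajectory
#' models for richness, abundance and gain/loss rates with interaction tests
#' and within-time contrasts, the specialist-vs-generalist early-succession
#' models, the Hellinger + partial RDA ordination with marginal permutation
#' tests and type-II scores, and three-set variance partitioning. All numeric
#' outputs are written to the output directory and are bit-identical across
#' reruns with the same config and seed.
#'
#' @param config a named list, or path to a YAML/JSON file containing one,
#'   with entries:
#'   \describe{
#'     \item{input}{list of `community`, `traits`, `sites` CSV paths, or
#'       omitted to simulate.}
#'     \item{simulate}{list passed to [sim_params()] (used when `input` is
#'       absent).}
#'     \item{seed}{integer; governs simulation and permutations (default 1).}
#'     \item{groups}{character vector of functional groups (default all six).}
#'     \item{n_perm}{permutations for the RDA tests (default 999).}
#'     \item{score_threshold}{species-label threshold (default 0.2).}
#'     \item{contrast_adjust}{p adjustment for within-time contrasts
#'       (default "none").}
#'     \item{random}{random-effect policy for [fit_trajectory()]
#'       (default "auto").}
#'     \item{figures}{write PNG figures (default TRUE).}
#'     \item{out}{output directory (required).}
#'   }
#' @return invisibly, a list with every fitted object and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  if (is.null(config$out)) stop("config$out (output directory) is required")
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  groups <- config$groups %||% c("specialist", "generalist", "fungivore",
                                 "wood_feeder", "predator",
                                 "omnivore_saprophage")
  n_perm <- config$n_perm %||% 999
  thr <- config$score_threshold %||% 0.2
  adjust <- config$contrast_adjust %||% "none"
  random <- config$random %||% "auto"
  figures <- config$figures %||% TRUE

  logf <- file.path(out, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               ..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("woodsucc ", as.character(utils::packageVersion("woodsucc")),
          " | R ", as.character(getRversion()), " | seed ", seed)

  if (!is.null(config$input)) {
    community <- read_community(config$input$community)
    traits <- read_traits(config$input$traits)
    sites <- read_sites(config$input$sites)
    logline("stage input: read ", length(species_ids(community)),
            " species from ", config$input$community)
  } else {
    params <- do.call(sim_params, config$simulate %||% list())
    study <- simulate_study(params, seed = seed)
    community <- study$community
    traits <- study$traits
    sites <- study$sites
    logline("stage simulate: generated study with seed ", seed)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  aspen <- stage("filter", filter_aspen(community, traits))
  logline("stage filter: ", length(species_ids(aspen)), " host-associated of ",
          length(species_ids(community)), " species; ",
          total_abundance(aspen), " individuals retained")

  results <- list(community = aspen, traits = traits, sites = sites)
  results$models <- list()
  for (g in groups) {
    res <- stage(paste0("models[", g, "]"), {
      series <- aggregate_group(aspen, traits, g)
      to <- turnover_rates(aspen, traits, g)
      fits <- list()
      for (resp in c("richness", "abundance", "Gp", "Lp")) {
        src <- if (resp %in% c("richness", "abundance")) series else to
        log_messages <- function(expr) withCallingHandlers(expr,
          message = function(m) {
            logline("models[", g, "/", resp, "]: ", trimws(conditionMessage(m)))
            invokeRestart("muffleMessage")
          })
        fit <- log_messages(
          fit_trajectory(src, sites, response = resp, random = random))
        lrt <- log_messages(interaction_lrt(fit))
        fits[[resp]] <- list(fit = fit, lrt = lrt,
                             contrasts = within_time_contrasts(fit, adjust),
                             predictions = stats::predict(fit))
      }
      list(series = series, turnover = to, fits = fits)
    })
    write_turnover(res$turnover, file.path(out, paste0("turnover_", g, ".csv")))
    report <- lapply(res$fits, function(f) list(
      family = f$fit$family,
      random_structure = f$fit$random_structure,
      coefficients = as.list(glmmTMB::fixef(f$fit$model)$cond),
      lrt = f$lrt[c("chi2", "df", "p")],
      contrasts = f$contrasts,
      predictions = f$predictions))
    jsonlite::write_json(report,
                         file.path(out, paste0("model_report_", g, ".json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (figures) {
      grDevices::png(file.path(out, paste0("trajectories_", g, ".png")),
                     1200, 900, res = 150)
      graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
      for (resp in names(res$fits)) {
        set.seed(seed) # jitter only
        plot(res$fits[[resp]]$fit, main = paste(g, resp))
      }
      grDevices::dev.off()
    }
    results$models[[g]] <- res
    logline("stage models[", g, "]: interaction LRT p (Gp) = ",
            signif(res$fits$Gp$lrt$p, 3))
  }

  results$spec_gen <- stage("specialist_generalist", {
    sp <- aggregate_group(aspen, traits, "specialist")
    ge <- aggregate_group(aspen, traits, "generalist")
    lapply(stats::setNames(c("richness", "abundance"),
                           c("richness", "abundance")),
           function(r) specialist_generalist_model(sp, ge, sites, response = r))
  })
  jsonlite::write_json(
    lapply(results$spec_gen, function(m)
      list(three_way = m$three_way, fold_changes = as.list(m$fold_changes))),
    file.path(out, "spec_gen_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")

  results$ordination <- stage("ordination", {
    smp <- community_to_samples(aspen, sites)
    H <- hellinger(smp$Y)
    rda <- partial_rda(H, smp$data, ~ year * environment, ~landscape)
    tests <- lapply(
      stats::setNames(c("year", "environment", "year:environment"),
                      c("year", "environment", "interaction")),
      function(tm) marginal_permutation_test(
        H, smp$data, ~ year * environment, ~landscape,
        term = tm, n_perm = n_perm, seed = seed))
    scores <- ordination_scores(rda, scaling = 2, threshold = thr)
    list(samples = smp, H = H, rda = rda, tests = tests, scores = scores)
  })
  ordn <- results$ordination
  sc_tab <- do.call(rbind, lapply(c("site", "species", "centroid"),
    function(tp) {
      d <- ordn$scores[[c(site = "sites", species = "species",
                          centroid = "centroids")[tp]]]
      data.frame(entity = rownames(d), type = tp,
                 axis1 = d$RDA1,
                 axis2 = if ("RDA2" %in% names(d)) d$RDA2 else NA_real_,
                 flagged = tp == "species" &
                   rownames(d) %in% ordn$scores$flagged)
    }))
  utils::write.csv(sc_tab, file.path(out, "ordination_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(eigenvalues = ordn$rda$eig,
         eigenvalues_unconstrained = ordn$rda$eig_unconstrained,
         total = ordn$rda$total, R2 = ordn$rda$R2, adjR2 = ordn$rda$adjR2,
         permutation_tests = lapply(ordn$tests, function(t)
           t[c("term", "F", "df", "df_resid", "p", "n_perm", "seed")])),
    file.path(out, "rda_summary.json"), auto_unbox = TRUE, digits = NA)
  logline("stage ordination: R2 = ", signif(ordn$rda$R2, 4),
          ", interaction F = ", signif(ordn$tests$interaction$F, 4),
          ", p = ", signif(ordn$tests$interaction$p, 4))

  results$varpart <- stage("varpart",
    varpart3(ordn$H, ordn$samples$data))
  jsonlite::write_json(
    list(subsets = results$varpart$subsets,
         fractions = as.list(results$varpart$fractions),
         n = results$varpart$n),
    file.path(out, "varpart.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  logline("stage varpart: unique E/Y/F = ",
          paste(signif(results$varpart$fractions[1:3], 3), collapse = "/"))

  if (figures) {
    grDevices::png(file.path(out, "triplot.png"), 1400, 700, res = 150)
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 1, 1))
    plot(ordn$rda, threshold = thr)
    plot(results$varpart)
    grDevices::dev.off()
  }
  logline("pipeline complete")
  invisible(c(results, list(out = out)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
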