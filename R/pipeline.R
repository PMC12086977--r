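# End-to-end orchestration: simulate or ingest a bag table, estimate decay
# rates, test mixture additivity, run concordance analyses, summarize the
# environment, and write a reproducible report bundle.

#' Run configuration for the analysis pipeline
#'
#' @param mode `"simulate"` (generate data with the synthetic module) or
#'   `"analyze"` (read a bag table from `bag_table`).
#' @param out_dir Output directory; created if needed.
#' @param seed Master seed; fixes every random stream of the run.
#' @param bag_table Path to a bag-table CSV (analyze mode).
#' @param moisture_table Optional path to a per-plot moisture summary CSV with
#'   columns `plot`, `mean_swc_pct`, `swc_cv_pct` (analyze mode).
#' @param sim A [synthetic_config()] (simulate mode). Its seed is overridden
#'   by `seed`.
#' @param env A [synthetic_environment_config()].
#' @param time_basis `"years"` or `"gdd"`.
#' @param covariates_on Include plot-level moisture covariates in the fit.
#' @param tie_correction Tie correction for Kendall's W.
#' @param critical_z Critical value for the additivity verdicts.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "analyze"),
                       out_dir = tempfile("litterdecay_run_"),
                       seed = 1L,
                       bag_table = NULL, moisture_table = NULL,
                       sim = synthetic_config(),
                       env = synthetic_environment_config(),
                       time_basis = c("years", "gdd"),
                       covariates_on = FALSE,
                       tie_correction = TRUE,
                       critical_z = 1.96) {
  mode <- match.arg(mode)
  time_basis <- match.arg(time_basis)
  if (mode == "analyze" && is.null(bag_table)) {
    stop_domain("analyze mode requires 'bag_table'")
  }
  structure(list(
    mode = mode, out_dir = out_dir, seed = as.integer(seed),
    bag_table = bag_table, moisture_table = moisture_table,
    sim = sim, env = env, time_basis = time_basis,
    covariates_on = covariates_on, tie_correction = tie_correction,
    critical_z = critical_z
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirror the arguments of [run_config()]; `sim:` and `env:`
#' sub-maps mirror [synthetic_config()] / [synthetic_environment_config()]
#' fields (the true-k table as a `cell: k` map under `sim: true_k`).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$true_k)) {
    tk <- treatment_cells()
    tk$k <- as.numeric(unlist(sim_args$true_k)[tk$cell])
    sim_args$true_k <- tk
  }
  if (!is.null(sim_args$mesh_effects)) {
    sim_args$mesh_effects <- unlist(sim_args$mesh_effects)
  }
  env_args <- y$env %||% list()
  for (f in c("swc_mean_by_exclusion", "swc_cv_by_exclusion")) {
    if (!is.null(env_args[[f]])) env_args[[f]] <- unlist(env_args[[f]])
  }
  if (!is.null(env_args$grid_shape)) {
    env_args$grid_shape <- as.integer(unlist(env_args$grid_shape))
  }
  args <- y[setdiff(names(y), c("sim", "env"))]
  args$sim <- do.call(synthetic_config, sim_args)
  args$env <- do.call(synthetic_environment_config, env_args)
  do.call(run_config, args)
}

pipeline_log <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
}

#' Run the full litterbag analysis pipeline
#'
#' Executes the stages in order (data, instantaneous k, multigroup fit,
#' additivity, concordance, environment summary), logging each, and writes a
#' report bundle to `config$out_dir`: the bag table, per-bag rates, slope and
#' additivity tables (CSV), concordance statistics (JSON), an environment
#' summary, a human-readable `summary.txt` (values rounded to 3 decimals for
#' rates and 1 for percentages; all CSV/JSON values at full precision), and a
#' `manifest.json` capturing config, seed and package version. A failing stage
#' aborts the run with the stage named and removes partial outputs.
#'
#' @param config A [run_config()].
#' @return The report bundle, invisibly: list with `bags`, `instantaneous`,
#'   `fit`, `additivity`, `concordance`, `environment`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  written <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  result <- tryCatch({
    # -- data ---------------------------------------------------------------
    stage <- "data"
    bags <- if (config$mode == "simulate") {
      sim <- config$sim
      sim$seed <- substream_seed(config$seed, 10L)
      generate_bags(sim)
    } else {
      read_bag_table(config$bag_table)
    }
    pipeline_log(log_path, stage, sprintf("%d bag records", nrow(bags)))
    emit("bags.csv", function(p) write_bag_table(bags, p))

    # -- instantaneous k ----------------------------------------------------
    stage <- "instantaneous_k"
    inst <- bag_instantaneous_k(bags)
    pipeline_log(log_path, stage,
                 sprintf("mean whole-bag k = %.3f year^-1", mean(inst$k)))
    emit("instantaneous_k.csv", function(p)
      utils::write.csv(inst, p, row.names = FALSE, na = ""))

    # -- environment (needed before the fit when covariates are on) --------
    stage <- "environment"
    env_summary <- pipeline_environment(config, bags, log_path)
    emit("environment_summary.csv", function(p)
      utils::write.csv(env_summary$plots, p, row.names = FALSE, na = ""))

    # -- multigroup fit -----------------------------------------------------
    stage <- "fit"
    covariates <- NULL
    if (config$covariates_on && !is.null(env_summary$plots)) {
      covariates <- env_summary$plots[, c("plot", "mean_swc_pct", "swc_cv_pct")]
    }
    fit <- fit_multigroup(bags, time_basis = config$time_basis,
                          covariates = covariates)
    pipeline_log(log_path, stage, sprintf(
      "intercept %.3f, R^2 %.3f over %d cells",
      fit$intercept$estimate, fit$r_squared, nrow(fit$slopes)))
    emit("fit_slopes.csv", function(p)
      utils::write.csv(fit$slopes, p, row.names = FALSE))
    emit("fit_summary.json", function(p) jsonlite::write_json(
      list(intercept = fit$intercept, r_squared = fit$r_squared,
           adj_r_squared = fit$adj_r_squared, n = fit$n,
           time_basis = fit$time_basis,
           covariates = fit$covariates),
      p, auto_unbox = TRUE, digits = NA, null = "null"))

    # -- additivity ---------------------------------------------------------
    stage <- "additivity"
    addv <- test_additivity(fit, critical = config$critical_z)
    pipeline_log(log_path, stage, sprintf(
      "%d combination(s) tested; verdicts: %s", nrow(addv),
      paste(addv$verdict, collapse = ", ")))
    emit("additivity.csv", function(p)
      utils::write.csv(addv, p, row.names = FALSE))

    # -- concordance --------------------------------------------------------
    stage <- "concordance"
    date_tab <- rank_block_table(inst, inst$percent_remaining, "removal_day")
    w_dates <- kendalls_w(date_tab, tie_correction = config$tie_correction)
    last_day <- max(inst$removal_day)
    at_end <- inst[inst$removal_day == last_day, ]
    mesh_tab <- rank_block_table(at_end, at_end$k, "mesh")
    w_mesh <- kendalls_w(mesh_tab, tie_correction = config$tie_correction)
    loss_end <- tapply(
      100 - at_end$percent_remaining,
      cell_label(at_end$proliferation, at_end$exclusion, at_end$species), mean)
    rho <- spearman_rho(as.numeric(loss_end[fit$slopes$cell]),
                        fit$slopes$estimate)
    pipeline_log(log_path, stage, sprintf(
      "W(dates) = %.3f, W(mesh) = %.3f, rho(loss, slope) = %.3f",
      w_dates$w, w_mesh$w, rho))
    conc <- list(
      removal_dates = list(w = w_dates$w, chi_squared = w_dates$chi_squared,
                           df = w_dates$df, p_value = w_dates$p_value),
      mesh_sizes = list(w = w_mesh$w, chi_squared = w_mesh$chi_squared,
                        df = w_mesh$df, p_value = w_mesh$p_value),
      spearman_loss_vs_slope = rho
    )
    emit("concordance.json", function(p)
      jsonlite::write_json(conc, p, auto_unbox = TRUE, digits = NA))

    # -- report -------------------------------------------------------------
    stage <- "report"
    emit("summary.txt", function(p)
      write_pipeline_summary(p, bags, fit, addv, conc, env_summary,
                             config$critical_z))
    emit("manifest.json", function(p) jsonlite::write_json(
      list(package = "litterdecay",
           version = as.character(utils::packageVersion("litterdecay")),
           seed = config$seed, mode = config$mode,
           time_basis = config$time_basis,
           covariates_on = config$covariates_on,
           critical_z = config$critical_z,
           n_bags = nrow(bags)),
      p, auto_unbox = TRUE, digits = NA))
    pipeline_log(log_path, stage, "report bundle complete")

    list(bags = bags, instantaneous = inst, fit = fit, additivity = addv,
         concordance = conc, environment = env_summary,
         files = c(written, log_path))
  }, error = function(e) {
    unlink(written)
    stop_domain(sprintf("pipeline failed at stage '%s': %s",
                        stage, conditionMessage(e)))
  })
  invisible(result)
}

pipeline_environment <- function(config, bags, log_path) {
  if (config$mode == "analyze") {
    if (is.null(config$moisture_table)) {
      pipeline_log(log_path, "environment", "no moisture table supplied")
      return(list(plots = NULL, by_exclusion = NULL))
    }
    plots <- utils::read.csv(config$moisture_table, stringsAsFactors = FALSE)
    needed <- c("plot", "mean_swc_pct", "swc_cv_pct")
    if (!all(needed %in% names(plots))) {
      stop_domain("moisture table schema error: needs columns ",
                  paste(needed, collapse = ", "))
    }
  } else {
    plot_tab <- unique(bags[, c("site", "plot", "proliferation", "exclusion")])
    grids <- lapply(seq_len(nrow(plot_tab)), function(i) {
      generate_moisture_grid(
        config$env, plot_tab$exclusion[i],
        seed = substream_seed(config$seed, 100L + i))
    })
    plots <- cbind(plot_tab, data.frame(
      mean_swc_pct = vapply(grids, `[[`, numeric(1), "mean"),
      swc_cv_pct = vapply(grids, `[[`, numeric(1), "cv_percent")
    ))
  }
  by_excl <- NULL
  if ("exclusion" %in% names(plots)) {
    by_excl <- merge(
      group_means(plots$mean_swc_pct, plots$exclusion),
      group_means(plots$swc_cv_pct, plots$exclusion),
      by = c("group"), suffixes = c("_swc", "_cv"))
  }
  pipeline_log(log_path, "environment",
               sprintf("%d plot summaries", nrow(plots)))
  list(plots = plots, by_exclusion = by_excl)
}

write_pipeline_summary <- function(path, bags, fit, addv, conc, env_summary,
                                   critical_z = 1.96) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(sprintf(...), "\n", file = con, sep = "")
  w("Litterbag decay analysis summary")
  w("================================")
  w("Bags analysed: %d", nrow(bags))
  w("")
  w("Multigroup decay fit (%s basis): intercept %.3f ln%% (%.1f%%), R2 %.3f (adj %.3f)",
    fit$time_basis, fit$intercept$estimate, exp(fit$intercept$estimate),
    fit$r_squared, fit$adj_r_squared)
  w("%-16s %8s %8s %8s", "cell", "k", "lower", "upper")
  for (i in seq_len(nrow(fit$slopes))) {
    w("%-16s %8.3f %8.3f %8.3f", fit$slopes$cell[i],
      fit$slopes$estimate[i], fit$slopes$lower[i], fit$slopes$upper[i])
  }
  w("")
  w("Mixture additivity (critical |z| = %.2f):", critical_z)
  for (i in seq_len(nrow(addv))) {
    w("  prolif=%s excl=%s: observed %.3f vs expected %.3f, z = %.2f -> %s",
      addv$proliferation[i], addv$exclusion[i], addv$observed_k[i],
      addv$expected_k[i], addv$z[i], addv$verdict[i])
  }
  w("")
  w("Concordance: W over removal dates %.3f (p %.3g); W over mesh sizes %.3f (p %.3g)",
    conc$removal_dates$w, conc$removal_dates$p_value,
    conc$mesh_sizes$w, conc$mesh_sizes$p_value)
  w("Spearman rho, 90-day mass loss vs fitted slope: %.3f",
    conc$spearman_loss_vs_slope)
  if (!is.null(env_summary$by_exclusion)) {
    w("")
    w("Soil moisture by exclusion level (plot means):")
    be <- env_summary$by_exclusion
    for (i in seq_len(nrow(be))) {
      w("  exclusion=%s: mean SWC %.1f%%, mean CV %.1f%%",
        be$group[i], be$mean_swc[i], be$mean_cv[i])
    }
  }
  invisible(path)
}
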