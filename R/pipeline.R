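#' Configuration of a full analysis run
#'
#' Collects every knob of [run_pipeline()] in one validated object so a
#' study run is reproducible from a single artifact. The same structure can
#' be read from a YAML file with [read_run_config()].
#'
#' @param input Path to the trial CSV ([read_trials()] format).
#' @param out_dir Output directory (created if needed).
#' @param column_map Named character vector for [read_trials()].
#' @param rules A [filter_rules()] object.
#' @param env_input Optional path to an environment CSV for
#'   [ordinate_environment()].
#' @param min_cells Passed to [assign_home()].
#' @param n_boot Bootstrap refits for [yearly_hfa()].
#' @param n_perm Permutation replicates for [null_distribution()].
#' @param probs Envelope probabilities for [null_summary()].
#' @param seed Master seed, recorded in every output artifact.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, out_dir,
                       column_map = character(),
                       rules = filter_rules(),
                       env_input = NULL,
                       min_cells = 1L, n_boot = 200L, n_perm = 999L,
                       probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                       seed = 1L) {
  structure(list(input = input, out_dir = out_dir, column_map = column_map,
                 rules = rules, env_input = env_input,
                 min_cells = as.integer(min_cells),
                 n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
                 probs = as.numeric(probs), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Flat YAML keys mirror the [run_config()] arguments; `rules` is a nested
#' block with the [filter_rules()] fields.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  rules <- do.call(filter_rules, as.list(y$rules))
  args <- y[setdiff(names(y), "rules")]
  args$rules <- rules
  if (!is.null(args$column_map)) args$column_map <- unlist(args$column_map)
  do.call(run_config, args)
}

#' Run the full home-field advantage analysis
#'
#' End-to-end orchestration: read and filter the trials, standardize within
#' cells, assign homes, fit the full and control yield models, partition
#' variance (with and without the home term), estimate the yearly advantage
#' and its trend, the mean-yield trend, the stability trade-off, and the
#' permutation null with its envelopes. Tables are written as TSV and every
#' scalar lands in a JSON run summary together with the master seed, the
#' package version and input file digests. Any stage failure aborts the run
#' with the stage name; partial outputs are removed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every intermediate object and `summary`
#'   (the JSON summary as a list).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) stop("config must be a run_config",
                                            call. = FALSE)
  if (!file.exists(config$input)) {
    stop("input path does not exist: ", config$input, call. = FALSE)
  }
  if (!is.null(config$env_input) && !file.exists(config$env_input)) {
    stop("env_input path does not exist: ", config$env_input, call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    write.table(obj, path, sep = "\t", row.names = FALSE, quote = FALSE)
    written <<- c(written, path)
    path
  }
  say <- function(...) if (!quiet) message(...)
  stage <- "setup"
  result <- tryCatch({
    stage <- "read_trials"
    trials <- read_trials(config$input, config$column_map)
    stage <- "filter_trials"
    filtered <- filter_trials(trials, config$rules, quiet = quiet)
    if (nrow(filtered) == 0L) stop("no records left after filtering")
    say(sprintf("analyzing %d records: %d varieties, %d sites, %d site-years",
                nrow(filtered), length(unique(filtered$variety)),
                length(unique(filtered$site)),
                length(unique(cell_key(filtered)))))
    stage <- "relative_yields"
    rel <- relative_yields(filtered)
    stage <- "assign_home"
    home <- assign_home(rel, config$min_cells)
    emit(home$home, "home_map.tsv")
    stage <- "fit_hfa"
    full <- fit_hfa(filtered, home, include_home = TRUE)
    control <- fit_hfa(filtered, home, include_home = FALSE)
    cmp <- compare_models(full, control)
    share <- home_share_of_residual(filtered, home)
    coefs <- data.frame(term = names(full$coefficients),
                        estimate = unname(full$coefficients),
                        se = unname(full$se))
    emit(coefs, "hfa_coefficients.tsv")
    stage <- "variance_partition"
    vp0 <- variance_partition(filtered)
    vp1 <- variance_partition(filtered, home, include_home = TRUE)
    emit(vp0, "variance_partition.tsv")
    emit(vp1, "variance_partition_with_home.tsv")
    stage <- "yearly_hfa"
    yearly <- yearly_hfa(filtered, home, n_boot = config$n_boot,
                         seed = config$seed)
    emit(as.data.frame(yearly), "yearly_hfa.tsv")
    stage <- "trend_regression"
    hfa_trend <- trend_regression(data.frame(year = yearly$year,
                                             value = yearly$estimate))
    mean_yield <- aggregate(yield ~ year, filtered, mean)
    yield_trend <- trend_regression(data.frame(year = mean_yield$year,
                                               value = mean_yield$yield))
    stage <- "stability_regression"
    stab <- stability_regression(filtered, home)
    stage <- "null_distribution"
    nd <- null_distribution(filtered, n_perm = config$n_perm, n_boot = 0L,
                            seed = config$seed, min_cells = config$min_cells)
    ns <- NULL
    if (config$n_perm > 0L) {
      ns <- null_summary(nd, probs = config$probs, observed = yearly)
      draws_long <- data.frame(
        year = rep(nd$years, each = nd$n_perm),
        replicate = rep(seq_len(nd$n_perm), length(nd$years)),
        estimate = as.vector(nd$draws))
      emit(draws_long, "null_draws.tsv")
      emit(ns$quantiles, "null_summary.tsv")
      emit(ns$tails, "null_tails.tsv")
    }
    ord <- NULL
    if (!is.null(config$env_input)) {
      stage <- "ordinate_environment"
      ord <- ordinate_environment(read_env_table(config$env_input))
      emit(data.frame(id = rownames(ord$scores), ord$scores), "env_scores.tsv")
      emit(data.frame(variable = rownames(ord$loadings), ord$loadings),
           "env_loadings.tsv")
    }
    stage <- "summary"
    shares <- setNames(as.list(vp0$share), paste0("share_", gsub(":", "_", vp0$term)))
    summary <- c(list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("homefield")),
      input = config$input,
      input_md5 = unname(tools::md5sum(config$input)),
      n_records = nrow(filtered),
      n_varieties = length(unique(filtered$variety)),
      n_sites = length(unique(filtered$site)),
      n_site_years = length(unique(cell_key(filtered))),
      mean_yield = mean(filtered$yield),
      hfa_estimate = full$hfa,
      hfa_se_model = full$hfa_se,
      hfa_pct_of_mean = 100 * full$hfa / mean(filtered$yield),
      aic_full = full$aic, aic_control = control$aic,
      bic_full = full$bic, bic_control = control$bic,
      delta_aic = cmp$delta_aic, delta_bic = cmp$delta_bic,
      home_share_of_residual = share$share_residual,
      home_share_of_total = share$share_total),
      shares,
      list(
        hfa_trend_slope = hfa_trend$slope, hfa_trend_adj_r2 = hfa_trend$adj_r2,
        hfa_trend_p = hfa_trend$p_slope,
        yield_trend_slope = yield_trend$slope,
        yield_trend_adj_r2 = yield_trend$adj_r2,
        yield_trend_p = yield_trend$p_slope,
        stability_slope = stab$slope, stability_r2 = stab$r2,
        n_perm = config$n_perm))
    if (!is.null(ord)) {
      summary$env_prop_var_pc1_4 <- sum(ord$prop_var[seq_len(min(4, length(ord$prop_var)))])
    }
    json_path <- file.path(config$out_dir, "run_summary.json")
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, json_path)
    list(trials = trials, filtered = filtered, home = home, full = full,
         control = control, comparison = cmp, home_share = share,
         variance_partition = vp0, variance_partition_with_home = vp1,
         yearly = yearly, hfa_trend = hfa_trend, yield_trend = yield_trend,
         stability = stab, null = nd, null_summary = ns, ordination = ord,
         summary = summary)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}
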