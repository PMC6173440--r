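#' Plain-text dataset directory
#'
#' `write_dataset()` stores a named numeric matrix as a tab-separated file
#' inside a dataset directory and records it in the directory's JSON
#' manifest; `read_dataset()` reads one back by name. The directory is the
#' package's interchange container: every dataset is a human-inspectable
#' TSV, and `manifest.json` lists names, dimensions, and content hashes.
#'
#' @param dir dataset directory (created if needed).
#' @param name dataset name (file stem).
#' @param x numeric matrix (or vector, stored as one row).
#' @return `write_dataset()` returns the file path invisibly;
#'   `read_dataset()` returns a matrix.
#' @export
write_dataset <- function(dir, name, x) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  mpath <- file.path(dir, "manifest.json")
  man <- if (file.exists(mpath))
    jsonlite::read_json(mpath, simplifyVector = FALSE) else list()
  man[[name]] <- list(file = basename(path), nrow = nrow(x), ncol = ncol(x),
                      md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(man, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  if (!file.exists(path)) stop("no dataset '", name, "' in ", dir)
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

# full default configuration; user keys are validated against this tree
default_config <- function() {
  list(
    seed = 1,
    output_dir = "netfluct_out",
    stages = c("synth", "simulate", "analyze"),
    connectome = list(n_nodes = 40, n_modules = 4, intra_density = 0.5,
                      inter_density = 0.1, weight_meanlog = 0,
                      weight_sdlog = 1),
    reference_bold = list(generate = FALSE, n_timepoints = 600,
                          tr_seconds = 0.72, observation_noise_sd = 0.2,
                          segregation_strength = 0.55),
    simulation = list(preset = "reduced", coupling = 30, mean_delay_ms = 10),
    analysis = list(cart_restarts = 20, kmeans_restarts = 50),
    search = list(coupling_values = c(20, 30, 40),
                  mean_delay_values_ms = c(6, 10, 14),
                  n_samples_stage1 = 2, n_samples_stage2 = 2),
    surrogate = list(n_surrogates = 3, n_samples = 2)
  )
}

#' Experiment configuration
#'
#' Loads a YAML file (or takes a list), validates every key against the
#' known configuration tree (unknown keys are rejected), and fills missing
#' values with defaults.
#'
#' @param x path to a YAML file, a list, or `NULL` for pure defaults.
#' @return An `experiment_config` list with all defaults materialized.
#' @export
experiment_config <- function(x = NULL) {
  user <- if (is.null(x)) list()
          else if (is.character(x)) yaml::read_yaml(x)
          else if (is.list(x)) x
          else stop("config must be a file path or a list")
  cfg <- merge_config(default_config(), user, path = "")
  structure(cfg, class = "experiment_config")
}

merge_config <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) stop("config key ", k, " must be a mapping")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

log_line <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(...)))
}

#' Run an end-to-end experiment
#'
#' Executes the requested stages in dependency order inside the configured
#' output directory: `synth` (generate the connectome and, optionally,
#' reference BOLD with planted states), `simulate` (one modeled BOLD sample
#' at the configured operating point), `analyze` (long/time-resolved FC,
#' FCD, cartography, state estimation, transition statistics), `search`
#' (reduced two-stage grid search against self-generated reference), and
#' `surrogate` (fluctuation ratios on rewired connectomes). Writes a
#' resolved copy of the configuration and a manifest listing every output
#' file with its MD5 hash and the seeds used.
#'
#' @param config an [experiment_config()] (or something accepted by it).
#' @return The manifest, invisibly: list with `files` (data frame of path,
#'   md5), `seed`, `stages`.
#' @export
run_experiment <- function(config = experiment_config()) {
  if (!inherits(config, "experiment_config"))
    config <- experiment_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(out, "resolved_config.yaml"))
  stages <- config$stages
  valid <- c("synth", "simulate", "analyze", "search", "surrogate")
  if (length(setdiff(stages, valid)) > 0)
    stop("unknown stage(s): ", paste(setdiff(stages, valid), collapse = ", "))
  needs <- list(simulate = "synth", analyze = "simulate",
                search = "synth", surrogate = "synth")
  for (s in intersect(names(needs), stages))
    if (!needs[[s]] %in% stages)
      stop("stage '", s, "' requires stage '", needs[[s]], "' in the config")

  opts <- model_opts(config$simulation$preset)
  sc <- NULL; bold <- NULL

  if ("synth" %in% stages) {
    log_line("synth", "generating connectome (seed %d)", config$seed)
    cc <- config$connectome
    spec <- synthetic_connectome_spec(
      n_nodes = cc$n_nodes, n_modules = cc$n_modules,
      intra_density = cc$intra_density, inter_density = cc$inter_density,
      weight_lognormal_params = c(cc$weight_meanlog, cc$weight_sdlog),
      seed = config$seed)
    sc <- generate_connectome(spec)
    write_connectome(sc, file.path(out, "connectome"))
    if (isTRUE(config$reference_bold$generate)) {
      rb <- config$reference_bold
      bspec <- synthetic_bold_spec(
        n_nodes = cc$n_nodes, n_timepoints = rb$n_timepoints,
        tr_seconds = rb$tr_seconds,
        observation_noise_sd = rb$observation_noise_sd,
        segregation_strength = rb$segregation_strength,
        seed = config$seed + 1)
      ref <- generate_state_bold(bspec)
      write_dataset(file.path(out, "reference"), "bold", ref$bold$signal)
      writeLines(ref$true_states,
                 file.path(out, "reference", "true_states.txt"))
    }
  }

  if ("simulate" %in% stages) {
    sim <- config$simulation
    log_line("simulate", "k = %g, mean delay = %g ms, seed %d",
             sim$coupling, sim$mean_delay_ms, config$seed)
    samp <- model_bold_sample(sc, sim$coupling, sim$mean_delay_ms,
                              seed = config$seed, opts = opts)
    bold <- samp$bold
    write_dataset(file.path(out, "simulation"), "bold", bold$signal)
    write_dataset(file.path(out, "simulation"), "order_parameter",
                  samp$order$magnitude)
    write_dataset(file.path(out, "simulation"), "synchrony_metastability",
                  c(samp$order$synchrony, samp$order$metastability))
  }

  if ("analyze" %in% stages) {
    log_line("analyze", "FC, cartography, states")
    an <- config$analysis
    fc <- long_timescale_fc(bold)
    write_dataset(file.path(out, "analysis"), "fc_long", fc$values)
    trfc <- time_resolved_fc(bold, opts$window)
    write_dataset(file.path(out, "analysis"), "fcd",
                  fcd_distribution(trfc)$correlations)
    prof <- cartography(trfc, n_restarts = an$cart_restarts,
                        seed = config$seed)
    write_dataset(file.path(out, "analysis"), "modularity", prof$modularity)
    write_dataset(file.path(out, "analysis"), "participation",
                  prof$participation)
    write_dataset(file.path(out, "analysis"), "zscores", prof$zscores)
    hist <- joint_histogram(prof)
    states <- estimate_states(hist, rowMeans(prof$participation),
                              restarts = an$kmeans_restarts,
                              seed = config$seed)
    writeLines(as.character(states$labels),
               file.path(out, "analysis", "states.txt"))
    ts <- transition_stats(states, step_seconds = prof$step_seconds)
    write_dataset(file.path(out, "analysis"), "transition_matrix",
                  ts$transition_matrix)
    write_dataset(file.path(out, "analysis"), "dwell_seconds",
                  ts$mean_dwell_seconds)
  }

  if ("search" %in% stages) {
    se <- config$search
    log_line("search", "%d x %d grid", length(se$coupling_values),
             length(se$mean_delay_values_ms))
    sim <- config$simulation
    refruns <- lapply(seq_len(2), function(i)
      model_bold_sample(sc, sim$coupling, sim$mean_delay_ms,
                        seed = config$seed + 100 + i, opts = opts)$bold)
    ref <- reference_summaries(refruns, opts$window,
                               cart_restarts = config$analysis$cart_restarts,
                               seed = config$seed)
    grid <- parameter_grid(se$coupling_values, se$mean_delay_values_ms)
    res <- run_grid(sc, grid, ref, n_samples_stage1 = se$n_samples_stage1,
                    n_samples_stage2 = se$n_samples_stage2,
                    seed = config$seed, opts = opts,
                    cart_restarts = config$analysis$cart_restarts)
    utils::write.table(res$stage1, file.path(out, "search_stage1.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$stage2))
      utils::write.table(res$stage2, file.path(out, "search_stage2.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("surrogate" %in% stages) {
    su <- config$surrogate
    sim <- config$simulation
    log_line("surrogate", "%d surrogates", su$n_surrogates)
    refruns <- lapply(seq_len(2), function(i)
      model_bold_sample(sc, sim$coupling, sim$mean_delay_ms,
                        seed = config$seed + 200 + i, opts = opts)$bold)
    ref <- reference_summaries(refruns, opts$window,
                               cart_restarts = config$analysis$cart_restarts,
                               seed = config$seed)
    tab <- surrogate_fluctuation_ratios(
      sc, sim$coupling, sim$mean_delay_ms, ref,
      n_surrogates = su$n_surrogates, n_samples = su$n_samples,
      seed = config$seed, opts = opts,
      cart_restarts = config$analysis$cart_restarts)
    utils::write.table(tab, file.path(out, "surrogate_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  manifest <- list(seed = config$seed, stages = stages,
                   files = data.frame(path = files,
                                      md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Command-line dispatcher
#'
#' Thin entry point used by the `netfluct` Rscript wrapper:
#' `netfluct <synth|simulate|analyze|search|surrogate> --config <file>
#' [--seed N] [--out DIR]`. Each subcommand runs the corresponding stage
#' plus its dependencies.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status: 0 success, 2 validation error, 1 runtime
#'   error.
#' @export
netfluct_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stage_chains <- list(synth = "synth",
                       simulate = c("synth", "simulate"),
                       analyze = c("synth", "simulate", "analyze"),
                       search = c("synth", "search"),
                       surrogate = c("synth", "surrogate"))
  if (length(args) < 1 || !args[1] %in% names(stage_chains)) {
    message("usage: netfluct <synth|simulate|analyze|search|surrogate> ",
            "[--config FILE] [--seed N] [--out DIR]")
    return(2L)
  }
  get_opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else NULL
  }
  cfg <- tryCatch({
    cfg <- experiment_config(get_opt("--config"))
    if (!is.null(get_opt("--seed"))) cfg$seed <- as.integer(get_opt("--seed"))
    if (!is.null(get_opt("--out"))) cfg$output_dir <- get_opt("--out")
    cfg$stages <- stage_chains[[args[1]]]
    cfg
  }, error = function(e) {
    message("configuration error: ", conditionMessage(e))
    NULL
  })
  if (is.null(cfg)) return(2L)
  tryCatch({
    run_experiment(cfg)
    0L
  }, error = function(e) {
    message("runtime error: ", conditionMessage(e))
    1L
  })
}
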