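#' Run a multi-stage analysis pipeline
#'
#' Orchestrates the package's stages from a single configuration (a list or a
#' YAML file): synthetic-data generation, trajectory binding/orientation
#' analysis, Kir decay-rate estimation, off-sensing charge integration and
#' F-V Boltzmann fitting. The configuration is validated before any stage
#' runs; every stage writes its result as TSV into the output directory, the
#' resolved configuration is serialized alongside, and summary report tables
#' in the style of the simulation summary ("table1": one row per trajectory
#' with the three time-fraction columns) and the F-V fit summary ("table2":
#' one row per Boltzmann component) are emitted. Reruns with the same
#' configuration and seed are identical.
#'
#' Supported stage types (each stage is a named list with a `type` field):
#'
#' * `simulate_trajectory` — params `n_frames`, `f_pd`, `f_c2`,
#'   `f_productive`, optional `resolution`, `bilayer`, `jitter_sd_nm`,
#'   `schedule` (`"block"` or `"telegraph"`).
#' * `traj_analyze` — `input` (name of a `simulate_trajectory` stage) or
#'   `path` (trajectory CSV), plus `resolution`, `bilayer`.
#' * `kir_activity` — `path` (recording CSV with `episode`, `time_ms`,
#'   `current_uA`) or `simulate` (params for [sim_kir_recording()]), plus
#'   `depol_ms`, optional `plateau` (`"free"`/`"zero"`).
#' * `sensing_charge` — `simulate` (params for [sim_sensing_sweeps()]) or
#'   `path`/`pn_path` CSVs plus `step_onset_ms`, `pn_order`.
#' * `fv_fit` — `path` (CSV with `v_mV`, `f`) or `simulate` (params for
#'   [sim_fv_dataset()]), and `components` (1, 2 or `"auto"`).
#'
#' @param config A list or path to a YAML file.
#' @return A run report (list of class `vsp_run_report`): per-stage status and
#'   output paths, the report tables, and the output directory. Stage errors
#'   are recorded in the report, which then carries `success = FALSE`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("config file '%s' does not exist", config),
        class = "vsp_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  config <- validate_run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))

  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character()
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
  }

  results <- list()
  statuses <- list()
  table1 <- list()
  table2 <- list()
  base_seed <- config$seed %||% 1

  for (i in seq_along(config$stages)) {
    name <- names(config$stages)[i]
    stage <- config$stages[[i]]
    seed_i <- (base_seed + 1000 * i) %% .Machine$integer.max
    t0 <- Sys.time()
    res <- tryCatch({
      out <- run_stage(stage, name, results, seed_i)
      if (!is.null(out$table)) {
        tsv <- file.path(out_dir, paste0(name, ".tsv"))
        write.table(out$table, tsv, sep = "\t", row.names = FALSE,
          quote = FALSE)
        out$path <- tsv
      }
      if (identical(stage$type, "traj_analyze")) {
        res_lab <- stage$resolution %||% "at"
        bil_lab <- stage$bilayer %||% "popc"
        table1[[name]] <- dplyr::bind_cols(
          tibble(stage = name, resolution = res_lab, bilayer = bil_lab),
          out$summary)
      }
      if (identical(stage$type, "fv_fit")) {
        table2[[name]] <- dplyr::bind_cols(tibble(stage = name), out$summary)
      }
      log_msg("stage '%s' (%s) ok in %.2f s", name, stage$type,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
      out
    }, error = function(e) {
      log_msg("stage '%s' (%s) FAILED: %s", name, stage$type,
        conditionMessage(e))
      structure(list(error = conditionMessage(e)), class = "vsp_stage_error")
    })
    results[[name]] <- res
    statuses[[name]] <- !inherits(res, "vsp_stage_error")
  }

  table1 <- if (length(table1)) dplyr::bind_rows(table1) else NULL
  table2 <- if (length(table2)) dplyr::bind_rows(table2) else NULL
  if (!is.null(table1)) {
    write.csv(table1, file.path(out_dir, "table1_binding_fractions.csv"),
      row.names = FALSE)
  }
  if (!is.null(table2)) {
    write.csv(table2, file.path(out_dir, "table2_boltzmann_fits.csv"),
      row.names = FALSE)
  }
  writeLines(log_lines, log_path)

  structure(list(
    success = all(unlist(statuses)),
    stages = statuses,
    results = results,
    table1 = table1, table2 = table2,
    output_dir = out_dir
  ), class = "vsp_run_report")
}

#' @export
print.vsp_run_report <- function(x, ...) {
  cat(sprintf("<vsp_run_report> %s; output: %s\n",
    if (x$success) "all stages ok" else "FAILURES", x$output_dir))
  for (n in names(x$stages)) {
    cat(sprintf("  %s: %s\n", n, if (x$stages[[n]]) "ok" else "failed"))
  }
  invisible(x)
}

validate_run_config <- function(config) {
  if (!is.list(config)) abort("config must be a list", class = "vsp_config_error")
  if (is.null(config$output_dir)) {
    abort("config$output_dir is required", class = "vsp_config_error")
  }
  if (is.null(config$stages) || !length(config$stages) ||
      is.null(names(config$stages)) || any(names(config$stages) == "")) {
    abort("config$stages must be a named list of stages",
      class = "vsp_config_error")
  }
  known <- c("simulate_trajectory", "traj_analyze", "kir_activity",
    "sensing_charge", "fv_fit")
  seen <- character()
  for (i in seq_along(config$stages)) {
    name <- names(config$stages)[i]
    st <- config$stages[[i]]
    if (is.null(st$type) || !st$type %in% known) {
      abort(sprintf("stage '%s': unknown type '%s'", name,
        st$type %||% "<missing>"), class = "vsp_config_error")
    }
    for (fld in c("path", "pn_path")) {
      if (!is.null(st[[fld]]) && !file.exists(st[[fld]])) {
        abort(sprintf("stage '%s': input file '%s' does not exist",
          name, st[[fld]]), class = "vsp_config_error")
      }
    }
    if (!is.null(st$input) && !st$input %in% seen) {
      abort(sprintf("stage '%s': input stage '%s' not defined earlier",
        name, st$input), class = "vsp_config_error")
    }
    if (st$type == "traj_analyze" && is.null(st$input) && is.null(st$path)) {
      abort(sprintf("stage '%s': needs `input` or `path`", name),
        class = "vsp_config_error")
    }
    seen <- c(seen, name)
  }
  config
}

run_stage <- function(stage, name, results, seed) {
  switch(stage$type,
    simulate_trajectory = {
      sched <- if (identical(stage$schedule, "telegraph")) {
        schedule_telegraph(stage$n_frames, stage$f_pd, stage$f_c2,
          stage$f_productive, seed = stage$seed %||% seed)
      } else {
        schedule_block(stage$n_frames, stage$f_pd, stage$f_c2,
          stage$f_productive)
      }
      traj <- sim_membrane_trajectory(
        sched,
        resolution = stage$resolution %||% "at",
        bilayer = stage$bilayer %||% "popc",
        seed = stage$seed %||% seed,
        jitter_sd_nm = stage$jitter_sd_nm %||% 0
      )
      list(result = traj, table = NULL)
    },
    traj_analyze = {
      traj <- if (!is.null(stage$input)) {
        up <- results[[stage$input]]
        if (inherits(up, "vsp_stage_error")) {
          abort(sprintf("upstream stage '%s' failed", stage$input))
        }
        up$result
      } else {
        read_trajectory_csv(stage$path)
      }
      trace <- analyze_trajectory(traj,
        resolution = stage$resolution %||% "at",
        bilayer = stage$bilayer %||% "popc")
      summary <- summarize_binding(trace)
      list(result = trace, table = as_tibble(trace), summary = summary)
    },
    kir_activity = {
      rec <- if (!is.null(stage$simulate)) {
        do.call(sim_kir_recording,
          c(stage$simulate, list(seed = stage$seed %||% seed)))
      } else {
        as_tibble(read.csv(stage$path))
      }
      protocol <- attr(rec, "protocol") %||%
        kir_protocol(depol_duration_ms = stage$depol_ms %||% 300)
      series <- build_decay_series(rec, protocol)
      fit <- fit_decay(series, plateau = stage$plateau %||% "free")
      list(result = fit, table = glance(fit), summary = glance(fit))
    },
    sensing_charge = {
      if (!is.null(stage$simulate)) {
        gen <- do.call(sim_sensing_sweeps,
          c(stage$simulate, list(seed = stage$seed %||% seed)))
        sweep <- gen$sweep
        pn <- gen$pn_sweeps
        onset <- gen$step_onset_ms
        order <- gen$pn_order
      } else {
        sweep <- as_tibble(read.csv(stage$path))
        pn <- as_tibble(read.csv(stage$pn_path))
        onset <- stage$step_onset_ms
        order <- stage$pn_order %||% 4
      }
      res <- integrate_off_sensing_charge(sweep, pn, onset, order)
      list(result = res, table = res, summary = res)
    },
    fv_fit = {
      fv <- if (!is.null(stage$simulate)) {
        do.call(sim_fv_dataset,
          c(stage$simulate, list(seed = stage$seed %||% seed)))
      } else {
        as_tibble(read.csv(stage$path))
      }
      ncomp <- stage$components %||% "auto"
      fit <- if (identical(ncomp, "auto")) {
        sel <- select_model(fv)
        if (sel$n_components == 2) sel$fit2 else sel$fit1
      } else {
        fit_boltzmann(fv, as.integer(ncomp))
      }
      summary <- dplyr::select(tidy(fit), "component", "ratio_pct",
        "A", "v_half_mV", "slope_mV")
      list(result = fit, table = tidy(fit), summary = summary)
    },
    abort(sprintf("unknown stage type '%s'", stage$type),
      class = "vsp_config_error")
  )
}
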