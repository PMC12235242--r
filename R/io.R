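# Text-based interfaces: YAML configuration (column, components, method
# program), delimited chromatogram files, the benchmark manifest and run
# manifests. All formats are plain text; configuration accepts the units the
# method is written in (mm, cm/h, CV) and converts to SI on load.

#' Write / read a model configuration
#'
#' The configuration is a YAML file with three blocks: `column`
#' (`length_mm`, `id_mm`, `porosity`, `ligand_density`, `plate_count`),
#' `components` (list of `name`, `nu`, `keq`, `sigma`, `kkin`) and `program`
#' (list of steps with `kind`, `percentB` or `percentB_range`,
#' `velocity_cm_h`, `volume_cv`, optional `feed` map for the load step).
#'
#' @param column a [column_spec()]
#' @param components list of [component_params()]
#' @param program a [method_program()] (optional for `write_config`)
#' @param path file path
#' @return `read_config` returns a list with elements `column`, `components`
#'   and (if present) `program`
#' @export
write_config <- function(column, components, program = NULL, path) {
  cfg <- list(
    column = list(length_mm = column$length * 1000,
                  id_mm = column$inner_diameter * 1000,
                  porosity = column$total_porosity,
                  ligand_density = column$ligand_density,
                  plate_count = column$plate_count),
    components = lapply(components, function(p)
      list(name = p$name, nu = p$charge_nu, keq = p$keq,
           sigma = p$sigma, kkin = p$kkin)))
  if (!is.null(program))
    cfg$program <- lapply(program$steps, function(s) {
      st <- list(kind = s$kind,
                 velocity_cm_h = ms_to_cmh(s$velocity),
                 volume_cv = s$duration_cv)
      if (s$kind == "gradient")
        st$percentB_range <- c(s$percentB_start, s$percentB_end)
      else st$percentB <- s$percentB_start
      if (s$kind == "load") st$feed <- as.list(s$feed)
      st
    })
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  col <- column_spec(length = cfg$column$length_mm / 1000,
                     inner_diameter = cfg$column$id_mm / 1000,
                     total_porosity = cfg$column$porosity,
                     ligand_density = cfg$column$ligand_density,
                     plate_count = cfg$column$plate_count)
  comps <- lapply(cfg$components, function(p)
    component_params(p$name, p$nu, p$keq, p$sigma, p$kkin))
  out <- list(column = col, components = comps)
  if (!is.null(cfg$program)) {
    steps <- lapply(cfg$program, function(s) {
      pb <- if (!is.null(s$percentB_range)) s$percentB_range
            else rep(s$percentB, 2)
      feed <- if (!is.null(s$feed)) unlist(s$feed) else c(W = 0, P = 0, S = 0)
      method_step(s$kind, pb[1], pb[2], velocity = cmh_to_ms(s$velocity_cm_h),
                  duration_cv = s$volume_cv, feed = feed)
    })
    out$program <- method_program(steps, col)
  }
  out
}

#' Write / read a benchmark data set
#'
#' Each experiment becomes a pair of files in `dir`: an observation table
#' (`<label>_observations.csv` with `time_s`, `volume_cv`, fraction window
#' bounds, `modifier_percentB`, `c_W_gL`, `c_P_gL`, `c_S_gL`) and a config
#' echo (`<label>_config.yml`); `manifest.csv` lists labels, roles and file
#' names.
#'
#' @param experiments list of [experiment()]s with observations
#' @param components the SDM parameters echoed into each config
#' @param dir output directory (created if missing)
#' @return `read_benchmark` returns the list of experiments
#' @export
write_benchmark <- function(experiments, components, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(experiments, function(ex) {
    obs_file <- paste0(ex$label, "_observations.csv")
    cfg_file <- paste0(ex$label, "_config.yml")
    obs <- ex$observations
    names(obs) <- sub("^c_([WPS])$", "c_\\1_gL", names(obs))
    utils::write.csv(obs, file.path(dir, obs_file), row.names = FALSE)
    write_config(ex$program$column, components, ex$program,
                 file.path(dir, cfg_file))
    data.frame(label = ex$label, role = ex$role,
               observations = obs_file, config = cfg_file)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(man)), function(i) {
    cfg <- read_config(file.path(dir, man$config[i]))
    obs <- tibble::as_tibble(utils::read.csv(file.path(dir, man$observations[i])))
    names(obs) <- sub("^c_([WPS])_gL$", "c_\\1", names(obs))
    experiment(man$label[i], cfg$program, role = man$role[i],
               observations = obs)
  })
}

#' Read an experiment's components from its benchmark config
#'
#' @param dir benchmark directory written by [write_benchmark()]
#' @return list of [component_params()]
#' @export
read_benchmark_components <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  read_config(file.path(dir, man$config[1]))$components
}

#' Write a fit report
#'
#' The per-epoch loss history (total and per experiment) as CSV, and the
#' best parameters as a named-parameter archive next to it.
#'
#' @param fit a [train_correction()] result
#' @param path CSV path; the parameter archive takes the same stem with
#'   suffix `_params.csv`
#' @return `path`, invisibly
#' @export
write_fit_report <- function(fit, path) {
  hist <- data.frame(epoch = seq_along(fit$history), loss = fit$history)
  hist <- cbind(hist, as.data.frame(fit$per_experiment))
  utils::write.csv(hist, path, row.names = FALSE)
  save_network(fit$theta, sub("\\.csv$", "_params.csv", path))
  invisible(path)
}

#' Write a run manifest
#'
#' JSON key/value record emitted once per command-line run: command,
#' arguments, seed, package version, output paths and wall-clock time.
#'
#' @param path manifest path
#' @param command command name
#' @param args character vector of raw arguments
#' @param seed the run's seed
#' @param outputs output path(s)
#' @param elapsed_s wall-clock seconds
#' @return `path`, invisibly
#' @export
write_manifest <- function(path, command, args, seed, outputs, elapsed_s) {
  jsonlite::write_json(
    list(command = command, arguments = args, seed = seed,
         package_version = as.character(utils::packageVersion("chromsol")),
         outputs = outputs, wall_clock_s = elapsed_s,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
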