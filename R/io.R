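# Trajectory serialisation: tidy CSVs plus a JSON sidecar holding the
# configuration, engine tag, seed and stop information.

config_to_list <- function(config) {
  out <- unclass(config)
  out$fitness <- unclass(out$fitness)
  out$type <- if (inherits(config, "free_living_config")) "free_living"
              else "cytoplasmic"
  out
}

config_from_list <- function(x) {
  fs <- x$fitness
  spec <- fitness_spec(s_b = fs$s_b, s_d = fs$s_d,
                       beneficial_shape = fs$beneficial_shape,
                       deleterious_shape = fs$deleterious_shape,
                       n_ref = fs$n_ref, gamma_ref = fs$gamma_ref,
                       s_FL = fs$s_FL,
                       beneficial_exponent = fs$theta_b,
                       deleterious_exponent = fs$theta_d)
  if (identical(x$type, "free_living")) {
    free_living_config(N_FL = x$N_FL, l = x$l, mu_b = x$mu_b,
                       mu_d = x$mu_d, fitness = spec,
                       stop_rule = x$stop_rule, gamma = x$gamma,
                       max_generations = x$max_generations, seed = x$seed)
  } else {
    sim_config(N = x$N, n = x$n, b = x$b, l = x$l, mu_b = x$mu_b,
               mu_d = x$mu_d, fitness = spec, inheritance = x$inheritance,
               stop_rule = x$stop_rule, gamma = x$gamma,
               max_generations = x$max_generations, seed = x$seed)
  }
}

#' Write a trajectory to disk
#'
#' Writes `<prefix>_summary.csv` (one row per generation),
#' `<prefix>_classes.csv` (long per-generation class-frequency table) and
#' `<prefix>_meta.json` (configuration, engine, seed, stop reason).
#'
#' @param traj A `cyto_trajectory`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return The directory, invisibly.
#' @export
write_trajectory <- function(traj, dir, prefix = "run") {
  stopifnot(inherits(traj, "cyto_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(traj$summary,
                   file.path(dir, paste0(prefix, "_summary.csv")))
  readr::write_csv(traj$class_freq,
                   file.path(dir, paste0(prefix, "_classes.csv")))
  meta <- list(engine = traj$engine, stop = traj$stop,
               config = config_to_list(traj$config))
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param dir Directory holding the files.
#' @param prefix File name prefix used when writing.
#' @return A `cyto_trajectory` (without the cell-level final state, which
#'   is not serialised).
#' @export
read_trajectory <- function(dir, prefix = "run") {
  summary <- readr::read_csv(file.path(dir, paste0(prefix, "_summary.csv")),
                             show_col_types = FALSE)
  class_freq <- readr::read_csv(
    file.path(dir, paste0(prefix, "_classes.csv")), show_col_types = FALSE)
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  structure(list(summary = summary, class_freq = class_freq,
                 config = config_from_list(meta$config),
                 engine = meta$engine,
                 stop = list(generation = meta$stop$generation,
                             reason = meta$stop$reason,
                             truncated = isTRUE(meta$stop$truncated)),
                 final_state = NULL),
            class = "cyto_trajectory")
}
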