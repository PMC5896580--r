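#' Derive independent replicate seeds from a base seed
#'
#' Replicate `r` of a run uses the `r`-th element of this stream, so
#' replicates are mutually independent yet fully reproducible from the base
#' seed.
#'
#' @param base_seed Integer base seed.
#' @param k Number of seeds.
#' @return Integer vector of `k` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(base_seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(base_seed)
  sample.int(2147483646L, k)
}

run_config <- function(config) {
  if (inherits(config, "free_living_config")) run_free_living(config)
  else run_simulation(config)
}

#' Standard per-replicate metric set
#'
#' Computes the full analysis-layer summary of one trajectory: stop
#' generation, final substitution means, generations per beneficial
#' substitution (when defined), sweep statistics `m_g` and `c_g`, ratchet
#' counts, hitchhiking index (when both ratchet kinds occurred), and
#' trajectory-mean variance panels.
#'
#' @param traj A `cyto_trajectory`.
#' @return A one-row tibble.
#' @export
trajectory_metrics <- function(traj) {
  last <- traj$summary[nrow(traj$summary), ]
  sw <- sweep_stats(traj)
  ev <- detect_ratchets(traj)
  nb <- sum(ev$kind == "beneficial")
  nd <- sum(ev$kind == "deleterious")
  phi <- phi_unc <- NA_real_
  if (nb > 0 && nd > 0) {
    hh <- hitchhiking_index(ev, traj$stop$generation)
    phi <- hh$phi
    phi_unc <- hh$phi_uncensored
  }
  gps <- if (last$mean_alpha > 0) traj$stop$generation / last$mean_alpha
         else NA_real_
  tibble::tibble(
    stop_generation = traj$stop$generation,
    truncated = isTRUE(traj$stop$truncated),
    mean_alpha = last$mean_alpha, mean_kappa = last$mean_kappa,
    generations_per_substitution = gps,
    m_g = sw$m_g, c_g = sw$c_g,
    n_beneficial_ratchets = nb, n_deleterious_ratchets = nd,
    phi = phi, phi_uncensored = phi_unc,
    mean_within_cell_variance = mean(traj$summary$within_cell_var_alpha),
    mean_between_cell_fitness_variance =
      mean(traj$summary$between_cell_fitness_var))
}

#' Run seeded replicates of one configuration
#'
#' @param config A [sim_config()] or [free_living_config()].
#' @param replicates Number of replicates.
#' @param base_seed Base seed; replicate seeds come from [derive_seeds()].
#' @param keep_trajectories Return the trajectory objects alongside the
#'   metrics (default `TRUE`; set to `FALSE` to save memory on large
#'   grids).
#' @return A list with `metrics` (tibble, one row per replicate, including
#'   `replicate` and `seed`) and `trajectories` (list or `NULL`).
#' @export
run_replicates <- function(config, replicates, base_seed,
                           keep_trajectories = TRUE) {
  seeds <- derive_seeds(base_seed, replicates)
  trajs <- if (keep_trajectories) vector("list", replicates) else NULL
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- seeds[r]
    traj <- run_config(cfg)
    if (keep_trajectories) trajs[[r]] <- traj
    rows[[r]] <- dplyr::bind_cols(
      tibble::tibble(replicate = r, seed = seeds[r]),
      trajectory_metrics(traj))
  }
  list(metrics = dplyr::bind_rows(rows), trajectories = trajs)
}

#' Experiment presets
#'
#' Returns the ready-made parameter grids for the package's standard
#' experiments, all built on the default conditions `N = 1000`, `n = 50`,
#' `l = 20000` bp, `gamma = 5`, with a relaxed (`b = n/2 = 25`) or tight
#' (`b = n/10 = 5`) transmission bottleneck:
#'
#' * `"beneficial_sweeps"`: beneficial-only model (`mu_d = 0`,
#'   `mu_b = 1e-8`, `s_b = 0.1`, linear fitness), run until every genome
#'   carries at least `gamma` beneficial substitutions, for uniparental and
#'   biparental inheritance at both bottlenecks.
#' * `"clonal_interference"`: the beneficial-only grid plus the matched
#'   free-living population (`N_FL = 50000`, `s_FL = 1`).
#' * `"deleterious_ratchet"`: deleterious-only model (`mu_b = 0`,
#'   `mu_d = 1e-7`, `s_d = 0.1`, concave-down deleterious fitness), 10000
#'   generations.
#' * `"hitchhiking"` / `"adaptive_ratio"`: combined model (`mu_b = 1e-8`,
#'   `mu_d = 1e-7`, `s_b = s_d = 0.1`, linear beneficial and concave-down
#'   deleterious fitness), 10000 generations, four inheritance/bottleneck
#'   regimes.
#' * `"freeliving_scan"`: beneficial-only free-living populations scanning
#'   `s_FL` over 1, 2, 5, 10, 20, 50 at `N_FL = 1000` and `N_FL = 50000`.
#'
#' @param name Preset name.
#' @param s_b,s_d Selection coefficients, overridable per preset.
#' @return An `experiment_grid`: a tibble with a `label` column and a
#'   `config` list-column, one row per grid cell.
#' @export
preset <- function(name = c("beneficial_sweeps", "clonal_interference",
                            "deleterious_ratchet", "hitchhiking",
                            "adaptive_ratio", "freeliving_scan"),
                   s_b = 0.1, s_d = 0.1) {
  name <- match.arg(name)
  regimes <- expand.grid(inheritance = c("uniparental", "biparental"),
                         b = c(25L, 5L), stringsAsFactors = FALSE)
  regimes$label <- paste0(ifelse(regimes$inheritance == "uniparental",
                                 "UPI", "BPI"),
                          ifelse(regimes$b == 25L, "_relaxed", "_tight"))
  beneficial_only <- function(inheritance, b) sim_config(
    b = b, mu_b = 1e-8, mu_d = 0,
    fitness = fitness_spec(s_b = s_b, s_d = 0, beneficial_shape = "linear",
                           deleterious_shape = "linear"),
    inheritance = inheritance, stop_rule = "all_genomes_reach_gamma",
    max_generations = 60000)
  combined <- function(inheritance, b) sim_config(
    b = b, mu_b = 1e-8, mu_d = 1e-7,
    fitness = fitness_spec(s_b = s_b, s_d = s_d,
                           beneficial_shape = "linear",
                           deleterious_shape = "concave_down"),
    inheritance = inheritance, stop_rule = "fixed_generations",
    max_generations = 10000)
  deleterious_only <- function(inheritance, b) sim_config(
    b = b, mu_b = 0, mu_d = 1e-7,
    fitness = fitness_spec(s_b = 0, s_d = s_d, beneficial_shape = "linear",
                           deleterious_shape = "concave_down"),
    inheritance = inheritance, stop_rule = "fixed_generations",
    max_generations = 10000)
  free_living_beneficial <- function(N_FL, s_FL) free_living_config(
    N_FL = N_FL, mu_b = 1e-8, mu_d = 0,
    fitness = fitness_spec(s_b = s_b, s_d = 0, beneficial_shape = "linear",
                           deleterious_shape = "linear", s_FL = s_FL),
    stop_rule = "all_genomes_reach_gamma", max_generations = 60000)

  grid <- switch(
    name,
    beneficial_sweeps = tibble::tibble(
      label = regimes$label,
      config = Map(beneficial_only, regimes$inheritance, regimes$b)),
    clonal_interference = tibble::tibble(
      label = c("free_living", regimes$label),
      config = c(list(free_living_beneficial(50000L, 1)),
                 Map(beneficial_only, regimes$inheritance, regimes$b))),
    deleterious_ratchet = tibble::tibble(
      label = regimes$label,
      config = Map(deleterious_only, regimes$inheritance, regimes$b)),
    hitchhiking = ,
    adaptive_ratio = tibble::tibble(
      label = regimes$label,
      config = Map(combined, regimes$inheritance, regimes$b)),
    freeliving_scan = {
      cells <- expand.grid(s_FL = c(1, 2, 5, 10, 20, 50),
                           N_FL = c(1000L, 50000L))
      tibble::tibble(
        label = sprintf("FL_N%d_sFL%g", cells$N_FL, cells$s_FL),
        config = Map(free_living_beneficial, cells$N_FL, cells$s_FL))
    })
  structure(grid, class = c("experiment_grid", class(grid)),
            preset = name)
}

#' Run an experiment grid
#'
#' Runs `replicates` seeded replicates of every grid cell, collects
#' [trajectory_metrics()] per replicate, and aggregates each metric to a
#' mean and standard error of the mean per cell. Replicate failures are
#' recorded (with the error message) and the grid continues.
#'
#' @param grid An `experiment_grid` from [preset()], or any tibble with
#'   `label` and `config` columns.
#' @param replicates Replicates per cell.
#' @param base_seed Base seed; cell `i`, replicate `r` uses seed
#'   `derive_seeds(base_seed + i - 1, replicates)[r]`.
#' @param out_dir Optional directory: writes `replicates.csv`,
#'   `summary.csv` and a `provenance.json` sidecar (seeds, configs,
#'   package version).
#' @return A list with `replicates` (per-replicate tibble), `summary`
#'   (mean and `sem` columns per metric and cell), and `failures`.
#' @export
run_grid <- function(grid, replicates = 20, base_seed = 1,
                     out_dir = NULL) {
  stopifnot(all(c("label", "config") %in% names(grid)))
  all_rows <- list()
  failures <- list()
  for (i in seq_len(nrow(grid))) {
    seeds <- derive_seeds(base_seed + i - 1L, replicates)
    for (r in seq_len(replicates)) {
      cfg <- grid$config[[i]]
      cfg$seed <- seeds[r]
      res <- tryCatch(
        dplyr::bind_cols(
          tibble::tibble(label = grid$label[i], replicate = r,
                         seed = seeds[r]),
          trajectory_metrics(run_config(cfg))),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <- tibble::tibble(
          label = grid$label[i], replicate = r, seed = seeds[r],
          message = conditionMessage(res))
      } else {
        all_rows[[length(all_rows) + 1L]] <- res
      }
    }
  }
  reps <- dplyr::bind_rows(all_rows)
  num <- names(reps)[vapply(reps, is.numeric, logical(1))]
  num <- setdiff(num, c("replicate", "seed"))
  summary <- dplyr::summarise(
    dplyr::group_by(reps, label),
    dplyr::across(dplyr::all_of(num),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       sem = ~{
                         v <- .x[!is.na(.x)]
                         if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                         else NA_real_
                       })),
    .groups = "drop")
  out <- list(replicates = reps, summary = summary,
              failures = dplyr::bind_rows(failures))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(reps, file.path(out_dir, "replicates.csv"))
    readr::write_csv(summary, file.path(out_dir, "summary.csv"))
    prov <- list(
      preset = attr(grid, "preset"),
      base_seed = base_seed, replicates = replicates,
      labels = grid$label,
      configs = lapply(grid$config, config_to_list),
      package_version = as.character(utils::packageVersion("cytosim")))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
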