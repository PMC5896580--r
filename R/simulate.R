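#' Simulation configuration for the cytoplasmic-genome model
#'
#' @param N Number of diploid host cells.
#' @param n Cytoplasmic genome copies per host cell.
#' @param b Transmission bottleneck: copies sampled into each gamete
#'   (`1 <= b <= n/2`; `b = 1` is additionally allowed when `n = 1` so the
#'   engine can emulate a single-genome population).
#' @param l Genome length in base pairs.
#' @param mu_b,mu_d Beneficial and deleterious mutation rates per site per
#'   generation.
#' @param fitness A [fitness_spec()].
#' @param inheritance `"uniparental"` or `"biparental"`.
#' @param stop_rule `"all_genomes_reach_gamma"` (beneficial-only runs stop
#'   once every genome in the population carries at least `gamma` beneficial
#'   substitutions) or `"fixed_generations"`.
#' @param gamma Per-genome beneficial substitution target used by the
#'   `all_genomes_reach_gamma` stop rule.
#' @param max_generations Horizon for `fixed_generations`, and safety cap
#'   for `all_genomes_reach_gamma` (exceeding it flags the trajectory as
#'   truncated rather than erroring).
#' @param seed Integer seed; a run is fully determined by `(config, seed)`.
#'   `NULL` leaves the RNG state untouched.
#' @return A `sim_config` object.
#' @export
sim_config <- function(N = 1000, n = 50, b = 25, l = 20000,
                       mu_b = 1e-8, mu_d = 1e-7,
                       fitness = fitness_spec(n_ref = n),
                       inheritance = c("uniparental", "biparental"),
                       stop_rule = c("all_genomes_reach_gamma",
                                     "fixed_generations"),
                       gamma = 5, max_generations = 10000, seed = NULL) {
  inheritance <- match.arg(inheritance)
  stop_rule <- match.arg(stop_rule)
  stopifnot(N >= 1, n >= 1, l >= 1,
            mu_b >= 0, mu_b <= 1, mu_d >= 0, mu_d <= 1,
            gamma >= 1, max_generations >= 1,
            inherits(fitness, "fitness_spec"))
  if (mu_b + mu_d > 1) stop("mu_b + mu_d must not exceed 1")
  if (!(b >= 1 && (b <= n / 2 || (b == 1 && n == 1))))
    stop("bottleneck must satisfy 1 <= b <= n/2")
  structure(
    list(N = as.integer(N), n = as.integer(n), b = as.integer(b),
         l = as.integer(l), mu_b = mu_b, mu_d = mu_d, fitness = fitness,
         inheritance = inheritance, stop_rule = stop_rule,
         gamma = as.integer(gamma),
         max_generations = as.integer(max_generations),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  N = %d hosts, n = %d copies/cell, b = %d (%s inheritance)\n",
              x$N, x$n, x$b, x$inheritance))
  cat(sprintf("  l = %d bp, mu_b = %g, mu_d = %g\n", x$l, x$mu_b, x$mu_d))
  cat(sprintf("  stop: %s (gamma = %d, max %d generations)\n",
              x$stop_rule, x$gamma, x$max_generations))
  invisible(x)
}

new_trajectory <- function(summary, class_freq, config, engine, stop,
                           final_state = NULL) {
  total <- sum(class_freq$count[class_freq$generation ==
                                  class_freq$generation[1]])
  class_freq$freq <- class_freq$count / total
  structure(list(summary = summary, class_freq = class_freq,
                 config = config, engine = engine, stop = stop,
                 final_state = final_state),
            class = "cyto_trajectory")
}

#' @export
print.cyto_trajectory <- function(x, ...) {
  cat(sprintf("<cyto_trajectory: %s engine>\n", x$engine))
  cat(sprintf("  %d generations recorded; stopped at generation %d (%s%s)\n",
              nrow(x$summary), x$stop$generation, x$stop$reason,
              if (isTRUE(x$stop$truncated)) ", truncated" else ""))
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("  final mean alpha = %.3f, mean kappa = %.3f, %d classes\n",
              last$mean_alpha, last$mean_kappa, last$n_classes))
  invisible(x)
}

#' Run the cytoplasmic-genome simulation
#'
#' Iterates the four-stage life cycle (mutation, selection, gametogenesis,
#' mating/repopulation) from an all-wild-type founder population until the
#' configured stop rule fires, recording one generation record immediately
#' after each repopulation (and one for the founder generation 0).
#'
#' @param config A [sim_config()].
#' @param engine `"cpp"` (compiled engine, default) or `"reference"` (the
#'   pure-R stage functions composed by [advance_generation()]; equivalent
#'   in distribution, orders of magnitude slower -- intended for validation
#'   on small instances).
#' @param initial_state Optional starting state overriding the wild-type
#'   founder: a list with integer vectors `alpha`, `kappa` and a `K x N`
#'   integer matrix `counts` (class by cell copy numbers, columns summing to
#'   `n`).
#' @return A `cyto_trajectory`: list with `summary` (one row per
#'   generation: mean/min/max substitution counts, within-cell variance of
#'   the per-copy substitution count, between-cell fitness variance, class
#'   counts), `class_freq` (long table of per-generation class frequencies),
#'   `stop` (generation, reason, truncation flag), the `config`, and the
#'   final cell-level state.
#' @export
run_simulation <- function(config, engine = c("cpp", "reference"),
                           initial_state = NULL) {
  stopifnot(inherits(config, "sim_config"))
  engine <- match.arg(engine)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (engine == "cpp") {
    fs <- config$fitness
    res <- cpp_run_cytoplasmic(
      config$N, config$n, config$b, config$l, config$mu_b, config$mu_d,
      fs$s_b, fs$s_d, fs$theta_b, fs$theta_d, fs$X,
      config$inheritance == "uniparental",
      config$stop_rule == "all_genomes_reach_gamma",
      config$gamma, config$max_generations, initial_state)
    summary <- tibble::as_tibble(res$summary)
    class_freq <- tibble::as_tibble(res$class_freq)
    new_trajectory(summary, class_freq, config, "cytoplasmic",
                   list(generation = res$stop_generation,
                        reason = res$stop_reason,
                        truncated = res$truncated),
                   final_state = res$final_state)
  } else {
    run_simulation_reference(config, initial_state)
  }
}

# summary row + class table for one population snapshot (reference engine)
population_record <- function(pop, config) {
  spec <- config$fitness
  n <- config$n
  loads <- vapply(pop$cells, cell_loads, numeric(2))
  w <- cell_fitness(loads["x", ], loads["y", ], spec)
  per_cell_var <- function(which) {
    vapply(pop$cells, function(cell) {
      v <- cell[[which]]
      m1 <- sum(v * cell$count) / n
      sum(v^2 * cell$count) / n - m1^2
    }, numeric(1))
  }
  cls <- do.call(rbind, lapply(pop$cells, function(cell)
    cell[, c("alpha", "kappa", "count")]))
  tab <- stats::aggregate(count ~ alpha + kappa, data = cls, FUN = sum)
  G <- config$N * n
  list(
    summary = tibble::tibble(
      generation = pop$generation,
      mean_alpha = sum(tab$alpha * tab$count) / G,
      mean_kappa = sum(tab$kappa * tab$count) / G,
      min_alpha = min(tab$alpha), min_kappa = min(tab$kappa),
      max_alpha = max(tab$alpha), max_kappa = max(tab$kappa),
      n_classes = nrow(tab),
      within_cell_var_alpha = mean(per_cell_var("alpha")),
      within_cell_var_kappa = mean(per_cell_var("kappa")),
      mean_cell_classes = mean(vapply(pop$cells, nrow, integer(1))),
      between_cell_fitness_var = mean(w^2) - mean(w)^2,
      mean_fitness = mean(w)),
    class_freq = tibble::tibble(generation = pop$generation,
                                alpha = tab$alpha, kappa = tab$kappa,
                                count = as.numeric(tab$count)))
}

run_simulation_reference <- function(config, initial_state = NULL) {
  pop <- if (is.null(initial_state)) {
    founder_population(config$N, config$n)
  } else {
    cells <- lapply(seq_len(ncol(initial_state$counts)), function(j) {
      keep <- initial_state$counts[, j] > 0
      cell_state(initial_state$alpha[keep], initial_state$kappa[keep],
                 initial_state$counts[keep, j])
    })
    cyto_population(cells)
  }
  gamma_reached <- function(pop)
    all(vapply(pop$cells, function(cell) min(cell$alpha), numeric(1)) >=
          config$gamma)
  recs <- list(population_record(pop, config))
  truncated <- FALSE
  reason <- "max_generations"
  on_gamma <- config$stop_rule == "all_genomes_reach_gamma"
  if (on_gamma && gamma_reached(pop)) {
    reason <- "all_genomes_reach_gamma"
  } else {
    repeat {
      pop <- advance_generation(pop, config)
      recs[[length(recs) + 1L]] <- population_record(pop, config)
      if (on_gamma && gamma_reached(pop)) {
        reason <- "all_genomes_reach_gamma"
        break
      }
      if (pop$generation >= config$max_generations) {
        truncated <- on_gamma
        break
      }
    }
  }
  final <- {
    tabs <- lapply(pop$cells, function(cell) cell)
    cls <- unique(do.call(rbind, lapply(tabs, function(t) t[, 1:2])))
    cls <- cls[order(cls$alpha, cls$kappa), , drop = FALSE]
    counts <- sapply(tabs, function(t) {
      m <- merge(cls, t, all.x = TRUE)
      m <- m[order(m$alpha, m$kappa), ]
      ifelse(is.na(m$count), 0L, m$count)
    })
    list(alpha = cls$alpha, kappa = cls$kappa,
         counts = matrix(as.integer(counts), nrow = nrow(cls)))
  }
  new_trajectory(dplyr::bind_rows(lapply(recs, `[[`, "summary")),
                 dplyr::bind_rows(lapply(recs, `[[`, "class_freq")),
                 config, "cytoplasmic",
                 list(generation = pop$generation, reason = reason,
                      truncated = truncated),
                 final_state = final)
}
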