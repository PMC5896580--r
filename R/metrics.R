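#' @importFrom dplyr %>%
NULL

# presence mask over generations: is any genome with >= a beneficial
# substitutions present?  Equivalent to max_alpha >= a, and robust to the
# "exactly a" class being consumed by onward mutation.
presence_geq <- function(traj, a) traj$summary$max_alpha >= a

#' Drift/selection phase decomposition
#'
#' Splits the accumulation of each successive beneficial substitution class
#' into a drift phase and a selection phase. The drift phase of class
#' `alpha` starts when a genome with `alpha` beneficial substitutions is
#' first observed and ends when such genomes persist in the population (the
#' start of their final uninterrupted presence interval before a genome with
#' `alpha + 1` substitutions appears); the selection phase runs from there
#' until the `alpha + 1` class is first seen. Presence of class `alpha` is
#' judged as "any genome with at least `alpha` substitutions", so onward
#' mutation cannot spuriously extinguish a class.
#'
#' Aggregate summaries conventionally exclude `alpha = 1`, whose dynamics
#' are dominated by the all-wild-type starting conditions; see
#' [phase_summary()].
#'
#' @param traj A `cyto_trajectory` from a beneficial-substitution run.
#' @return A tibble with one row per beneficial class reached: `alpha`,
#'   `first_seen`, `persist_start`, `next_class_seen` (`NA` if the next
#'   class never appeared), `drift_length`, `selection_length`, `n_losses`,
#'   `n_regains`.
#' @export
compute_phases <- function(traj) {
  stopifnot(inherits(traj, "cyto_trajectory"))
  gens <- traj$summary$generation
  amax <- max(traj$summary$max_alpha)
  rows <- list()
  for (a in seq_len(amax)) {
    mask <- presence_geq(traj, a)
    if (!any(mask)) next
    first_seen <- gens[which(mask)[1]]
    nxt <- if (a + 1 <= amax && any(traj$summary$max_alpha >= a + 1)) {
      gens[which(traj$summary$max_alpha >= a + 1)[1]]
    } else NA_integer_
    horizon <- if (is.na(nxt)) gens[length(gens)] else nxt
    win <- which(gens >= first_seen & gens <= horizon)
    mwin <- mask[win]
    absent <- which(!mwin)
    persist_start <- if (length(absent) == 0) first_seen else
      if (absent[length(absent)] == length(win)) NA_integer_ else
        gens[win[absent[length(absent)] + 1L]]
    if (is.na(persist_start)) next  # class absent at end of run: no
                                    # persistence interval to report
    in_drift <- win[gens[win] >= first_seen & gens[win] < persist_start]
    md <- mask[c(in_drift, in_drift[length(in_drift)] + 1L)]
    n_losses <- if (length(in_drift) == 0) 0L else
      sum(md[-length(md)] & !md[-1])
    n_regains <- if (length(in_drift) == 0) 0L else
      sum(!md[-length(md)] & md[-1])
    rows[[a]] <- tibble::tibble(
      alpha = a, first_seen = first_seen, persist_start = persist_start,
      next_class_seen = nxt,
      drift_length = persist_start - first_seen,
      selection_length = if (is.na(nxt)) NA_integer_ else
        nxt - persist_start,
      n_losses = as.integer(n_losses), n_regains = as.integer(n_regains))
  }
  dplyr::bind_rows(rows)
}

#' Mean drift and selection phase lengths
#'
#' @param phases Output of [compute_phases()].
#' @param exclude_alpha Classes excluded from the means (default `1`).
#' @return A one-row tibble with `mean_drift`, `mean_selection`, and the
#'   number of classes contributing.
#' @export
phase_summary <- function(phases, exclude_alpha = 1) {
  keep <- phases[!(phases$alpha %in% exclude_alpha) &
                   !is.na(phases$next_class_seen), ]
  tibble::tibble(mean_drift = mean(keep$drift_length),
                 mean_selection = mean(keep$selection_length),
                 n_classes = nrow(keep))
}

#' Per-generation loss and regain probabilities during the drift phase
#'
#' Within the drift phase of beneficial class `alpha`, `P_lose` is the
#' number of loss events divided by the number of drift-phase generations in
#' which the class was present, and `P_regain` is the number of regain
#' events divided by the number of drift-phase generations in which it was
#' absent (after its first appearance). A class that was never lost has
#' `P_lose = 0` and an undefined (`NA`) `P_regain`.
#'
#' @param traj A `cyto_trajectory`.
#' @param alpha Beneficial class index.
#' @return A one-row tibble: `alpha`, `P_lose`, `P_regain`, `n_losses`,
#'   `n_regains`, `present_generations`, `absent_generations`.
#' @export
loss_regain_probabilities <- function(traj, alpha) {
  ph <- compute_phases(traj)
  ph <- ph[ph$alpha == alpha, ]
  if (nrow(ph) == 0)
    stop(sprintf("beneficial class %d was never observed", alpha))
  gens <- traj$summary$generation
  mask <- presence_geq(traj, alpha)
  drift <- gens >= ph$first_seen & gens < ph$persist_start
  present <- sum(mask & drift)
  absent <- sum(!mask & drift)
  tibble::tibble(
    alpha = alpha,
    P_lose = if (ph$n_losses == 0) 0 else ph$n_losses / present,
    P_regain = if (absent == 0) NA_real_ else ph$n_regains / absent,
    n_losses = ph$n_losses, n_regains = ph$n_regains,
    present_generations = present, absent_generations = absent)
}

#' Mean generations per beneficial substitution
#'
#' The stop generation of a beneficial-only run divided by the
#' population-mean number of beneficial substitutions per genome at stop.
#'
#' @param traj A `cyto_trajectory` run under the `all_genomes_reach_gamma`
#'   stop rule.
#' @return Generations per substitution (numeric scalar); carries attribute
#'   `truncated = TRUE` when the run hit its safety cap, in which case the
#'   value is computed on the truncated horizon.
#' @export
generations_per_substitution <- function(traj) {
  stopifnot(inherits(traj, "cyto_trajectory"))
  last <- traj$summary[nrow(traj$summary), ]
  if (last$mean_alpha <= 0)
    stop("undefined: no beneficial substitutions accumulated")
  out <- traj$stop$generation / last$mean_alpha
  if (isTRUE(traj$stop$truncated)) attr(out, "truncated") <- TRUE
  out
}

# long class-frequency table collapsed to the grouping used for sweep and
# coexistence statistics: beneficial classes in beneficial-only runs, full
# (alpha, kappa) classes otherwise
sweep_groups <- function(traj, by = c("auto", "alpha", "class")) {
  by <- match.arg(by)
  cf <- traj$class_freq
  if (by == "auto") by <- if (all(cf$kappa == 0)) "alpha" else "class"
  if (by == "alpha") {
    out <- dplyr::summarise(dplyr::group_by(cf, generation, alpha),
                            freq = sum(freq), .groups = "drop")
    out$group <- out$alpha
  } else {
    out <- cf
    out$group <- paste(cf$alpha, cf$kappa, sep = ":")
  }
  out
}

#' Sweep slope and coexisting-class count
#'
#' Clonal-interference statistics of a trajectory. `c_g` is the mean (over
#' generations) number of genome classes simultaneously present. `m_g` is a
#' linear approximation of the decline slope of near-fixed ("wild type")
#' classes: for every class whose frequency attains at least `high`
#' (99.5%), the drop is timed from the first generation at or above `high`
#' (the generation the class becomes the near-fixed wild type) to its first
#' subsequent generation below `low` (0.5%), and
#' `m_g = -99.5 / mean(duration)` in percent per generation. Classes still
#' above `low` at the end of the run are censored and excluded; if no class
#' ever attains `high`, `m_g` is `NA` while `c_g` is still computed.
#'
#' @param traj A `cyto_trajectory`.
#' @param by Grouping of classes: `"alpha"` (beneficial count only),
#'   `"class"` (distinct `(alpha, kappa)` pairs), or `"auto"` (default:
#'   `"alpha"` when the run has no deleterious mutations, else `"class"`).
#' @param high,low Fixation and loss thresholds as frequencies (defaults
#'   0.995 and 0.005).
#' @return A one-row tibble: `m_g` (%/generation, `<= 0`), `c_g` (`>= 1`),
#'   `n_sweeps` (declines measured).
#' @export
sweep_stats <- function(traj, by = c("auto", "alpha", "class"),
                        high = 0.995, low = 0.005) {
  stopifnot(inherits(traj, "cyto_trajectory"))
  grp <- sweep_groups(traj, by)
  c_g <- nrow(grp) / length(unique(grp$generation))
  durations <- c()
  for (g in unique(grp$group[grp$freq >= high])) {
    sub <- grp[grp$group == g, ]
    first_high <- min(sub$generation[sub$freq >= high])
    below <- sub$generation[sub$freq < low & sub$generation > first_high]
    # a generation with no row means frequency zero (class lost entirely)
    all_gens <- unique(grp$generation)
    gone <- setdiff(all_gens[all_gens > first_high], sub$generation)
    below <- c(below, gone)
    if (length(below) == 0) next  # censored: still common at end of run
    durations <- c(durations, min(below) - first_high)
  }
  tibble::tibble(
    m_g = if (length(durations) == 0) NA_real_ else -99.5 / mean(durations),
    c_g = c_g, n_sweeps = length(durations))
}

#' Detect beneficial and deleterious ratchet events
#'
#' A beneficial ratchet is a generation in which the genome class carrying
#' the fewest beneficial substitutions is lost (the population minimum of
#' `alpha` strictly increases); a deleterious ratchet is the same event for
#' `kappa` -- a click of Muller's ratchet. A jump of the minimum by more
#' than one in a single generation still counts as one event; the jump size
#' is recorded for diagnostics.
#'
#' @param traj A `cyto_trajectory`.
#' @return A tibble with columns `kind` (`"beneficial"` or
#'   `"deleterious"`), `generation`, and `jump`.
#' @export
detect_ratchets <- function(traj) {
  stopifnot(inherits(traj, "cyto_trajectory"))
  s <- traj$summary
  out <- list()
  for (kind in c("beneficial", "deleterious")) {
    m <- if (kind == "beneficial") s$min_alpha else s$min_kappa
    d <- diff(m)
    hit <- which(d > 0)
    if (length(hit))
      out[[kind]] <- tibble::tibble(kind = kind,
                                    generation = s$generation[hit + 1L],
                                    jump = d[hit])
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0)
    res <- tibble::tibble(kind = character(), generation = integer(),
                          jump = integer())
  res[order(res$generation), ]
}

#' Genetic hitchhiking index
#'
#' Measures how closely deleterious ratchets follow beneficial ratchets
#' relative to a random-placement null. For each beneficial ratchet at
#' generation `g`, the observed gap is the number of generations to the
#' first deleterious ratchet at or after `g` (a deleterious ratchet in the
#' same generation gives a gap of zero). Beneficial ratchets with no
#' subsequent deleterious ratchet before the end of the run are censored
#' and contribute their censored gap `T - g`; the index is also reported
#' with censored pairs excluded. The null expectation places the observed
#' number `D` of deleterious ratchets uniformly at random over the `T`
#' generations, giving a forward waiting time of `T / D`. The index is
#' `phi = mean(observed gap) / (T / D)`: `phi < 1` indicates hitchhiking
#' (deleterious substitutions fix in the wake of beneficial ones),
#' `phi ~ 1` independence, `phi > 1` inhibition.
#'
#' @param events Either a `cyto_trajectory` (ratchets are detected with
#'   [detect_ratchets()]) or a tibble of events with columns `kind` and
#'   `generation`.
#' @param total_generations Length `T` of the observation window; defaults
#'   to the trajectory's stop generation when `events` is a trajectory.
#' @return A list of class `hitchhiking_result`: `pairs` (per beneficial
#'   ratchet: generation, gap, censored flag, per-pair index value),
#'   `observed_mean_gap`, `expected_gap`, `phi`, `phi_uncensored`,
#'   `n_beneficial`, `n_deleterious`, `n_censored`. With no deleterious
#'   ratchets `phi` is `NA`.
#' @export
hitchhiking_index <- function(events, total_generations = NULL) {
  if (inherits(events, "cyto_trajectory")) {
    total_generations <- total_generations %||% events$stop$generation
    events <- detect_ratchets(events)
  }
  stopifnot(!is.null(total_generations), total_generations >= 1)
  T_ <- total_generations
  bg <- sort(events$generation[events$kind == "beneficial"])
  dg <- sort(events$generation[events$kind == "deleterious"])
  if (length(bg) == 0)
    stop("no beneficial ratchet observed; index undefined")
  nxt <- findInterval(bg - 1e-9, dg) + 1L  # first deleterious >= each bg
  censored <- nxt > length(dg)
  gap <- ifelse(censored, T_ - bg, dg[pmin(nxt, length(dg))] - bg)
  D <- length(dg)
  expected <- if (D == 0) NA_real_ else T_ / D
  pairs <- tibble::tibble(beneficial_generation = bg, gap = gap,
                          censored = censored,
                          pair_index = gap / expected)
  obs <- mean(gap)
  obs_unc <- if (all(censored)) NA_real_ else mean(gap[!censored])
  structure(list(
    pairs = pairs, observed_mean_gap = obs,
    observed_mean_gap_uncensored = obs_unc,
    expected_gap = expected,
    phi = if (D == 0) NA_real_ else obs / expected,
    phi_uncensored = if (D == 0) NA_real_ else obs_unc / expected,
    n_beneficial = length(bg), n_deleterious = D,
    n_censored = sum(censored)), class = "hitchhiking_result")
}

#' @export
print.hitchhiking_result <- function(x, ...) {
  cat("<hitchhiking_result>\n")
  cat(sprintf("  %d beneficial, %d deleterious ratchets (%d censored pairs)\n",
              x$n_beneficial, x$n_deleterious, x$n_censored))
  cat(sprintf("  observed mean gap %.2f vs expected %.2f: phi = %.3f (uncensored %.3f)\n",
              x$observed_mean_gap, x$expected_gap, x$phi, x$phi_uncensored))
  invisible(x)
}

#' Adaptive-evolution ratio
#'
#' The ratio of beneficial to deleterious substitutions at a fixed horizon,
#' aggregated as a mean of per-replicate ratios: for each replicate the
#' population-mean beneficial substitutions per genome is divided by the
#' corresponding mean deleterious substitutions, and these ratios are then
#' averaged (mean of ratios, not ratio of means). Replicates with zero mean
#' deleterious substitutions are excluded and counted.
#'
#' @param final_states A data frame with one row per replicate and columns
#'   `mean_alpha` and `mean_kappa` (per-genome means at the horizon).
#' @return A one-row tibble: `ratio` (mean of per-replicate ratios), `sem`
#'   (standard error of that mean), `n`, `n_excluded`.
#' @export
adaptive_ratio <- function(final_states) {
  stopifnot(all(c("mean_alpha", "mean_kappa") %in% names(final_states)))
  ok <- final_states$mean_kappa > 0
  r <- final_states$mean_alpha[ok] / final_states$mean_kappa[ok]
  if (length(r) == 0) stop("undefined: all replicates excluded")
  tibble::tibble(ratio = mean(r),
                 sem = if (length(r) > 1) stats::sd(r) / sqrt(length(r))
                       else NA_real_,
                 n = length(r), n_excluded = sum(!ok))
}

#' Within-cell and between-cell variance panels
#'
#' From a full cell-level snapshot, computes (1) the within-cell variance:
#' the variance, across each cell's genome copies, of the per-copy
#' beneficial substitution count (population-variance convention, divisor
#' `n`), averaged over cells; and (2) the between-cell variance of cell
#' fitness across the population. The per-copy deleterious variance and the
#' mean number of distinct classes per cell are returned alongside, since
#' "variance in the genomes carried by cells" is also sometimes read as
#' class diversity.
#'
#' @param state A cell-level snapshot: either a `cyto_population` or a
#'   `final_state` list (`alpha`, `kappa`, `K x N` count matrix) as stored
#'   on a `cyto_trajectory`.
#' @param spec The [fitness_spec()] used to evaluate cell fitness.
#' @return A one-row tibble: `within_cell_variance`,
#'   `between_cell_fitness_variance`, `within_cell_variance_kappa`,
#'   `mean_cell_classes`.
#' @export
variance_panels <- function(state, spec) {
  if (inherits(state, "cyto_population")) {
    cls <- sort(unique(unlist(lapply(state$cells, function(cell)
      paste(cell$alpha, cell$kappa)))))
    alpha <- as.integer(sub(" .*", "", cls))
    kappa <- as.integer(sub(".* ", "", cls))
    counts <- vapply(state$cells, function(cell) {
      v <- integer(length(cls))
      v[match(paste(cell$alpha, cell$kappa), cls)] <- cell$count
      v
    }, integer(length(cls)))
    counts <- matrix(counts, nrow = length(cls))
    state <- list(alpha = alpha, kappa = kappa, counts = counts)
  }
  counts <- state$counts
  n <- colSums(counts)
  xa <- colSums(counts * state$alpha)
  xk <- colSums(counts * state$kappa)
  va <- colSums(counts * state$alpha^2) / n - (xa / n)^2
  vk <- colSums(counts * state$kappa^2) / n - (xk / n)^2
  w <- cell_fitness(xa, xk, spec)
  tibble::tibble(
    within_cell_variance = mean(va),
    between_cell_fitness_variance = mean(w^2) - mean(w)^2,
    within_cell_variance_kappa = mean(vk),
    mean_cell_classes = mean(colSums(counts > 0)))
}
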