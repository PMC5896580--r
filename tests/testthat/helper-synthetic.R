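# Build a cyto_trajectory by hand from a long class-frequency table
# (generation, alpha, kappa, count); used to test the metrics layer against
# exactly constructed inputs.

make_trajectory <- function(cf, stop_reason = "fixed_generations",
                            truncated = FALSE) {
  cf <- cf[order(cf$generation, cf$alpha, cf$kappa), ]
  by_gen <- split(cf, cf$generation)
  summary <- dplyr::bind_rows(lapply(by_gen, function(g) {
    tot <- sum(g$count)
    tibble::tibble(
      generation = g$generation[1],
      mean_alpha = sum(g$alpha * g$count) / tot,
      mean_kappa = sum(g$kappa * g$count) / tot,
      min_alpha = min(g$alpha), min_kappa = min(g$kappa),
      max_alpha = max(g$alpha), max_kappa = max(g$kappa),
      n_classes = nrow(g),
      within_cell_var_alpha = NA_real_, within_cell_var_kappa = NA_real_,
      mean_cell_classes = NA_real_, between_cell_fitness_var = NA_real_,
      mean_fitness = NA_real_)
  }))
  totals <- tapply(cf$count, cf$generation, sum)
  stopifnot(length(unique(totals)) == 1)  # genome count must be conserved
  cf$freq <- cf$count / totals[[1]]
  structure(list(summary = summary, class_freq = tibble::as_tibble(cf),
                 config = NULL, engine = "synthetic",
                 stop = list(generation = max(cf$generation),
                             reason = stop_reason, truncated = truncated),
                 final_state = NULL),
            class = "cyto_trajectory")
}

# class-frequency table for one beneficial class with an explicit presence
# profile, padded with a wild-type background so totals are conserved
presence_table <- function(total = 100, ...) {
  # ...: named vectors class = data.frame(gen, count)
  classes <- list(...)
  rows <- list()
  gens <- sort(unique(unlist(lapply(classes, function(x) x$gen))))
  for (g in gens) {
    used <- 0
    for (nm in names(classes)) {
      sub <- classes[[nm]][classes[[nm]]$gen == g, ]
      if (nrow(sub) == 1 && sub$count > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          generation = g, alpha = as.integer(nm), kappa = 0L,
          count = sub$count)
        used <- used + sub$count
      }
    }
    stopifnot(used <= total)
    if (used < total && !("0" %in% names(classes)))
      rows[[length(rows) + 1]] <- data.frame(
        generation = g, alpha = 0L, kappa = 0L, count = total - used)
  }
  do.call(rbind, rows)
}
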