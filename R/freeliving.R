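#' Configuration for the free-living asexual null model
#'
#' Free-living cells carry a single asexual genome and live a two-stage life
#' cycle: mutation, then Wright-Fisher selection proportional to
#' [free_living_fitness()]. Matched comparisons set `N_FL` either to the
#' number of hosts (`N`) or to the total number of cytoplasmic genomes
#' (`N * n`), but any positive size is accepted.
#'
#' @param N_FL Free-living population size.
#' @param l,mu_b,mu_d As in [sim_config()].
#' @param fitness A [fitness_spec()] with linear shapes; its `s_FL` scales
#'   the per-substitution fitness effect relative to a substitution on one
#'   cytoplasmic genome.
#' @param stop_rule,gamma,max_generations,seed As in [sim_config()]; under
#'   `all_genomes_reach_gamma` the run stops once every free-living genome
#'   carries at least `gamma` beneficial substitutions.
#' @return A `free_living_config` object.
#' @export
free_living_config <- function(N_FL = 50000, l = 20000,
                               mu_b = 1e-8, mu_d = 0,
                               fitness = fitness_spec(
                                 beneficial_shape = "linear",
                                 deleterious_shape = "linear"),
                               stop_rule = c("all_genomes_reach_gamma",
                                             "fixed_generations"),
                               gamma = 5, max_generations = 10000,
                               seed = NULL) {
  stop_rule <- match.arg(stop_rule)
  stopifnot(N_FL >= 1, l >= 1, mu_b >= 0, mu_b <= 1, mu_d >= 0, mu_d <= 1,
            gamma >= 1, max_generations >= 1,
            inherits(fitness, "fitness_spec"))
  if (mu_b + mu_d > 1) stop("mu_b + mu_d must not exceed 1")
  if (fitness$beneficial_shape != "linear" ||
      fitness$deleterious_shape != "linear")
    stop("free-living runs require linear fitness shapes")
  structure(
    list(N_FL = as.integer(N_FL), l = as.integer(l), mu_b = mu_b,
         mu_d = mu_d, fitness = fitness, stop_rule = stop_rule,
         gamma = as.integer(gamma),
         max_generations = as.integer(max_generations),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "free_living_config")
}

# Zero-truncated Binomial(l, mu) sampler: per-genome mutation count given
# that the genome received at least one hit.
rtruncbinom <- function(m, l, mu) {
  if (m == 0) return(integer(0))
  p0 <- (1 - mu)^l
  u <- runif(m) * (1 - p0)
  out <- integer(m)
  for (i in seq_len(m)) {
    k <- 1L
    pk <- l * mu * (1 - mu)^(l - 1)
    cum <- pk
    while (u[i] > cum && k < l) {
      pk <- pk * ((l - k) / (k + 1)) * (mu / (1 - mu))
      k <- k + 1L
      cum <- cum + pk
    }
    out[i] <- k
  }
  out
}

# Allocate M distinct mutated genomes across classes: sequential
# multivariate hypergeometric over the class counts.
allocate_hits <- function(counts, M) {
  K <- length(counts)
  hits <- integer(K)
  left <- sum(counts)
  rem <- M
  for (i in seq_len(K)) {
    if (rem == 0) break
    hits[i] <- rhyper(1, counts[i], left - counts[i], rem)
    rem <- rem - hits[i]
    left <- left - counts[i]
  }
  hits
}

#' Run the free-living asexual simulation
#'
#' Class-count Wright-Fisher engine: each generation every genome receives
#' independent `Binomial(l, mu)` beneficial and deleterious mutation counts
#' (applied sparsely but exactly through the number of hit genomes and
#' zero-truncated draws), then `N_FL` cells are resampled with replacement
#' proportional to [free_living_fitness()]. The trajectory schema matches
#' [run_simulation()]; as every cell carries a single genome, the
#' within-cell variance columns are identically zero and each cell holds one
#' class.
#'
#' @param config A [free_living_config()].
#' @return A `cyto_trajectory` with engine tag `"free_living"`.
#' @export
run_free_living <- function(config) {
  stopifnot(inherits(config, "free_living_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  spec <- config$fitness
  N <- config$N_FL
  alpha <- 0L; kappa <- 0L; counts <- N

  mutate_classes <- function(alpha, kappa, counts, mu, beneficial) {
    if (mu <= 0) return(list(alpha = alpha, kappa = kappa, counts = counts))
    p1 <- 1 - (1 - mu)^config$l
    M <- rbinom(1, N, p1)
    if (M == 0) return(list(alpha = alpha, kappa = kappa, counts = counts))
    hits <- allocate_hits(counts, M)
    for (i in which(hits > 0)) {
      ks <- rtruncbinom(hits[i], config$l, mu)
      counts[i] <- counts[i] - hits[i]
      for (k in ks) {
        a2 <- alpha[i] + if (beneficial) k else 0L
        k2 <- kappa[i] + if (beneficial) 0L else k
        j <- which(alpha == a2 & kappa == k2)
        if (length(j) == 0) {
          alpha <- c(alpha, a2); kappa <- c(kappa, k2); counts <- c(counts, 1L)
        } else {
          counts[j] <- counts[j] + 1L
        }
      }
    }
    list(alpha = alpha, kappa = kappa, counts = counts)
  }

  # growable trajectory accumulators (plain vectors; tibbles built once at
  # the end, which keeps long runs cheap)
  acc <- new.env(parent = emptyenv())
  acc$sum <- vector("list", 0)
  acc$cf <- vector("list", 0)
  record <- function(gen, alpha, kappa, counts) {
    w <- free_living_fitness(alpha, kappa, spec)
    mw <- sum(w * counts) / N
    acc$sum[[length(acc$sum) + 1L]] <- c(
      gen, sum(alpha * counts) / N, sum(kappa * counts) / N,
      min(alpha), min(kappa), max(alpha), max(kappa), length(counts),
      sum(w^2 * counts) / N - mw^2, mw)
    acc$cf[[length(acc$cf) + 1L]] <- list(gen, alpha, kappa,
                                          as.numeric(counts))
  }

  gen <- 0L
  record(gen, alpha, kappa, counts)
  truncated <- FALSE
  reason <- "max_generations"
  on_gamma <- config$stop_rule == "all_genomes_reach_gamma"
  while (!(on_gamma && min(alpha) >= config$gamma)) {
    if (gen >= config$max_generations) {
      truncated <- on_gamma
      break
    }
    st <- mutate_classes(alpha, kappa, counts, config$mu_b, TRUE)
    st <- mutate_classes(st$alpha, st$kappa, st$counts, config$mu_d, FALSE)
    w <- free_living_fitness(st$alpha, st$kappa, spec)
    mass <- st$counts * w
    if (sum(mass) <= 0)
      stop(sprintf(
        "population extinct: all cell fitness values are zero at generation %d",
        gen))
    newc <- as.integer(rmultinom(1, N, mass))
    keep <- newc > 0
    alpha <- st$alpha[keep]; kappa <- st$kappa[keep]; counts <- newc[keep]
    gen <- gen + 1L
    record(gen, alpha, kappa, counts)
  }
  if (on_gamma && min(alpha) >= config$gamma) reason <- "all_genomes_reach_gamma"
  smat <- do.call(rbind, acc$sum)
  summary <- tibble::tibble(
    generation = as.integer(smat[, 1]), mean_alpha = smat[, 2],
    mean_kappa = smat[, 3], min_alpha = as.integer(smat[, 4]),
    min_kappa = as.integer(smat[, 5]), max_alpha = as.integer(smat[, 6]),
    max_kappa = as.integer(smat[, 7]), n_classes = as.integer(smat[, 8]),
    within_cell_var_alpha = 0, within_cell_var_kappa = 0,
    mean_cell_classes = 1,
    between_cell_fitness_var = smat[, 9], mean_fitness = smat[, 10])
  class_freq <- tibble::tibble(
    generation = rep.int(vapply(acc$cf, function(r) as.integer(r[[1]]),
                                integer(1)),
                         vapply(acc$cf, function(r) length(r[[2]]),
                                integer(1))),
    alpha = unlist(lapply(acc$cf, `[[`, 2)),
    kappa = unlist(lapply(acc$cf, `[[`, 3)),
    count = unlist(lapply(acc$cf, `[[`, 4)))
  new_trajectory(summary, class_freq, config, "free_living",
                 list(generation = gen, reason = reason,
                      truncated = truncated),
                 final_state = list(alpha = alpha, kappa = kappa,
                                    counts = matrix(as.integer(counts),
                                                    ncol = 1)))
}
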