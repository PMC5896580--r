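# Exhaustive enumeration oracle for one full life-cycle generation on a
# tiny instance: N = 2 diploid cells, n = 2 genome copies, b = 1, l = 1,
# beneficial mutations only.  Enumerates every mutation / selection /
# gametogenesis / pairing / repopulation outcome with its exact probability
# and returns the distribution of the offspring composition, keyed by the
# sorted multiset of per-cell copy substitution counts.

offspring_key <- function(cells)
  paste(sort(vapply(cells, function(x) paste(sort(x), collapse = "-"),
                    character(1))), collapse = "|")

enumerate_generation <- function(cells, mu, s_b, X, uniparental) {
  stopifnot(length(cells) == 2, all(lengths(cells) == 2))
  probs <- new.env(parent = emptyenv())
  add <- function(key, p) {
    cur <- get0(key, envir = probs, ifnotfound = 0)
    assign(key, cur + p, envir = probs)
  }
  wfun <- function(cc) (1 - s_b) + s_b * min(sum(cc), X) / X
  copies <- unlist(cells)
  for (mask in 0:15) {
    bits <- as.integer(intToBits(mask))[1:4]
    pmut <- prod(ifelse(bits == 1, mu, 1 - mu))
    mut <- list(copies[1:2] + bits[1:2], copies[3:4] + bits[3:4])
    w <- vapply(mut, wfun, numeric(1))
    for (i in 1:2) for (j in 1:2) {
      psel <- (w[i] / sum(w)) * (w[j] / sum(w))
      sel <- list(mut[[i]], mut[[j]])
      # b = 1: each gamete is one uniformly chosen copy of its parent
      for (gA1 in 1:2) for (ga1 in 1:2) for (gA2 in 1:2) for (ga2 in 1:2) {
        pgam <- 1 / 16
        gA <- c(sel[[1]][gA1], sel[[2]][gA2])
        ga <- c(sel[[1]][ga1], sel[[2]][ga2])
        for (perm in list(c(1, 2), c(2, 1))) {
          ppair <- 1 / 2
          base <- pmut * psel * pgam * ppair
          if (uniparental) {
            off <- list(rep(gA[1], 2), rep(gA[2], 2))
            add(offspring_key(off), base)
          } else {
            pool <- list(c(gA[1], ga[perm[1]]), c(gA[2], ga[perm[2]]))
            for (c1 in 0:2) for (c2 in 0:2) {
              pdraw <- dbinom(c1, 2, 0.5) * dbinom(c2, 2, 0.5)
              off <- list(
                c(rep(pool[[1]][1], c1), rep(pool[[1]][2], 2 - c1)),
                c(rep(pool[[2]][1], c2), rep(pool[[2]][2], 2 - c2)))
              add(offspring_key(off), base * pdraw)
            }
          }
        }
      }
    }
  }
  out <- unlist(as.list(probs))
  stopifnot(abs(sum(out) - 1) < 1e-12)
  out
}

# the same tiny instance as a sim_config plus its engine initial state;
# starting cells: one homoplasmic wild type, one heteroplasmic (0, 1)
tiny_instance <- function(inheritance, mu = 0.2, s_b = 0.5) {
  list(
    cells = list(c(0L, 0L), c(0L, 1L)),
    config = sim_config(
      N = 2, n = 2, b = 1, l = 1, mu_b = mu, mu_d = 0,
      fitness = fitness_spec(s_b = s_b, s_d = 0,
                             beneficial_shape = "linear",
                             deleterious_shape = "linear",
                             n_ref = 2, gamma_ref = 1),
      inheritance = inheritance, stop_rule = "fixed_generations",
      max_generations = 1),
    initial_state = list(alpha = c(0L, 1L), kappa = c(0L, 0L),
                         counts = matrix(c(2L, 0L, 1L, 1L), nrow = 2)))
}

# offspring key of an engine final state (K x N counts matrix)
final_state_key <- function(fs) {
  cells <- lapply(seq_len(ncol(fs$counts)), function(j)
    rep(fs$alpha, fs$counts[, j]))
  offspring_key(cells)
}

# chi-squared comparison of observed keys against enumerated probabilities,
# pooling categories with small expectation
chisq_against <- function(keys, expected_probs, min_expected = 10) {
  n <- length(keys)
  obs <- table(factor(keys, levels = names(expected_probs)))
  stopifnot(sum(obs) == n)  # every observed key must be enumerable
  exp <- expected_probs * n
  ord <- order(exp)
  pooled_obs <- c(); pooled_exp <- c()
  acc_o <- 0; acc_e <- 0
  for (i in ord) {
    acc_o <- acc_o + obs[i]; acc_e <- acc_e + exp[i]
    if (acc_e >= min_expected) {
      pooled_obs <- c(pooled_obs, acc_o); pooled_exp <- c(pooled_exp, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  pooled_obs[length(pooled_obs)] <- pooled_obs[length(pooled_obs)] + acc_o
  pooled_exp[length(pooled_exp)] <- pooled_exp[length(pooled_exp)] + acc_e
  stat <- sum((pooled_obs - pooled_exp)^2 / pooled_exp)
  stats::pchisq(stat, df = length(pooled_obs) - 1, lower.tail = FALSE)
}
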