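#' Construct a cell state
#'
#' A cell is a multiset of genome classes: each class is identified by its
#' beneficial and deleterious substitution counts (`alpha`, `kappa`) and held
#' at some copy number. Diploid hosts hold `n` copies, gametes hold `b`.
#'
#' @param alpha,kappa Integer vectors of per-class substitution counts.
#' @param count Integer vector of copy numbers per class (all positive).
#' @return A `cell_state`: a data frame with columns `alpha`, `kappa`,
#'   `count`.
#' @export
cell_state <- function(alpha = 0L, kappa = 0L, count = 1L) {
  stopifnot(length(alpha) == length(kappa), length(alpha) == length(count),
            all(alpha >= 0), all(kappa >= 0), all(count > 0))
  alpha <- as.integer(alpha); kappa <- as.integer(kappa)
  count <- as.integer(count)
  o <- order(alpha, kappa)
  alpha <- alpha[o]; kappa <- kappa[o]; count <- count[o]
  first <- c(TRUE, diff(alpha) != 0 | diff(kappa) != 0)
  cell <- data.frame(
    alpha = alpha[first], kappa = kappa[first],
    count = as.integer(rowsum(count, cumsum(first))[, 1]))
  class(cell) <- c("cell_state", "data.frame")
  cell
}

n_copies <- function(cell) sum(cell$count)

#' Total substitution loads of a cell
#'
#' @param cell A [cell_state()].
#' @return Named numeric vector `c(x = total beneficial, y = total
#'   deleterious)` summed over all genome copies.
#' @export
cell_loads <- function(cell) {
  c(x = sum(cell$alpha * cell$count), y = sum(cell$kappa * cell$count))
}

#' Construct a population of host cells
#'
#' @param cells List of [cell_state()] objects (one per host).
#' @param generation Generation index (integer, `>= 0`).
#' @return A `cyto_population`.
#' @export
cyto_population <- function(cells, generation = 0L) {
  stopifnot(is.list(cells), length(cells) >= 1,
            all(vapply(cells, inherits, logical(1), "cell_state")))
  structure(list(generation = as.integer(generation), cells = cells),
            class = "cyto_population")
}

#' Initial all-wild-type population
#'
#' @param N Number of host cells.
#' @param n Genome copies per cell.
#' @return A `cyto_population` in which every cell is homoplasmic for the
#'   zero-substitution class.
#' @export
founder_population <- function(N, n) {
  cyto_population(replicate(N, cell_state(0L, 0L, as.integer(n)),
                            simplify = FALSE))
}

# expand a cell's class table to one row index per genome copy
expand_copies <- function(cell) rep.int(seq_len(nrow(cell)), cell$count)

#' Mutation stage for one cell
#'
#' Every genome copy independently receives `Binomial(l, mu_b)` new
#' beneficial and `Binomial(l, mu_d)` new deleterious substitutions, added to
#' its class counts. Substitution counts never decrease (no back mutation)
#' and the copy number of the cell is unchanged. Site saturation is ignored:
#' each generation draws over all `l` sites, which is accurate while the
#' expected per-genome substitution load stays far below `l`.
#'
#' @param cell A [cell_state()].
#' @param l Genome length in base pairs.
#' @param mu_b,mu_d Per-site per-generation beneficial and deleterious
#'   mutation rates; `mu_b + mu_d` must not exceed 1.
#' @return The mutated `cell_state`.
#' @export
mutate_cell <- function(cell, l, mu_b, mu_d) {
  stopifnot(inherits(cell, "cell_state"), l >= 1,
            mu_b >= 0, mu_d >= 0, mu_b <= 1, mu_d <= 1)
  if (mu_b + mu_d > 1)
    stop("mu_b + mu_d must not exceed 1")
  if (mu_b == 0 && mu_d == 0) return(cell)
  idx <- expand_copies(cell)
  da <- stats::rbinom(length(idx), l, mu_b)
  dk <- stats::rbinom(length(idx), l, mu_d)
  cell_state(cell$alpha[idx] + da, cell$kappa[idx] + dk,
             rep(1L, length(idx)))
}

#' Selection stage on host cells
#'
#' Samples `N` cells with replacement, with probability proportional to each
#' cell's relative fitness under `spec` evaluated at its total substitution
#' loads. The generation index is unchanged: selection is a
#' within-generation stage.
#'
#' @param pop A [cyto_population()].
#' @param spec A [fitness_spec()].
#' @return The post-selection `cyto_population`.
#' @export
select_hosts <- function(pop, spec) {
  stopifnot(inherits(pop, "cyto_population"))
  loads <- vapply(pop$cells, cell_loads, numeric(2))
  w <- cell_fitness(loads["x", ], loads["y", ], spec)
  if (all(w <= 0))
    stop(sprintf("population extinct: all cell fitness values are zero at generation %d",
                 pop$generation))
  idx <- sample.int(length(pop$cells), length(pop$cells), replace = TRUE,
                    prob = w)
  cyto_population(pop$cells[idx], pop$generation)
}

#' Gametogenesis for one cell
#'
#' The parent produces two gametes, one of mating type `A` and one of type
#' `a`, each carrying exactly `b` genome copies drawn independently with
#' replacement from the parent's copies.
#'
#' @param cell A diploid [cell_state()] with `n` copies.
#' @param b Transmission bottleneck size, `b <= n / 2`.
#' @return List with elements `A` and `a`, each a `cell_state` of `b`
#'   copies.
#' @export
gametogenesis <- function(cell, b) {
  n <- n_copies(cell)
  stopifnot(b >= 1, b <= n / 2 || (b == 1 && n == 1))
  idx <- expand_copies(cell)
  draw <- function() {
    take <- idx[sample.int(length(idx), b, replace = TRUE)]
    cell_state(cell$alpha[take], cell$kappa[take], rep(1L, b))
  }
  list(A = draw(), a = draw())
}

#' Mating and repopulation stage
#'
#' `A`-type gametes are paired uniformly at random with `a`-type gametes.
#' Under uniparental inheritance only the `A` gamete's `b` genomes enter the
#' zygote pool; under biparental inheritance the pooled `2b` genomes of both
#' gametes do. Each new diploid cell is then restored to `n` genome copies by
#' sampling with replacement from its pool.
#'
#' @param gametes_A,gametes_a Lists of `N` gamete [cell_state()]s of each
#'   mating type.
#' @param inheritance `"uniparental"` or `"biparental"`.
#' @param n Genome copies per diploid cell.
#' @param generation Generation index assigned to the new population.
#' @return A `cyto_population` of `N` diploid cells.
#' @export
mate_and_repopulate <- function(gametes_A, gametes_a,
                                inheritance = c("uniparental", "biparental"),
                                n, generation = 0L) {
  inheritance <- match.arg(inheritance)
  if (length(gametes_A) != length(gametes_a))
    stop("internal consistency error: gamete pools differ in size")
  N <- length(gametes_A)
  pairing <- sample.int(N, N)
  cells <- vector("list", N)
  for (j in seq_len(N)) {
    pool <- if (inheritance == "uniparental") gametes_A[[j]] else
      cell_state(c(gametes_A[[j]]$alpha, gametes_a[[pairing[j]]]$alpha),
                 c(gametes_A[[j]]$kappa, gametes_a[[pairing[j]]]$kappa),
                 c(gametes_A[[j]]$count, gametes_a[[pairing[j]]]$count))
    idx <- expand_copies(pool)
    take <- idx[sample.int(length(idx), n, replace = TRUE)]
    cells[[j]] <- cell_state(pool$alpha[take], pool$kappa[take],
                             rep(1L, n))
  }
  cyto_population(cells, generation)
}

#' Advance a population by one full generation
#'
#' Applies the four life-cycle stages in order -- mutation, selection,
#' gametogenesis, mating/repopulation -- and increments the generation
#' index. This is the reference R implementation of the life cycle; long
#' runs use the equivalent compiled engine through [run_simulation()].
#'
#' @param pop A [cyto_population()].
#' @param config A [sim_config()].
#' @return The next generation's `cyto_population`.
#' @export
advance_generation <- function(pop, config) {
  stopifnot(inherits(pop, "cyto_population"), inherits(config, "sim_config"))
  mutated <- lapply(pop$cells, mutate_cell, l = config$l,
                    mu_b = config$mu_b, mu_d = config$mu_d)
  selected <- select_hosts(cyto_population(mutated, pop$generation),
                           config$fitness)
  gam <- lapply(selected$cells, gametogenesis, b = config$b)
  mate_and_repopulate(lapply(gam, `[[`, "A"), lapply(gam, `[[`, "a"),
                      config$inheritance, config$n,
                      generation = pop$generation + 1L)
}
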