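#' Fitness specification for host cells and free-living cells
#'
#' Builds the fitness map used by both simulation engines. A cell's relative
#' fitness depends only on the total number of beneficial (`x`) and
#' deleterious (`y`) substitutions carried by its cytoplasmic genomes. Both
#' axes saturate at `X = n_ref * gamma_ref` substitutions: a cell with zero
#' beneficial substitutions has fitness `1 - s_b` and a cell with `X` or more
#' has fitness 1 on the beneficial axis; a cell with zero deleterious
#' substitutions has fitness 1 and a cell with `X` or more has `1 - s_d` on
#' the deleterious axis.
#'
#' Between the endpoints the curves are endpoint-anchored power functions of
#' `u = min(x, X) / X`: the beneficial component is
#' `(1 - s_b) + s_b * u^theta` and the deleterious component is
#' `1 - s_d * u^theta`. The shape names fix the default exponent (beneficial:
#' `concave_up` 2, `linear` 1, `concave_down` 1/2; deleterious:
#' `concave_down` 2, `linear` 1) and can be overridden through
#' `beneficial_exponent` / `deleterious_exponent` to swap in alternative
#' forms with the same endpoints.
#'
#' @param s_b Beneficial selection coefficient, `0 <= s_b < 1`.
#' @param s_d Deleterious selection coefficient, `0 <= s_d < 1`.
#' @param beneficial_shape One of `"concave_up"`, `"linear"`,
#'   `"concave_down"`.
#' @param deleterious_shape One of `"concave_down"`, `"linear"`.
#' @param n_ref Reference genomes-per-cell count (the `n` the fitness axes
#'   are scaled to).
#' @param gamma_ref Reference per-genome substitution target; the saturation
#'   point of both axes is `n_ref * gamma_ref` substitutions.
#' @param s_FL Free-living scaling factor (>= 1): a substitution on a
#'   free-living genome has an `s_FL`-fold effect on its cell's fitness
#'   relative to a substitution on one cytoplasmic genome. Used only by
#'   [free_living_fitness()].
#' @param beneficial_exponent,deleterious_exponent Optional overrides of the
#'   shape exponents.
#' @return An object of class `fitness_spec`.
#' @examples
#' spec <- fitness_spec(s_b = 0.1, s_d = 0.1, n_ref = 50, gamma_ref = 5)
#' beneficial_factor(0, spec)    # 0.9
#' beneficial_factor(250, spec)  # 1.0
#' @export
fitness_spec <- function(s_b = 0.1, s_d = 0.1,
                         beneficial_shape = c("linear", "concave_up", "concave_down"),
                         deleterious_shape = c("concave_down", "linear"),
                         n_ref = 50, gamma_ref = 5, s_FL = 1,
                         beneficial_exponent = NULL,
                         deleterious_exponent = NULL) {
  beneficial_shape <- match.arg(beneficial_shape)
  deleterious_shape <- match.arg(deleterious_shape)
  stopifnot(s_b >= 0, s_b < 1, s_d >= 0, s_d < 1,
            n_ref >= 1, gamma_ref > 0, s_FL >= 1)
  theta_b <- beneficial_exponent %||%
    switch(beneficial_shape, concave_up = 2, linear = 1, concave_down = 0.5)
  theta_d <- deleterious_exponent %||%
    switch(deleterious_shape, concave_down = 2, linear = 1)
  stopifnot(theta_b > 0, theta_d > 0)
  structure(
    list(s_b = s_b, s_d = s_d,
         beneficial_shape = beneficial_shape,
         deleterious_shape = deleterious_shape,
         n_ref = n_ref, gamma_ref = gamma_ref, s_FL = s_FL,
         theta_b = theta_b, theta_d = theta_d,
         X = n_ref * gamma_ref),
    class = "fitness_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fitness_spec <- function(x, ...) {
  cat("<fitness_spec>\n")
  cat(sprintf("  beneficial: %s (s_b = %g, exponent %g)\n",
              x$beneficial_shape, x$s_b, x$theta_b))
  cat(sprintf("  deleterious: %s (s_d = %g, exponent %g)\n",
              x$deleterious_shape, x$s_d, x$theta_d))
  cat(sprintf("  saturation X = n_ref * gamma_ref = %g * %g = %g\n",
              x$n_ref, x$gamma_ref, x$X))
  cat(sprintf("  free-living scaling s_FL = %g\n", x$s_FL))
  invisible(x)
}

#' Beneficial component of cell fitness
#'
#' Maps the total number of beneficial substitutions in a cell onto the
#' interval `[1 - s_b, 1]`. Monotone non-decreasing; exactly `1 - s_b` at 0
#' and exactly 1 at or beyond the saturation point `X = n_ref * gamma_ref`.
#'
#' @param x Total beneficial substitutions in the cell (vectorised,
#'   non-negative).
#' @param spec A [fitness_spec()].
#' @return Fitness component(s) in `[1 - s_b, 1]`.
#' @export
beneficial_factor <- function(x, spec) {
  stopifnot(inherits(spec, "fitness_spec"))
  if (any(x < 0)) stop("beneficial substitution count must be non-negative")
  u <- pmin(x, spec$X) / spec$X
  (1 - spec$s_b) + spec$s_b * u^spec$theta_b
}

#' Deleterious component of cell fitness
#'
#' Maps the total number of deleterious substitutions in a cell onto
#' `[1 - s_d, 1]`. Monotone non-increasing; exactly 1 at 0 and exactly
#' `1 - s_d` at or beyond `X`. Under the default concave-down shape the
#' decline is slow near zero and steep near `X`, reflecting that cells
#' tolerate a small load of mutant genomes but are strongly affected once a
#' high proportion of their genomes carry deleterious substitutions.
#'
#' @param y Total deleterious substitutions in the cell (vectorised,
#'   non-negative).
#' @inheritParams beneficial_factor
#' @return Fitness component(s) in `[1 - s_d, 1]`.
#' @export
deleterious_factor <- function(y, spec) {
  stopifnot(inherits(spec, "fitness_spec"))
  if (any(y < 0)) stop("deleterious substitution count must be non-negative")
  u <- pmin(y, spec$X) / spec$X
  1 - spec$s_d * u^spec$theta_d
}

#' Relative fitness of a host cell
#'
#' Additive combination of the beneficial and deleterious components: the
#' deviations from 1 are summed, `w = w_b(x) + w_d(y) - 1`, floored at zero
#' so the result is always a valid sampling weight. Reduces to
#' [beneficial_factor()] when `y = 0` and to [deleterious_factor()] when
#' `x = 0`.
#'
#' @param x,y Total beneficial and deleterious substitutions in the cell
#'   (vectorised).
#' @inheritParams beneficial_factor
#' @return Relative fitness value(s), `>= 0`.
#' @export
cell_fitness <- function(x, y, spec) {
  pmax(0, beneficial_factor(x, spec) + deleterious_factor(y, spec) - 1)
}

#' Relative fitness of a free-living cell
#'
#' Fitness of a single-genome free-living cell carrying `alpha` beneficial
#' and `kappa` deleterious substitutions. Each substitution moves fitness by
#' `s_FL` times the per-substitution increment of the linear cytoplasmic
#' fitness function referenced to `X = n_ref * gamma_ref`, clamped at the
#' same endpoints (beneficial component at 1, deleterious at `1 - s_d`), and
#' the two components combine additively as in [cell_fitness()]. Only linear
#' shapes are meaningful here; requesting a non-linear shape is a
#' configuration error.
#'
#' @param alpha,kappa Per-genome beneficial and deleterious substitution
#'   counts (vectorised).
#' @inheritParams beneficial_factor
#' @return Relative fitness value(s), `>= 0`.
#' @export
free_living_fitness <- function(alpha, kappa, spec) {
  stopifnot(inherits(spec, "fitness_spec"))
  if (spec$beneficial_shape != "linear" || spec$deleterious_shape != "linear")
    stop("free-living fitness requires linear beneficial and deleterious shapes")
  if (any(alpha < 0) || any(kappa < 0))
    stop("substitution counts must be non-negative")
  wb <- pmin(1, (1 - spec$s_b) + spec$s_b * spec$s_FL * alpha / spec$X)
  wd <- pmax(1 - spec$s_d, 1 - spec$s_d * spec$s_FL * kappa / spec$X)
  pmax(0, wb + wd - 1)
}
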