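#' Infection kernels
#'
#' The probability that a virus-host encounter leads to lysis is the
#' product of two kernel values: a compatibility probability C (can this
#' virus recognize and attach to this host?) and a virulence probability
#' V (does a compatible encounter end in lytic infection?). Each kernel
#' comes in a trade-off based form, driven by the individuals' genes, and
#' a null form that draws uniformly from `[0, 1]`.
#'
#' Trade-off compatibility couples the host's nutrient-affinity gene
#' `g_alpha` to the virus's adsorption gene `g_beta` and host-range gene
#' `g_nu`:
#' \deqn{C_t = \exp(-|g_\alpha - g_\beta| / g_\nu)}
#' so infection is most likely when the competitive host trait matches
#' the viral attachment trait, and broad host range (large `g_nu`)
#' forgives mismatch. Trade-off virulence penalizes breadth:
#' \deqn{V_t = \min(1,\; \beta_n g_\beta / g_\nu)}
#' with `beta_n` the volume-normalized adsorption coefficient — narrow
#' host range and strong adsorption make an attached virus more lethal.
#' `g_nu` is floored at `gene_floor_eps` in both denominators; at
#' `g_alpha == g_beta` compatibility is exactly 1 for any `g_nu`.
#'
#' All four functions are vectorized and recycle arguments.
#'
#' @param g_alpha Host nutrient-affinity gene value(s) in `[0, 1]`.
#' @param g_nu Virus host-range (memory) gene value(s) in `[0, 1]`.
#' @param g_beta Virus adsorption gene value(s) in `[0, 1]`.
#' @param beta_n Volume-normalized adsorption coefficient (`beta / V`),
#'   non-negative.
#' @param gene_floor_eps Floor for `g_nu` in denominators.
#' @param n Number of random kernel draws.
#' @param scale Upper end of the random-virulence draw. The null model for
#'   virulence randomizes the genotypic ratio `g_beta / g_nu` while keeping
#'   the physical adsorption scale, so the simulation engine draws random
#'   virulence uniformly on `[0, beta_n]`; the default `scale = 1` gives a
#'   plain unit-interval draw.
#' @return Probabilities in `[0, 1]`.
#' @examples
#' compat_tradeoff(0.1, 0.1, 0.1)        # identical genes: 1
#' compat_tradeoff(0.2, 0.1, 0.1)        # exp(-1)
#' virulence_tradeoff(0.1, 0.1, 6.2e-5)  # g_beta == g_nu: beta_n itself
#' @name kernels
NULL

check_gene <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1)) {
    stop(sprintf("%s must be numeric in [0, 1]", name), call. = FALSE)
  }
}

#' @rdname kernels
#' @export
compat_tradeoff <- function(g_alpha, g_nu, g_beta, gene_floor_eps = 1e-9) {
  check_gene(g_alpha, "g_alpha")
  check_gene(g_nu, "g_nu")
  check_gene(g_beta, "g_beta")
  exp(-abs(g_alpha - g_beta) / pmax(g_nu, gene_floor_eps))
}

#' @rdname kernels
#' @export
compat_random <- function(n = 1L) {
  stats::runif(n)
}

#' @rdname kernels
#' @export
virulence_tradeoff <- function(g_nu, g_beta, beta_n, gene_floor_eps = 1e-9) {
  check_gene(g_nu, "g_nu")
  check_gene(g_beta, "g_beta")
  if (any(beta_n < 0)) stop("beta_n must be non-negative", call. = FALSE)
  pmin(1, beta_n * g_beta / pmax(g_nu, gene_floor_eps))
}

#' @rdname kernels
#' @export
virulence_random <- function(n = 1L, scale = 1) {
  if (scale < 0 || scale > 1) stop("scale must lie in [0, 1]", call. = FALSE)
  scale * stats::runif(n)
}
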