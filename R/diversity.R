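#' Shannon entropy of a trait distribution
#'
#' Bins gene values into `n_bins` equal-width bins on `[0, 1]` and
#' returns the Shannon entropy (natural log) of the bin frequencies:
#' `H = -sum(p_k * log(p_k))` over occupied bins. A monomorphic sample
#' gives 0; the maximum is `log(n_bins)`. Entropies are comparable only
#' at a fixed `n_bins`.
#'
#' @param gene_values Numeric vector of gene values in `[0, 1]`.
#' @param n_bins Number of bins.
#' @return Entropy (dimensionless, nats).
#' @examples
#' shannon_entropy(rep(0.3, 100), 50)          # 0
#' shannon_entropy(c(rep(0.05, 10), rep(0.55, 10)), 10)  # log(2)
#' @export
shannon_entropy <- function(gene_values, n_bins = 50L) {
  if (length(gene_values) == 0L) {
    stop("entropy of an empty population is undefined", call. = FALSE)
  }
  check_gene(gene_values, "gene_values")
  stopifnot(n_bins >= 1L)
  k <- pmin(as.integer(n_bins) - 1L, floor(gene_values * n_bins))
  counts <- tabulate(k + 1L, nbins = as.integer(n_bins))
  entropy_from_counts(counts)
}

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Trait-diversity time series
#'
#' Per-step Shannon entropy of the three gene distributions (`g_alpha`
#' for hosts, `g_nu` and `g_beta` for viruses), computed from the binned
#' gene histograms recorded along a trajectory. Steps where a population
#' is extinct yield `NA` (entropy undefined), not 0.
#'
#' @param trajectory A `sim_trajectory` from [run_simulation()].
#' @param n_bins Bin count; must match the binning the trajectory was
#'   recorded with (`trajectory$n_bins`).
#' @return Data frame with columns `t`, `H_g_alpha`, `H_g_nu`,
#'   `H_g_beta`.
#' @export
diversity_timeseries <- function(trajectory, n_bins = trajectory$n_bins) {
  stopifnot(inherits(trajectory, "sim_trajectory"))
  if (!identical(as.integer(n_bins), trajectory$n_bins)) {
    stop(sprintf(paste0("trajectory gene histograms were recorded with %d bins; ",
                        "re-run run_simulation() with n_bins = %d to change binning"),
                 trajectory$n_bins, as.integer(n_bins)), call. = FALSE)
  }
  ent_series <- function(H) {
    apply(H, 2L, function(cts) {
      if (sum(cts) == 0L) NA_real_ else entropy_from_counts(cts)
    })
  }
  data.frame(t = trajectory$records$t,
             H_g_alpha = ent_series(trajectory$hist$g_alpha),
             H_g_nu = ent_series(trajectory$hist$g_nu),
             H_g_beta = ent_series(trajectory$hist$g_beta))
}
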