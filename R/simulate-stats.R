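#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Gene means are drawn log-uniformly over `mean_range`; counts are negative
#' binomial with the stated dispersion (Poisson when `dispersion = 0`). A
#' fraction `de_fraction` of genes has its group-2 mean multiplied by
#' `fold_change`.
#'
#' @param n_genes number of genes.
#' @param n_per_group replicates per group (two groups).
#' @param mean_range length-2 numeric range of baseline gene means.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2); >= 0.
#' @param de_fraction fraction of genes with a planted fold change.
#' @param fold_change multiplicative group-2 effect for planted genes (> 0).
#' @param seed RNG seed.
#' @return list with `counts` (an [count_matrix()] with library totals equal
#'   to column sums), `groups` (factor), and `is_de` (logical truth labels).
#' @export
simulate_counts <- function(n_genes, n_per_group,
                            mean_range = c(20, 2000),
                            dispersion = 0.1,
                            de_fraction = 0,
                            fold_change = 2,
                            seed = 1L) {
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  if (fold_change <= 0) stop("'fold_change' must be > 0")
  if (de_fraction < 0 || de_fraction > 1) stop("'de_fraction' must be in [0, 1]")
  stopifnot(n_genes >= 1, n_per_group >= 1, all(mean_range > 0))
  set.seed(seed)
  mu0 <- exp(stats::runif(n_genes, log(mean_range[1]), log(mean_range[2])))
  n_de <- round(de_fraction * n_genes)
  is_de <- rep(FALSE, n_genes)
  if (n_de > 0) is_de[sample.int(n_genes, n_de)] <- TRUE
  mu2 <- mu0 * ifelse(is_de, fold_change, 1)

  draw <- function(mu, n) {
    m <- matrix(rep(mu, n), nrow = length(mu))
    if (dispersion == 0)
      matrix(stats::rpois(length(m), m), nrow = length(mu))
    else
      matrix(stats::rnbinom(length(m), size = 1 / dispersion, mu = m),
             nrow = length(mu))
  }
  counts <- cbind(draw(mu0, n_per_group), draw(mu2, n_per_group))
  rownames(counts) <- sprintf("GENE%05d", seq_len(n_genes))
  colnames(counts) <- c(sprintf("g1_%d", seq_len(n_per_group)),
                        sprintf("g2_%d", seq_len(n_per_group)))
  groups <- factor(rep(c("g1", "g2"), each = n_per_group))
  list(counts = count_matrix(counts, colSums(counts), species = "human"),
       groups = groups, is_de = is_de)
}

#' Simulate a noisy exponential tumor growth series
#'
#' Volumes follow `V0 * 2^(t / Td) * exp(eps)` with
#' `eps ~ Normal(0, noise_sd^2)` on the log scale.
#'
#' @param V0 starting volume (> 0), in any consistent volume unit.
#' @param doubling_time doubling time Td in days (> 0).
#' @param timepoints measurement days.
#' @param noise_sd log-scale noise standard deviation.
#' @param seed RNG seed.
#' @return data.frame with `day` and `volume`.
#' @export
simulate_growth <- function(V0, doubling_time, timepoints,
                            noise_sd = 0, seed = 1L) {
  if (V0 <= 0) stop("'V0' must be > 0")
  if (doubling_time <= 0) stop("'doubling_time' must be > 0")
  set.seed(seed)
  eps <- stats::rnorm(length(timepoints), 0, noise_sd)
  data.frame(day = timepoints,
             volume = V0 * 2^(timepoints / doubling_time) * exp(eps))
}
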