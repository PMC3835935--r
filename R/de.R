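#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order. The adjustment is not idempotent (re-adjusting adjusted values is
#' meaningless) and preserves order on sorted inputs.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted values in `[0, 1]`, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Estimate per-gene negative-binomial dispersions
#'
#' Method-of-moments dispersion within each group of replicates, computed on
#' counts rescaled to a common library size, pooled across groups and shrunk
#' toward the common (all-gene median) dispersion with a fixed weight.
#'
#' @param counts an `xs_counts` or a counts matrix.
#' @param groups factor over samples (columns) with two or more levels.
#' @param library_totals totals for rescaling; taken from the object when
#'   `counts` is an `xs_counts`.
#' @param shrink weight in `[0, 1]` given to the common dispersion
#'   (default 0.7; strong shrinkage stabilizes the noisy per-gene moment
#'   estimates at small replicate numbers).
#' @return numeric vector of per-gene dispersions (>= 0), with the common
#'   dispersion as attribute `common`.
#' @export
estimate_dispersion <- function(counts, groups, library_totals = NULL,
                                shrink = 0.7) {
  if (inherits(counts, "xs_counts")) {
    library_totals <- counts$library_totals
    counts <- counts$counts
  }
  if (is.null(library_totals)) library_totals <- colSums(counts)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(counts))
  # rescale to the mean library size so within-group variance is comparable
  y <- sweep(counts, 2L, mean(library_totals) / library_totals, "*")

  sizes <- table(groups)
  usable <- names(sizes)[sizes >= 2L]
  if (length(usable) == 0L)
    stop("at least one group with >= 2 samples is required")
  if (length(usable) < nlevels(groups))
    warning("single-sample group(s) ignored for dispersion estimation; ",
            "common dispersion applies")

  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts))
  for (g in usable) {
    yg <- y[, groups == g, drop = FALSE]
    m <- rowMeans(yg)
    v <- apply(yg, 1L, stats::var)
    df <- ncol(yg) - 1L
    ok <- m > 0
    phi_g <- ifelse(ok, (v - m) / m^2, 0)
    num <- num + df * phi_g
    den <- den + df
  }
  phi <- pmax(0, num / den)
  common <- stats::median(phi[rowSums(counts) > 0])
  if (!is.finite(common)) common <- 0
  out <- pmax(0, (1 - shrink) * phi + shrink * common)
  attr(out, "common") <- common
  out
}

#' Conditional negative-binomial exact-style test
#'
#' Tests equality of group means for one gene. Group sums are modeled as
#' negative binomial (Poisson when `dispersion = 0`); conditional on the
#' pooled total, the two-sided p-value sums the probabilities of all splits
#' as or less likely than the observed one (minimum-likelihood convention).
#' With `dispersion = 0` the conditional distribution is exactly binomial in
#' the library-size share.
#'
#' @param counts_A,counts_B non-negative integer counts per sample.
#' @param dispersion NB dispersion (>= 0).
#' @param totals_A,totals_B per-sample library totals.
#' @return two-sided p-value in `(0, 1]`.
#' @export
nb_exact_test <- function(counts_A, counts_B, dispersion,
                          totals_A = rep(1, length(counts_A)),
                          totals_B = rep(1, length(counts_B))) {
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  if (any(c(counts_A, counts_B) < 0)) stop("counts must be non-negative")
  sA <- sum(counts_A); sB <- sum(counts_B)
  s <- sA + sB
  if (s == 0) return(1)
  TA <- sum(totals_A); TB <- sum(totals_B)
  k <- 0:s
  if (dispersion == 0) {
    logp <- stats::dbinom(k, s, TA / (TA + TB), log = TRUE)
  } else {
    mu <- s / (TA + TB)
    logp <- stats::dnbinom(k, size = length(counts_A) / dispersion,
                           mu = mu * TA, log = TRUE) +
            stats::dnbinom(s - k, size = length(counts_B) / dispersion,
                           mu = mu * TB, log = TRUE)
    logp <- logp - log(sum(exp(logp - max(logp)))) - max(logp)
  }
  obs <- logp[sA + 1L]
  min(1, sum(exp(logp[logp <= obs + 1e-7])))
}

#' Differential expression between two groups
#'
#' Per-gene conditional NB exact-style tests with moment/shrinkage
#' dispersions, Benjamini-Hochberg adjustment, and a `fdr < 0.05` call.
#' Log2 fold changes are computed on mean CPM with a 0.5 offset to avoid
#' log of zero.
#'
#' @param counts an `xs_counts`.
#' @param groups two-level factor over the samples.
#' @param fdr_threshold FDR call threshold (default 0.05).
#' @param normalization `"median_ratio"` (default) rescales the library
#'   totals by median-of-ratios size factors, which keeps tests calibrated
#'   when a minority of strongly changed genes shifts the column sums
#'   (composition bias); `"library_totals"` uses the stored totals as is.
#' @return data.frame: `gene_id`, `log_fold_change` (group 2 vs group 1),
#'   `p_value`, `fdr`, `is_de`.
#' @export
differential_expression <- function(counts, groups, fdr_threshold = 0.05,
                                    normalization = c("median_ratio",
                                                      "library_totals")) {
  stopifnot(inherits(counts, "xs_counts"))
  normalization <- match.arg(normalization)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (nrow(counts$counts) == 0L) stop("empty count matrix")
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  m <- counts$counts
  tot <- counts$library_totals
  if (normalization == "median_ratio") {
    sf <- median_ratio_size_factors(m)
    tot <- sf * mean(tot) / mean(sf)
  }
  counts_eff <- counts
  counts_eff$library_totals <- tot
  disp <- estimate_dispersion(m, groups, library_totals = tot)
  p <- vapply(seq_len(nrow(m)), function(i) {
    nb_exact_test(m[i, ia], m[i, ib], disp[i], tot[ia], tot[ib])
  }, numeric(1))
  cpm <- cpm_normalize(m, tot)
  lfc <- log2((rowMeans(cpm[, ib, drop = FALSE]) + 0.5) /
              (rowMeans(cpm[, ia, drop = FALSE]) + 0.5))
  fdr <- bh_adjust(p)
  data.frame(gene_id = rownames(m),
             log_fold_change = lfc,
             p_value = p,
             fdr = fdr,
             is_de = fdr < fdr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

# DESeq-style median-of-ratios size factors (geometric-mean reference)
median_ratio_size_factors <- function(m) {
  lg <- rowMeans(log(m))
  use <- is.finite(lg)
  if (sum(use) < 10L) return(colSums(m) / mean(colSums(m)))
  apply(m, 2L, function(col) exp(stats::median(log(col[use]) - lg[use])))
}
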