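#' Read gene sets from a GMT file
#'
#' @param path GMT path (set id, description, then member genes, tab
#'   separated).
#' @return named list of unique member gene id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "", USE.NAMES = FALSE)
  out
}

# Wallenius non-central hypergeometric pmf over the full support.
# m1 in-set genes, m2 out-of-set, n draws, odds = weight ratio. Uses the
# integral representation with substitution u = t^(1/D), which makes the
# integrand smooth; at odds == 1 the integral has an exact beta closed form
# (and the distribution is centrally hypergeometric).
dwallenius_support <- function(m1, m2, n, odds) {
  lo <- max(0L, n - m2); hi <- min(n, m1)
  x <- lo:hi
  if (odds == 1) {
    D <- m1 + m2 - n
    logI <- if (D == 0) 0 else log(D) + lbeta(D, n + 1)
    logp <- lchoose(m1, x) + lchoose(m2, n - x) + logI
    p <- exp(logp)
    return(list(x = x, p = p / sum(p)))
  }
  p <- vapply(x, function(xi) {
    D <- odds * (m1 - xi) + (m2 - (n - xi))
    if (D <= 0) return(1)  # everything drawn: degenerate point
    lc <- lchoose(m1, xi) + lchoose(m2, n - xi) + log(D)
    f <- function(u) {
      lg <- (D - 1) * log(u)
      lg[u == 0] <- if (D >= 1) -Inf else Inf
      v <- exp(xi * log1p(-pmin(u^odds, 1 - 1e-16)) +
               (n - xi) * log1p(-pmin(u, 1 - 1e-16)) + lg + lc)
      v[u == 0 & D > 1] <- 0
      v
    }
    stats::integrate(f, 0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
  }, numeric(1))
  list(x = x, p = p / sum(p))
}

#' Wallenius non-central hypergeometric gene-set enrichment
#'
#' Approximates the distribution of gene-set members among differentially
#' expressed genes by weighted sampling without replacement: the odds
#' parameter is the ratio of the mean bias weight of in-set genes to that of
#' out-of-set genes. With uniform weights this reduces exactly to the central
#' hypergeometric (one-sided Fisher) test. Reported are the upper-tail
#' (over-representation) and lower-tail (under-representation) probabilities
#' of the observed in-set DE count.
#'
#' @param de_flags named logical vector over the gene universe (TRUE =
#'   differentially expressed).
#' @param gene_sets named list of member gene id vectors (e.g. [read_gmt()]).
#' @param bias_weights optional positive weights named by gene (e.g. gene
#'   length or mean expression); default uniform.
#' @return data.frame: `set_id`, `n_in_set`, `n_de_in_set`, `odds`,
#'   `p_over`, `p_under`.
#' @export
wallenius_enrichment <- function(de_flags, gene_sets, bias_weights = NULL) {
  if (is.null(names(de_flags))) stop("'de_flags' must be named by gene")
  universe <- names(de_flags)
  N <- length(universe)
  n_de <- sum(de_flags)
  if (is.null(bias_weights)) {
    bias_weights <- stats::setNames(rep(1, N), universe)
  } else {
    bias_weights <- bias_weights[universe]
    if (anyNA(bias_weights) || any(bias_weights <= 0))
      stop("bias weights must be positive for every universe gene")
  }
  rows <- lapply(names(gene_sets), function(sid) {
    members <- intersect(gene_sets[[sid]], universe)
    m1 <- length(members)
    x <- sum(de_flags[members])
    if (N == 0L || n_de == 0L || m1 == 0L)
      return(data.frame(set_id = sid, n_in_set = m1, n_de_in_set = x,
                        odds = NA_real_, p_over = 1, p_under = 1,
                        stringsAsFactors = FALSE))
    inset <- universe %in% members
    odds <- mean(bias_weights[inset]) / mean(bias_weights[!inset])
    d <- dwallenius_support(m1, N - m1, n_de, odds)
    data.frame(set_id = sid, n_in_set = m1, n_de_in_set = x,
               odds = odds,
               p_over = min(1, sum(d$p[d$x >= x])),
               p_under = min(1, sum(d$p[d$x <= x])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-tailed Fisher's exact test
#'
#' Exact two-tailed p-value for a 2x2 contingency table, summing the
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed the observed table's (minimum-likelihood
#' convention).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-tailed p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table, alternative = "two.sided")$p.value
}
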