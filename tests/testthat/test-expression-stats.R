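# step-up BH computed straight from its definition, as an independent check
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(43)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= 0 & q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # order-preserving
  }
})

test_that("dispersion estimation recovers planted values", {
  simP <- simulate_counts(300, 50, dispersion = 0, de_fraction = 0, seed = 47)
  dP <- estimate_dispersion(simP$counts, simP$groups)
  expect_lte(median(dP), 0.05)

  flat <- count_matrix(matrix(7L, 20, 6,
                              dimnames = list(paste0("g", 1:20),
                                              paste0("s", 1:6))),
                       library_totals = rep(140, 6))
  d0 <- estimate_dispersion(flat, rep(c("a", "b"), each = 3))
  expect_true(all(d0 == 0))

  simN <- simulate_counts(300, 50, dispersion = 0.4, de_fraction = 0,
                          seed = 48)
  dN <- estimate_dispersion(simN$counts, simN$groups)
  expect_gte(median(dN), 0.25)
  expect_lte(median(dN), 0.55)

  expect_warning(
    estimate_dispersion(flat$counts, c("a", "a", "a", "b", "b", "c")),
    "single-sample")
})

test_that("the conditional NB test matches enumeration in the Poisson limit", {
  expect_equal(nb_exact_test(c(3, 4), c(3, 4), 0.1), 1)
  expect_equal(nb_exact_test(0, 0, 0.2), 1)
  expect_error(nb_exact_test(1, 2, -0.5), ">= 0")

  # dispersion 0, equal library sizes: conditional law is Binomial(s, 1/2);
  # enumerate the two-sided minimum-likelihood sum directly
  binom_oracle <- function(sA, sB) {
    s <- sA + sB
    pk <- dbinom(0:s, s, 0.5)
    sum(pk[pk <= pk[sA + 1] * (1 + 1e-7)])
  }
  expect_equal(nb_exact_test(5, 0, 0), binom_oracle(5, 0))
  for (sA in 0:6) for (sB in 0:6) {
    if (sA + sB == 0) next
    expect_equal(nb_exact_test(sA, sB, 0), binom_oracle(sA, sB))
  }
})

test_that("differential expression controls FDR and finds planted effects", {
  sim <- simulate_counts(2000, 5, dispersion = 0.1, de_fraction = 0.05,
                         fold_change = 6, seed = 12)
  de <- differential_expression(sim$counts, sim$groups)
  flagged <- de$is_de
  sens <- sum(flagged & sim$is_de) / sum(sim$is_de)
  obs_fdr <- sum(flagged & !sim$is_de) / max(1, sum(flagged))
  expect_gte(sens, 0.5)
  expect_lte(obs_fdr, 0.10)
  expect_true(all(de$is_de == (de$fdr < 0.05)))
  # planted effects are up in group 2
  expect_gt(median(de$log_fold_change[sim$is_de]), 1)
})

test_that("null simulations give uniform p-values and few flags", {
  sim <- simulate_counts(2000, 5, dispersion = 0.1, de_fraction = 0,
                         seed = 11)
  de <- differential_expression(sim$counts, sim$groups)
  expect_lte(mean(de$is_de), 0.05)
  ks <- suppressWarnings(stats::ks.test(de$p_value, "punif"))$statistic
  expect_lte(unname(ks), 0.05)
})

test_that("all-zero genes are never called differentially expressed", {
  m <- matrix(c(0, 0, 0, 0, 10, 20, 30, 40), 2, 4, byrow = TRUE,
              dimnames = list(c("zero", "expr"), paste0("s", 1:4)))
  cm <- count_matrix(m, library_totals = rep(1e6, 4))
  de <- differential_expression(cm, c("a", "a", "b", "b"))
  expect_equal(de$p_value[de$gene_id == "zero"], 1)
  expect_false(de$is_de[de$gene_id == "zero"])
})

test_that("NB test ranks genes like an independent exact-test implementation", {
  skip_if_not_installed("edgeR")
  sim <- simulate_counts(300, 4, dispersion = 0.15, de_fraction = 0.2,
                         fold_change = 4, seed = 53)
  de <- differential_expression(sim$counts, sim$groups)
  y <- edgeR::DGEList(counts = sim$counts$counts,
                      group = sim$groups)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y)
  et <- edgeR::exactTest(y)
  expect_gt(cor(-log10(de$p_value), -log10(et$table$PValue),
                method = "spearman"), 0.9)
})

test_that("Wallenius enrichment reduces to the central hypergeometric at odds 1", {
  set.seed(57)
  de <- stats::setNames(rep(FALSE, 40), paste0("g", 1:40))
  de[sample(40, 12)] <- TRUE
  sets <- list(s1 = paste0("g", 1:10), s2 = paste0("g", 30:40))
  res <- wallenius_enrichment(de, sets)
  for (i in 1:2) {
    m1 <- res$n_in_set[i]; x <- res$n_de_in_set[i]
    expect_equal(res$p_over[i],
                 phyper(x - 1, m1, 40 - m1, 12, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(res$p_under[i], phyper(x, m1, 40 - m1, 12),
                 tolerance = 1e-12)
  }
  # empty set and empty DE list fall back to p = 1
  expect_equal(wallenius_enrichment(de, list(none = "absent"))$p_over, 1)
  de0 <- stats::setNames(rep(FALSE, 40), paste0("g", 1:40))
  expect_equal(wallenius_enrichment(de0, sets)$p_over, c(1, 1))
})

test_that("Wallenius tails match weighted sampling without replacement", {
  # universe 20, set of 6 with weight 2.5, draw 8: exponential-race draws
  # are equivalent to successive weighted sampling without replacement
  n_mc <- 1e6
  set.seed(59)
  w <- c(rep(2.5, 6), rep(1, 14))
  e <- matrix(stats::rexp(n_mc * 20, rate = rep(w, each = n_mc)), n_mc, 20)
  # an in-set gene is drawn iff its exponential arrival ranks in the first 8
  x_mc <- integer(n_mc)
  for (j in 1:6) {
    r <- rep(1L, n_mc)
    for (k in 1:20) if (k != j) r <- r + (e[, k] < e[, j])
    x_mc <- x_mc + (r <= 8L)
  }
  de <- stats::setNames(rep(FALSE, 20), paste0("g", 1:20))
  weights <- stats::setNames(w, paste0("g", 1:20))
  for (x_obs in c(3, 4, 5)) {
    de[] <- FALSE; de[1:x_obs] <- TRUE
    de[paste0("g", 7:(7 + 8 - x_obs - 1))] <- TRUE  # 8 DE genes total
    res <- wallenius_enrichment(de, list(s = paste0("g", 1:6)),
                                bias_weights = weights)
    p_hat <- mean(x_mc >= x_obs)
    se <- sqrt(p_hat * (1 - p_hat) / n_mc)
    expect_lte(abs(res$p_over - p_hat), 3 * se + 1e-12)
  }
})

test_that("Fisher's exact test is exact, symmetric and handles degeneracy", {
  expect_equal(round(fisher_exact(matrix(c(3, 11, 26, 19), 2, byrow = TRUE)),
                     2), 0.03)
  expect_equal(fisher_exact(matrix(c(0, 5, 0, 7), 2, byrow = TRUE)), 1)
  set.seed(61)
  for (i in 1:25) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact(tab)
    expect_equal(fisher_exact(tab[2:1, ]), p)
    expect_equal(fisher_exact(tab[, 2:1]), p)
    expect_equal(fisher_exact(t(tab)), p)
  }
})

test_that("stromal scores separate carcinoma from stroma-retaining profiles", {
  sig <- signature_definition()
  expr <- stats::setNames(rep(0, 15), c(sig$stromal_genes, sig$epithelial_genes))
  expr[sig$epithelial_genes] <- 8
  cx <- stromal_score(expr, sig)
  expect_lt(cx$score, 0)
  expect_identical(cx$call, "CX")

  expr_sym <- stats::setNames(rep(5, 15),
                              c(sig$stromal_genes, sig$epithelial_genes))
  expect_equal(stromal_score(expr_sym, sig)$score, 0)
  expect_identical(stromal_score(expr_sym, sig)$call, "CX")  # boundary

  # planted profiles: stromal genes 32x higher in SX-like samples
  set.seed(67)
  genes <- c(sig$stromal_genes, sig$epithelial_genes, paste0("other", 1:50))
  for (i in 1:10) {
    base <- stats::setNames(rnorm(length(genes), 5, 0.5), genes)
    sx <- base; sx[sig$stromal_genes] <- sx[sig$stromal_genes] + log2(32)
    cx2 <- base; cx2[sig$stromal_genes] <- cx2[sig$stromal_genes] - log2(32)
    expect_identical(stromal_score(sx, sig)$call, "SX")
    expect_identical(stromal_score(cx2, sig)$call, "CX")
  }
  expect_error(stromal_score(c(FN1 = 1), sig), "each signature list")
})

test_that("qPCR ratios normalize to GAPDH and flag floor substitutions", {
  q <- function(n0, det = TRUE) qpcr_measurement(n0, det)
  expect_equal(qpcr_ratio(q(5), q(5), q(2), q(2), floor = 0.1)$ratio, 1)
  hand <- qpcr_ratio(q(8), q(2), q(4), q(2), floor = 0.1)
  expect_equal(hand$ratio, 2)
  expect_identical(hand$flag, "none")

  down <- qpcr_ratio(q(NA, FALSE), q(2), q(4), q(2), floor = 0.5)
  expect_equal(down$ratio, (0.5 / 4) / (2 / 2))
  expect_identical(down$flag, "down")
  up <- qpcr_ratio(q(2), q(NA, FALSE), q(4), q(2), floor = 0.5)
  expect_identical(up$flag, "up")
  both <- qpcr_ratio(q(NA, FALSE), q(NA, FALSE), q(4), q(2), floor = 0.5)
  expect_identical(both$flag, "indeterminate")
  expect_error(qpcr_ratio(q(1), q(1), q(NA, FALSE), q(2), floor = 0.5),
               "GAPDH")
})
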