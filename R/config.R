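#' Simulation configuration
#'
#' Bundle of parameters controlling the synthetic xenograft RNA-seq generator:
#' paired orthologous single-exon transcripts at a given per-base divergence,
#' and truth-labeled reads drawn from a configurable human/mouse mixture with
#' independent per-base sequencing error.
#'
#' @param n_genes number of orthologue pairs to simulate.
#' @param gene_length_range integer vector of length 2; transcript lengths are
#'   drawn uniformly from this range (bp).
#' @param divergence per-base substitution probability between the human and
#'   mouse copy of each transcript, in `[0, 1]`. Default 0.12, the order of
#'   typical human-mouse exonic divergence.
#' @param read_length read length in bp. Default 50.
#' @param error_rate per-base sequencing error probability in `[0, 1]`.
#' @param species_mix named fractions `c(human = , mouse = )` summing to 1;
#'   each fragment's species of origin is drawn from this mixture.
#' @param paired logical; emit paired-end fragments (two mates per fragment)?
#' @param seed integer seed; the same configuration and seed reproduce all
#'   generated files byte for byte.
#'
#' @return An object of class `xs_config` (a validated list).
#' @export
sim_config <- function(n_genes = 60L,
                       gene_length_range = c(300L, 1500L),
                       divergence = 0.12,
                       read_length = 50L,
                       error_rate = 0.01,
                       species_mix = c(human = 0.9, mouse = 0.1),
                       paired = TRUE,
                       seed = 1L) {
  stopifnot(is.numeric(n_genes), length(n_genes) == 1L, n_genes >= 1)
  stopifnot(length(gene_length_range) == 2L,
            all(gene_length_range >= 1),
            gene_length_range[1] <= gene_length_range[2])
  if (!is.numeric(divergence) || divergence < 0 || divergence > 1)
    stop("'divergence' must be a fraction in [0, 1]")
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate > 1)
    stop("'error_rate' must be a fraction in [0, 1]")
  stopifnot(is.numeric(read_length), read_length >= 1)
  if (read_length > gene_length_range[1])
    stop("'read_length' must not exceed the shortest transcript length")
  if (length(species_mix) != 2L || is.null(names(species_mix)) ||
      !setequal(names(species_mix), c("human", "mouse")))
    stop("'species_mix' must be named fractions c(human = , mouse = )")
  if (any(species_mix < 0) || abs(sum(species_mix) - 1) > 1e-9)
    stop("'species_mix' fractions must be non-negative and sum to 1 (tol 1e-9)")
  stopifnot(is.logical(paired), length(paired) == 1L)
  stopifnot(is.numeric(seed), length(seed) == 1L)

  structure(list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    divergence = divergence,
    read_length = as.integer(read_length),
    error_rate = error_rate,
    species_mix = species_mix[c("human", "mouse")],
    paired = paired,
    seed = as.integer(seed)
  ), class = "xs_config")
}

#' @export
print.xs_config <- function(x, ...) {
  cat("xenosplit simulation config\n")
  cat(sprintf("  genes: %d (%d-%d bp), divergence %.3f\n",
              x$n_genes, x$gene_length_range[1], x$gene_length_range[2],
              x$divergence))
  cat(sprintf("  reads: %d bp, %s, error rate %.4f, mix human %.3f / mouse %.3f\n",
              x$read_length, if (x$paired) "paired" else "single-end",
              x$error_rate, x$species_mix["human"], x$species_mix["mouse"]))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
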