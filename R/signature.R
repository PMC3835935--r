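#' Stromal/epithelial signature definition
#'
#' Defines the gene lists used to call a xenograft's human component as
#' carcinoma-only (CX) or stroma-retaining (SX). Defaults cover canonical
#' human stromal markers (fibronectin, vimentin, endosialin, stromal
#' collagens, matrix metallopeptidases, endothelial PECAM1 and the CD3
#' T-cell complex) against epithelial markers.
#'
#' @param stromal_genes,epithelial_genes disjoint character vectors.
#' @param threshold score cutoff above which a sample is called SX.
#' @return list of class `xs_signature`.
#' @export
signature_definition <- function(
    stromal_genes = c("FN1", "VIM", "CD248", "COL1A2", "COL6A2", "COL6A3",
                      "MMP2", "MMP9", "PECAM1", "CD3D", "CD3E", "CD3G"),
    epithelial_genes = c("EPCAM", "CEACAM5", "CDH1"),
    threshold = 0) {
  if (length(intersect(stromal_genes, epithelial_genes)))
    stop("stromal and epithelial gene lists must be disjoint")
  structure(list(stromal_genes = unique(stromal_genes),
                 epithelial_genes = unique(epithelial_genes),
                 threshold = threshold),
            class = "xs_signature")
}

#' Stromal signature score and CX/SX call
#'
#' Score = mean log-expression of the stromal genes minus mean log-expression
#' of the epithelial genes; a sample scoring above the threshold is called a
#' stromal xenograft (SX), otherwise a carcinoma xenograft (CX).
#'
#' @param sample_expression named numeric vector of log-scale expression
#'   (e.g. a column of a `log2(CPM + 1)` matrix).
#' @param signature an [signature_definition()].
#' @return list with `score`, `call` (`"CX"` or `"SX"`), and the number of
#'   signature genes found per list.
#' @export
stromal_score <- function(sample_expression,
                          signature = signature_definition()) {
  stopifnot(inherits(signature, "xs_signature"))
  if (is.null(names(sample_expression)))
    stop("'sample_expression' must be named by gene")
  s <- intersect(signature$stromal_genes, names(sample_expression))
  e <- intersect(signature$epithelial_genes, names(sample_expression))
  if (length(s) == 0L || length(e) == 0L)
    stop("at least one gene of each signature list must be present")
  score <- mean(sample_expression[s]) - mean(sample_expression[e])
  list(score = score,
       call = if (score > signature$threshold) "SX" else "CX",
       n_stromal = length(s), n_epithelial = length(e))
}

#' qPCR measurement
#'
#' @param N0 estimated starting concentration (arbitrary units; > 0 when
#'   detectable).
#' @param detectable was the transcript detected?
#' @return list of class `xs_qpcr`.
#' @export
qpcr_measurement <- function(N0, detectable = TRUE) {
  if (detectable && (!is.numeric(N0) || is.na(N0) || N0 <= 0))
    stop("detectable measurements require N0 > 0")
  structure(list(N0 = if (detectable) N0 else NA_real_,
                 detectable = detectable), class = "xs_qpcr")
}

#' GAPDH-normalized qPCR expression ratio between two samples
#'
#' Computes `(N0_target_a / N0_gapdh_a) / (N0_target_b / N0_gapdh_b)`.
#' Undetectable target measurements are substituted with the floor (minimal
#' expression) value and flagged: `"down"` when the numerator sample's target
#' was undetectable, `"up"` for the denominator sample, `"indeterminate"`
#' when both were undetectable. GAPDH must be detectable in both samples.
#'
#' @param target_a,target_b [qpcr_measurement()]s of the target gene in the
#'   numerator and denominator samples.
#' @param gapdh_a,gapdh_b GAPDH measurements in the same samples.
#' @param floor minimal expression value substituted for undetectable
#'   transcript.
#' @return list with `ratio` and `flag` in
#'   `{"none","down","up","indeterminate"}`.
#' @export
qpcr_ratio <- function(target_a, target_b, gapdh_a, gapdh_b, floor) {
  for (m in list(target_a, target_b, gapdh_a, gapdh_b))
    stopifnot(inherits(m, "xs_qpcr"))
  if (!gapdh_a$detectable || !gapdh_b$detectable)
    stop("GAPDH must be detectable in both samples")
  if (!is.numeric(floor) || floor <= 0) stop("'floor' must be > 0")
  na <- if (target_a$detectable) target_a$N0 else floor
  nb <- if (target_b$detectable) target_b$N0 else floor
  flag <- if (!target_a$detectable && !target_b$detectable) "indeterminate"
          else if (!target_a$detectable) "down"
          else if (!target_b$detectable) "up"
          else "none"
  list(ratio = (na / gapdh_a$N0) / (nb / gapdh_b$N0), flag = flag)
}
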