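#' Fit a tumor volume series to exponential growth
#'
#' Least-squares line fit of `ln(volume)` against time: `V(t) = V0 * e^(kt)`,
#' with doubling time `Td = ln(2) / k` and the coefficient of determination
#' R-squared computed on the log scale. A series with no volume variation
#' gives `k = 0`, `R2 = 0` and an undefined doubling time; a negative slope
#' (shrinking tumor) also leaves `Td` undefined, with the sign flagged by
#' `k < 0`.
#'
#' @param timepoints measurement days (strictly increasing, length >= 3), or
#'   a data.frame with columns `day` and `volume` (e.g. from
#'   [simulate_growth()]).
#' @param volumes positive volumes, same length as `timepoints`.
#' @return list of class `xs_growth_fit`: `V0`, `k` (per day), `Td` (days;
#'   `NA` when `k <= 0`), `R2`, `classification`.
#' @export
fit_exponential <- function(timepoints, volumes = NULL) {
  if (is.data.frame(timepoints)) {
    volumes <- timepoints$volume
    timepoints <- timepoints$day
  }
  if (length(timepoints) != length(volumes) || length(volumes) < 3L)
    stop("at least three (time, volume) points are required")
  if (any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing")
  if (any(volumes <= 0)) stop("volumes must be positive")

  y <- log(volumes)
  if (stats::var(y) == 0) {
    fit <- structure(list(V0 = volumes[1], k = 0, Td = NA_real_, R2 = 0),
                     class = "xs_growth_fit")
    fit$classification <- classify_growth(fit)
    return(fit)
  }
  lmfit <- stats::lm(y ~ timepoints)
  k <- unname(stats::coef(lmfit)[2])
  V0 <- exp(unname(stats::coef(lmfit)[1]))
  R2 <- 1 - sum(stats::residuals(lmfit)^2) / sum((y - mean(y))^2)
  fit <- structure(list(V0 = V0, k = k,
                        Td = if (k > 0) log(2) / k else NA_real_,
                        R2 = R2),
                   class = "xs_growth_fit")
  fit$classification <- classify_growth(fit)
  fit
}

#' Classify a growth fit as exponential or not
#'
#' A series is called non-exponential when the exponential fit explains less
#' than half the log-scale variance (`R2 < 0.5`, strict) or when the fitted
#' growth rate is not positive.
#'
#' @param fit an `xs_growth_fit`.
#' @return `"exponential"` or `"non_exponential"`.
#' @export
classify_growth <- function(fit) {
  stopifnot(inherits(fit, "xs_growth_fit"))
  if (fit$R2 < 0.5 || fit$k <= 0) "non_exponential" else "exponential"
}

#' @export
print.xs_growth_fit <- function(x, ...) {
  cat(sprintf("exponential growth fit: V0 = %.3g, k = %.4f /day, Td = %s days, R2 = %.3f (%s)\n",
              x$V0, x$k,
              if (is.na(x$Td)) "NA" else sprintf("%.2f", x$Td),
              x$R2, x$classification))
  invisible(x)
}

#' Fit growth series for a table of tumors
#'
#' @param df data.frame with columns `sample_id`, `day`, `volume`.
#' @param path optional TSV output path.
#' @return data.frame with one row per sample: `sample_id`, `V0`, `k`, `Td`,
#'   `R2`, `classification`.
#' @export
fit_growth_table <- function(df, path = NULL) {
  stopifnot(all(c("sample_id", "day", "volume") %in% names(df)))
  rows <- lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$day), ]
    f <- fit_exponential(d$day, d$volume)
    data.frame(sample_id = d$sample_id[1], V0 = f$V0, k = f$k, Td = f$Td,
               R2 = f$R2, classification = f$classification,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
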