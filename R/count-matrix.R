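#' Gene-by-sample count matrix with library totals
#'
#' Light container for species-specific gene counts: a non-negative integer
#' matrix (genes x samples), per-sample library totals used as the
#' counts-per-million divisor basis, and a species label.
#'
#' @param counts non-negative numeric matrix with gene rownames and sample
#'   colnames.
#' @param library_totals per-sample totals (defaults to column sums); must be
#'   at least the column sums of assigned counts.
#' @param species `"human"` or `"mouse"`.
#' @return An object of class `xs_counts`.
#' @export
count_matrix <- function(counts, library_totals = colSums(counts),
                         species = c("human", "mouse")) {
  species <- match.arg(species)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  if (is.null(colnames(counts))) stop("counts must have sample colnames")
  if (length(library_totals) != ncol(counts))
    stop("one library total per sample required")
  if (any(library_totals + 1e-8 < colSums(counts)))
    stop("library totals cannot be smaller than assigned column sums")
  structure(list(counts = counts,
                 library_totals = stats::setNames(as.numeric(library_totals),
                                                  colnames(counts)),
                 species = species),
            class = "xs_counts")
}

#' @export
print.xs_counts <- function(x, ...) {
  cat(sprintf("xs_counts: %d %s genes x %d samples\n",
              nrow(x$counts), x$species, ncol(x$counts)))
  invisible(x)
}

#' @export
dim.xs_counts <- function(x) dim(x$counts)

#' Counts-per-million normalization
#'
#' Divides each count by its sample's library total expressed in millions:
#' `count / (library_total / 1e6)`.
#'
#' @param x an `xs_counts` object, or a numeric vector/matrix of counts.
#' @param library_total per-sample totals; taken from the object when `x` is
#'   an `xs_counts`.
#' @return normalized values with the shape of the input counts.
#' @export
cpm_normalize <- function(x, library_total = NULL) {
  if (inherits(x, "xs_counts")) {
    m <- x$counts
    library_total <- x$library_totals
  } else {
    m <- x
  }
  if (is.null(library_total)) stop("'library_total' is required")
  if (any(library_total <= 0)) stop("library totals must be > 0")
  if (is.matrix(m)) {
    sweep(m, 2L, library_total / 1e6, "/")
  } else {
    m / (library_total / 1e6)
  }
}
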