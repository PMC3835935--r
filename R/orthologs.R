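#' Load a 1:1 human-mouse orthologue table
#'
#' Reads a two-column TSV (`human_gene<TAB>mouse_gene`, with header) and
#' enforces strict 1:1 pairing: every row involving a gene that appears more
#' than once on either side is dropped, with a warning giving the number of
#' dropped rows.
#'
#' @param path TSV path.
#' @return data.frame of class `xs_ortholog_map` with columns `human_gene`,
#'   `mouse_gene`; attribute `n_dropped` records the discarded rows.
#' @export
load_ortholog_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stop("orthologue table must have two columns")
  df <- df[, 1:2]
  names(df) <- c("human_gene", "mouse_gene")
  if (anyNA(df) || any(df == ""))
    stop("malformed orthologue rows (empty fields)")
  ortholog_map(df)
}

#' @rdname load_ortholog_map
#' @param pairs data.frame with columns `human_gene`, `mouse_gene`.
#' @export
ortholog_map <- function(pairs) {
  stopifnot(all(c("human_gene", "mouse_gene") %in% names(pairs)))
  dup_h <- pairs$human_gene %in% pairs$human_gene[duplicated(pairs$human_gene)]
  dup_m <- pairs$mouse_gene %in% pairs$mouse_gene[duplicated(pairs$mouse_gene)]
  drop <- dup_h | dup_m
  if (any(drop))
    warning(sum(drop), " row(s) dropped to enforce 1:1 orthologue pairing")
  out <- pairs[!drop, c("human_gene", "mouse_gene")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  class(out) <- c("xs_ortholog_map", "data.frame")
  out
}

#' Build a joint human/mouse expression matrix over orthologue pairs
#'
#' Each physical xenograft sample contributes a human (`-H`) and a murine
#' (`-M`) pseudo-sample column; samples present only in the human counts
#' contribute `-H` only. Rows are the orthologue pairs found in both count
#' matrices. Values are `transform(CPM)`; the default transform is
#' `log2(x + 1)`.
#'
#' @param human_counts an `xs_counts` with species `"human"`.
#' @param mouse_counts an `xs_counts` with species `"mouse"`, or `NULL`.
#' @param map an `xs_ortholog_map`.
#' @param transform function applied to the CPM values; use `identity` for
#'   raw CPM.
#' @return numeric matrix (pairs x pseudo-samples) with rownames
#'   `human_gene|mouse_gene` and a `pairs` attribute.
#' @export
build_joint_matrix <- function(human_counts, mouse_counts, map,
                               transform = function(x) log2(x + 1)) {
  stopifnot(inherits(human_counts, "xs_counts"),
            inherits(map, "xs_ortholog_map"))
  keep <- map$human_gene %in% rownames(human_counts$counts)
  if (!is.null(mouse_counts)) {
    stopifnot(inherits(mouse_counts, "xs_counts"))
    keep <- keep & map$mouse_gene %in% rownames(mouse_counts$counts)
  }
  pairs <- map[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("no orthologue pairs overlap the count matrices")

  hv <- transform(cpm_normalize(human_counts))[pairs$human_gene, , drop = FALSE]
  colnames(hv) <- paste0(colnames(hv), "-H")
  out <- hv
  if (!is.null(mouse_counts)) {
    mv <- transform(cpm_normalize(mouse_counts))[pairs$mouse_gene, , drop = FALSE]
    colnames(mv) <- paste0(colnames(mv), "-M")
    out <- cbind(hv, mv)
  }
  if (anyDuplicated(colnames(out))) stop("pseudo-sample labels must be unique")
  if (any(!is.finite(out)) || any(out < 0))
    stop("joint matrix values must be finite and non-negative")
  rownames(out) <- paste(pairs$human_gene, pairs$mouse_gene, sep = "|")
  attr(out, "pairs") <- pairs
  out
}

#' Pearson correlation between two expression vectors
#'
#' @param x,y equal-length numeric vectors (length >= 2).
#' @param gene_subset optional character vector of names to restrict to (both
#'   vectors must be named), e.g. a housekeeping gene list.
#' @param subset_label label recorded for the subset used.
#' @return list with `r`, `n`, and `gene_subset`.
#' @export
pearson <- function(x, y, gene_subset = NULL, subset_label = "all") {
  if (!is.null(gene_subset)) {
    if (is.null(names(x)) || is.null(names(y)))
      stop("named vectors required to take a gene subset")
    keep <- intersect(names(x), gene_subset)
    x <- x[keep]; y <- y[keep]
    if (subset_label == "all") subset_label <- "custom"
  }
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 2L) stop("at least two genes required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in an input vector")
  list(r = stats::cor(x, y), n = length(x), gene_subset = subset_label)
}

#' Hierarchically cluster pseudo-samples of a joint matrix
#'
#' Pairwise Pearson correlation is computed between all columns; the distance
#' between two samples is the Euclidean distance between their rows of the
#' correlation matrix; agglomerative hierarchical clustering (average linkage
#' by default) is then applied, and the dendrogram is also serialized to
#' Newick.
#'
#' @param mat matrix with >= 2 columns (e.g. from [build_joint_matrix()]).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return list with `hclust`, `newick`, `correlations`, `distances`.
#' @export
cluster_samples <- function(mat, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (ncol(mat) < 2L) stop("at least two columns required for clustering")
  r <- stats::cor(mat)
  d <- stats::dist(r)
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc,
       newick = ape::write.tree(ape::as.phylo(hc)),
       correlations = r,
       distances = d)
}

#' Export scatter-plot data for a pairwise sample comparison
#'
#' For two pseudo-samples, emits per-gene values with flags for genes
#' expressed in both or only one sample and for membership in a housekeeping
#' list.
#'
#' @param mat joint (or any) expression matrix.
#' @param sample_a,sample_b column names.
#' @param housekeeping optional character vector of housekeeping row names.
#' @return data.frame: `gene`, `value_a`, `value_b`, `status`
#'   (`shared`/`only_a`/`only_b`/`absent`), `housekeeping`.
#' @export
scatter_data <- function(mat, sample_a, sample_b, housekeeping = NULL) {
  stopifnot(all(c(sample_a, sample_b) %in% colnames(mat)))
  a <- mat[, sample_a]; b <- mat[, sample_b]
  status <- ifelse(a > 0 & b > 0, "shared",
            ifelse(a > 0, "only_a", ifelse(b > 0, "only_b", "absent")))
  data.frame(gene = rownames(mat), value_a = a, value_b = b,
             status = status,
             housekeeping = rownames(mat) %in% (housekeeping %||% character(0)),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Illustrative housekeeping gene list
#'
#' A small set of commonly used human housekeeping gene symbols for subset
#' correlations and demonstrations. This is an illustrative default, not a
#' curated consensus list; analyses of real data should supply their own
#' list.
#'
#' @return character vector of gene symbols.
#' @export
default_housekeeping_genes <- function() {
  c("GAPDH", "ACTB", "B2M", "TUBB", "RPL13A", "RPLP0", "TBP", "PPIA",
    "HPRT1", "PGK1", "UBC", "YWHAZ")
}
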