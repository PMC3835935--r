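#' Load gene models from GTF files
#'
#' Reads exon records from one or more GTF annotation sources (e.g. RefSeq and
#' KnownGenes exports) and merges them per gene: all exons of a gene from all
#' sources are unioned, with overlapping exons collapsed. Interval arithmetic
#' is delegated to GenomicRanges; GTF's 1-based inclusive coordinates are kept
#' in that representation throughout.
#'
#' @param gtf_paths character vector of GTF paths.
#' @param species `"human"` or `"mouse"`.
#' @return An `xs_gene_models` list with `exons` (a `GRangesList`, one element
#'   of merged exons per gene) and `species`.
#' @export
load_gene_models <- function(gtf_paths, species = c("human", "mouse")) {
  species <- match.arg(species)
  stopifnot(length(gtf_paths) >= 1L)
  grl <- lapply(gtf_paths, function(p) {
    gr <- rtracklayer::import(p, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) && is.null(gr$gene_id))
      stop("GTF lacks gene_id attribute: ", p)
    gr
  })
  all_ex <- suppressWarnings(do.call(c, grl))
  if (length(all_ex) == 0L) stop("no exon records found in ", paste(gtf_paths, collapse = ", "))
  by_gene <- GenomicRanges::split(all_ex, all_ex$gene_id)
  merged <- GenomicRanges::reduce(by_gene)
  structure(list(exons = merged, species = species,
                 sources = gtf_paths),
            class = "xs_gene_models")
}

#' @export
print.xs_gene_models <- function(x, ...) {
  cat(sprintf("xs_gene_models: %d %s genes (%d merged exons)\n",
              length(x$exons), x$species, sum(lengths(x$exons))))
  invisible(x)
}

#' Count reads completely contained within gene exons
#'
#' Implements the containment counting rule: a read is ascribed to a gene only
#' if its aligned interval lies entirely within a single merged exon of that
#' gene. Each mate is tested separately and a paired fragment is counted once,
#' for the gene that wholly contains both mates; a fragment contained in exons
#' of more than one gene is counted for none and tallied as
#' ambiguous-assignment. Counting is unstranded.
#'
#' @param sam_path species-partitioned SAM/BAM of one sample.
#' @param models `xs_gene_models` of the matching species.
#' @param library_total CPM divisor basis for this sample; defaults to the
#'   number of fragments in `sam_path` (the species-classified total).
#' @param sample_id column label.
#' @return An `xs_counts` with one column, carrying an `audit` attribute:
#'   `assigned`, `ambiguous_assignment`, `unassigned`, `total` (fragments).
#' @export
count_contained_reads <- function(sam_path, models,
                                  library_total = NULL,
                                  sample_id = "sample") {
  stopifnot(inherits(models, "xs_gene_models"))
  dt <- read_sam_records(sam_path, tags = character(0))
  qname <- flag <- NULL
  total_frags <- length(unique(dt$qname))
  mapped <- dt[bitwAnd(flag, 4L) == 0L]

  known <- mapped$rname %in% seqlevels_of(models)
  if (any(!known))
    warning(sum(!known), " mapped record(s) on contigs absent from the gene models")
  mapped <- mapped[known]

  gene_ids <- names(models$exons)
  counts <- stats::setNames(integer(length(gene_ids)), gene_ids)
  n_ambig <- 0L
  if (nrow(mapped)) {
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(mapped$cigar)
    reads <- GenomicRanges::GRanges(mapped$rname,
                                    IRanges::IRanges(mapped$pos, width = w))
    flat <- unlist(models$exons, use.names = FALSE)
    flat_gene <- rep(gene_ids, lengths(models$exons))
    hits <- GenomicRanges::findOverlaps(reads, flat, type = "within",
                                        ignore.strand = TRUE)
    # per-record gene sets
    rec_gene <- data.table::data.table(
      rec = S4Vectors::queryHits(hits),
      gene = flat_gene[S4Vectors::subjectHits(hits)])
    rec <- gene <- NULL
    rec_gene <- unique(rec_gene)
    per_rec <- rec_gene[, .(genes = list(gene)), by = rec]
    rec_sets <- vector("list", nrow(mapped))
    rec_sets[per_rec$rec] <- per_rec$genes

    # fragment-level resolution: every mapped mate must be contained in the
    # same single gene
    frag <- split(seq_len(nrow(mapped)), mapped$qname)
    res <- vapply(frag, function(ix) {
      sets <- rec_sets[ix]
      if (any(vapply(sets, is.null, logical(1)))) return("")      # unassigned
      common <- Reduce(intersect, sets)
      if (length(common) == 1L) return(common)
      if (length(common) > 1L) return(NA_character_)              # ambiguous
      NA_character_                                               # conflicting genes
    }, character(1))
    n_ambig <- sum(is.na(res))
    tab <- table(res[!is.na(res) & res != ""])
    counts[names(tab)] <- as.integer(tab)
  }

  assigned <- sum(counts)
  if (is.null(library_total)) library_total <- total_frags
  if (library_total <= 0) library_total <- max(1, assigned)
  cm <- count_matrix(matrix(counts, ncol = 1L,
                            dimnames = list(gene_ids, sample_id)),
                     library_totals = library_total,
                     species = models$species)
  attr(cm, "audit") <- list(assigned = assigned,
                            ambiguous_assignment = n_ambig,
                            unassigned = total_frags - assigned - n_ambig,
                            total = total_frags)
  cm
}

seqlevels_of <- function(models) {
  unique(as.character(GenomicRanges::seqnames(unlist(models$exons,
                                                     use.names = FALSE))))
}

#' Combine single-sample count columns into one matrix
#'
#' @param columns list of one-column `xs_counts` sharing a gene universe.
#' @return a combined `xs_counts`.
#' @export
bind_count_columns <- function(columns) {
  stopifnot(length(columns) >= 1L)
  genes <- rownames(columns[[1]]$counts)
  mats <- lapply(columns, function(cm) {
    stopifnot(identical(rownames(cm$counts), genes))
    cm$counts
  })
  count_matrix(do.call(cbind, mats),
               library_totals = unlist(lapply(columns, `[[`, "library_totals")),
               species = columns[[1]]$species)
}
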