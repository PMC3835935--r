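#' Variant locus specification
#'
#' @param label display label, e.g. `"APC:Q861*"`.
#' @param contig reference contig name.
#' @param position 1-based coordinate of the variant base.
#' @param ref_allele,alt_allele single, distinct bases.
#' @return list of class `xs_locus`.
#' @export
variant_locus <- function(label, contig, position, ref_allele, alt_allele) {
  stopifnot(is.numeric(position), position >= 1)
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  if (nchar(ref_allele) != 1L || nchar(alt_allele) != 1L)
    stop("alleles must be single bases")
  if (ref_allele == alt_allele) stop("ref and alt alleles must differ")
  structure(list(label = label, contig = contig,
                 position = as.integer(position),
                 ref_allele = ref_allele, alt_allele = alt_allele),
            class = "xs_locus")
}

#' Read variant loci from a TSV
#'
#' Expected columns: `label`, `contig`, `position`, `ref`, `alt` (header
#' required).
#'
#' @param path TSV path.
#' @return list of [variant_locus()] objects.
#' @export
load_loci <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  need <- c("label", "contig", "position", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("locus table needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    variant_locus(df$label[i], df$contig[i], as.integer(df$position[i]),
                  df$ref[i], df$alt[i]))
}

#' Strand-stratified allele counts at a locus
#'
#' Pileup over all aligned reads covering the position (located through each
#' read's CIGAR, so indels elsewhere in the read are handled; deletions and
#' reference skips spanning the position are ignored). Each covering read's
#' base is classified as WT (reference allele), mutant (alternate allele) or
#' other, stratified by the alignment strand from the SAM reverse-strand
#' FLAG bit. Overlapping mates are counted independently. No base- or
#' mapping-quality filter is applied by default.
#'
#' @param sam_path SAM/BAM path.
#' @param locus an [variant_locus()].
#' @param min_base_quality optional minimum base quality (default 0).
#' @return list of class `xs_allele_counts`: `fwd_wt`, `fwd_mut`, `rev_wt`,
#'   `rev_mut`, `n_other`, plus the locus.
#' @export
pileup_at_locus <- function(sam_path, locus, min_base_quality = 0L) {
  stopifnot(inherits(locus, "xs_locus"))
  bam <- as_bam(sam_path)
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  zero <- structure(list(fwd_wt = 0L, fwd_mut = 0L, rev_wt = 0L,
                         rev_mut = 0L, n_other = 0L, locus = locus),
                    class = "xs_allele_counts")
  if (!locus$contig %in% names(targets)) {
    warning("contig '", locus$contig, "' absent from alignments; zero counts")
    return(zero)
  }
  which <- GenomicRanges::GRanges(locus$contig,
                                  IRanges::IRanges(locus$position,
                                                   locus$position))
  pp <- Rsamtools::PileupParam(max_depth = 1000000L,
                               min_base_quality = as.integer(min_base_quality),
                               min_mapq = 0L,
                               min_nucleotide_depth = 1L,
                               distinguish_strands = TRUE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  res <- Rsamtools::pileup(bam,
                           scanBamParam = Rsamtools::ScanBamParam(which = which),
                           pileupParam = pp)
  if (nrow(res) == 0L) return(zero)
  res <- res[res$pos == locus$position, , drop = FALSE]
  cnt <- function(base, strand)
    sum(res$count[res$nucleotide == base & res$strand == strand])
  fwd_wt <- cnt(locus$ref_allele, "+"); rev_wt <- cnt(locus$ref_allele, "-")
  fwd_mut <- cnt(locus$alt_allele, "+"); rev_mut <- cnt(locus$alt_allele, "-")
  structure(list(fwd_wt = fwd_wt, fwd_mut = fwd_mut,
                 rev_wt = rev_wt, rev_mut = rev_mut,
                 n_other = sum(res$count) - fwd_wt - fwd_mut - rev_wt - rev_mut,
                 locus = locus),
            class = "xs_allele_counts")
}

#' Build strand-stratified allele counts directly
#'
#' @param fwd_wt,fwd_mut,rev_wt,rev_mut non-negative integers.
#' @param n_other reads whose base matches neither allele.
#' @return list of class `xs_allele_counts`.
#' @export
allele_counts <- function(fwd_wt, fwd_mut, rev_wt, rev_mut, n_other = 0L) {
  v <- c(fwd_wt, fwd_mut, rev_wt, rev_mut, n_other)
  if (any(v < 0)) stop("counts must be non-negative")
  structure(list(fwd_wt = fwd_wt, fwd_mut = fwd_mut, rev_wt = rev_wt,
                 rev_mut = rev_mut, n_other = n_other, locus = NULL),
            class = "xs_allele_counts")
}

#' Integer percent wild-type / mutant allele fractions
#'
#' Percentages are over WT + mutant reads only (bases matching neither allele
#' are excluded from the denominator). The wild-type percentage is rounded
#' half-up to an integer and the mutant percentage is its complement, so the
#' two always sum to 100.
#'
#' @param counts an `xs_allele_counts`.
#' @return list with `pct_wt`, `pct_mut` (integers; `NA` with
#'   `undefined = TRUE` when no WT or mutant reads cover the locus).
#' @export
allele_fractions <- function(counts) {
  stopifnot(inherits(counts, "xs_allele_counts"))
  wt <- counts$fwd_wt + counts$rev_wt
  mut <- counts$fwd_mut + counts$rev_mut
  total <- wt + mut
  if (total == 0)
    return(list(pct_wt = NA_integer_, pct_mut = NA_integer_,
                undefined = TRUE))
  pct_wt <- as.integer(floor(100 * wt / total + 0.5))
  list(pct_wt = pct_wt, pct_mut = 100L - pct_wt, undefined = FALSE)
}

#' Tabulate strand-stratified allele tallies over loci
#'
#' @param sam_path SAM/BAM of one sample.
#' @param loci list of [variant_locus()] objects.
#' @param sample_id sample label.
#' @param path optional TSV output path.
#' @return data.frame with columns `label`, `sample`, `fwd_wt`, `fwd_mut`,
#'   `rev_wt`, `rev_mut`, `pct_wt`, `pct_mut`.
#' @export
tally_report <- function(sam_path, loci, sample_id = "sample", path = NULL) {
  rows <- lapply(loci, function(loc) {
    ct <- pileup_at_locus(sam_path, loc)
    fr <- allele_fractions(ct)
    data.frame(label = loc$label, sample = sample_id,
               fwd_wt = ct$fwd_wt, fwd_mut = ct$fwd_mut,
               rev_wt = ct$rev_wt, rev_mut = ct$rev_mut,
               pct_wt = fr$pct_wt, pct_mut = fr$pct_mut,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
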