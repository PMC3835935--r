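#' Summarize best-alignment mismatches against two genomes
#'
#' Scans the same reads aligned to a human and a mouse reference and records,
#' per fragment, the best (minimum) mismatch count in each genome. For
#' paired-end data mate mismatches are summed and a fragment counts as aligned
#' in a genome only if both mates have at least one mapped alignment there.
#' Mismatches are taken from the `NM` tag (minimum over all reported
#' alignments of a mate, secondary included); when `NM` is absent the `MD` tag
#' is used, and a mapped record carrying neither is a hard error.
#'
#' @param sam_human,sam_mouse paths to SAM (or BAM) files of the same reads
#'   aligned to the human and mouse references.
#' @return data.frame with one row per fragment: `read_id`,
#'   `nm_human`, `nm_mouse` (NA when unaligned in that genome).
#' @export
summarize_alignments <- function(sam_human, sam_mouse) {
  h <- genome_best_nm(sam_human)
  m <- genome_best_nm(sam_mouse)
  ids <- sort(unique(c(h$read_id, m$read_id)))
  out <- data.frame(read_id = ids,
                    nm_human = h$nm[match(ids, h$read_id)],
                    nm_mouse = m$nm[match(ids, m$read_id)],
                    stringsAsFactors = FALSE)
  out
}

# per-fragment best NM in one genome; NA when not aligned there
genome_best_nm <- function(path) {
  dt <- read_sam_records(path)
  if (nrow(dt) == 0L)
    return(data.frame(read_id = character(0), nm = numeric(0)))
  qname <- mate <- flag <- nm_rec <- n <- n_exp <- NULL # data.table NSE
  dt[, mate := data.table::fifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)]
  mapped <- dt[bitwAnd(flag, 4L) == 0L]
  all_ids <- unique(dt$qname)
  if (nrow(mapped) == 0L)
    return(data.frame(read_id = all_ids, nm = NA_real_))
  nm <- mapped$NM
  if (anyNA(nm)) {
    fill <- is.na(nm)
    nm[fill] <- md_mismatches(mapped$MD[fill])
    if (anyNA(nm)) {
      bad <- mapped$qname[which(is.na(nm))[1]]
      stop("mapped record without NM or MD tag (read ", bad, " in ", path, ")")
    }
  }
  mapped[, nm_rec := as.numeric(nm)]
  n_mates <- length(unique(mapped$mate))
  per_mate <- mapped[, .(best = min(nm_rec)), by = .(qname, mate)]
  per_frag <- per_mate[, .(nm = sum(best), n = .N), by = qname]
  # a fragment is aligned only if every sequenced mate mapped
  expected <- dt[, .(n_exp = length(unique(mate))), by = qname]
  per_frag <- merge(per_frag, expected, by = "qname")
  per_frag[n < n_exp, nm := NA_real_]
  res <- data.frame(read_id = per_frag$qname, nm = per_frag$nm,
                    stringsAsFactors = FALSE)
  missing <- setdiff(all_ids, res$read_id)
  if (length(missing))
    res <- rbind(res, data.frame(read_id = missing, nm = NA_real_))
  res
}

#' Classify fragments by comparative alignment fidelity
#'
#' A fragment aligned in both genomes is called for the genome it matches
#' with fewer mismatching bases; equal mismatch counts are ambiguous. A
#' fragment aligned in only one genome is called for that genome, and one
#' aligned in neither is unaligned.
#'
#' @param summary data.frame from [summarize_alignments()].
#' @return character vector in `{"human","mouse","ambiguous","unaligned"}`,
#'   one value per row of `summary`.
#' @export
classify_reads <- function(summary) {
  h <- summary$nm_human
  m <- summary$nm_mouse
  out <- rep("ambiguous", nrow(summary))
  out[is.na(h) & is.na(m)] <- "unaligned"
  out[!is.na(h) & is.na(m)] <- "human"
  out[is.na(h) & !is.na(m)] <- "mouse"
  both <- !is.na(h) & !is.na(m)
  out[both & h < m] <- "human"
  out[both & h > m] <- "mouse"
  out
}

SPECIES_CLASSES <- c("human", "mouse", "ambiguous", "unaligned")

#' Partition a sample's reads by species of origin
#'
#' Runs the comparative dual-genome classification over a sample and reports
#' per-class counts and percentages (of all input fragments). Optionally
#' writes, per species class, a filtered SAM holding exactly that class's
#' alignments against its own genome.
#'
#' @param sam_human,sam_mouse alignment files as in [summarize_alignments()].
#' @param sample_id sample label for reporting.
#' @param out_dir optional directory for filtered SAM output
#'   (`<sample_id>.human.sam` with the human-class reads' human-genome
#'   alignments, and `<sample_id>.mouse.sam` likewise).
#' @return An `xs_partition` list: `sample_id`, `total_reads`, `counts` and
#'   `fractions` (percentages) per class, and `read_ids` per class. With zero
#'   input reads the fractions are `NA` and flagged via `undefined_fractions`.
#' @export
partition_sample <- function(sam_human, sam_mouse, sample_id,
                             out_dir = NULL) {
  summ <- summarize_alignments(sam_human, sam_mouse)
  cls <- classify_reads(summ)
  counts <- vapply(SPECIES_CLASSES, function(k) sum(cls == k), integer(1))
  total <- nrow(summ)
  fractions <- if (total > 0) 100 * counts / total
               else stats::setNames(rep(NA_real_, 4L), SPECIES_CLASSES)
  read_ids <- split(summ$read_id, factor(cls, levels = SPECIES_CLASSES))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    filter_sam(sam_human, read_ids$human,
               file.path(out_dir, paste0(sample_id, ".human.sam")))
    filter_sam(sam_mouse, read_ids$mouse,
               file.path(out_dir, paste0(sample_id, ".mouse.sam")))
  }
  structure(list(sample_id = sample_id, total_reads = total,
                 counts = counts, fractions = fractions,
                 undefined_fractions = total == 0,
                 read_ids = read_ids, summary = summ),
            class = "xs_partition")
}

#' @export
print.xs_partition <- function(x, ...) {
  cat(sprintf("xs_partition '%s': %d fragments\n", x$sample_id, x$total_reads))
  for (k in SPECIES_CLASSES)
    cat(sprintf("  %-10s %9d  %s\n", k, x$counts[[k]],
                if (x$undefined_fractions) "NA"
                else sprintf("%6.2f%%", x$fractions[[k]])))
  invisible(x)
}

# keep header lines plus mapped records of the selected reads
filter_sam <- function(sam_path, keep_ids, out_path) {
  if (grepl("\\.bam$", sam_path, ignore.case = TRUE))
    stop("filtered output requires text SAM input")
  con <- file(sam_path, "r"); on.exit(close(con))
  keep <- character(0)
  out <- file(out_path, "w")
  on.exit(close(out), add = TRUE)
  repeat {
    lines <- readLines(con, n = 65536L)
    if (length(lines) == 0L) break
    hdr <- startsWith(lines, "@")
    body <- lines[!hdr]
    writeLines(lines[hdr], out)
    if (length(body)) {
      qn <- sub("\t.*", "", body)
      flag <- as.integer(sub("^[^\t]*\t([0-9]+)\t.*", "\\1", body))
      writeLines(body[qn %in% keep_ids & bitwAnd(flag, 4L) == 0L], out)
    }
  }
  invisible(out_path)
}

#' Tabulate species partitions across samples
#'
#' One row per sample with total fragments, human fragment count, and
#' two-decimal percentages per class.
#'
#' @param results list of `xs_partition` objects (a single object is
#'   accepted).
#' @param path optional TSV output path.
#' @return data.frame with columns `sample_id`, `total_reads`, `human_reads`,
#'   `human_pct`, `mouse_pct`, `ambiguous_pct`, `unaligned_pct`.
#' @export
partition_report <- function(results, path = NULL) {
  if (inherits(results, "xs_partition")) results <- list(results)
  if (length(results) == 0L) stop("at least one partition result required")
  rows <- lapply(results, function(r) {
    data.frame(sample_id = r$sample_id,
               total_reads = r$total_reads,
               human_reads = r$counts[["human"]],
               human_pct = round(r$fractions[["human"]], 2),
               mouse_pct = round(r$fractions[["mouse"]], 2),
               ambiguous_pct = round(r$fractions[["ambiguous"]], 2),
               unaligned_pct = round(r$fractions[["unaligned"]], 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(format(out, nsmall = 2, trim = TRUE), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
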