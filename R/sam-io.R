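.datatable.aware <- TRUE

# SAM ingestion. Text SAM is converted once to sorted/indexed BAM with
# Rsamtools; all record access then goes through scanBam.

as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  if (!file.exists(path)) stop("no such alignment file: ", path)
  dest <- sub("\\.sam$", "", path, ignore.case = TRUE)
  dest <- tempfile(basename(dest))
  Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
}

# all records (mapped and unmapped) as a data.table
read_sam_records <- function(path, tags = c("NM", "MD")) {
  bam <- as_bam(path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = tags)
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  dt <- data.table::data.table(
    qname = res$qname,
    flag = res$flag,
    rname = as.character(res$rname),
    pos = res$pos,
    cigar = res$cigar)
  for (tg in tags) {
    v <- res$tag[[tg]]
    data.table::set(dt, j = tg,
                    value = if (is.null(v)) rep(NA, nrow(dt)) else v)
  }
  dt
}

# mismatch count from an MD tag (substitutions only; deletion runs skipped)
md_mismatches <- function(md) {
  vapply(md, function(x) {
    if (is.na(x)) return(NA_integer_)
    toks <- regmatches(x, gregexpr("\\^[A-Z]+|[A-Z]", x))[[1]]
    sum(!startsWith(toks, "^"))
  }, integer(1), USE.NAMES = FALSE)
}

sam_seqinfo <- function(path) {
  bam <- as_bam(path)
  hd <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  hd
}
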