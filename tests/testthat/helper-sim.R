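# shared fixtures built in code

# small dual-genome dataset: references + reads + SAM pair in a temp dir
make_sim_sample <- function(n_genes = 20, n_reads = 400, seed = 42,
                            divergence = 0.12, error_rate = 0.01,
                            species_mix = c(human = 0.8, mouse = 0.2),
                            paired = TRUE, max_mismatch = 10L) {
  cfg <- sim_config(n_genes = n_genes, divergence = divergence,
                    error_rate = error_rate, species_mix = species_mix,
                    paired = paired, seed = seed)
  refs <- generate_reference_set(cfg)
  reads <- simulate_reads(refs, n_reads = n_reads)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  sam_h <- file.path(dir, "human.sam")
  sam_m <- file.path(dir, "mouse.sam")
  al <- emit_alignments(reads, refs, sam_h, sam_m, max_mismatch = max_mismatch)
  list(cfg = cfg, refs = refs, reads = reads,
       sam_human = sam_h, sam_mouse = sam_m, nm = al, dir = dir)
}

# brute-force Hamming distance between two equal-length strings
hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

revcomp_str <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# write a SAM file from a record data.frame (qname, flag, rname, pos, cigar,
# seq, opt) against a named contig-length vector
write_test_sam <- function(records, contigs, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    line <- paste(r$qname, r$flag, r$rname, r$pos, 60, r$cigar, "*", 0, 0,
                  r$seq, strrep("I", nchar(r$seq)), sep = "\t")
    if (!is.null(r$opt) && nzchar(r$opt)) line <- paste(line, r$opt, sep = "\t")
    line
  }, character(1))
  writeLines(c(header, body), path)
  path
}
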