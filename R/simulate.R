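BASES <- c("A", "C", "G", "T")

# n x width character matrix from equal-length strings
seq_matrix <- function(x, width) {
  if (length(x) == 0L) return(matrix(character(0), 0L, width))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = width, byrow = TRUE)
}

collapse_rows <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  apply(m, 1L, paste0, collapse = "")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_matrix <- function(m) {
  if (nrow(m) == 0L) return(m)
  r <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  matrix(COMPLEMENT[r], nrow = nrow(r), ncol = ncol(r))
}

# substitute each flagged base uniformly to one of the other three
mutate_bases <- function(mat, idx) {
  if (length(idx) == 0L) return(mat)
  old <- match(mat[idx], BASES)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  mat[idx] <- BASES[((old - 1L + shift) %% 4L) + 1L]
  mat
}

#' Generate one orthologous human/mouse transcript pair
#'
#' Draws a random "human" transcript and derives its "mouse" orthologue by
#' substituting each base independently with probability `divergence`, always
#' to a different base (no indels). The number of substituted positions is
#' therefore Binomial(`length`, `divergence`)-distributed.
#'
#' @param length transcript length in bp (>= 1).
#' @param divergence per-base substitution probability in `[0, 1]`.
#' @param seed optional integer; when given, seeds the RNG first.
#' @return list with `human_seq`, `mouse_seq` (strings) and
#'   `substituted_positions` (1-based integer positions where they differ).
#' @export
generate_ortholog_pair <- function(length, divergence, seed = NULL) {
  if (!is.numeric(length) || length < 1) stop("'length' must be positive")
  if (!is.numeric(divergence) || divergence < 0 || divergence > 1)
    stop("'divergence' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  h <- sample(BASES, length, replace = TRUE)
  sub <- which(stats::runif(length) < divergence)
  m <- matrix(h, nrow = 1L)
  m <- mutate_bases(m, sub)
  list(human_seq = paste0(h, collapse = ""),
       mouse_seq = paste0(m[1L, ], collapse = ""),
       substituted_positions = sub)
}

#' Generate a paired human/mouse reference set
#'
#' Simulates `n_genes` orthologous transcript pairs and (optionally) writes
#' them out as two FASTA files, one single-exon GTF per species, and a
#' two-column orthologue table. Gene `i` of the human reference is the
#' orthologue of gene `i` of the mouse reference; each transcript is its own
#' contig, with one exon spanning it entirely, so read containment and pileup
#' are exactly checkable.
#'
#' @param config an [sim_config()] object.
#' @param out_dir optional directory; when given, files
#'   `human.fa`, `mouse.fa`, `human.gtf`, `mouse.gtf`, `orthologs.tsv` are
#'   written there (created if needed).
#' @return An `xs_references` list: named sequence vectors `human` and
#'   `mouse`, `orthologs` data.frame (`human_gene`, `mouse_gene`),
#'   `substituted_positions` (per-pair list), `lengths`, and file `paths`.
#' @export
generate_reference_set <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "xs_config"))
  set.seed(config$seed)
  n <- config$n_genes
  lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 n, replace = TRUE)
  hg <- sprintf("HGENE%04d", seq_len(n))
  mg <- sprintf("MGENE%04d", seq_len(n))
  human <- character(n); mouse <- character(n); subs <- vector("list", n)
  for (i in seq_len(n)) {
    pair <- generate_ortholog_pair(lens[i], config$divergence)
    human[i] <- pair$human_seq
    mouse[i] <- pair$mouse_seq
    subs[[i]] <- pair$substituted_positions
  }
  names(human) <- hg
  names(mouse) <- mg
  orth <- data.frame(human_gene = hg, mouse_gene = mg,
                     stringsAsFactors = FALSE)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      human_fasta = file.path(out_dir, "human.fa"),
      mouse_fasta = file.path(out_dir, "mouse.fa"),
      human_gtf = file.path(out_dir, "human.gtf"),
      mouse_gtf = file.path(out_dir, "mouse.gtf"),
      orthologs = file.path(out_dir, "orthologs.tsv")
    )
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(human),
                                paths$human_fasta)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(mouse),
                                paths$mouse_fasta)
    write_single_exon_gtf(hg, lens, paths$human_gtf)
    write_single_exon_gtf(mg, lens, paths$mouse_gtf)
    utils::write.table(orth, paths$orthologs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  structure(list(human = human, mouse = mouse, orthologs = orth,
                 substituted_positions = subs, lengths = lens,
                 config = config, paths = paths),
            class = "xs_references")
}

write_single_exon_gtf <- function(gene_ids, lengths, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s.1";', gene_ids, gene_ids)
  lines <- paste(gene_ids, "xenosplit", "exon", 1L, lengths,
                 ".", "+", ".", attrs, sep = "\t")
  writeLines(lines, path)
}

#' Simulate truth-labeled reads from a reference set
#'
#' Fragments are drawn gene-uniformly from the species given by the
#' configuration's mixture, with uniform start positions; every base is then
#' flipped independently (to a different base) with probability `error_rate`.
#' In paired mode two mates are taken from the two ends of an insert of at
#' least one read length, the second mate reverse-complemented, and FASTQ
#' output uses `/1`/`/2` mate naming. Phred qualities are constant.
#'
#' @param refs an `xs_references` object.
#' @param config the [sim_config()] used (defaults to the one stored in
#'   `refs`).
#' @param n_reads number of fragments to simulate (a mate pair counts once).
#' @param out_dir optional directory for FASTQ output (`reads.fq`, or
#'   `reads_1.fq` / `reads_2.fq` when paired).
#' @param insert_size target insert size for paired mode, truncated to the
#'   transcript length; default 200 bp.
#' @param seed RNG seed; defaults to `config$seed + 1L` so that reference
#'   generation and read simulation are independently reproducible.
#' @return An `xs_reads` list holding the truth table (`truth`: `read_id`,
#'   `true_species`, `source_gene`, `source_position` 0-based), the per-mate
#'   sequence matrices, fragment coordinates, and FASTQ paths if written.
#' @export
simulate_reads <- function(refs, config = refs$config, n_reads,
                           out_dir = NULL, insert_size = 200L, seed = NULL) {
  stopifnot(inherits(refs, "xs_references"), inherits(config, "xs_config"))
  if (!is.numeric(n_reads) || n_reads < 0) stop("'n_reads' must be >= 0")
  n_reads <- as.integer(n_reads)
  rl <- config$read_length
  if (rl > min(refs$lengths))
    stop("read length exceeds the shortest transcript")
  if (is.null(seed)) seed <- config$seed + 1L
  set.seed(seed)

  species <- if (n_reads > 0L)
    sample(c("human", "mouse"), n_reads, replace = TRUE,
           prob = config$species_mix)
  else character(0)
  gene_idx <- if (n_reads > 0L)
    sample.int(config$n_genes, n_reads, replace = TRUE) else integer(0)
  lens <- refs$lengths[gene_idx]
  insert <- if (config$paired) pmin(lens, as.integer(insert_size))
            else rep(rl, n_reads)
  insert <- pmax(insert, rl)
  start <- if (n_reads > 0L)
    1L + floor(stats::runif(n_reads) * (lens - insert + 1L)) else integer(0)

  src <- ifelse(species == "human",
                refs$human[gene_idx], refs$mouse[gene_idx])
  m1 <- seq_matrix(substring(src, start, start + rl - 1L), rl)
  m2 <- NULL
  if (config$paired) {
    w2 <- substring(src, start + insert - rl, start + insert - 1L)
    m2 <- revcomp_matrix(seq_matrix(w2, rl))
  }
  # sequencing error: independent per-base flips, never to the same base
  if (config$error_rate > 0 && n_reads > 0L) {
    m1 <- mutate_bases(m1, which(stats::runif(length(m1)) < config$error_rate))
    if (config$paired)
      m2 <- mutate_bases(m2, which(stats::runif(length(m2)) < config$error_rate))
  }

  ids <- sprintf("read%06d", seq_len(n_reads))
  source_gene <- ifelse(species == "human",
                        names(refs$human)[gene_idx],
                        names(refs$mouse)[gene_idx])
  truth <- data.frame(read_id = ids,
                      true_species = species,
                      source_gene = as.character(source_gene),
                      source_position = start - 1L,
                      stringsAsFactors = FALSE)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    qual <- strrep("I", rl)
    if (config$paired) {
      paths <- list(fastq_1 = file.path(out_dir, "reads_1.fq"),
                    fastq_2 = file.path(out_dir, "reads_2.fq"))
      write_fastq(paste0(ids, "/1"), collapse_rows(m1), qual, paths$fastq_1)
      write_fastq(paste0(ids, "/2"), collapse_rows(m2), qual, paths$fastq_2)
    } else {
      paths <- list(fastq = file.path(out_dir, "reads.fq"))
      write_fastq(ids, collapse_rows(m1), qual, paths$fastq)
    }
  }

  structure(list(truth = truth, species = species, gene_idx = gene_idx,
                 start = start, insert = insert,
                 mate1 = m1, mate2 = m2, config = config, paths = paths),
            class = "xs_reads")
}

write_fastq <- function(ids, seqs, qual, path) {
  if (length(seqs) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  invisible(path)
}

#' Write dual-genome SAM alignments for simulated reads
#'
#' The simulator knows each fragment's true locus in its source genome and the
#' orthologous locus in the other genome (orthologous transcripts have equal
#' length by construction), so it writes both alignments directly. Each
#' emitted alignment carries an `NM:i:` tag equal to the Hamming distance
#' between the read and the covered reference window; a mate whose distance
#' exceeds `max_mismatch` is emitted as an unmapped record in that SAM.
#'
#' @param reads an `xs_reads` object.
#' @param refs the `xs_references` the reads were simulated from.
#' @param sam_human,sam_mouse output SAM paths.
#' @param max_mismatch per-mate mismatch cutoff above which the alignment is
#'   suppressed (emitted unmapped), emulating an aligner's mismatch tolerance.
#'   Default 10.
#' @return invisibly, a list with the two SAM paths and the per-genome NM
#'   matrices (`nm_human`, `nm_mouse`; one column per mate).
#' @export
emit_alignments <- function(reads, refs, sam_human, sam_mouse,
                            max_mismatch = 10L) {
  stopifnot(inherits(reads, "xs_reads"), inherits(refs, "xs_references"))
  if (nrow(reads$truth) != length(reads$gene_idx))
    stop("reads object lacks truth labels for its fragments")
  nm_h <- genome_nm(reads, refs$human)
  nm_m <- genome_nm(reads, refs$mouse)
  write_genome_sam(reads, names(refs$human), refs$lengths, nm_h,
                   max_mismatch, sam_human)
  write_genome_sam(reads, names(refs$mouse), refs$lengths, nm_m,
                   max_mismatch, sam_mouse)
  invisible(list(sam_human = sam_human, sam_mouse = sam_mouse,
                 nm_human = nm_h, nm_mouse = nm_m))
}

# per-mate Hamming distance of every fragment against one genome
genome_nm <- function(reads, genome) {
  n <- length(reads$gene_idx)
  rl <- reads$config$read_length
  if (n == 0L) return(matrix(integer(0), 0L, if (reads$config$paired) 2L else 1L))
  src <- genome[reads$gene_idx]
  w1 <- seq_matrix(substring(src, reads$start, reads$start + rl - 1L), rl)
  nm1 <- as.integer(rowSums(reads$mate1 != w1))
  if (!reads$config$paired) return(matrix(nm1, ncol = 1L))
  s2 <- reads$start + reads$insert - rl
  w2 <- seq_matrix(substring(src, s2, s2 + rl - 1L), rl)
  nm2 <- as.integer(rowSums(revcomp_matrix(reads$mate2) != w2))
  cbind(nm1, nm2, deparse.level = 0L)
}

write_genome_sam <- function(reads, contigs, lengths, nm, max_mismatch, path) {
  rl <- reads$config$read_length
  n <- length(reads$gene_idx)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs, lengths),
              "@PG\tID:xenosplit\tPN:xenosplit")
  if (n == 0L) { writeLines(header, path); return(invisible(path)) }

  rname <- contigs[reads$gene_idx]
  qual <- strrep("I", rl)
  cigar <- sprintf("%dM", rl)
  ids <- reads$truth$read_id

  if (!reads$config$paired) {
    mapped <- nm[, 1L] <= max_mismatch
    seqs <- collapse_rows(reads$mate1)
    rec <- ifelse(mapped,
      paste(ids, 0L, rname, reads$start, 60L, cigar, "*", 0L, 0L, seqs, qual,
            sprintf("NM:i:%d", nm[, 1L]), sep = "\t"),
      paste(ids, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, seqs, qual, sep = "\t"))
    writeLines(c(header, rec), path)
    return(invisible(path))
  }

  pos1 <- reads$start
  pos2 <- reads$start + reads$insert - rl
  map1 <- nm[, 1L] <= max_mismatch
  map2 <- nm[, 2L] <= max_mismatch
  s1 <- collapse_rows(reads$mate1)
  s2 <- collapse_rows(reads$mate2)
  # FLAG bits: paired(1) + proper(2) + mate strand bits + first/second in pair
  f1 <- 1L + 64L + ifelse(map1, 0L, 4L) +
        ifelse(map2, 32L, 8L) + ifelse(map1 & map2, 2L, 0L)
  f2 <- 1L + 128L + ifelse(map2, 16L, 4L) +
        ifelse(map1, 0L, 8L) + ifelse(map1 & map2, 2L, 0L)
  rec1 <- paste(ids, f1,
                ifelse(map1, rname, "*"),
                ifelse(map1, pos1, 0L), ifelse(map1, 60L, 0L),
                ifelse(map1, cigar, "*"),
                ifelse(map2, rname, "*"), ifelse(map2, pos2, 0L),
                ifelse(map1 & map2, reads$insert, 0L),
                s1, qual, sep = "\t")
  rec1 <- ifelse(map1, paste0(rec1, sprintf("\tNM:i:%d", nm[, 1L])), rec1)
  rec2 <- paste(ids, f2,
                ifelse(map2, rname, "*"),
                ifelse(map2, pos2, 0L), ifelse(map2, 60L, 0L),
                ifelse(map2, cigar, "*"),
                ifelse(map1, rname, "*"), ifelse(map1, pos1, 0L),
                ifelse(map1 & map2, -reads$insert, 0L),
                s2, qual, sep = "\t")
  rec2 <- ifelse(map2, paste0(rec2, sprintf("\tNM:i:%d", nm[, 2L])), rec2)
  writeLines(c(header, as.vector(rbind(rec1, rec2))), path)
  invisible(path)
}
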