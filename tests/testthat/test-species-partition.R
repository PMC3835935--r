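test_that("fragments are classified by comparative mismatch fidelity", {
  summ <- data.frame(
    read_id = c("a", "b", "c", "d", "e", "f"),
    nm_human = c(0, 2, NA, 3, NA, 1),
    nm_mouse = c(3, 2, NA, 1, 4, NA))
  expect_identical(classify_reads(summ),
                   c("human", "ambiguous", "unaligned", "mouse",
                     "mouse", "human"))
})

test_that("alignment summaries take the per-mate minimum over all alignments", {
  contigs <- c(chrH = 5000L)
  seq40 <- strrep("A", 40)
  # read r1 reported twice in human (NM 2 and 5): best must be 2
  rec_h <- data.frame(
    qname = c("r1", "r1", "r2"),
    flag = c(0L, 256L, 0L),
    rname = "chrH", pos = c(100L, 300L, 700L), cigar = "40M",
    seq = seq40, opt = c("NM:i:2", "NM:i:5", "NM:i:1"),
    stringsAsFactors = FALSE)
  # r2 present only in human's mapped records; r3 only in mouse
  rec_m <- data.frame(
    qname = c("r1", "r3"),
    flag = c(0L, 0L),
    rname = "chrM", pos = c(100L, 200L), cigar = "40M",
    seq = seq40, opt = c("NM:i:4", "NM:i:0"),
    stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  sam_h <- write_test_sam(rec_h, contigs, file.path(d, "h.sam"))
  sam_m <- write_test_sam(rec_m, c(chrM = 5000L), file.path(d, "m.sam"))
  summ <- summarize_alignments(sam_h, sam_m)
  summ <- summ[order(summ$read_id), ]
  expect_equal(summ$nm_human, c(2, 1, NA))
  expect_equal(summ$nm_mouse, c(4, NA, 0))
})

test_that("summaries agree with a brute-force scan of both SAM files", {
  s <- make_sim_sample(n_genes = 15, n_reads = 300, seed = 31)
  summ <- summarize_alignments(s$sam_human, s$sam_mouse)
  ord <- match(s$reads$truth$read_id, summ$read_id)
  # oracle: parse SAM text directly, min NM per mate, sum if both mates map
  oracle <- function(path) {
    lines <- readLines(path)
    body <- strsplit(lines[!startsWith(lines, "@")], "\t")
    qn <- vapply(body, `[`, "", 1)
    fl <- as.integer(vapply(body, `[`, "", 2))
    nm <- vapply(body, function(f) {
      hit <- grep("^NM:i:", f, value = TRUE)
      if (length(hit)) as.integer(sub("NM:i:", "", hit[1])) else NA_integer_
    }, integer(1))
    mapped <- bitwAnd(fl, 4L) == 0L
    mate <- ifelse(bitwAnd(fl, 128L) > 0L, 2L, 1L)
    vapply(unique(qn), function(q) {
      best <- tapply(nm[mapped & qn == q], mate[mapped & qn == q], min)
      if (length(best) < length(unique(mate[qn == q]))) NA_real_
      else sum(best)
    }, numeric(1))
  }
  oh <- oracle(s$sam_human)
  om <- oracle(s$sam_mouse)
  expect_equal(summ$nm_human[ord], unname(oh[s$reads$truth$read_id]))
  expect_equal(summ$nm_mouse[ord], unname(om[s$reads$truth$read_id]))
})

test_that("NM falls back to MD and missing both is a hard error", {
  contigs <- c(chrH = 1000L)
  rec <- data.frame(qname = "r1", flag = 0L, rname = "chrH", pos = 10L,
                    cigar = "8M", seq = "ACGTACGT", opt = "MD:Z:3A2C1",
                    stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  sam_md <- write_test_sam(rec, contigs, file.path(d, "md.sam"))
  rec$opt <- ""
  sam_none <- write_test_sam(rec, contigs, file.path(d, "none.sam"))
  empty <- write_test_sam(rec[0, ], contigs, file.path(d, "e.sam"))
  summ <- summarize_alignments(sam_md, empty)
  expect_equal(summ$nm_human, 2)  # two substituted bases in the MD string
  expect_error(summarize_alignments(sam_none, empty), "NM or MD")
})

test_that("partitions conserve reads and are symmetric under species swap", {
  s <- make_sim_sample(n_genes = 20, n_reads = 500, seed = 12)
  p <- partition_sample(s$sam_human, s$sam_mouse, "fwd")
  expect_identical(sum(p$counts), p$total_reads)
  expect_identical(p$total_reads, 500L)
  expect_equal(sum(p$fractions), 100)
  expect_false(anyDuplicated(unlist(p$read_ids)) > 0)

  swapped <- partition_sample(s$sam_mouse, s$sam_human, "rev")
  expect_identical(swapped$counts[["human"]], p$counts[["mouse"]])
  expect_identical(swapped$counts[["mouse"]], p$counts[["human"]])
  expect_identical(swapped$counts[["ambiguous"]], p$counts[["ambiguous"]])
  expect_identical(swapped$counts[["unaligned"]], p$counts[["unaligned"]])
})

test_that("identical references make every aligned error-free read ambiguous", {
  s <- make_sim_sample(n_genes = 10, n_reads = 200, seed = 13,
                       divergence = 0, error_rate = 0)
  p <- partition_sample(s$sam_human, s$sam_mouse, "zero-divergence")
  aligned <- p$total_reads - p$counts[["unaligned"]]
  expect_identical(p$counts[["ambiguous"]], aligned)
})

test_that("species classification matches truth labels on a mixed sample", {
  s <- make_sim_sample(n_genes = 30, n_reads = 4000, seed = 14,
                       species_mix = c(human = 0.9, mouse = 0.1))
  p <- partition_sample(s$sam_human, s$sam_mouse, "mix")
  cls <- classify_reads(p$summary)[match(s$reads$truth$read_id,
                                         p$summary$read_id)]
  # fragments whose covered windows hold no substitution are necessarily
  # ambiguous; exclude them from the accuracy denominator
  rl <- s$cfg$read_length
  n_subs <- vapply(seq_len(nrow(s$reads$truth)), function(i) {
    subs <- s$refs$substituted_positions[[s$reads$gene_idx[i]]]
    st <- s$reads$start[i]; st2 <- st + s$reads$insert[i] - rl
    sum(subs >= st & subs < st + rl) + sum(subs >= st2 & subs < st2 + rl)
  }, integer(1))
  informative <- n_subs > 0
  acc <- mean(cls[informative] == s$reads$truth$true_species[informative])
  expect_gte(acc, 0.99)
})

test_that("pure human samples are rarely flagged as mouse", {
  s <- make_sim_sample(n_genes = 25, n_reads = 5000, seed = 15,
                       species_mix = c(human = 1, mouse = 0))
  p <- partition_sample(s$sam_human, s$sam_mouse, "pure")
  expect_lte(p$fractions[["mouse"]], 0.2)
})

test_that("partition reports reproduce printed-percentage arithmetic", {
  fake_partition <- function(id, counts) {
    counts <- stats::setNames(as.integer(counts),
                              c("human", "mouse", "ambiguous", "unaligned"))
    total <- sum(counts)
    structure(list(sample_id = id, total_reads = total, counts = counts,
                   fractions = 100 * counts / total,
                   undefined_fractions = FALSE, read_ids = list()),
              class = "xs_partition")
  }
  r <- partition_report(fake_partition("S", c(950, 40, 10, 0)))
  expect_equal(r$human_pct, 95.00)
  expect_equal(r$mouse_pct, 4.00)
  expect_equal(r$ambiguous_pct, 1.00)

  # printed sequencing yields: total and human counts reproduce the printed
  # human percentage at two decimals
  tot <- 187239646; hum <- 178775171
  r2 <- partition_report(fake_partition(
    "D55949.X2", c(hum, 7227519, tot - hum - 7227519, 0)))
  expect_equal(r2$human_pct, 95.48)

  # rounding audit: per-row two-decimal percentages sum to 100 +/- 0.02
  set.seed(99)
  for (i in 1:50) {
    counts <- as.integer(rmultinom(1, sample(1000:100000, 1),
                                   prob = runif(4)))
    rr <- partition_report(fake_partition("x", counts))
    total_pct <- rr$human_pct + rr$mouse_pct + rr$ambiguous_pct +
                 rr$unaligned_pct
    expect_lte(abs(total_pct - 100), 0.02)
  }
})

test_that("filtered SAM output contains exactly the class's own-genome alignments", {
  s <- make_sim_sample(n_genes = 15, n_reads = 300, seed = 16)
  out <- withr::local_tempdir()
  p <- partition_sample(s$sam_human, s$sam_mouse, "flt", out_dir = out)
  flt <- readLines(file.path(out, "flt.human.sam"))
  body <- flt[!startsWith(flt, "@")]
  expect_setequal(unique(sub("\t.*", "", body)), p$read_ids$human)
  flags <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2))
  expect_true(all(bitwAnd(flags, 4L) == 0L))
})

test_that("empty input yields a flagged zero partition", {
  d <- withr::local_tempdir()
  contigs <- c(chrH = 100L)
  empty_h <- write_test_sam(
    data.frame(qname = character(0), flag = integer(0), rname = character(0),
               pos = integer(0), cigar = character(0), seq = character(0),
               opt = character(0)), contigs, file.path(d, "h.sam"))
  empty_m <- write_test_sam(
    data.frame(qname = character(0), flag = integer(0), rname = character(0),
               pos = integer(0), cigar = character(0), seq = character(0),
               opt = character(0)), c(chrM = 100L), file.path(d, "m.sam"))
  p <- partition_sample(empty_h, empty_m, "empty")
  expect_identical(p$total_reads, 0L)
  expect_true(p$undefined_fractions)
  expect_true(all(is.na(p$fractions)))
})
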