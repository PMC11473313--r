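write_fastq <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", strrep("I", nchar(seqs)))), con)
  close(con)
  path
}

make_probe_set <- function(n = 3, flank = 30, seed = 42) {
  withr::with_seed(seed, {
    junction_probes(
      fusion_id = paste0("FG", seq_len(n)),
      isoform_key = paste0("FG", seq_len(n), "|iso1"),
      probe_sequence = vapply(seq_len(n), function(i) random_dna_string(2 * flank), character(1)),
      breakpoint_offset = flank
    )
  })
}

test_that("index windows equal brute-force breakpoint-spanning enumeration", {
  probes <- make_probe_set(3)
  for (params in list(c(20, 10), c(30, 12), c(60, 20))) {
    idx <- build_junction_index(probes, match_len = params[1], anchor = params[2])
    want <- unique(unlist(lapply(seq_len(nrow(probes)), function(i) {
      brute_force_windows(
        probes$probe_sequence[i], probes$breakpoint_offset[i],
        params[1], params[2]
      )
    })))
    expect_setequal(idx$keys, want)
  }
})

test_that("a full-length probe window indexes to a single key", {
  probes <- make_probe_set(1, flank = 30)
  idx <- build_junction_index(probes, match_len = 60, anchor = 10)
  expect_length(idx$keys, 1)
  expect_equal(idx$keys, probes$probe_sequence)
  expect_equal(idx$probe_idx[[1]], 1L)
})

test_that("windows containing N are excluded from the index", {
  p <- junction_probes("FG1", "FG1|iso1",
    paste0(strrep("A", 29), "N", strrep("C", 30)),
    breakpoint_offset = 30
  )
  idx <- build_junction_index(p, match_len = 20, anchor = 10)
  # the only anchor-compliant window covers positions 21-40 and contains the N
  expect_length(idx$keys, 0)
})

test_that("probes shorter than the window are rejected by name", {
  p <- junction_probes("FG1", "shorty", strrep("ACGT", 4), breakpoint_offset = 8)
  expect_error(build_junction_index(p, match_len = 20, anchor = 8), "shorty")
  expect_error(build_junction_index(make_probe_set(1), match_len = 10, anchor = 10), "2 \\* anchor")
})

test_that("probes sharing a 5' side do not share breakpoint-spanning keys", {
  withr::with_seed(7, {
    left <- random_dna_string(30)
    p <- junction_probes(
      c("FGa", "FGb"), c("ka", "kb"),
      c(paste0(left, random_dna_string(30)), paste0(left, random_dna_string(30))),
      breakpoint_offset = 30
    )
    idx <- build_junction_index(p, match_len = 20, anchor = 10)
    multi <- vapply(idx$probe_idx, length, integer(1))
    expect_true(all(multi == 1))
  })
})

test_that("scanner finds planted probes on either strand", {
  withr::with_seed(9, {
    probes <- make_probe_set(2)
    idx <- build_junction_index(probes)
    read <- paste0(random_dna_string(7), probes$probe_sequence[1], random_dna_string(13))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
    fq <- write_fastq(c(read, rc), withr::local_tempfile(fileext = ".fastq"))
    rep_on <- scan_reads(fq, idx, sample_id = "s1")
    expect_equal(rep_on$read_count, c(2L, 0L))
    expect_equal(rep_on$positive, c(TRUE, FALSE))
    rep_off <- scan_reads(fq, idx, sample_id = "s1", with_reverse_complement = FALSE)
    expect_equal(rep_off$read_count, c(1L, 0L))
  })
})

test_that("random junction-free reads never hit the index", {
  withr::with_seed(13, {
    probes <- make_probe_set(2)
    idx <- build_junction_index(probes, match_len = 30, anchor = 15)
    reads <- vapply(1:2000, function(i) random_dna_string(100), character(1))
    fq <- write_fastq(reads, withr::local_tempfile(fileext = ".fastq.gz"))
    report <- scan_reads(fq, idx)
    expect_equal(sum(report$read_count), 0)
    expect_false(any(report$positive))
  })
})

test_that("scan results are independent of read order, chunking, and file splits", {
  withr::with_seed(21, {
    probes <- make_probe_set(3)
    idx <- build_junction_index(probes)
    planted <- c(
      vapply(1:6, function(i) {
        paste0(random_dna_string(5), probes$probe_sequence[1 + i %% 3], random_dna_string(35))
      }, character(1)),
      vapply(1:20, function(i) random_dna_string(100), character(1))
    )
    base <- scan_reads(
      write_fastq(planted, withr::local_tempfile(fileext = ".fastq")),
      idx, sample_id = "s"
    )
    shuffled <- scan_reads(
      write_fastq(sample(planted), withr::local_tempfile(fileext = ".fastq")),
      idx, sample_id = "s"
    )
    chunked <- scan_reads(
      write_fastq(planted, withr::local_tempfile(fileext = ".fastq")),
      idx, sample_id = "s", chunk_size = 3
    )
    split2 <- scan_reads(
      c(
        write_fastq(planted[1:11], withr::local_tempfile(fileext = ".fastq")),
        write_fastq(planted[12:26], withr::local_tempfile(fileext = ".fastq"))
      ),
      idx, sample_id = "s"
    )
    expect_identical(base, shuffled)
    expect_identical(base, chunked)
    expect_identical(base, split2)
  })
})

test_that("malformed FASTQ records are reported with their record number", {
  probes <- make_probe_set(1)
  idx <- build_junction_index(probes)
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "no_at_sign", "ACGT", "+", "IIII"), path)
  expect_error(scan_reads(path, idx), "record\\(s\\) at: 2")
  writeLines(c("@r1", "ACGT", "+", "III"), path) # qual length mismatch
  expect_error(scan_reads(path, idx), "malformed")
  writeLines(c("@r1", "ACGT", "+"), path)
  expect_error(scan_reads(path, idx), "truncated|incomplete")
})

test_that("reads shorter than the window still match probes with both anchors", {
  probes <- make_probe_set(1, flank = 30)
  idx <- build_junction_index(probes, match_len = 40, anchor = 10)
  # 24-base fragment centred on the breakpoint: spans 12 bases each side
  frag <- substr(probes$probe_sequence, 19, 42)
  fq <- write_fastq(frag, withr::local_tempfile(fileext = ".fastq"))
  expect_equal(scan_reads(fq, idx)$read_count, 1L)
  # fragment on one side of the junction only: anchors fail
  one_side <- substr(probes$probe_sequence, 1, 24)
  fq2 <- write_fastq(one_side, withr::local_tempfile(fileext = ".fastq"))
  expect_equal(scan_reads(fq2, idx)$read_count, 0L)
})

test_that("probe FASTA round-trips with pipe-delimited isoform keys intact", {
  probes <- junction_probes(
    fusion_id = c("A-B", "C-D"),
    isoform_key = c("A|B|chr1:10|chr1:99", "C|D|chr2:5|chr2:50"),
    probe_sequence = c(strrep("ACGT", 15), strrep("GGCA", 15)),
    breakpoint_offset = 30L
  )
  path <- withr::local_tempfile(fileext = ".fa")
  write_probe_fasta(probes, path)
  back <- read_probe_fasta(path)
  expect_equal(as.data.frame(back), as.data.frame(probes))
})

test_that("scan summaries collapse runs to patients for the stats stage", {
  design <- toy_design()
  reports <- tibble::tibble(
    sample_id = c("r1", "r2", "r4", "r5"),
    fusion_id = "FG1",
    isoform_key = "FG1|iso1",
    read_count = c(3L, 1L, 0L, 2L),
    positive = c(TRUE, TRUE, FALSE, TRUE)
  )
  s <- summarize_scan(reports, design)
  # p1 positive via two runs (once), p2 negative, c1 positive
  expect_equal(nrow(s$presence), 2)
  rec <- s$recurrence
  expect_equal(rec$positive_patients[rec$cohort == "case"], 1)
  expect_equal(rec$positive_patients[rec$cohort == "control"], 1)
  # empty reports give zero counts
  s0 <- summarize_scan(reports[reports$read_count > 99, ], design)
  expect_equal(nrow(s0$presence), 0)
})

test_that("probe validation rejects non-nucleotide characters and duplicate keys", {
  expect_error(junction_probes("f", "k", "ACGU"), "A/C/G/T/N")
  expect_error(
    junction_probes(c("f", "f"), c("k", "k"), c("ACGT", "ACGT")),
    "unique"
  )
})
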