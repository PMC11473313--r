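# Independent oracles and fixture builders shared across test files.

# Brute-force rule classifier: enumerates the decision table case by case,
# computing the gap from sorted interval endpoints rather than the package's
# pmax/pmin arithmetic. Scalar, deliberately naive.
brute_force_classify <- function(a, b, threshold = 200000) {
  if (a$chrom != b$chrom) {
    return(list(category = "GENOMIC", mechanism = "interchromosomal_translocation", gap = NA_real_))
  }
  # gap: bases strictly between the intervals, from sorted endpoints
  left <- if (a$start <= b$start) a else b
  right <- if (a$start <= b$start) b else a
  gap <- if (right$start <= left$end) 0 else right$start - left$end
  if (a$strand != b$strand) {
    return(list(category = "GENOMIC", mechanism = "inversion", gap = gap))
  }
  upstream <- if (a$strand == "+") a$start <= b$start else a$end >= b$end
  if (!upstream) {
    return(list(category = "GENOMIC", mechanism = "duplication_or_order_reversal", gap = gap))
  }
  if (gap <= threshold) {
    return(list(category = "EFG", mechanism = "readthrough", gap = gap))
  }
  list(category = "GENOMIC", mechanism = "distal_intrachromosomal", gap = gap)
}

# Random annotation of up to n genes across a couple of chromosomes,
# including occasional overlapping intervals.
random_annotation <- function(n, max_pos = 1e6) {
  starts <- sample.int(max_pos, n, replace = TRUE)
  lens <- sample(c(200, 2000, 50000), n, replace = TRUE)
  gene_model(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = sample(c("chrA", "chrB"), n, replace = TRUE),
    start = starts,
    end = starts + lens,
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

# Brute-force enumeration of breakpoint-spanning windows of one probe:
# every substring of length w whose span covers >= anchor bases each side.
brute_force_windows <- function(seq, offset, w, anchor) {
  n <- nchar(seq)
  wins <- character(0)
  for (s in seq_len(max(0, n - w + 1))) {
    e <- s + w - 1
    left <- offset - s + 1
    right <- e - offset
    if (left >= anchor && right >= anchor) {
      win <- substr(seq, s, e)
      if (!grepl("N", win, fixed = TRUE)) wins <- c(wins, win)
    }
  }
  unique(wins)
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small 4-gene annotation with one pair per mechanism regime.
toy_genes <- function() {
  gene_model(
    gene_id = c("UP", "DOWN", "MINUS", "FAR", "OTHER"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(1000, 52000, 100000, 500000, 1000),
    end = c(2000, 53000, 101000, 501000, 2000),
    strand = c("+", "+", "-", "+", "+")
  )
}

# A tiny two-patient design used by the bookkeeping tests.
toy_design <- function() {
  cohort_design(
    run_id = c("r1", "r2", "r3", "r4", "r5"),
    patient_id = c("p1", "p1", "p1", "p2", "c1"),
    cohort = c("case", "case", "case", "case", "control")
  )
}
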