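#' Junction probe table
#'
#' A probe is a short sequence straddling one fusion breakpoint:
#' `breakpoint_offset` bases of 5'-side sequence followed by the 3'-side
#' remainder. A read validates the isoform only if it matches the probe
#' across the breakpoint, so neither native parental gene can produce a hit.
#'
#' @param fusion_id Gene-pair identifier per probe.
#' @param isoform_key Isoform identifier per probe (unique).
#' @param probe_sequence Nucleotide string (`A/C/G/T/N`).
#' @param breakpoint_offset 1-based position of the last 5'-side base within
#'   the probe; defaults to half the probe length (symmetric probes).
#' @return Tibble of class `junction_probes`.
#' @export
junction_probes <- function(fusion_id, isoform_key, probe_sequence,
                            breakpoint_offset = NULL) {
  probe_sequence <- toupper(as.character(probe_sequence))
  if (any(grepl("[^ACGTN]", probe_sequence))) {
    abort("probe sequences may contain only A/C/G/T/N")
  }
  if (is.null(breakpoint_offset)) {
    breakpoint_offset <- as.integer(nchar(probe_sequence) / 2)
  }
  if (anyDuplicated(isoform_key)) {
    abort("isoform_key values must be unique across probes")
  }
  out <- tibble::tibble(
    fusion_id = as.character(fusion_id),
    isoform_key = as.character(isoform_key),
    probe_sequence = probe_sequence,
    breakpoint_offset = as.integer(breakpoint_offset)
  )
  class(out) <- c("junction_probes", class(out))
  out
}

#' Derive junction probes from breakpoints and a genome
#'
#' Takes `flank` bases ending at the 5' breakpoint and `flank` bases
#' starting after the 3' breakpoint. Breakpoints follow the package's
#' 0-based convention: `five_prime_pos` is the half-open end of the 5'
#' piece, `three_prime_pos` the 0-based start of the 3' piece.
#'
#' @param junctions Tibble from [fusion_junction()].
#' @param genome A named [Biostrings::DNAStringSet] (names = chromosomes).
#' @param flank Bases taken from each side (default 30; probes are
#'   `2 * flank` long).
#' @return A [junction_probes] tibble.
#' @export
make_junction_probes <- function(junctions, genome, flank = 30) {
  seqs <- vapply(seq_len(nrow(junctions)), function(i) {
    j <- junctions[i, ]
    left <- as.character(Biostrings::subseq(
      genome[[j$five_prime_chrom]],
      start = j$five_prime_pos - flank + 1, end = j$five_prime_pos
    ))
    right <- as.character(Biostrings::subseq(
      genome[[j$three_prime_chrom]],
      start = j$three_prime_pos + 1, end = j$three_prime_pos + flank
    ))
    paste0(left, right)
  }, character(1))
  junction_probes(
    fusion_id = junctions$fusion_id,
    isoform_key = junctions$isoform_key,
    probe_sequence = seqs,
    breakpoint_offset = flank
  )
}

#' Read and write probe FASTA
#'
#' Headers encode `fusion_id|isoform_key|breakpoint_offset`; since
#' isoform keys themselves contain `|` separators, the first field is the
#' fusion_id, the last the offset, and everything between is the key.
#'
#' @param probes A [junction_probes] tibble.
#' @param path FASTA path.
#' @return `write_probe_fasta` the path, invisibly; `read_probe_fasta` a
#'   [junction_probes] tibble.
#' @export
write_probe_fasta <- function(probes, path) {
  x <- Biostrings::DNAStringSet(probes$probe_sequence)
  names(x) <- paste(probes$fusion_id, probes$isoform_key,
    probes$breakpoint_offset,
    sep = "|"
  )
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_probe_fasta
#' @export
read_probe_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    abort(paste0(
      "malformed probe header(s): ",
      paste(head(names(x)[bad], 5), collapse = ", ")
    ))
  }
  junction_probes(
    fusion_id = vapply(parts, `[`, character(1), 1),
    isoform_key = vapply(parts, function(p) {
      paste(p[2:(length(p) - 1)], collapse = "|")
    }, character(1)),
    probe_sequence = as.character(x),
    breakpoint_offset = as.integer(vapply(parts, function(p) p[length(p)], character(1)))
  )
}

#' Build the exact-lookup junction index
#'
#' Hash-style index of every length-`match_len` window of every probe that
#' spans the breakpoint by at least `anchor` bases on each side. Windows
#' containing `N` are excluded. A window shared by several probes keeps all
#' of them (multi-hit). The anchor requirement is what gives the scanner
#' its specificity: a native-gene read can match one side of a probe but
#' never a breakpoint-spanning window.
#'
#' @param probes A [junction_probes] tibble.
#' @param match_len Window length; default `2 * anchor`. Every probe must be
#'   at least this long.
#' @param anchor Minimum bases required on each side of the breakpoint
#'   (default 10).
#' @return A `junction_index` list: `keys`, `probe_idx` (aligned list of
#'   probe row indices), `probes`, `match_len`, `anchor`.
#' @export
build_junction_index <- function(probes, match_len = 2 * anchor, anchor = 10) {
  stopifnot(anchor >= 1)
  force(match_len)
  if (match_len < 2 * anchor) {
    abort("match_len must be at least 2 * anchor to span the breakpoint")
  }
  too_short <- nchar(probes$probe_sequence) < match_len
  if (any(too_short)) {
    abort(paste0(
      "probe(s) shorter than match_len: ",
      paste(probes$isoform_key[too_short], collapse = ", ")
    ))
  }
  keys <- character(0)
  owners <- integer(0)
  for (i in seq_len(nrow(probes))) {
    seq_i <- probes$probe_sequence[i]
    L <- probes$breakpoint_offset[i]
    n <- nchar(seq_i)
    # window [s, s + match_len - 1] must contain [L - anchor + 1, L + anchor]
    s_min <- max(1, L + anchor - match_len + 1)
    s_max <- min(n - match_len + 1, L - anchor + 1)
    if (s_min > s_max) next
    wins <- substring(seq_i, s_min:s_max, (s_min:s_max) + match_len - 1)
    ok <- !grepl("N", wins, fixed = TRUE)
    keys <- c(keys, wins[ok])
    owners <- c(owners, rep(i, sum(ok)))
  }
  uniq <- unique(keys)
  probe_idx <- lapply(uniq, function(k) sort(unique(owners[keys == k])))
  structure(
    list(
      keys = uniq, probe_idx = probe_idx, probes = probes,
      match_len = as.integer(match_len), anchor = as.integer(anchor)
    ),
    class = "junction_index"
  )
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# parse one chunk of FASTQ lines into sequences; record_offset for error text
parse_fastq_chunk <- function(lines, record_offset) {
  if (length(lines) %% 4 != 0) {
    abort(paste0(
      "truncated FASTQ: record ", record_offset + length(lines) %/% 4 + 1,
      " is incomplete"
    ))
  }
  ids <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  bad <- !startsWith(ids, "@") | !startsWith(plus, "+") |
    nchar(seqs) != nchar(quals)
  if (any(bad)) {
    abort(paste0(
      "malformed FASTQ record(s) at: ",
      paste(record_offset + which(bad)[seq_len(min(5, sum(bad)))], collapse = ", ")
    ))
  }
  toupper(seqs)
}

# probe hits for a vector of read sequences; returns unique (read, probe) pairs
match_chunk <- function(seqs, index, with_reverse_complement) {
  n_reads <- length(seqs)
  if (with_reverse_complement) seqs <- c(seqs, revcomp(seqs))
  read_of <- rep(seq_len(n_reads), times = if (with_reverse_complement) 2 else 1)
  w <- index$match_len
  hit_read <- integer(0)
  hit_probe <- integer(0)

  long <- nchar(seqs) >= w
  if (any(long)) {
    ls <- seqs[long]
    lr <- read_of[long]
    maxlen <- max(nchar(ls))
    for (i in seq_len(maxlen - w + 1)) {
      wins <- substring(ls, i, i + w - 1)
      m <- match(wins, index$keys) # short windows never equal a full key
      found <- which(!is.na(m))
      for (f in found) {
        pids <- index$probe_idx[[m[f]]]
        hit_read <- c(hit_read, rep(lr[f], length(pids)))
        hit_probe <- c(hit_probe, pids)
      }
    }
  }
  # short reads: direct substring search within each probe, anchors enforced
  short <- which(!long)
  for (s in short) {
    rs <- seqs[s]
    if (nchar(rs) < 2 * index$anchor) next
    for (i in seq_len(nrow(index$probes))) {
      L <- index$probes$breakpoint_offset[i]
      pos <- gregexpr(rs, index$probes$probe_sequence[i], fixed = TRUE)[[1]]
      if (pos[1] == -1) next
      spans <- pos <= L - index$anchor + 1 &
        pos + nchar(rs) - 1 >= L + index$anchor
      if (any(spans)) {
        hit_read <- c(hit_read, read_of[s])
        hit_probe <- c(hit_probe, i)
      }
    }
  }
  unique(cbind(read = hit_read, probe = hit_probe))
}

#' Scan FASTQ reads against a junction index
#'
#' Streams reads in fixed-size chunks (memory independent of file size) and
#' counts, per probe, the reads containing an indexed breakpoint-spanning
#' window — forward or reverse-complement when
#' `with_reverse_complement = TRUE`. Matching is exact; base qualities are
#' ignored. A read matching several windows of one probe counts once for
#' that probe. Reads shorter than the window length are checked by direct
#' substring search against each probe, still requiring both anchors.
#'
#' @param fastq Path(s) to FASTQ files (plain or gzip) of one sample.
#' @param index A [build_junction_index()] result.
#' @param sample_id Sample label; defaults to the first file's base name.
#' @param with_reverse_complement Scan both strands (default `TRUE`).
#' @param chunk_size Reads per streamed chunk.
#' @return A scan report tibble, one row per probe: `sample_id`,
#'   `fusion_id`, `isoform_key`, `read_count`, `positive`
#'   (`read_count >= 1`). All probes are reported, including zeros.
#' @export
scan_reads <- function(fastq, index, sample_id = NULL,
                       with_reverse_complement = TRUE, chunk_size = 5000) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq[1]))
  }
  counts <- integer(nrow(index$probes))
  for (path in fastq) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con), add = TRUE)
    offset <- 0L
    repeat {
      lines <- readLines(con, n = 4L * chunk_size)
      if (length(lines) == 0) break
      seqs <- parse_fastq_chunk(lines, offset)
      hits <- match_chunk(seqs, index, with_reverse_complement)
      if (nrow(hits) > 0) {
        tab <- table(hits[, "probe"])
        idx <- as.integer(names(tab))
        counts[idx] <- counts[idx] + as.integer(tab)
      }
      offset <- offset + length(seqs)
    }
    close(con)
    on.exit() # already closed
  }
  tibble::tibble(
    sample_id = sample_id,
    fusion_id = index$probes$fusion_id,
    isoform_key = index$probes$isoform_key,
    read_count = counts,
    positive = counts >= 1
  )
}

#' Summarise scan reports into cohort recurrence
#'
#' Converts per-run scan reports (with `sample_id` equal to the run ID) into
#' per-patient presence and a per-cohort recurrence table, so scanner output
#' feeds the association machinery unchanged.
#'
#' @param reports Row-bound [scan_reads()] reports, one per run.
#' @param design A [cohort_design].
#' @param unit Count recurrence per `"isoform"` (isoform_key) or per
#'   `"fusion"` (gene pair).
#' @return List with `presence` (per-patient) and `recurrence`
#'   ([recurrence_table()] output).
#' @export
summarize_scan <- function(reports, design, unit = c("isoform", "fusion")) {
  unit <- match.arg(unit)
  pos <- reports[reports$positive, ]
  calls <- tibble::tibble(
    run_id = pos$sample_id,
    fusion_id = if (unit == "isoform") pos$isoform_key else pos$fusion_id
  )
  presence <- collapse_runs_to_patients(calls, design)
  list(presence = presence, recurrence = recurrence_table(presence, design))
}

#' Write a scan report as TSV
#'
#' @param report A [scan_reads()] report.
#' @param path Output path.
#' @export
write_scan_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}
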