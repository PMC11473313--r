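#' Build a gene model table
#'
#' The annotation container used throughout the package: one row per gene,
#' coordinates 0-based half-open. Classification depends only on
#' `(chrom, start, end, strand)`.
#'
#' @param gene_id Character vector of stable gene identifiers (unique).
#' @param chrom Chromosome name per gene.
#' @param start,end Integer gene-body bounds, 0-based half-open (`start < end`).
#' @param strand `"+"` or `"-"` per gene.
#' @param symbol Optional display names; defaults to `gene_id`.
#'
#' @return A tibble of class `gene_model` with columns `gene_id`, `symbol`,
#'   `chrom`, `start`, `end`, `strand`.
#' @export
#' @examples
#' gene_model(c("A", "B"), "chr1", c(0, 3000), c(2000, 5000), c("+", "+"))
gene_model <- function(gene_id, chrom, start, end, strand, symbol = gene_id) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    abort(paste0(
      "duplicated gene_id: ",
      paste(unique(gene_id[duplicated(gene_id)]), collapse = ", ")
    ))
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start >= end)) {
    abort("gene intervals must satisfy start < end (0-based half-open)")
  }
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' for every gene")
  }
  out <- tibble::tibble(
    gene_id = gene_id,
    symbol = as.character(symbol),
    chrom = as.character(chrom),
    start = start,
    end = end,
    strand = strand
  )
  class(out) <- c("gene_model", class(out))
  out
}

#' Read gene annotation from GTF or BED
#'
#' GTF rows with `type == "gene"` (or all rows when no type metadata is
#' present) are converted from 1-based inclusive to the package's 0-based
#' half-open convention. Six-column BED is already 0-based half-open.
#' A strand of `*`/`.` is rejected: strand drives the readthrough rule.
#'
#' @param path Path to a `.gtf`/`.gff` or `.bed` file.
#' @param format `"auto"` (by extension), `"gtf"`, or `"bed"`.
#' @return A [gene_model] tibble.
#' @export
read_gene_annotation <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gtf"
  }
  gr <- rtracklayer::import(path, format = format)
  meta <- S4Vectors::mcols(gr)
  if (format == "gtf" && "type" %in% names(meta)) {
    gr <- gr[as.character(meta$type) == "gene"]
    meta <- S4Vectors::mcols(gr)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) {
    abort("annotation contains features without strand; strand is mandatory")
  }
  ids <- if ("gene_id" %in% names(meta)) {
    as.character(meta$gene_id)
  } else if ("name" %in% names(meta)) {
    as.character(meta$name)
  } else {
    abort("annotation has neither gene_id (GTF) nor name (BED) fields")
  }
  symbols <- if ("gene_name" %in% names(meta)) as.character(meta$gene_name) else ids
  gene_model(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L, # GRanges is 1-based inclusive
    end = BiocGenerics::end(gr),
    strand = strand,
    symbol = symbols
  )
}

#' Write a gene model as GTF and/or BED
#'
#' @param genes A [gene_model] tibble.
#' @param gtf,bed Output paths; `NULL` skips that format.
#' @return Invisibly, the paths written.
#' @export
write_gene_annotation <- function(genes, gtf = NULL, bed = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    gene_id = genes$gene_id,
    gene_name = genes$symbol
  )
  if (!is.null(gtf)) {
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$source <- "fusionrec"
    rtracklayer::export(gr, gtf, format = "gtf")
  }
  if (!is.null(bed)) {
    S4Vectors::mcols(gr)$name <- genes$gene_id
    S4Vectors::mcols(gr)$score <- 0L
    rtracklayer::export(gr[, c("name", "score")], bed, format = "bed")
  }
  invisible(c(gtf = gtf, bed = bed))
}

gene_lookup <- function(genes, gene_id) {
  idx <- match(gene_id, genes$gene_id)
  if (anyNA(idx)) {
    abort(paste0(
      "gene(s) not found in annotation: ",
      paste(unique(gene_id[is.na(idx)]), collapse = ", ")
    ))
  }
  idx
}

#' Intergenic gap between two genes
#'
#' Bases strictly between the two gene bodies: 0 when they overlap or abut,
#' `NA` when the genes sit on different chromosomes (the gap is undefined
#' there, e.g. translocation partners). Vectorised over rows.
#'
#' @param a,b Single-row (or equal-length) subsets of a [gene_model], or the
#'   result of indexing one.
#' @return Numeric gap in bp, `NA` for cross-chromosome pairs.
#' @export
#' @examples
#' g <- gene_model(c("A", "B"), "chr1", c(1000, 2500), c(2000, 3000), c("+", "+"))
#' intergenic_gap(g[1, ], g[2, ]) # 500
intergenic_gap <- function(a, b) {
  gap <- pmax(0, pmax(a$start, b$start) - pmin(a$end, b$end))
  gap[a$chrom != b$chrom] <- NA_real_
  gap
}

#' Canonical fusion-junction (isoform) keys
#'
#' Deterministic identifier for one fusion isoform: partner genes plus both
#' breakpoints. The same gene pair with different breakpoints yields
#' different keys (distinct isoforms of one fusion gene).
#'
#' @param five_prime_gene,three_prime_gene Partner gene IDs (5' then 3').
#' @param five_prime_chrom,five_prime_pos 5' breakpoint.
#' @param three_prime_chrom,three_prime_pos 3' breakpoint.
#' @return Character vector of keys.
#' @export
isoform_key <- function(five_prime_gene, three_prime_gene,
                        five_prime_chrom, five_prime_pos,
                        three_prime_chrom, three_prime_pos) {
  if (any(five_prime_gene == three_prime_gene)) {
    abort("self-fusions (identical 5' and 3' gene) are rejected")
  }
  paste(
    five_prime_gene, three_prime_gene,
    paste0(five_prime_chrom, ":", format(five_prime_pos, scientific = FALSE, trim = TRUE)),
    paste0(three_prime_chrom, ":", format(three_prime_pos, scientific = FALSE, trim = TRUE)),
    sep = "|"
  )
}

#' Assemble fusion-junction records
#'
#' @inheritParams isoform_key
#' @param junction_sequence Optional nucleotide string spanning the junction.
#' @return Tibble with one row per junction, including `fusion_id`
#'   (gene-pair level, `5p-3p`) and `isoform_key`.
#' @export
fusion_junction <- function(five_prime_gene, three_prime_gene,
                            five_prime_chrom, five_prime_pos,
                            three_prime_chrom, three_prime_pos,
                            junction_sequence = NA_character_) {
  tibble::tibble(
    fusion_id = paste(five_prime_gene, three_prime_gene, sep = "-"),
    five_prime_gene = as.character(five_prime_gene),
    three_prime_gene = as.character(three_prime_gene),
    five_prime_chrom = as.character(five_prime_chrom),
    five_prime_pos = as.numeric(five_prime_pos),
    three_prime_chrom = as.character(three_prime_chrom),
    three_prime_pos = as.numeric(three_prime_pos),
    junction_sequence = as.character(junction_sequence),
    isoform_key = isoform_key(
      five_prime_gene, three_prime_gene,
      five_prime_chrom, five_prime_pos,
      three_prime_chrom, three_prime_pos
    )
  )
}

#' Classify fusion junctions as epigenetic or genomic
#'
#' The rule system. A junction is an epigenetic fusion gene (EFG) — a
#' readthrough cis-splicing product — iff its partner genes lie on the same
#' chromosome and strand, the 5' gene is transcriptionally upstream of the
#' 3' gene, and the intergenic gap between the gene bodies is at most
#' `gap_threshold` (boundary included). Everything else is GENOMIC with a
#' mechanism subtype:
#' * different chromosomes: `interchromosomal_translocation`
#' * same chromosome, opposite strands: `inversion`
#' * same chromosome and strand, transcriptional order reversed:
#'   `duplication_or_order_reversal`
#' * same chromosome and strand, correct order, gap above threshold:
#'   `distal_intrachromosomal`
#'
#' "Upstream" is strand-aware: on `+` the 5' gene body must not start
#' downstream of the 3' gene body; on `-` the mirror condition. Overlapping
#' same-strand genes in correct order (gap 0) are EFG. Neighbouring does not
#' mean adjacent: intervening genes are irrelevant, only the gap counts.
#'
#' @param junctions Tibble with columns `five_prime_gene`, `three_prime_gene`
#'   (e.g. from [fusion_junction()] or [read_fusion_calls()]).
#' @param annotation A [gene_model]; both partners of every junction must be
#'   present, otherwise an error naming the missing genes is raised.
#' @param gap_threshold Maximum readthrough gap in bp (default 200000).
#' @return The input with columns `category` (`"EFG"`/`"GENOMIC"`),
#'   `mechanism`, and `gap_bp` (`NA` across chromosomes) appended.
#' @export
classify_fusion <- function(junctions, annotation, gap_threshold = 200000) {
  stopifnot(is.numeric(gap_threshold), length(gap_threshold) == 1, gap_threshold >= 0)
  i5 <- gene_lookup(annotation, junctions$five_prime_gene)
  i3 <- gene_lookup(annotation, junctions$three_prime_gene)
  if (any(junctions$five_prime_gene == junctions$three_prime_gene)) {
    abort("self-fusions (identical 5' and 3' gene) are rejected")
  }
  a <- annotation[i5, ]
  b <- annotation[i3, ]
  gap <- intergenic_gap(a, b)

  same_chrom <- a$chrom == b$chrom
  same_strand <- a$strand == b$strand
  # transcriptionally upstream: 5' gene body not downstream of the 3' gene body
  upstream <- ifelse(a$strand == "+", a$start <= b$start, a$end >= b$end)

  mechanism <- dplyr::case_when(
    !same_chrom ~ "interchromosomal_translocation",
    !same_strand ~ "inversion",
    !upstream ~ "duplication_or_order_reversal",
    gap <= gap_threshold ~ "readthrough",
    TRUE ~ "distal_intrachromosomal"
  )
  dplyr::mutate(
    junctions,
    category = ifelse(mechanism == "readthrough", "EFG", "GENOMIC"),
    mechanism = mechanism,
    gap_bp = gap
  )
}

#' Aggregate junction isoforms to fusion genes
#'
#' The transcript-level unit is the junction isoform; the gene-level unit is
#' the partner pair. One fusion gene can express many isoforms.
#'
#' @param junctions Tibble with `five_prime_gene`, `three_prime_gene`,
#'   `isoform_key`.
#' @return Tibble with one row per gene pair: `fusion_gene`, `n_isoforms`,
#'   and a list-column `isoform_keys`.
#' @export
aggregate_to_fusion_genes <- function(junctions) {
  if (nrow(junctions) == 0) {
    return(tibble::tibble(
      fusion_gene = character(), n_isoforms = integer(),
      isoform_keys = list()
    ))
  }
  junctions |>
    dplyr::mutate(fusion_gene = paste(.data$five_prime_gene, .data$three_prime_gene, sep = "-")) |>
    dplyr::group_by(.data$fusion_gene) |>
    dplyr::summarise(
      n_isoforms = dplyr::n_distinct(.data$isoform_key),
      isoform_keys = list(sort(unique(.data$isoform_key)))
    ) |>
    dplyr::ungroup()
}

#' Write classified junctions to TSV
#'
#' Columns: `fusion_id`, `five_prime_gene`, `three_prime_gene`, `category`,
#' `mechanism`, `gap_bp`.
#'
#' @param classified Output of [classify_fusion()].
#' @param path Output path.
#' @export
write_classification <- function(classified, path) {
  readr::write_tsv(
    classified[, c(
      "fusion_id", "five_prime_gene", "three_prime_gene",
      "category", "mechanism", "gap_bp"
    )],
    path
  )
  invisible(path)
}
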