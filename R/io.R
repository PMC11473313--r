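#' Pipeline configuration
#'
#' Collects every tunable constant of the discovery procedure with its
#' default: two-sided significance level 0.01, recurrence filter of 5
#' patients, 200 kb readthrough gap threshold, per-individual somatic
#' fusion rate 3.6e-2 with coincidence count 5, probe anchor 10 bp and
#' flank 30 bp, and a zero-control fold pseudocount of 1.
#'
#' @param alpha Two-sided significance level.
#' @param min_count Recurrence filter (positive patients).
#' @param gap_threshold Readthrough gap threshold in bp.
#' @param somatic_rate,somatic_k Somatic-origin model parameters.
#' @param anchor,flank Junction-probe scanning parameters in bp.
#' @param zero_pseudocount Control pseudocount for zero-control folds.
#' @param seed Seed for any stochastic step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.01, min_count = 5, gap_threshold = 200000,
                            somatic_rate = 0.036, somatic_k = 5,
                            anchor = 10, flank = 30, zero_pseudocount = 1,
                            seed = 1L) {
  structure(
    list(
      alpha = alpha, min_count = min_count, gap_threshold = gap_threshold,
      somatic_rate = somatic_rate, somatic_k = somatic_k,
      anchor = anchor, flank = flank, zero_pseudocount = zero_pseudocount,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

call_columns_required <- c(
  "run_id", "patient_id", "cohort", "fusion_id",
  "five_prime_gene", "three_prime_gene",
  "five_prime_chrom", "five_prime_pos",
  "three_prime_chrom", "three_prime_pos"
)

#' Read a per-run fusion call table
#'
#' Tab-separated with a mandatory header. Required columns: `run_id`,
#' `patient_id`, `cohort`, `fusion_id`, `five_prime_gene`,
#' `three_prime_gene`, `five_prime_chrom`, `five_prime_pos`,
#' `three_prime_chrom`, `three_prime_pos`; `junction_sequence` is optional.
#' Coordinates are normalised to the package's 0-based convention on read.
#' Rows with missing required values are reported with their line numbers
#' and dropped, unless `strict = TRUE`, in which case they are an error.
#'
#' @param path TSV path.
#' @param coordinates `"0-based"` (native) or `"1-based"` (the 3' breakpoint
#'   start is shifted down by one on read).
#' @param strict Fail on malformed rows instead of dropping them.
#' @return Tibble of validated call records.
#' @export
read_fusion_calls <- function(path, coordinates = c("0-based", "1-based"),
                              strict = FALSE) {
  coordinates <- match.arg(coordinates)
  calls <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(call_columns_required, names(calls))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- !stats::complete.cases(calls[, call_columns_required])
  if (any(bad)) {
    msg <- paste0(
      sum(bad), " malformed row(s) at line(s): ",
      paste(head(which(bad) + 1L, 10), collapse = ", ")
    )
    if (strict) abort(msg)
    message("read_fusion_calls: dropping ", msg)
    calls <- calls[!bad, ]
  }
  if (coordinates == "1-based") {
    calls$three_prime_pos <- calls$three_prime_pos - 1L
  }
  calls
}

#' Write a per-run fusion call table
#'
#' @param calls Call tibble (see [read_fusion_calls()]).
#' @param path Output path.
#' @export
write_fusion_calls <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}

#' Read and write a cohort design table
#'
#' TSV with columns `run_id`, `patient_id`, `cohort`.
#'
#' @param path TSV path.
#' @return [cohort_design] tibble.
#' @export
read_cohort_design <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("run_id", "patient_id", "cohort"), names(d))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  cohort_design(d$run_id, d$patient_id, d$cohort)
}

#' @rdname read_cohort_design
#' @param design A [cohort_design].
#' @export
write_cohort_design <- function(design, path) {
  readr::write_tsv(design[, c("run_id", "patient_id", "cohort")], path)
  invisible(path)
}

#' Run the discovery pipeline end to end
#'
#' Classify every distinct junction isoform, collapse per-run calls to
#' unique patients, build the per-cohort recurrence table, test recurrent
#' fusions case against control, and summarise per category. The unit of
#' recurrence is the junction isoform (the `fusion_id` column of `calls`,
#' holding isoform keys when produced by [simulate_cohorts()]).
#'
#' @param calls Per-run call table (see [read_fusion_calls()]).
#' @param design A [cohort_design].
#' @param annotation A [gene_model].
#' @param config A [pipeline_config()].
#' @param out_dir If non-`NULL`, write `classification.tsv`,
#'   `association.tsv`, `presence_matrix.tsv` and `summary.tsv` there.
#' @return List: `classification`, `presence`, `recurrence`, `association`,
#'   `matrix`, `summary` (per-category counts and frequency means),
#'   `contribution` (genetic/environmental split, when both categories have
#'   significant positive fusions), `somatic` (coincidence probabilities at
#'   the configured rate for both cohort sizes).
#' @export
run_pipeline <- function(calls, design, annotation, config = pipeline_config(),
                         out_dir = NULL) {
  junctions <- calls |>
    dplyr::distinct(
      .data$fusion_id, .data$five_prime_gene, .data$three_prime_gene,
      .data$five_prime_chrom, .data$five_prime_pos,
      .data$three_prime_chrom, .data$three_prime_pos
    )
  classification <- classify_fusion(junctions, annotation, config$gap_threshold)
  categories <- setNames(classification$category, classification$fusion_id)

  presence <- collapse_runs_to_patients(calls, design)
  recurrence <- recurrence_table(presence, design)
  association <- associate(
    recurrence,
    alpha = config$alpha, min_count = config$min_count,
    zero_pseudocount = config$zero_pseudocount, categories = categories
  )
  m <- presence_matrix(presence, design,
    fusion_ids = association$fusion_id, cohort = "case"
  )

  sig_pos <- association[association$significant & association$direction == "positive", ]
  summary <- association |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      n_significant = sum(.data$significant),
      n_positive = sum(.data$significant & .data$direction == "positive"),
      n_negative = sum(.data$significant & .data$direction == "negative"),
      case_freq_min = min(.data$case_freq),
      case_freq_max = max(.data$case_freq),
      case_freq_mean = mean(.data$case_freq),
      control_freq_mean = mean(.data$control_freq),
      fold_mean = mean(.data$fold, na.rm = TRUE)
    ) |>
    dplyr::ungroup()

  contribution <- NULL
  ratios <- vapply(c("GENOMIC", "EFG"), function(cat) {
    rows <- sig_pos[!is.na(sig_pos$category) & sig_pos$category == cat, ]
    if (nrow(rows) == 0 || mean(rows$control_freq) == 0) {
      return(NA_real_)
    }
    mean(rows$case_freq) / mean(rows$control_freq)
  }, numeric(1))
  if (!anyNA(ratios)) {
    contribution <- contribution_split(ratios[["GENOMIC"]], ratios[["EFG"]])
  }
  sizes <- cohort_sizes(design)
  somatic <- dplyr::bind_rows(
    dplyr::mutate(
      somatic_origin_probability(config$somatic_rate, config$somatic_k, sizes[["case"]]),
      cohort = "case", .before = 1
    ),
    dplyr::mutate(
      somatic_origin_probability(config$somatic_rate, config$somatic_k, sizes[["control"]]),
      cohort = "control", .before = 1
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_classification(classification, file.path(out_dir, "classification.tsv"))
    readr::write_tsv(
      format_association(association, config$zero_pseudocount),
      file.path(out_dir, "association.tsv")
    )
    write_presence_matrix(m, file.path(out_dir, "presence_matrix.tsv"))
    readr::write_tsv(summary, file.path(out_dir, "summary.tsv"))
  }

  list(
    classification = classification, presence = presence,
    recurrence = recurrence, association = association, matrix = m,
    summary = summary, contribution = contribution, somatic = somatic
  )
}

#' Report-style association table
#'
#' Adds display columns rounded the way recurrence tables are
#' conventionally printed — percentages to two decimals, folds to one —
#' while keeping the exact machine columns.
#'
#' @param association An [associate()] result.
#' @param zero_pseudocount Unused here; kept so report provenance is
#'   explicit in the call.
#' @return The association tibble with `case_pct`, `control_pct`,
#'   `fold_display` columns appended.
#' @export
format_association <- function(association, zero_pseudocount = 1) {
  dplyr::mutate(
    association,
    case_pct = round(100 * .data$case_freq, 2),
    control_pct = round(100 * .data$control_freq, 2),
    fold_display = round(.data$fold, 1)
  )
}
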