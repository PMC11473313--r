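#' Build a cohort design
#'
#' Maps sequencing runs to patients and patients to cohorts. Cases may have
#' several runs (the study design this package emulates had three RNA-seq
#' runs per case patient); controls typically one.
#'
#' @param run_id Character vector of run identifiers (unique).
#' @param patient_id Patient owning each run.
#' @param cohort `"case"` or `"control"` per run; must be constant within a
#'   patient.
#' @return A tibble of class `cohort_design` with one row per run and
#'   attributes `n_case`, `n_control` (distinct patient counts).
#' @export
cohort_design <- function(run_id, patient_id, cohort) {
  run_id <- as.character(run_id)
  if (anyDuplicated(run_id)) {
    abort("run_id values must be unique (every run maps to exactly one patient)")
  }
  cohort <- as.character(cohort)
  if (!all(cohort %in% c("case", "control"))) {
    abort("cohort must be 'case' or 'control'")
  }
  design <- tibble::tibble(
    run_id = run_id,
    patient_id = as.character(patient_id),
    cohort = cohort
  )
  per_pat <- dplyr::distinct(design, .data$patient_id, .data$cohort)
  if (anyDuplicated(per_pat$patient_id)) {
    abort("a patient appears in both cohorts; cohorts must be disjoint")
  }
  attr(design, "n_case") <- sum(per_pat$cohort == "case")
  attr(design, "n_control") <- sum(per_pat$cohort == "control")
  class(design) <- c("cohort_design", class(design))
  design
}

#' Cohort sizes of a design
#'
#' @param design A [cohort_design].
#' @return Named vector `c(case = n_case, control = n_control)` of distinct
#'   patient counts.
#' @export
cohort_sizes <- function(design) {
  c(case = attr(design, "n_case"), control = attr(design, "n_control"))
}

#' Collapse per-run fusion calls to per-patient presence
#'
#' The unit of recurrence is the unique patient, not the sequencing run: a
#' patient is positive for a fusion iff at least one of its runs contains
#' it. Duplicated run-level records change nothing (idempotent), so a fusion
#' seen in five runs of one patient still counts one patient.
#'
#' @param calls Tibble with columns `run_id` and `fusion_id` (extra columns
#'   ignored). `fusion_id` here is whatever unit recurrence should be
#'   counted at — pass `isoform_key` values to count transcript isoforms.
#' @param design A [cohort_design]; every `run_id` in `calls` must appear in
#'   it, otherwise an error lists the offending IDs.
#' @return Tibble `patient_id`, `cohort`, `fusion_id`, one row per positive
#'   (patient, fusion) pair. Patients with no calls are retained in the
#'   design and simply have no rows here.
#' @export
collapse_runs_to_patients <- function(calls, design) {
  unknown <- setdiff(unique(calls$run_id), design$run_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "run ID(s) absent from cohort design: ",
      paste(unknown, collapse = ", ")
    ))
  }
  # the design is authoritative for patient/cohort membership
  calls[setdiff(names(calls), c("patient_id", "cohort"))] |>
    dplyr::inner_join(
      design[, c("run_id", "patient_id", "cohort")],
      by = "run_id"
    ) |>
    dplyr::distinct(.data$patient_id, .data$cohort, .data$fusion_id) |>
    dplyr::arrange(.data$patient_id, .data$fusion_id)
}

#' Per-cohort recurrence table
#'
#' For each fusion and each cohort: the number of distinct positive patients
#' and the exact recurrence frequency `positive_patients / cohort_size`.
#' Fusions absent from one cohort get an explicit zero row there.
#'
#' @param presence Output of [collapse_runs_to_patients()].
#' @param design A [cohort_design].
#' @return Tibble `fusion_id`, `cohort`, `positive_patients`, `cohort_size`,
#'   `frequency`.
#' @export
recurrence_table <- function(presence, design) {
  sizes <- cohort_sizes(design)
  fusions <- sort(unique(presence$fusion_id))
  grid <- tidyr_expand_grid(fusions, c("case", "control"))
  counts <- presence |>
    dplyr::count(.data$fusion_id, .data$cohort, name = "positive_patients")
  grid |>
    dplyr::left_join(counts, by = c("fusion_id", "cohort")) |>
    dplyr::mutate(
      positive_patients = ifelse(is.na(.data$positive_patients), 0L,
        .data$positive_patients
      ),
      cohort_size = unname(sizes[.data$cohort]),
      frequency = .data$positive_patients / .data$cohort_size
    )
}

# expand.grid with deterministic ordering and tibble output; avoids pulling
# tidyr in for one call
tidyr_expand_grid <- function(fusions, cohorts) {
  tibble::tibble(
    fusion_id = rep(fusions, each = length(cohorts)),
    cohort = rep(cohorts, times = length(fusions))
  )
}

#' Recurrence filter (n·p >= min_count)
#'
#' Retains fusions with at least `min_count` positive patients in the named
#' cohort — the discovery filter that makes the downstream Z-test honest
#' (the normal approximation needs expected counts of ~5). Boundary
#' inclusive: exactly `min_count` survives.
#'
#' @param records A [recurrence_table()] output.
#' @param min_count Minimum positive patients (default 5).
#' @param cohort Which cohort's count gates the filter.
#' @return Character vector of surviving `fusion_id`s, sorted by descending
#'   count then fusion_id.
#' @export
filter_recurrent <- function(records, min_count = 5, cohort = c("case", "control")) {
  stopifnot(min_count >= 1)
  cohort <- match.arg(cohort)
  kept <- records[records$cohort == cohort & records$positive_patients >= min_count, ]
  kept <- kept[order(-kept$positive_patients, kept$fusion_id), ]
  kept$fusion_id
}

#' Critical value of the two-sided Z-test
#'
#' Upper `alpha/2` quantile of the standard normal: 2.576 at `alpha = 0.01`.
#'
#' @param alpha Two-sided significance level in (0, 1).
#' @return The critical value.
#' @export
critical_z <- function(alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    abort("alpha must lie strictly between 0 and 1")
  }
  qnorm(1 - alpha / 2)
}

#' Pooled two-proportion Z-test
#'
#' `z = (x1/n1 - x2/n2) / sqrt(p(1-p)(1/n1 + 1/n2))` with pooled
#' `p = (x1+x2)/(n1+n2)`; two-sided p-value from the normal tail; no
#' continuity correction. Degenerate tables (pooled p of 0 or 1) return
#' `z = 0, p = 1`. Vectorised.
#'
#' @param x1,n1 Case positives and case cohort size.
#' @param x2,n2 Control positives and control cohort size.
#' @return Tibble with columns `z` and `p_value`.
#' @export
#' @examples
#' two_proportion_ztest(107, 122, 54, 252) # z ~ 12.14
two_proportion_ztest <- function(x1, n1, x2, n2) {
  if (any(n1 <= 0) || any(n2 <= 0)) abort("cohort sizes must be positive")
  if (any(x1 < 0) || any(x2 < 0) || any(x1 > n1) || any(x2 > n2)) {
    abort("counts must satisfy 0 <= x <= n")
  }
  pooled <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- ifelse(se == 0, 0, (x1 / n1 - x2 / n2) / se)
  tibble::tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Case/control fold enrichment
#'
#' Ratio of recurrence frequencies `(x1/n1) / (x2/n2)`. A zero control count
#' is replaced by `zero_pseudocount` positives so the fold stays finite
#' (e.g. 18/122 cases vs 0/252 controls with pseudocount 1 gives 37.2).
#' Both counts zero is undefined and returns `NA`. Vectorised.
#'
#' @inheritParams two_proportion_ztest
#' @param zero_pseudocount Control positives substituted when `x2 == 0`.
#' @return Numeric fold.
#' @export
fold_enrichment <- function(x1, n1, x2, n2, zero_pseudocount = 1) {
  if (any(n1 <= 0) || any(n2 <= 0)) abort("cohort sizes must be positive")
  x2_eff <- ifelse(x2 == 0, zero_pseudocount, x2)
  fold <- (x1 / n1) / (x2_eff / n2)
  fold[x1 == 0 & x2 == 0] <- NA_real_
  fold
}

#' Case-control association of recurrent fusions
#'
#' The full statistical procedure: a fusion enters testing if it has at
#' least `min_count` positive patients in either cohort; each tested fusion
#' gets the pooled two-proportion Z statistic, two-sided p-value, fold
#' enrichment, direction (sign of the frequency difference) and a
#' significance flag at `|z| >= critical_z(alpha)`. No multiple-testing
#' correction is applied in this mode; a Benjamini-Hochberg column is
#' appended for reference but never gates significance.
#'
#' @param records A [recurrence_table()] output covering both cohorts.
#' @param alpha Two-sided significance level (default 0.01).
#' @param min_count Recurrence filter threshold (default 5).
#' @param zero_pseudocount See [fold_enrichment()].
#' @param categories Optional named character vector mapping `fusion_id` to
#'   `"EFG"`/`"GENOMIC"` so results can be summarised per class.
#' @return Tibble, one row per tested fusion: counts, frequencies, `fold`,
#'   `z`, `p_value`, `p_adj_bh`, `direction`, `significant`, `category`.
#' @export
associate <- function(records, alpha = 0.01, min_count = 5,
                      zero_pseudocount = 1, categories = NULL) {
  if (nrow(records) == 0) abort("no recurrence records: empty cohorts")
  wide <- records |>
    dplyr::select("fusion_id", "cohort", "positive_patients", "cohort_size") |>
    tidyr_pivot_counts()
  if (any(wide$n_case == 0) || any(wide$n_control == 0)) {
    abort("both cohorts must be non-empty")
  }
  tested <- wide[wide$x_case >= min_count | wide$x_control >= min_count, ]
  zt <- two_proportion_ztest(tested$x_case, tested$n_case, tested$x_control, tested$n_control)
  out <- tibble::tibble(
    fusion_id = tested$fusion_id,
    case_count = tested$x_case,
    case_freq = tested$x_case / tested$n_case,
    control_count = tested$x_control,
    control_freq = tested$x_control / tested$n_control,
    z = zt$z,
    p_value = zt$p_value,
    fold = fold_enrichment(
      tested$x_case, tested$n_case, tested$x_control, tested$n_control,
      zero_pseudocount
    ),
    direction = ifelse(case_freq > control_freq, "positive", "negative"),
    significant = abs(zt$z) >= critical_z(alpha)
  )
  out$p_adj_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$category <- if (is.null(categories)) {
    NA_character_
  } else {
    unname(categories[out$fusion_id])
  }
  dplyr::arrange(out, dplyr::desc(.data$case_count), .data$fusion_id)
}

tidyr_pivot_counts <- function(records) {
  case <- records[records$cohort == "case", ]
  control <- records[records$cohort == "control", ]
  merged <- dplyr::full_join(
    dplyr::rename(case, x_case = "positive_patients", n_case = "cohort_size")[
      , c("fusion_id", "x_case", "n_case")
    ],
    dplyr::rename(control, x_control = "positive_patients", n_control = "cohort_size")[
      , c("fusion_id", "x_control", "n_control")
    ],
    by = "fusion_id"
  )
  merged$x_case[is.na(merged$x_case)] <- 0L
  merged$x_control[is.na(merged$x_control)] <- 0L
  n_case <- max(c(merged$n_case, 0), na.rm = TRUE)
  n_control <- max(c(merged$n_control, 0), na.rm = TRUE)
  merged$n_case[is.na(merged$n_case)] <- n_case
  merged$n_control[is.na(merged$n_control)] <- n_control
  merged
}

#' Cohort-scale discovery summary
#'
#' The headline arithmetic of a discovery run: average fusion transcripts
#' per patient and the share of transcripts surviving the recurrence
#' filter. E.g. 138,000 transcripts over 122 patients average 1,131 per
#' patient, of which 814 recurrent transcripts are 0.59%.
#'
#' @param total_transcripts Total fusion transcripts discovered in the
#'   cohort.
#' @param n_patients Patients in the cohort.
#' @param n_recurrent Transcripts surviving the recurrence filter.
#' @return Tibble `per_patient_average`, `recurrent_percent`.
#' @export
cohort_scale_summary <- function(total_transcripts, n_patients, n_recurrent) {
  if (any(n_patients <= 0) || any(total_transcripts < 0)) {
    abort("counts must be non-negative and n_patients positive")
  }
  tibble::tibble(
    per_patient_average = total_transcripts / n_patients,
    recurrent_percent = 100 * n_recurrent / total_transcripts
  )
}

#' Probability that recurrent identical fusions arise somatically
#'
#' If structural variants create a given fusion somatically at rate `rate`
#' per individual, the probability that `k` individuals independently
#' acquire the identical fusion is `rate^k`; over a cohort of `n` patients
#' the expected number of such coincidences is `n * rate^k`. With the
#' literature rate 3.6e-2 and k = 5, the coincidence probability is ~6e-8 —
#' the argument that five-patient recurrence in non-cancerous tissue implies
#' germline origin.
#'
#' @param rate Per-individual somatic fusion rate, in (0, 1).
#' @param k Number of individuals sharing the identical fusion (>= 1).
#' @param n Cohort size (optional; `NA` expected value if missing).
#' @return Tibble `coincidence_probability`, `expected_per_cohort`.
#' @export
somatic_origin_probability <- function(rate = 0.036, k = 5, n = NA) {
  if (!is.numeric(rate) || any(rate <= 0) || any(rate >= 1)) {
    abort("rate must lie strictly between 0 and 1")
  }
  if (any(k < 1)) abort("k must be >= 1")
  p <- rate^k
  tibble::tibble(
    coincidence_probability = p,
    expected_per_cohort = n * p
  )
}

#' Genetic vs environmental contribution split
#'
#' Apportions disease contribution between germline (HFG) and epigenetic
#' (EFG) fusion classes from the ratio of their case-vs-control
#' mean-frequency folds: `r = hfg/efg`, genetic share `100 r/(r+1)`,
#' environmental share the complement. Shares always sum to 100.
#'
#' @param hfg_fold_ratio,efg_fold_ratio Positive fold ratios.
#' @return Tibble `genetic_percent`, `environmental_percent`.
#' @export
contribution_split <- function(hfg_fold_ratio, efg_fold_ratio) {
  if (any(hfg_fold_ratio <= 0) || any(efg_fold_ratio <= 0)) {
    abort("fold ratios must be positive")
  }
  r <- hfg_fold_ratio / efg_fold_ratio
  genetic <- 100 * r / (r + 1)
  tibble::tibble(
    genetic_percent = genetic,
    environmental_percent = 100 - genetic
  )
}

#' Per-patient fusion burden
#'
#' Number of distinct positive fusion transcripts per patient, optionally
#' restricted to one class, with cohort summary statistics. Patients with
#' no positive fusions count 0.
#'
#' @param presence Output of [collapse_runs_to_patients()].
#' @param design A [cohort_design].
#' @param categories Optional named vector `fusion_id -> category`; with
#'   `class_filter`, restricts the burden to that class.
#' @param class_filter `"EFG"` or `"GENOMIC"`, or `NULL` for all.
#' @return List with `per_patient` (tibble `patient_id`, `cohort`, `burden`)
#'   and `summary` (tibble per cohort: `min`, `max`, `mean`).
#' @export
burden_per_sample <- function(presence, design, categories = NULL, class_filter = NULL) {
  if (!is.null(class_filter)) {
    if (is.null(categories)) abort("class_filter requires categories")
    keep <- names(categories)[categories == class_filter]
    presence <- presence[presence$fusion_id %in% keep, ]
  }
  patients <- dplyr::distinct(design, .data$patient_id, .data$cohort)
  per_patient <- presence |>
    dplyr::count(.data$patient_id, name = "burden") |>
    dplyr::right_join(patients, by = "patient_id") |>
    dplyr::mutate(burden = ifelse(is.na(.data$burden), 0L, .data$burden)) |>
    dplyr::arrange(.data$patient_id) |>
    dplyr::select("patient_id", "cohort", "burden")
  summary <- per_patient |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(
      min = min(.data$burden), max = max(.data$burden),
      mean = mean(.data$burden)
    ) |>
    dplyr::ungroup()
  list(per_patient = per_patient, summary = summary)
}

#' Binary patient-by-fusion presence matrix
#'
#' Entry 1 iff the patient is positive for the fusion. Rows (patients)
#' ordered by ID; columns (fusions) by descending case recurrence count,
#' ties by fusion_id — the deterministic layout exported for external
#' heatmap/clustering tools.
#'
#' @param presence Output of [collapse_runs_to_patients()].
#' @param design A [cohort_design].
#' @param fusion_ids Fusions to include (columns); defaults to all present.
#' @param cohort Restrict rows to one cohort, or `NULL` for all patients.
#' @return Integer matrix with dimnames.
#' @export
presence_matrix <- function(presence, design, fusion_ids = NULL, cohort = NULL) {
  patients <- dplyr::distinct(design, .data$patient_id, .data$cohort)
  if (!is.null(cohort)) patients <- patients[patients$cohort == cohort, ]
  if (is.null(fusion_ids)) fusion_ids <- unique(presence$fusion_id)
  case_patients <- patients$patient_id[patients$cohort == "case"]
  case_counts <- vapply(fusion_ids, function(f) {
    sum(presence$fusion_id == f & presence$patient_id %in% case_patients)
  }, integer(1))
  fusion_ids <- fusion_ids[order(-case_counts, fusion_ids)]
  rows <- sort(patients$patient_id)
  m <- matrix(0L, nrow = length(rows), ncol = length(fusion_ids),
    dimnames = list(rows, fusion_ids)
  )
  hit <- presence[presence$patient_id %in% rows & presence$fusion_id %in% fusion_ids, ]
  if (nrow(hit) > 0) {
    m[cbind(match(hit$patient_id, rows), match(hit$fusion_id, fusion_ids))] <- 1L
  }
  m
}

#' Write a presence matrix as TSV
#'
#' First column `patient_id`, then one column per fusion — the layout
#' external heatmap tools (e.g. Morpheus) ingest directly.
#'
#' @param m Output of [presence_matrix()].
#' @param path Output path.
#' @export
write_presence_matrix <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "patient_id")
  readr::write_tsv(df, path)
  invisible(path)
}
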