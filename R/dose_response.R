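# Dose-response assembly: per-condition summaries, the worst-control
# comparison rule, and dosimetry arithmetic.

# Direction of "better" for each summary metric.
.METRIC_HIGHER_BETTER <- c(reads = TRUE, pct_aligned = TRUE,
                           base_identity = TRUE, mean_read_length = TRUE,
                           skips_per_base = FALSE, stays_per_base = FALSE)

#' Summarize one condition into a report row
#'
#' Combines the per-stage outputs for a single run into the standard
#' per-condition summary: read count, percent of reads aligned, base
#' identity, mean read length, skips and stays per base, coverage
#' completeness and (optionally) the active pore count. A zero-read run
#' yields `reads = 0` with every quality field absent (`NA`), the way failed
#' high-dose runs are reported.
#'
#' @param bundle The `run_bundle` the other inputs were computed from.
#' @param metrics Per-read metrics from [bundle_metrics()].
#' @param alignments Alignment rows from [align_reads()].
#' @param coverage A [coverage_map()].
#' @param qc Optional [platform_qc()] result.
#' @return A one-row data frame (`metric_summary`).
#' @export
summarize_condition <- function(bundle, metrics = NULL, alignments = NULL,
                                coverage = NULL, qc = NULL) {
  stopifnot(inherits(bundle, "run_bundle"))
  active <- if (!is.null(qc)) qc$active_count else NA_integer_
  if (length(bundle$reads) == 0L) {
    return(data.frame(condition = bundle$condition,
                      dose_gray = bundle$dose_gray, reads = 0L,
                      pct_aligned = NA_real_, base_identity = NA_real_,
                      mean_read_length = NA_real_, skips_per_base = NA_real_,
                      stays_per_base = NA_real_, complete_coverage = NA,
                      active_pores = active, stringsAsFactors = FALSE))
  }
  if (is.null(metrics) || is.null(alignments) || is.null(coverage)) {
    stop("`metrics`, `alignments` and `coverage` are required for a run with reads")
  }
  ids <- vapply(bundle$reads, function(r) r$read_id, character(1))
  if (!setequal(ids, metrics$read_id) || !setequal(ids, alignments$read_id)) {
    stop("read_id sets of bundle, metrics and alignments do not match")
  }
  pooled <- pool_metrics(metrics)
  aln <- summarize_alignments(alignments)
  data.frame(condition = bundle$condition, dose_gray = bundle$dose_gray,
             reads = pooled$reads, pct_aligned = aln$pct_reads_aligned,
             base_identity = aln$mean_identity,
             mean_read_length = pooled$mean_read_length,
             skips_per_base = pooled$skips_per_base,
             stays_per_base = pooled$stays_per_base,
             complete_coverage = coverage$complete,
             active_pores = active, stringsAsFactors = FALSE)
}

#' Worst-control envelope
#'
#' For each metric, records the worst value among the control summaries:
#' the minimum for higher-is-better metrics (reads, percent aligned, base
#' identity, mean read length) and the maximum for lower-is-better metrics
#' (skips and stays per base). Controls that produced no reads are excluded.
#'
#' @param controls A data frame of control [summarize_condition()] rows
#'   (at least one with reads).
#' @return A `control_envelope`: named list of
#'   `list(worst = value, higher_better = flag)`.
#' @export
control_envelope <- function(controls) {
  controls <- controls[controls$reads > 0L, , drop = FALSE]
  if (nrow(controls) == 0L) {
    stop("the control envelope needs at least one control that produced reads")
  }
  env <- lapply(names(.METRIC_HIGHER_BETTER), function(m) {
    v <- controls[[m]]
    v <- v[!is.na(v)]
    list(worst = if (.METRIC_HIGHER_BETTER[[m]]) min(v) else max(v),
         higher_better = .METRIC_HIGHER_BETTER[[m]])
  })
  names(env) <- names(.METRIC_HIGHER_BETTER)
  structure(env, class = "control_envelope")
}

#' Flag a summary against the worst-performing control
#'
#' A metric is flagged only when it is strictly worse than the worst control
#' in that metric's direction; equalling the worst control is not a drop.
#'
#' @param summary A one-row [summarize_condition()] data frame.
#' @param envelope A [control_envelope()].
#' @return Named logical vector (one element per metric; `NA` where the
#'   summary value is absent).
#' @export
flag_vs_controls <- function(summary, envelope) {
  stopifnot(inherits(envelope, "control_envelope"))
  vapply(names(envelope), function(m) {
    if (!m %in% names(summary)) stop("unknown metric: ", m)
    v <- summary[[m]][1L]
    if (is.na(v)) return(NA)
    if (envelope[[m]]$higher_better) v < envelope[[m]]$worst
    else v > envelope[[m]]$worst
  }, logical(1))
}

#' Assemble a dose table
#'
#' Binds per-condition summaries into a dose-sorted table and flags each
#' read-producing non-control row whose metric falls strictly below (in the
#' metric's direction) the worst-performing control. By default controls are
#' the unirradiated (dose 0) rows. Zero-read conditions are kept as rows but
#' excluded from flagging (their quality fields are absent).
#'
#' @param summaries A data frame of [summarize_condition()] rows.
#' @param controls Logical vector marking control rows; defaults to
#'   `dose_gray == 0`.
#' @return A `dose_table` data frame: the summaries plus `is_control` and one
#'   `flag_<metric>` column per metric, with the envelope stored as an
#'   attribute.
#' @export
dose_table <- function(summaries, controls = summaries$dose_gray == 0) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1L)
  env <- control_envelope(summaries[controls, , drop = FALSE])
  o <- order(summaries$dose_gray)
  tab <- summaries[o, , drop = FALSE]
  is_control <- controls[o]
  flags <- t(vapply(seq_len(nrow(tab)), function(i) {
    if (is_control[i] || tab$reads[i] == 0L) {
      rep(NA, length(.METRIC_HIGHER_BETTER))
    } else {
      flag_vs_controls(tab[i, , drop = FALSE], env)
    }
  }, logical(length(.METRIC_HIGHER_BETTER))))
  colnames(flags) <- paste0("flag_", names(.METRIC_HIGHER_BETTER))
  out <- cbind(tab, is_control = is_control, as.data.frame(flags))
  rownames(out) <- NULL
  attr(out, "envelope") <- env
  class(out) <- c("dose_table", "data.frame")
  out
}

#' @export
print.dose_table <- function(x, digits = 4, ...) {
  cat("<dose_table> per-condition sequencing summaries vs worst control\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Convert an exposure in roentgen to absorbed dose in gray(Si)
#'
#' @param exposure_R Exposure in roentgen (>= 0).
#' @param factor Equivalence factor in gray(Si) per roentgen; the default is
#'   the photon-energy-dependent value used for ~1.25 MeV gamma dosimetry in
#'   silicon.
#' @return Dose in gray(Si).
#' @export
exposure_to_dose <- function(exposure_R, factor = 0.008656) {
  if (any(exposure_R < 0)) stop("`exposure_R` must be non-negative")
  if (any(factor < 0)) stop("`factor` must be non-negative")
  exposure_R * factor
}

#' Accumulated dose from a constant dose rate
#'
#' @param rate_gray_per_min Dose rate in gray per minute (>= 0).
#' @param minutes Irradiation time in minutes (>= 0).
#' @return Dose in gray.
#' @export
accumulated_dose <- function(rate_gray_per_min, minutes) {
  if (any(rate_gray_per_min < 0)) stop("`rate_gray_per_min` must be non-negative")
  if (any(minutes < 0)) stop("`minutes` must be non-negative")
  rate_gray_per_min * minutes
}

#' Mission transit dose
#'
#' Total absorbed dose in gray for a transit at a constant daily dose,
#' e.g. the ~332 microgray/day measured in a silicon detector en route to
#' Mars, accumulated over a 180-day flight.
#'
#' @param daily_dose_microgray Daily dose in microgray (>= 0).
#' @param days Transit duration in days (>= 0).
#' @return Dose in gray.
#' @examples
#' mission_dose(332, 180)  # < 0.1 gray
#' @export
mission_dose <- function(daily_dose_microgray, days) {
  if (any(daily_dose_microgray < 0)) stop("`daily_dose_microgray` must be non-negative")
  if (any(days < 0)) stop("`days` must be non-negative")
  daily_dose_microgray * days * 1e-6
}
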