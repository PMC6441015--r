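#' Classify wells as active from open-pore current statistics
#'
#' Emulates the platform quality control: a potential is applied and a well
#' counts as active when its open-pore current falls inside a rectangular
#' window and its current noise is at or below a cap. Both interval ends are
#' inclusive (boundary values count as active). The vendor's actual
#' classifier is proprietary; this rectangular rule is the simplest
#' configurable stand-in with the same interface. Counts are per well.
#'
#' @param observations Data frame with columns `well`, `open_pore_pA`,
#'   `noise_pA` (the wells table emitted by [simulate_run()] qualifies).
#' @param current_window Numeric `(low, high)` in pA, low < high. Default
#'   180-280 pA.
#' @param max_noise_pA Maximum tolerated current standard deviation (default
#'   15 pA).
#' @return A `qc_result`: `active_count` and `per_well` (named logical).
#' @export
classify_wells <- function(observations, current_window = c(180, 280),
                           max_noise_pA = 15) {
  req <- c("well", "open_pore_pA", "noise_pA")
  miss <- setdiff(req, names(observations))
  if (length(miss) > 0L) {
    stop("observations lack column(s): ", paste(miss, collapse = ", "))
  }
  if (length(current_window) != 2L || current_window[1] >= current_window[2]) {
    stop("`current_window` must be (low, high) with low < high")
  }
  if (any(observations$noise_pA < 0)) stop("`noise_pA` must be non-negative")
  active <- observations$open_pore_pA >= current_window[1] &
    observations$open_pore_pA <= current_window[2] &
    observations$noise_pA <= max_noise_pA
  names(active) <- as.character(observations$well)
  structure(list(active_count = sum(active), per_well = active),
            class = "qc_result")
}

#' Plan the MUX rotation of monitored wells
#'
#' Wells are partitioned into `ceiling(n_wells / n_channels)` rotation groups
#' of consecutive wells; MUX period `p` monitors the active wells of group
#' `(p - 1) mod n_groups`. A run of `run_hours` hours has
#' `ceiling(run_hours / mux_interval_hours)` periods; each monitored set can
#' never exceed `n_channels` wells.
#'
#' @param per_well Named logical map of well activity (from
#'   [classify_wells()] or a bundle's `well_alive`).
#' @param n_channels Wells monitored simultaneously (default 512).
#' @param mux_interval_hours Hours between MUX changes (default 8).
#' @param run_hours Run duration in hours.
#' @return A list with one integer vector of monitored well ids per period.
#' @examples
#' mux_plan(setNames(rep(TRUE, 2048), 1:2048), run_hours = 24)
#' @export
mux_plan <- function(per_well, n_channels = 512, mux_interval_hours = 8,
                     run_hours = 24) {
  if (run_hours <= 0) stop("`run_hours` must be positive")
  n_wells <- length(per_well)
  n_groups <- ceiling(n_wells / n_channels)
  n_periods <- ceiling(run_hours / mux_interval_hours)
  wells <- seq_len(n_wells)
  lapply(seq_len(n_periods), function(p) {
    g <- (p - 1L) %% n_groups
    gw <- wells[wells > g * n_channels & wells <= (g + 1L) * n_channels]
    gw[per_well[gw]]
  })
}

#' Platform QC of a simulated run
#'
#' Classifies the bundle's well observations and attaches the MUX monitoring
#' plan, mirroring the shape of a platform-QC report (active pore count plus
#' per-period monitored groups).
#'
#' @param bundle A `run_bundle`.
#' @param current_window,max_noise_pA Passed to [classify_wells()].
#' @return A `qc_result` with `active_count`, `per_well` and
#'   `monitored_groups`.
#' @export
platform_qc <- function(bundle, current_window = c(180, 280),
                        max_noise_pA = 15) {
  stopifnot(inherits(bundle, "run_bundle"))
  qc <- classify_wells(bundle$wells, current_window, max_noise_pA)
  qc$monitored_groups <- mux_plan(
    qc$per_well, n_channels = bundle$config$n_channels,
    mux_interval_hours = bundle$config$mux_interval_hours,
    run_hours = bundle$config$run_hours)
  qc
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d of %d wells active\n",
              x$active_count, length(x$per_well)))
  if (!is.null(x$monitored_groups)) {
    sizes <- vapply(x$monitored_groups, length, integer(1))
    cat(sprintf("  %d MUX period(s), monitored: %s\n", length(sizes),
                paste(sizes, collapse = ", ")))
  }
  invisible(x)
}
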