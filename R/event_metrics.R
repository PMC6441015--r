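#' Per-read event-level quality metrics
#'
#' Computes the event-level statistics used to assess read quality: the read
#' length implied by the move stream (`k + sum(moves)`), the number of stays
#' (events after the first with move 0: extra dwells on the same k-mer) and
#' skips (`sum(max(move - 1, 0))`: k-mers that produced no event), each also
#' normalized per called base.
#'
#' @param read A simulated read from [simulate_run()] (a list carrying an
#'   `events` data frame) or an event table itself: a data frame with at least
#'   a `move` column, ordered by time, whose first move is 0.
#' @param k K-mer length of the detector model. Taken from the `kmer` column
#'   when present; required otherwise.
#' @return A one-row data frame: `read_id`, `n_events`, `read_length`,
#'   `n_skips`, `n_stays`, `skips_per_base`, `stays_per_base`,
#'   `mean_event_pA`.
#' @examples
#' ev <- data.frame(mean_pA = 100, start_s = 1:6 / 10, dur_s = 0.1,
#'                  move = c(0L, 1L, 1L, 0L, 2L, 1L),
#'                  kmer = strrep("A", 5))
#' read_metrics(ev)
#' @export
read_metrics <- function(read, k = NULL) {
  read_id <- NA_character_
  events <- read
  if (!is.data.frame(read)) {
    if (is.null(read$events)) stop("`read` has no event table")
    events <- read$events
    read_id <- read$read_id %||% NA_character_
  }
  if (!"move" %in% names(events)) stop("event table lacks a `move` column")
  if (nrow(events) == 0L) stop("empty event list")
  moves <- events$move
  if (moves[1L] != 0L) {
    stop("malformed read: first event must have move 0 (it sets the initial k-mer)")
  }
  if (any(moves < 0L)) stop("malformed read: negative move value")
  if (is.null(k)) {
    if (!"kmer" %in% names(events)) stop("`k` is required when events lack a `kmer` column")
    k <- nchar(events$kmer[1L])
  }
  read_length <- k + sum(moves)
  n_stays <- sum(moves[-1L] == 0L)
  n_skips <- sum(pmax(moves - 1L, 0L))
  data.frame(
    read_id = read_id, n_events = nrow(events), read_length = read_length,
    n_skips = n_skips, n_stays = n_stays,
    skips_per_base = n_skips / read_length,
    stays_per_base = n_stays / read_length,
    mean_event_pA = if ("mean_pA" %in% names(events)) mean(events$mean_pA) else NA_real_)
}

#' Event metrics for every read of a bundle
#'
#' @param bundle A `run_bundle` from [simulate_run()] or [read_bundle()].
#' @return A data frame with one [read_metrics()] row per read (zero rows for
#'   an empty bundle).
#' @export
bundle_metrics <- function(bundle) {
  stopifnot(inherits(bundle, "run_bundle"))
  if (length(bundle$reads) == 0L) {
    return(data.frame(read_id = character(0), n_events = integer(0),
                      read_length = integer(0), n_skips = integer(0),
                      n_stays = integer(0), skips_per_base = numeric(0),
                      stays_per_base = numeric(0), mean_event_pA = numeric(0)))
  }
  as.data.frame(data.table::rbindlist(
    lapply(bundle$reads, read_metrics, k = bundle$k)))
}

#' Pool per-read metrics into condition-level rates
#'
#' The default pooling is base-weighted: total skip (stay) count divided by
#' total called bases, which is robust to short reads. The per-read mean of
#' the individual ratios is available as an alternative for comparison.
#'
#' @param per_read A data frame of [read_metrics()] rows (possibly empty).
#' @param method `"pooled"` (base-weighted totals, default) or
#'   `"per_read_mean"` (unweighted mean of per-read ratios).
#' @return A list: `reads`, `mean_read_length`, `skips_per_base`,
#'   `stays_per_base`. For an empty input the count is 0 and the rates are
#'   `NA` (absent, not zero).
#' @export
pool_metrics <- function(per_read, method = c("pooled", "per_read_mean")) {
  method <- match.arg(method)
  n <- nrow(per_read)
  if (n == 0L) {
    return(list(reads = 0L, mean_read_length = NA_real_,
                skips_per_base = NA_real_, stays_per_base = NA_real_))
  }
  if (method == "pooled") {
    tot <- sum(per_read$read_length)
    list(reads = n, mean_read_length = mean(per_read$read_length),
         skips_per_base = sum(per_read$n_skips) / tot,
         stays_per_base = sum(per_read$n_stays) / tot)
  } else {
    list(reads = n, mean_read_length = mean(per_read$read_length),
         skips_per_base = mean(per_read$skips_per_base),
         stays_per_base = mean(per_read$stays_per_base))
  }
}

#' Time-chunked metric series for a run
#'
#' Assigns reads to fixed-width time chunks by start time, pools metrics per
#' chunk, and reports when the run stopped producing reads and whether that
#' stop coincides with a MUX-change boundary (the 8-hourly rotation of the
#' monitored pore set), the signature of a flow cell that dies at a MUX
#' change.
#'
#' @param bundle A `run_bundle`.
#' @param per_read Per-read metrics, defaults to `bundle_metrics(bundle)`.
#' @param chunk_minutes Chunk width in minutes (default 10, resolving the
#'   8-hour MUX period into 48 points).
#' @return A `chunk_series`: `chunk_minutes`, `chunks` (data frame with
#'   `t_start_s`, `n_reads`, `skips_per_base`, `stays_per_base`,
#'   `mean_read_length`, `median_event_pA`), `stop_time_s` and
#'   `stopped_at_mux_boundary`. Chunks tile `[0, run_hours]` exactly and
#'   their read counts sum to the bundle total.
#' @export
time_chunks <- function(bundle, per_read = bundle_metrics(bundle),
                        chunk_minutes = 10) {
  stopifnot(inherits(bundle, "run_bundle"))
  if (!is.numeric(chunk_minutes) || chunk_minutes <= 0) {
    stop("`chunk_minutes` must be positive")
  }
  width <- chunk_minutes * 60
  total_s <- bundle$config$run_hours * 3600
  n_chunks <- as.integer(ceiling(total_s / width))
  starts <- vapply(bundle$reads, function(r) r$start_time_s, numeric(1))
  if (length(starts) > 0 && (any(starts < 0) || any(starts > total_s))) {
    stop("read start times fall outside the run duration")
  }
  idx <- pmin(as.integer(starts %/% width) + 1L, n_chunks)

  chunks <- data.frame(t_start_s = (seq_len(n_chunks) - 1L) * width,
                       n_reads = 0L, skips_per_base = NA_real_,
                       stays_per_base = NA_real_, mean_read_length = NA_real_,
                       median_event_pA = NA_real_)
  if (length(idx) > 0L) {
    cnt <- tabulate(idx, nbins = n_chunks)
    chunks$n_reads <- cnt
    for (ci in which(cnt > 0L)) {
      sel <- per_read[idx == ci, , drop = FALSE]
      p <- pool_metrics(sel)
      chunks$skips_per_base[ci] <- p$skips_per_base
      chunks$stays_per_base[ci] <- p$stays_per_base
      chunks$mean_read_length[ci] <- p$mean_read_length
      chunks$median_event_pA[ci] <- median(sel$mean_event_pA)
    }
  }

  stop_time_s <- if (length(starts) > 0L) max(starts) else 0
  mux_s <- bundle$config$mux_interval_hours * 3600
  mult <- round(stop_time_s / mux_s)
  stopped_at_mux <- length(starts) > 0L &&
    chunks$n_reads[n_chunks] == 0L &&
    mult >= 1 && abs(stop_time_s - mult * mux_s) <= width

  structure(list(chunk_minutes = chunk_minutes, chunks = chunks,
                 stop_time_s = stop_time_s,
                 stopped_at_mux_boundary = stopped_at_mux),
            class = "chunk_series")
}

#' @export
print.chunk_series <- function(x, ...) {
  occ <- sum(x$chunks$n_reads > 0)
  cat(sprintf(paste0("<chunk_series> %d chunks of %g min, %d occupied; ",
                     "last read at %.0f s%s\n"),
              nrow(x$chunks), x$chunk_minutes, occ, x$stop_time_s,
              if (x$stopped_at_mux_boundary) " (stopped at a MUX boundary)" else ""))
  invisible(x)
}
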