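#' Configure a dose-ladder pipeline
#'
#' Bundles everything [run_pipeline()] needs: the reference, the output
#' directory, the dose ladder with condition labels, and the per-stage
#' settings. All randomness descends deterministically from `seed`, expanded
#' per condition.
#'
#' @param reference A `pore_reference` or a FASTA path.
#' @param out_dir Output directory.
#' @param doses Dose ladder in gray; repeated dose-0 entries model replicate
#'   controls. Default mirrors a flow-cell experiment: two controls plus
#'   50, 300, 500 and 750 gray.
#' @param conditions Optional condition labels (defaults to `control_<i>` for
#'   dose 0 and `<dose>gray` otherwise).
#' @param run A [run_config()].
#' @param degradation A [degradation_params()].
#' @param model_k Pore-model k-mer length.
#' @param min_identity,min_span Aligner acceptance thresholds.
#' @param current_window,max_noise_pA Platform-QC thresholds.
#' @param chunk_minutes Time-chunk width for the per-run series.
#' @param seed Master integer seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(reference, out_dir,
                            doses = c(0, 0, 50, 300, 500, 750),
                            conditions = NULL,
                            run = run_config(),
                            degradation = degradation_params(),
                            model_k = 5,
                            min_identity = 0.55, min_span = 100,
                            current_window = c(180, 280), max_noise_pA = 15,
                            chunk_minutes = 10, seed = 1) {
  if (any(doses < 0)) stop("dose ladder values must be non-negative")
  if (is.null(conditions)) {
    conditions <- character(length(doses))
    nc <- 0L
    for (i in seq_along(doses)) {
      if (doses[i] == 0) {
        nc <- nc + 1L
        conditions[i] <- sprintf("control_%d", nc)
      } else {
        conditions[i] <- sprintf("%ggray", doses[i])
      }
    }
  }
  if (length(conditions) != length(doses) || anyDuplicated(conditions)) {
    stop("`conditions` must be unique labels, one per dose")
  }
  structure(list(reference = reference, out_dir = out_dir, doses = doses,
                 conditions = conditions, run = run,
                 degradation = degradation, model_k = model_k,
                 min_identity = min_identity, min_span = min_span,
                 current_window = current_window, max_noise_pA = max_noise_pA,
                 chunk_minutes = chunk_minutes, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full dose-ladder pipeline
#'
#' For every condition: simulate the run, persist the bundle, compute event
#' metrics and the time-chunked series, align reads, build the coverage map,
#' run the platform QC, and summarize. The per-condition summaries are then
#' assembled into a [dose_table()] flagged against the worst-performing
#' control, written as TSV and JSON under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return The `dose_table`, invisibly; artifacts live under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  ref <- config$reference
  if (is.character(ref)) ref <- load_reference(ref)
  stopifnot(inherits(ref, "pore_reference"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- build_pore_model(config$model_k,
                            seed = derive_seed(config$seed, 0L))

  rows <- vector("list", length(config$doses))
  for (i in seq_along(config$doses)) {
    dose <- config$doses[i]
    cond <- config$conditions[i]
    t0 <- proc.time()[["elapsed"]]
    bundle <- simulate_run(ref, model, config$run, config$degradation,
                           dose = dose, condition = cond,
                           seed = derive_seed(config$seed, i))
    cdir <- file.path(config$out_dir, cond)
    write_bundle(bundle, cdir)
    qc <- platform_qc(bundle, config$current_window, config$max_noise_pA)
    jsonlite::write_json(
      list(condition = cond, dose_gray = dose,
           active_count = qc$active_count,
           monitored_per_period = vapply(qc$monitored_groups, length,
                                         integer(1))),
      file.path(cdir, "qc.json"), auto_unbox = TRUE, digits = NA)

    if (length(bundle$reads) > 0L) {
      metrics <- bundle_metrics(bundle)
      data.table::fwrite(metrics, file.path(cdir, "read_metrics.tsv"),
                         sep = "\t")
      series <- time_chunks(bundle, metrics, config$chunk_minutes)
      data.table::fwrite(series$chunks, file.path(cdir, "chunks.tsv"),
                         sep = "\t")
      aln <- align_reads(bundle, ref, min_identity = config$min_identity,
                         min_span = config$min_span)
      data.table::fwrite(aln, file.path(cdir, "alignments.tsv"), sep = "\t")
      cov <- coverage_map(aln, ref$length)
      data.table::fwrite(
        data.frame(position = seq_along(cov$depth) - 1L, depth = cov$depth),
        file.path(cdir, "coverage.tsv"), sep = "\t")
      rows[[i]] <- summarize_condition(bundle, metrics, aln, cov, qc)
    } else {
      rows[[i]] <- summarize_condition(bundle, qc = qc)
    }
    say("[%s] dose %g gray: %d reads, %d active pores (%.1f s)",
        cond, dose, length(bundle$reads), qc$active_count,
        proc.time()[["elapsed"]] - t0)
  }

  summaries <- do.call(rbind, rows)
  tab <- dose_table(summaries, controls = config$doses == 0)
  data.table::fwrite(as.data.frame(tab),
                     file.path(config$out_dir, "dose_table.tsv"), sep = "\t")
  jsonlite::write_json(as.data.frame(tab),
                       file.path(config$out_dir, "dose_table.json"),
                       digits = NA, na = "null")
  invisible(tab)
}
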