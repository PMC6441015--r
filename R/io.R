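# Plain-text persistence: FASTA reference in, run bundles out as
# manifest JSON + FASTQ + events/wells TSV. The events TSV column order
# (read_id, event_index, mean_pA, start_s, dur_s, move, kmer) is the
# package's normative interchange schema.

#' Load a reference genome from FASTA
#'
#' Reads the first record, uppercases it, and rejects any non-A/C/G/T
#' character with its offset. The header is truncated at the first
#' whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A `pore_reference`.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  bases <- toupper(as.character(set[[1L]]))
  if (nchar(bases) == 0L) stop("first FASTA record is empty")
  bad <- regexpr("[^ACGT]", bases)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' at offset %d in %s",
                 substr(bases, bad, bad), bad, path))
  }
  id <- strsplit(names(set)[1L], "\\s+")[[1L]][1L]
  new_reference(id, bases)
}

#' Write a reference as FASTA
#'
#' @param reference A `pore_reference`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path, width = 70) {
  stopifnot(inherits(reference, "pore_reference"))
  starts <- seq(1L, reference$length, by = width)
  lines <- substring(reference$bases, starts,
                     pmin(starts + width - 1L, reference$length))
  writeLines(c(paste0(">", reference$id), lines), path)
  invisible(path)
}

.fastq_header <- function(r) {
  sprintf("@%s ch=%d well=%d t=%.9f ref=%d-%d:%s bc=%s",
          r$read_id, r$channel, r$well, r$start_time_s,
          r$true_interval$ref_start, r$true_interval$ref_end,
          r$true_interval$strand,
          if (is.na(r$true_barcode)) "." else r$true_barcode)
}

.parse_fastq_header <- function(h, lineno) {
  m <- regmatches(h, regexec(
    "^@(\\S+) ch=(\\d+) well=(\\d+) t=([0-9.eE+-]+) ref=(\\d+)-(\\d+):([+-]) bc=(\\S+)$",
    h))[[1L]]
  if (length(m) != 9L) {
    stop(sprintf("malformed FASTQ header at line %d: %s", lineno, h))
  }
  list(read_id = m[2L], channel = as.integer(m[3L]), well = as.integer(m[4L]),
       start_time_s = as.numeric(m[5L]),
       true_interval = list(ref_start = as.integer(m[6L]),
                            ref_end = as.integer(m[7L]), strand = m[8L]),
       true_barcode = if (m[9L] == ".") NA_character_ else m[9L])
}

#' Write a run bundle to a directory
#'
#' Emits `manifest.json` (config, dose, condition, seed, well summary),
#' `reads.fastq` (uniform placeholder qualities; channel, well, start time,
#' true interval and barcode in the header comment), `events.tsv`
#' (columns `read_id, event_index, mean_pA, start_s, dur_s, move, kmer`) and
#' `wells.tsv` (`well, open_pore_pA, noise_pA, alive`).
#'
#' @param bundle A `run_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "run_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  manifest <- list(
    format = "poredose_run_bundle", version = 1L,
    condition = bundle$condition, dose_gray = bundle$dose_gray,
    k = bundle$k, seed = bundle$seed,
    config = Filter(Negate(is.null), list(
      n_wells = cfg$n_wells, n_channels = cfg$n_channels,
      run_hours = cfg$run_hours, mux_interval_hours = cfg$mux_interval_hours,
      mean_reads_per_active_channel_per_hour = cfg$mean_reads_per_active_channel_per_hour,
      fragment_length_log_mean = cfg$fragment_length_log_mean,
      fragment_length_log_sd = cfg$fragment_length_log_sd,
      seed = cfg$seed,
      barcodes = if (!is.null(cfg$barcodes)) list(
        labels = cfg$barcodes$entries$label,
        sequences = cfg$barcodes$entries$sequence,
        max_edit = cfg$barcodes$max_edit))),
    wells = list(total = length(bundle$well_alive),
                 alive = sum(bundle$well_alive)),
    n_reads = length(bundle$reads))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  fq <- unlist(lapply(bundle$reads, function(r) {
    c(.fastq_header(r), r$called_bases, "+", strrep("I", nchar(r$called_bases)))
  }))
  writeLines(fq %||% character(0), file.path(dir, "reads.fastq"))

  ev <- if (length(bundle$reads) > 0L) {
    data.table::rbindlist(lapply(bundle$reads, function(r) {
      data.table::data.table(read_id = r$read_id,
                             event_index = seq_len(nrow(r$events)),
                             mean_pA = r$events$mean_pA,
                             start_s = r$events$start_s,
                             dur_s = r$events$dur_s,
                             move = r$events$move,
                             kmer = r$events$kmer)
    }))
  } else {
    data.table::data.table(read_id = character(0), event_index = integer(0),
                           mean_pA = numeric(0), start_s = numeric(0),
                           dur_s = numeric(0), move = integer(0),
                           kmer = character(0))
  }
  data.table::fwrite(ev, file.path(dir, "events.tsv"), sep = "\t")
  data.table::fwrite(bundle$wells, file.path(dir, "wells.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a run bundle back from a directory
#'
#' Validates the on-disk schema (required columns, per-read monotone event
#' times) and reconstructs the bundle; a [write_bundle()] round trip
#' reproduces every field.
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `run_bundle`.
#' @export
read_bundle <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", dir)
  man <- jsonlite::fromJSON(man_path, simplifyVector = TRUE)
  if (!identical(man$format, "poredose_run_bundle")) {
    stop("not a poredose run bundle: ", dir)
  }
  bc <- NULL
  if (!is.null(man$config$barcodes)) {
    bc <- barcode_set(man$config$barcodes$labels,
                      man$config$barcodes$sequences,
                      man$config$barcodes$max_edit)
  }
  cfg <- run_config(
    n_wells = man$config$n_wells, n_channels = man$config$n_channels,
    run_hours = man$config$run_hours,
    mux_interval_hours = man$config$mux_interval_hours,
    mean_reads_per_active_channel_per_hour = man$config$mean_reads_per_active_channel_per_hour,
    fragment_length_log_mean = man$config$fragment_length_log_mean,
    fragment_length_log_sd = man$config$fragment_length_log_sd,
    barcodes = bc, seed = man$config$seed)

  wells <- as.data.frame(data.table::fread(file.path(dir, "wells.tsv"),
                                           sep = "\t"))
  need <- c("well", "open_pore_pA", "noise_pA", "alive")
  miss <- setdiff(need, names(wells))
  if (length(miss) > 0L) {
    stop("wells.tsv lacks column(s): ", paste(miss, collapse = ", "))
  }
  wells$well <- as.integer(wells$well)

  ev <- as.data.frame(data.table::fread(file.path(dir, "events.tsv"),
                                        sep = "\t"))
  need <- c("read_id", "event_index", "mean_pA", "start_s", "dur_s", "move",
            "kmer")
  miss <- setdiff(need, names(ev))
  if (length(miss) > 0L) {
    stop("events.tsv lacks column(s): ", paste(miss, collapse = ", "))
  }

  fq <- readLines(file.path(dir, "reads.fastq"))
  if (length(fq) %% 4L != 0L) stop("reads.fastq is not a 4-line-record FASTQ")
  n_reads <- length(fq) %/% 4L
  ids <- character(n_reads)
  reads <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    off <- (i - 1L) * 4L
    hdr <- .parse_fastq_header(fq[off + 1L], off + 1L)
    hdr$called_bases <- fq[off + 2L]
    ids[i] <- hdr$read_id
    reads[[i]] <- hdr
  }

  ev_by_read <- split(seq_len(nrow(ev)), factor(ev$read_id, levels = ids))
  for (i in seq_len(n_reads)) {
    rows <- ev_by_read[[ids[i]]]
    if (length(rows) == 0L) stop("no events for read ", ids[i])
    rows <- rows[order(ev$event_index[rows])]
    st <- ev$start_s[rows]
    if (is.unsorted(st)) {
      bad <- rows[which(diff(st) < 0)[1L] + 1L]
      stop(sprintf("non-monotone event times for read %s (events.tsv row %d)",
                   ids[i], bad))
    }
    reads[[i]]$events <- data.frame(mean_pA = ev$mean_pA[rows],
                                    start_s = st, dur_s = ev$dur_s[rows],
                                    move = as.integer(ev$move[rows]),
                                    kmer = ev$kmer[rows])
    reads[[i]] <- reads[[i]][c("read_id", "channel", "well", "start_time_s",
                               "true_interval", "true_barcode",
                               "called_bases", "events")]
  }
  if (any(!ev$read_id %in% ids)) {
    stop("events.tsv refers to read ids missing from reads.fastq")
  }

  structure(list(config = cfg, dose_gray = man$dose_gray,
                 condition = man$condition, k = as.integer(man$k),
                 seed = as.integer(man$seed), wells = wells,
                 well_alive = wells$alive, reads = reads),
            class = "run_bundle")
}
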