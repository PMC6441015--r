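#' Define a barcode set
#'
#' @param labels Unique barcode labels.
#' @param sequences Barcode sequences (non-empty A/C/G/T strings), one per
#'   label.
#' @param max_edit Maximum edit distance at which a barcode is still accepted.
#' @return A `barcode_set` with `entries` (data frame `label`, `sequence`)
#'   and `max_edit`.
#' @export
barcode_set <- function(labels, sequences, max_edit = 3) {
  if (length(labels) != length(sequences) || length(labels) == 0L) {
    stop("`labels` and `sequences` must be non-empty and of equal length")
  }
  if (anyDuplicated(labels)) stop("barcode labels must be unique")
  if (any(nchar(sequences) == 0L)) stop("barcode sequences must be non-empty")
  lapply(sequences, base_codes)  # validates the alphabet
  structure(list(entries = data.frame(label = as.character(labels),
                                      sequence = as.character(sequences),
                                      stringsAsFactors = FALSE),
                 max_edit = as.integer(max_edit)),
            class = "barcode_set")
}

#' Default 12-barcode set
#'
#' A deterministic analog of a 12-library rapid barcoding kit: 12 labels
#' `BC01`..`BC12` with 24-base sequences generated once (fixed internal seed)
#' under a minimum pairwise edit distance of 10, so single-digit edit errors
#' can never flip one barcode into another.
#'
#' @param max_edit Maximum accepted edit distance (default 3).
#' @return A [barcode_set()].
#' @export
default_barcodes <- function(max_edit = 3) {
  seqs <- with_seed(1417L, {
    out <- character(0)
    while (length(out) < 12L) {
      cand <- codes_to_string(sample.int(4L, 24L, replace = TRUE) - 1L)
      if (length(out) == 0L || min(adist(cand, out)) >= 10L) {
        out <- c(out, cand)
      }
    }
    out
  })
  barcode_set(sprintf("BC%02d", 1:12), seqs, max_edit = max_edit)
}

#' Assign a read to a barcode
#'
#' Scans a prefix window of the read (default: first 100 bases) for the
#' barcode with the smallest infix edit distance (barcode fully consumed,
#' window ends free). The label is returned only when that distance is at
#' most `max_edit` and strictly smaller than the runner-up's; otherwise the
#' read is `"unclassified"` -- mirroring how low-quality reads fail barcode
#' assignment.
#'
#' @param query Called base sequence (an empty string is unclassified, not an
#'   error).
#' @param barcodes A [barcode_set()].
#' @param window Number of leading bases scanned.
#' @return A single label, or `"unclassified"`.
#' @export
demux <- function(query, barcodes, window = 100) {
  stopifnot(inherits(barcodes, "barcode_set"))
  if (!is.character(query) || length(query) != 1L) {
    stop("`query` must be a single character string")
  }
  if (nchar(query) == 0L) return("unclassified")
  win <- base_codes(substr(query, 1L, window))
  d <- vapply(barcodes$entries$sequence,
              function(b) edit_infix_cpp(base_codes(b), win), integer(1),
              USE.NAMES = FALSE)
  o <- order(d)
  runner_up <- if (length(d) > 1L) d[o[2L]] else Inf
  if (d[o[1L]] <= barcodes$max_edit && d[o[1L]] < runner_up) {
    barcodes$entries$label[o[1L]]
  } else {
    "unclassified"
  }
}

#' Demultiplex every read of a bundle (or a character vector)
#'
#' @param x A `run_bundle` or character vector of sequences.
#' @param barcodes A [barcode_set()].
#' @param window Prefix window passed to [demux()].
#' @return A character vector of labels (named by read id for bundles).
#' @export
demux_reads <- function(x, barcodes, window = 100) {
  if (inherits(x, "run_bundle")) {
    seqs <- vapply(x$reads, function(r) r$called_bases, character(1))
    names(seqs) <- vapply(x$reads, function(r) r$read_id, character(1))
  } else {
    seqs <- x
  }
  vapply(seqs, demux, character(1), barcodes = barcodes, window = window)
}
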