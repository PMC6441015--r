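# Built-in semi-global aligner: query fully aligned, free reference ends,
# unit scores (match +1, mismatch/gap -1). On references longer than
# .FULL_DP_REF_MAX the DP is banded around a diagonal located by exact k-mer
# seeding; at or below it the band covers the whole matrix, so the result is
# the exhaustive optimum (this also makes the aligner exact on the short
# sequences used for oracle comparisons).

.FULL_DP_REF_MAX <- 2000L
.SEED_K <- 11L
.SEED_MAX_HITS <- 16L

#' Build a reusable k-mer seed index for a reference
#'
#' @param reference A `pore_reference`.
#' @param seed_k Seed k-mer length.
#' @return An opaque index object consumed by [align_read()].
#' @export
ref_seed_index <- function(reference, seed_k = .SEED_K) {
  stopifnot(inherits(reference, "pore_reference"))
  codes <- base_codes(reference$bases)
  kc <- kmer_codes(codes, seed_k)
  ord <- order(kc)
  list(seed_k = seed_k, codes_sorted = kc[ord], pos_sorted = ord,
       ref_len = reference$length, ref_codes = codes,
       rc_codes = rev(3L - codes))
}

# Median diagonal (ref_pos - query_pos) of exact seed matches, or NA when the
# query lacks a credible seed cluster on this strand. Requiring at least
# .SEED_MIN_VOTES co-diagonal hits rejects the scattered chance matches a
# wrong-strand (or foreign) query produces against a large reference.
.SEED_MIN_VOTES <- 4L

.seed_diagonal <- function(q_codes, index, band) {
  qk <- kmer_codes(q_codes, index$seed_k)
  if (length(qk) == 0L) return(NA_real_)
  hi <- findInterval(qk, index$codes_sorted)
  lo <- findInterval(qk - 1L, index$codes_sorted)
  cnt <- hi - lo
  sel <- which(cnt > 0L & cnt <= .SEED_MAX_HITS)
  if (length(sel) == 0L) return(NA_real_)
  reps <- cnt[sel]
  sidx <- sequence(reps) + rep.int(lo[sel], reps)
  d <- index$pos_sorted[sidx] - rep.int(sel, reps)  # ref pos - query pos
  b <- max(16L, band %/% 2L)
  bin <- (d - min(d)) %/% b
  votes <- table(bin)
  if (max(votes) < .SEED_MIN_VOTES) return(NA_real_)
  best <- as.integer(names(which.max(votes)))
  stats::median(d[bin >= best - 1L & bin <= best + 1L])
}

#' Align one read to the reference
#'
#' Best semi-global alignment (query fully aligned, reference ends free) over
#' both strands with unit match/mismatch/gap scores. Among equal-score
#' alignments the one with the most matches -- equivalently the highest
#' identity -- wins; remaining ties prefer the smaller reference start, then
#' the plus strand. On large references the dynamic program is banded
#' (half-width `max(band_min, band_frac * query length)`) around a diagonal
#' found by exact seed k-mer voting; reads without any seed hit are reported
#' unaligned.
#'
#' @param query Called base sequence (non-empty A/C/G/T string).
#' @param reference A `pore_reference`.
#' @param min_identity Minimum identity for the `aligned` flag (default 0.55:
#'   permissive for high-error nanopore-like reads, yet well above the
#'   25-35% identity of a random placement).
#' @param min_span Minimum query length for the `aligned` flag (default 100
#'   bases).
#' @param band_frac,band_min Band half-width as a fraction of query length
#'   and its floor.
#' @param identity_denom `"columns"` (default) counts every alignment column:
#'   `matches / (matches + mismatches + insertions + deletions)`;
#'   `"query"` divides by aligned query bases only.
#' @param index Optional [ref_seed_index()] (built on the fly otherwise);
#'   pass it when aligning many reads.
#' @return A one-row data frame: `aligned`, `ref_start`, `ref_end` (0-based
#'   half-open), `strand`, `matches`, `mismatches`, `insertions`,
#'   `deletions`, `identity`.
#' @examples
#' ref <- make_reference(500, seed = 1)
#' q <- substr(ref$bases, 101, 200)
#' align_read(q, ref, min_span = 50)
#' @export
align_read <- function(query, reference, min_identity = 0.55, min_span = 100,
                       band_frac = 0.2, band_min = 32,
                       identity_denom = c("columns", "query"), index = NULL) {
  stopifnot(inherits(reference, "pore_reference"))
  identity_denom <- match.arg(identity_denom)
  if (!is.character(query) || length(query) != 1L || nchar(query) == 0L) {
    stop("`query` must be a single non-empty sequence")
  }
  if (reference$length == 0L) stop("empty reference")
  n <- nchar(query)
  full <- reference$length <= .FULL_DP_REF_MAX
  if (!full && is.null(index)) index <- ref_seed_index(reference)
  ref_codes <- if (!is.null(index)) index$ref_codes else base_codes(reference$bases)
  q_fwd <- base_codes(query)
  band <- max(band_min, ceiling(band_frac * n))

  best <- NULL
  for (strand in c("+", "-")) {
    q_codes <- if (strand == "+") q_fwd else rev(3L - q_fwd)
    if (full) {
      dlo <- -n
      dhi <- reference$length
    } else {
      dc <- .seed_diagonal(q_codes, index, band)
      if (is.na(dc)) next
      dlo <- as.integer(dc - band)
      dhi <- as.integer(dc + band)
    }
    a <- semiglobal_align_cpp(q_codes, ref_codes, dlo, dhi)
    a$strand <- strand
    if (is.null(best) ||
        a$score > best$score ||
        (a$score == best$score && a$matches > best$matches) ||
        (a$score == best$score && a$matches == best$matches &&
         a$ref_start < best$ref_start)) {
      best <- a
    }
  }

  if (is.null(best)) {
    return(data.frame(aligned = FALSE, ref_start = NA_integer_,
                      ref_end = NA_integer_, strand = NA_character_,
                      matches = NA_integer_, mismatches = NA_integer_,
                      insertions = NA_integer_, deletions = NA_integer_,
                      identity = NA_real_))
  }
  denom <- if (identity_denom == "columns") {
    best$matches + best$mismatches + best$insertions + best$deletions
  } else {
    best$matches + best$mismatches + best$insertions
  }
  identity <- best$matches / denom
  data.frame(aligned = identity >= min_identity && n >= min_span,
             ref_start = best$ref_start, ref_end = best$ref_end,
             strand = best$strand, matches = best$matches,
             mismatches = best$mismatches, insertions = best$insertions,
             deletions = best$deletions, identity = identity)
}

#' Align all reads of a bundle (or a named sequence set)
#'
#' @param x A `run_bundle` or a named character vector of sequences.
#' @param reference A `pore_reference`.
#' @param ... Passed to [align_read()].
#' @return A data frame of [align_read()] rows with a leading `read_id`
#'   column.
#' @export
align_reads <- function(x, reference, ...) {
  if (inherits(x, "run_bundle")) {
    seqs <- vapply(x$reads, function(r) r$called_bases, character(1))
    names(seqs) <- vapply(x$reads, function(r) r$read_id, character(1))
  } else {
    seqs <- x
    if (is.null(names(seqs))) names(seqs) <- sprintf("read_%06d", seq_along(seqs))
  }
  if (length(seqs) == 0L) {
    return(data.frame(read_id = character(0), aligned = logical(0),
                      ref_start = integer(0), ref_end = integer(0),
                      strand = character(0), matches = integer(0),
                      mismatches = integer(0), insertions = integer(0),
                      deletions = integer(0), identity = numeric(0)))
  }
  index <- if (reference$length > .FULL_DP_REF_MAX) ref_seed_index(reference)
  rows <- lapply(seqs, align_read, reference = reference, index = index, ...)
  out <- as.data.frame(data.table::rbindlist(rows))
  cbind(read_id = names(seqs), out, stringsAsFactors = FALSE)
}

#' Summarize alignment results
#'
#' @param results A data frame of [align_reads()] rows.
#' @return A list: `pct_reads_aligned` (percent of reads with
#'   `aligned == TRUE`) and `mean_identity` (percent, averaged over aligned
#'   reads only). Both `NA` when there are no reads.
#' @export
summarize_alignments <- function(results) {
  n <- nrow(results)
  if (n == 0L) {
    return(list(pct_reads_aligned = NA_real_, mean_identity = NA_real_))
  }
  aligned <- results$aligned %in% TRUE
  list(pct_reads_aligned = 100 * sum(aligned) / n,
       mean_identity = if (any(aligned)) 100 * mean(results$identity[aligned])
                       else NA_real_)
}

#' Per-position depth of coverage
#'
#' Increments depth over every aligned read's reference interval. Coverage is
#' complete when every reference position is covered at least once; total
#' depth always equals the sum of aligned interval lengths.
#'
#' @param results A data frame of [align_reads()] rows.
#' @param ref_length Reference length in bases.
#' @return A `coverage_map`: `depth` (integer vector of length `ref_length`)
#'   and `complete`.
#' @export
coverage_map <- function(results, ref_length) {
  if (ref_length < 1) stop("`ref_length` must be positive")
  delta <- integer(ref_length + 1L)
  sel <- which(results$aligned %in% TRUE)
  if (length(sel) > 0L) {
    s <- results$ref_start[sel]
    e <- results$ref_end[sel]
    if (any(s < 0L) || any(e > ref_length) || any(e <= s)) {
      stop("aligned interval out of reference bounds")
    }
    ds <- tabulate(s + 1L, nbins = ref_length + 1L)
    de <- tabulate(e + 1L, nbins = ref_length + 1L)
    delta <- ds - de
  }
  depth <- cumsum(delta[seq_len(ref_length)])
  structure(list(depth = as.integer(depth), complete = all(depth >= 1L)),
            class = "coverage_map")
}

#' @export
print.coverage_map <- function(x, ...) {
  cat(sprintf("<coverage_map> %d positions, mean depth %.2f, %scomplete\n",
              length(x$depth), mean(x$depth), if (x$complete) "" else "NOT "))
  invisible(x)
}
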