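#' Generate a random reference sequence
#'
#' Draws an i.i.d. nucleotide sequence with a target GC fraction, standing in
#' for a small reference genome (the lambda phage genome, ~48.5 kb, is the
#' intended scale).
#'
#' @param length Number of bases (positive integer).
#' @param gc_fraction Expected fraction of G+C bases, strictly between 0 and 1.
#' @param seed Integer seed; the same seed reproduces the identical sequence.
#' @param id Sequence label used in FASTA output and alignment reports.
#' @return A `pore_reference` object with fields `id`, `bases` and `length`.
#' @examples
#' ref <- make_reference(1000, gc_fraction = 0.5, seed = 1)
#' ref$length
#' @export
make_reference <- function(length, gc_fraction = 0.5, seed = 1,
                           id = sprintf("synthetic_ref_%d", length)) {
  if (!is.numeric(length) || length(length) != 1L || length < 1 ||
      length != floor(length)) {
    stop("`length` must be a positive integer")
  }
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1) {
    stop("`gc_fraction` must lie strictly between 0 and 1")
  }
  codes <- with_seed(seed, {
    p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
           gc_fraction / 2, (1 - gc_fraction) / 2)
    sample.int(4L, size = length, replace = TRUE, prob = p) - 1L
  })
  new_reference(id, codes_to_string(codes))
}

new_reference <- function(id, bases) {
  structure(list(id = id, bases = bases, length = nchar(bases)),
            class = "pore_reference")
}

#' @export
print.pore_reference <- function(x, ...) {
  gc <- mean(strsplit(substr(x$bases, 1, min(x$length, 100000L)), "")[[1]] %in%
               c("G", "C"))
  cat(sprintf("<pore_reference> %s: %d bases (GC %.1f%% in first %d)\n",
              x$id, x$length, 100 * gc, min(x$length, 100000L)))
  invisible(x)
}

#' Build a synthetic k-mer pore model
#'
#' Assigns every k-mer a reproducible mean current level spread uniformly over
#' 60-130 pA with a per-k-mer standard deviation of 1.5-3 pA, emulating the
#' current-level table the detector uses: one event reports the residency of
#' one k-mer (k = 5 by default, matching the five-base detection window of the
#' platform).
#'
#' @param k K-mer length, between 1 and 8.
#' @param seed Integer seed; the same `(k, seed)` reproduces identical tables.
#' @return A `pore_model` with fields `k`, `kmers`, `mean`, `sd`. Entry `i`
#'   describes the k-mer whose base-4 code (A=0, C=1, G=2, T=3, first base most
#'   significant) is `i - 1`.
#' @export
build_pore_model <- function(k = 5, seed = 1) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > 8 || k != floor(k)) {
    stop("`k` must be an integer between 1 and 8")
  }
  k <- as.integer(k)
  n <- 4L^k
  g <- expand.grid(rep(list(.BASES), k), stringsAsFactors = FALSE)
  kmers <- do.call(paste0, g[, rev(seq_len(k)), drop = FALSE])
  lev <- with_seed(seed, list(mean = runif(n, 60, 130), sd = runif(n, 1.5, 3)))
  structure(list(k = k, kmers = kmers, mean = lev$mean, sd = lev$sd),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("<pore_model> k=%d, %d k-mers, levels %.1f-%.1f pA\n",
              x$k, length(x$kmers), min(x$mean), max(x$mean)))
  invisible(x)
}

#' Radiation degradation parameters
#'
#' Parameterizes how an absorbed dose degrades a simulated run: Hill-type pore
#' survival, linear-in-dose inflation of stay/skip/basecall-error rates, a
#' linear current drift, and a hard dose threshold above which a run produces
#' no reads at all (mirroring flow cells that fail outright at high dose).
#'
#' @param d50_pore Dose (gray) at which pore survival is 50%.
#' @param hill Hill steepness of the survival curve (> 0).
#' @param p_stay0,p_skip0 Baseline per-event stay and skip probabilities.
#' @param c_stay,c_skip Linear inflation of those probabilities per gray.
#' @param p_sub0,p_ins0 Baseline basecall substitution and insertion rates.
#' @param c_err Linear inflation per gray applied to both error rates.
#' @param drift_pA_per_gray Shift of in-sequencing event currents, pA per gray.
#' @param d_fail Dose (gray) at or above which a run yields zero reads.
#' @return A `degradation_params` object.
#' @export
degradation_params <- function(d50_pore = 400, hill = 4,
                               p_stay0 = 0.10, c_stay = 1e-4,
                               p_skip0 = 0.04, c_skip = 5e-5,
                               p_sub0 = 0.06, p_ins0 = 0.02, c_err = 2e-4,
                               drift_pA_per_gray = 0.02, d_fail = 500) {
  for (nm in c("p_stay0", "p_skip0", "p_sub0", "p_ins0")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v >= 1) stop(sprintf("`%s` must be in [0, 1)", nm))
  }
  for (nm in c("c_stay", "c_skip", "c_err")) {
    if (get(nm) < 0) stop(sprintf("`%s` must be non-negative", nm))
  }
  if (d50_pore <= 0) stop("`d50_pore` must be positive")
  if (hill <= 0) stop("`hill` must be positive")
  if (d_fail <= 0) stop("`d_fail` must be positive")
  structure(list(d50_pore = d50_pore, hill = hill,
                 p_stay0 = p_stay0, c_stay = c_stay,
                 p_skip0 = p_skip0, c_skip = c_skip,
                 p_sub0 = p_sub0, p_ins0 = p_ins0, c_err = c_err,
                 drift_pA_per_gray = drift_pA_per_gray, d_fail = d_fail),
            class = "degradation_params")
}

#' Effective rates at a given dose
#'
#' Evaluates the degradation model: survival follows a Hill curve
#' `1 / (1 + (dose / d50_pore)^hill)`, every rate is its baseline plus a
#' linear dose term clamped to `[0, 0.95]`, the current shift is linear, and
#' the run is alive only below `d_fail`.
#'
#' @param params A [degradation_params()] object.
#' @param dose Absorbed dose in gray (>= 0).
#' @return A list with `survival`, `p_stay`, `p_skip`, `p_sub`, `p_ins`,
#'   `current_shift` (pA) and `run_alive`.
#' @examples
#' effective_rates(degradation_params(), 300)
#' @export
effective_rates <- function(params, dose) {
  stopifnot(inherits(params, "degradation_params"))
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0) {
    stop("`dose` must be a single non-negative number")
  }
  clamp <- function(x) pmin(pmax(x, 0), 0.95)
  list(
    survival = 1 / (1 + (dose / params$d50_pore)^params$hill),
    p_stay = clamp(params$p_stay0 + params$c_stay * dose),
    p_skip = clamp(params$p_skip0 + params$c_skip * dose),
    p_sub = clamp(params$p_sub0 + params$c_err * dose),
    p_ins = clamp(params$p_ins0 + params$c_err * dose),
    current_shift = params$drift_pA_per_gray * dose,
    run_alive = dose < params$d_fail
  )
}

#' Run configuration
#'
#' Flow-cell geometry and throughput settings. Defaults reflect the platform:
#' 2048 wells of which 512 are monitored at a time, an 8-hour MUX rotation,
#' 24-hour runs, and a per-channel read rate sized so a healthy full-length
#' run produces a few hundred thousand reads.
#'
#' @param n_wells Total pore wells on the flow cell.
#' @param n_channels Wells monitored simultaneously (<= `n_wells`).
#' @param run_hours Run duration in hours.
#' @param mux_interval_hours Hours between MUX changes (rotation of the
#'   monitored well group).
#' @param mean_reads_per_active_channel_per_hour Poisson read rate per alive
#'   monitored well.
#' @param fragment_length_log_mean,fragment_length_log_sd Log-normal
#'   parameters of template fragment length (bases).
#' @param barcodes Optional barcode set (see [barcode_set()]); when supplied,
#'   each read is tagged with a uniformly drawn barcode whose sequence is
#'   prepended to the template before simulation.
#' @param seed Default integer seed used by [simulate_run()].
#' @return A `run_config` object.
#' @export
run_config <- function(n_wells = 2048, n_channels = 512,
                       run_hours = 24, mux_interval_hours = 8,
                       mean_reads_per_active_channel_per_hour = 30,
                       fragment_length_log_mean = log(3000),
                       fragment_length_log_sd = 0.5,
                       barcodes = NULL, seed = 1) {
  if (n_channels > n_wells) stop("`n_channels` must not exceed `n_wells`")
  if (run_hours <= 0) stop("`run_hours` must be positive")
  if (mux_interval_hours <= 0) stop("`mux_interval_hours` must be positive")
  if (mean_reads_per_active_channel_per_hour < 0) {
    stop("`mean_reads_per_active_channel_per_hour` must be non-negative")
  }
  if (fragment_length_log_sd < 0) stop("`fragment_length_log_sd` must be >= 0")
  if (!is.null(barcodes)) stopifnot(inherits(barcodes, "barcode_set"))
  structure(list(
    n_wells = as.integer(n_wells), n_channels = as.integer(n_channels),
    run_hours = run_hours, mux_interval_hours = mux_interval_hours,
    mean_reads_per_active_channel_per_hour = mean_reads_per_active_channel_per_hour,
    fragment_length_log_mean = fragment_length_log_mean,
    fragment_length_log_sd = fragment_length_log_sd,
    barcodes = barcodes, seed = as.integer(seed)), class = "run_config")
}

#' Simulate one sequencing run
#'
#' Generates a full synthetic run: wells die independently with probability
#' `1 - survival(dose)`; reads are drawn only from alive wells of the
#' currently monitored MUX group; each read is an event walk over a template
#' fragment in which a stay emits an extra event (move 0), a skip advances
#' three template bases while calling two (move 2, one deletion), an
#' insertion emits a spurious base (move 1, no advance), and an ordinary step
#' calls one base (move 1). Substitution errors are applied to all called
#' bases; event currents come from the pore model plus Gaussian noise and the
#' dose-dependent drift. At or above `d_fail` the run yields zero reads.
#'
#' For every read the called length equals `k + sum(moves)` by construction.
#'
#' @param reference A [make_reference()] result (or `pore_reference`).
#' @param model A [build_pore_model()] result.
#' @param config A [run_config()].
#' @param params A [degradation_params()].
#' @param dose Absorbed dose in gray.
#' @param condition Condition label; defaults to `"control"` at dose 0 and
#'   `"<dose>gray"` otherwise.
#' @param seed Integer seed (defaults to `config$seed`); identical inputs and
#'   seed reproduce the identical bundle.
#' @return A `run_bundle`: `config`, `dose_gray`, `condition`, `k`, `seed`,
#'   `wells` (per-well QC observations with truth column `alive`),
#'   `well_alive`, and `reads` (list of simulated reads, each with `read_id`,
#'   `channel`, `well`, `start_time_s`, `true_interval`, `true_barcode`,
#'   `called_bases` and an `events` data frame).
#' @export
simulate_run <- function(reference, model = build_pore_model(),
                         config = run_config(),
                         params = degradation_params(),
                         dose = 0, condition = NULL, seed = config$seed) {
  stopifnot(inherits(reference, "pore_reference"),
            inherits(model, "pore_model"),
            inherits(config, "run_config"),
            inherits(params, "degradation_params"))
  k <- model$k
  if (reference$length < k) stop("reference shorter than the model k-mer")
  if (is.null(condition)) {
    condition <- if (dose == 0) "control" else sprintf("%ggray", dose)
  }
  er <- effective_rates(params, dose)

  with_seed(seed, {
    n_wells <- config$n_wells
    alive <- runif(n_wells) < er$survival
    wells <- .simulate_wells(alive)

    reads <- list()
    if (er$run_alive && config$mean_reads_per_active_channel_per_hour > 0) {
      reads <- .simulate_reads(reference, model, config, er, alive)
    }
    structure(list(config = config, dose_gray = dose, condition = condition,
                   k = k, seed = as.integer(seed), wells = wells,
                   well_alive = alive, reads = reads),
              class = "run_bundle")
  })
}

# Platform-QC well observations. Alive wells draw open-pore currents strictly
# inside the default QC window (190-270 pA, noise 2-12 pA); dead wells draw
# low, noisy currents strictly outside it. The QC classifier therefore
# recovers the alive state exactly, so active-count variability reflects pore
# survival sampling alone. The dose current drift models in-sequencing levels
# and is deliberately not applied to open-pore QC currents.
.simulate_wells <- function(alive) {
  n <- length(alive)
  open_pA <- numeric(n)
  noise <- numeric(n)
  na <- sum(alive)
  open_pA[alive] <- runif(na, 190, 270)
  noise[alive] <- runif(na, 2, 12)
  open_pA[!alive] <- runif(n - na, 0, 150)
  noise[!alive] <- runif(n - na, 0, 30)
  data.frame(well = seq_len(n), open_pore_pA = open_pA, noise_pA = noise,
             alive = alive)
}

.simulate_reads <- function(reference, model, config, er, alive) {
  k <- model$k
  ref_len <- reference$length
  ref_codes <- base_codes(reference$bases)
  rc_codes <- rev(3L - ref_codes)

  l_min <- min(200L, ref_len - 2L)
  if (l_min < k + 1L) stop("reference too short to draw fragments from")

  bc <- config$barcodes
  bc_codes <- if (!is.null(bc)) lapply(bc$entries$sequence, base_codes)

  n_channels <- config$n_channels
  n_groups <- ceiling(config$n_wells / n_channels)
  n_periods <- ceiling(config$run_hours / config$mux_interval_hours)
  rate <- config$mean_reads_per_active_channel_per_hour

  well_v <- integer(0); t_v <- numeric(0)
  for (p in seq_len(n_periods)) {
    t0 <- (p - 1) * config$mux_interval_hours
    hours_p <- min(config$mux_interval_hours, config$run_hours - t0)
    g <- (p - 1) %% n_groups
    gw <- seq.int(g * n_channels + 1L, min((g + 1L) * n_channels, config$n_wells))
    gw <- gw[alive[gw]]
    if (length(gw) == 0L) next
    n_p <- rpois(1L, length(gw) * rate * hours_p)
    if (n_p == 0L) next
    well_v <- c(well_v, sample(gw, n_p, replace = TRUE))
    t_v <- c(t_v, (t0 + sort(runif(n_p, 0, hours_p))) * 3600)
  }
  n_reads <- length(well_v)
  if (n_reads == 0L) return(list())

  # Fragment ends may truncate at the molecule boundaries (a linear genome is
  # fragmented, so terminal fragments exist), with at least l_min bases
  # retained: start positions are uniform over [-(L - l_min), ref_len - l_min]
  # and the interval is clipped to the reference. This keeps coverage roughly
  # uniform all the way to both reference ends.
  lens <- pmin(pmax(round(rlnorm(n_reads, config$fragment_length_log_mean,
                                 config$fragment_length_log_sd)),
                    l_min), ref_len - 2L)
  s_raw <- pmin(floor(runif(n_reads, -(lens - l_min), ref_len - l_min + 1)),
                ref_len - l_min)
  starts <- pmax(0, s_raw)                                # 0-based
  lens <- pmin(s_raw + lens, ref_len) - starts            # realized length
  strands <- ifelse(runif(n_reads) < 0.5, "+", "-")
  bc_idx <- if (!is.null(bc)) sample.int(nrow(bc$entries), n_reads, replace = TRUE)

  reads <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    reads[[i]] <- .sim_read(
      read_id = sprintf("read_%06d", i),
      channel = as.integer((well_v[i] - 1L) %% n_channels + 1L),
      well = as.integer(well_v[i]),
      start_time_s = t_v[i],
      ref_codes = ref_codes, rc_codes = rc_codes, ref_len = ref_len,
      s0 = as.integer(starts[i]), nominal_len = as.integer(lens[i]),
      strand = strands[i],
      bc_label = if (!is.null(bc)) bc$entries$label[bc_idx[i]] else NA_character_,
      bc_codes = if (!is.null(bc)) bc_codes[[bc_idx[i]]],
      model = model, er = er)
  }
  reads
}

# One read: event walk over the (optionally barcoded) template fragment.
.sim_read <- function(read_id, channel, well, start_time_s,
                      ref_codes, rc_codes, ref_len, s0, nominal_len, strand,
                      bc_label, bc_codes, model, er) {
  k <- model$k
  lb <- length(bc_codes)  # 0 when unbarcoded

  # iid translocation decisions until at least `target` template bases beyond
  # the initial k-mer are consumed; the realized fragment may extend the
  # nominal draw by at most 2 bases (a trailing skip), never truncating the
  # decision stream (keeps event-type fractions exactly binomial).
  target <- lb + nominal_len - k
  adv_mean <- max(3 * er$p_skip + (1 - er$p_stay - er$p_skip - er$p_ins), 0.05)
  type <- integer(0)  # 1 stay, 2 skip, 3 ins, 4 step
  consumed <- 0L
  while (consumed < target) {
    need <- ceiling((target - consumed) / adv_mean * 1.3) + 25L
    u <- runif(need)
    tt <- ifelse(u < er$p_stay, 1L,
          ifelse(u < er$p_stay + er$p_skip, 2L,
          ifelse(u < er$p_stay + er$p_skip + er$p_ins, 3L, 4L)))
    adv <- c(0L, 3L, 0L, 1L)[tt]
    cum <- consumed + cumsum(adv)
    hit <- which(cum >= target)
    if (length(hit) > 0L) {
      tt <- tt[seq_len(hit[1L])]
      consumed <- cum[hit[1L]]
      type <- c(type, tt)
    } else {
      consumed <- cum[need]
      type <- c(type, tt)
    }
  }

  total_len <- k + consumed                 # template bases incl. barcode
  frag_ref_len <- total_len - lb            # bases taken from the reference
  e0 <- s0 + frag_ref_len                   # 0-based half-open end
  if (e0 > ref_len) {                       # trailing-skip overshoot at the
    s0 <- s0 - (e0 - ref_len)               # reference end: shift left (<= 2)
    e0 <- ref_len
  }
  frag_codes <- if (strand == "+") {
    ref_codes[(s0 + 1L):e0]
  } else {
    rc_codes[(ref_len - e0 + 1L):(ref_len - s0)]
  }
  if (lb > 0L) frag_codes <- c(bc_codes, frag_codes)

  type <- c(0L, type)                       # type[1] == 0 marks the initial event
  n_ev <- length(type)
  adv <- integer(n_ev)                      # template advance per event
  adv[1L] <- k
  adv[-1L] <- c(0L, 3L, 0L, 1L)[type[-1L]]  # stay, skip, ins, step
  moves <- integer(n_ev)                    # called-sequence advance (fast5 move)
  moves[-1L] <- c(0L, 2L, 1L, 1L)[type[-1L]]
  pos <- cumsum(adv)                        # template position after each event
  n_call <- moves
  n_call[1L] <- k

  src <- rep.int(pos, n_call) + (sequence(n_call) - rep.int(n_call, n_call))
  called <- frag_codes[src]
  ins_mask <- rep.int(type == 3L, n_call)
  n_ins <- sum(ins_mask)
  if (n_ins > 0L) called[ins_mask] <- sample.int(4L, n_ins, replace = TRUE) - 1L
  if (er$p_sub > 0) {
    sub <- runif(length(called)) < er$p_sub
    n_sub <- sum(sub)
    if (n_sub > 0L) {
      called[sub] <- (called[sub] + sample.int(3L, n_sub, replace = TRUE)) %% 4L
    }
  }

  kc_all <- kmer_codes(frag_codes, k)       # k-mer ending at template pos j
  kcode <- kc_all[pos - k + 1L]
  mean_pA <- model$mean[kcode + 1L] +
    rnorm(n_ev, 0, model$sd[kcode + 1L]) + er$current_shift
  dur_s <- rexp(n_ev, rate = 400)
  ev_start <- start_time_s + cumsum(c(0, dur_s[-n_ev]))

  list(read_id = read_id, channel = channel, well = well,
       start_time_s = start_time_s,
       true_interval = list(ref_start = s0, ref_end = e0, strand = strand),
       true_barcode = bc_label,
       called_bases = codes_to_string(called),
       events = data.frame(mean_pA = mean_pA, start_s = ev_start,
                           dur_s = dur_s, move = moves,
                           kmer = model$kmers[kcode + 1L]))
}

#' @export
print.run_bundle <- function(x, ...) {
  cat(sprintf("<run_bundle> condition '%s', %g gray: %d reads, %d/%d wells alive\n",
              x$condition, x$dose_gray, length(x$reads),
              sum(x$well_alive), length(x$well_alive)))
  if (length(x$reads) > 0) {
    rl <- vapply(x$reads, function(r) nchar(r$called_bases), numeric(1))
    cat(sprintf("  called length: mean %.0f (range %d-%d); run %g h, k=%d\n",
                mean(rl), min(rl), max(rl), x$config$run_hours, x$k))
  }
  invisible(x)
}
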