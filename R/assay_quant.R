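# Quantification of the functional assays: junctional conductance in dual
# voltage clamp, half-amplitude idealization of single-channel records,
# unitary conductance and open probability, dye-uptake slopes, and the
# ratiometric Fura-2 calcium signal.

#' Junctional conductance
#'
#' Dual voltage-clamp formula `g_j = -I_b / (V_a - V_b)`: the current
#' recorded in the non-stepped cell b divided by the transjunctional
#' voltage, sign-inverted. With I_b in pA and voltages in mV the result is
#' in nS. Vectorized over `I_b` (and `V_a`).
#'
#' @param I_b current in the non-stepped cell (pA).
#' @param V_a potential of the stepped cell (mV).
#' @param V_b holding potential of cell b (mV; -60 in the published
#'   protocol).
#' @return Junctional conductance (nS).
#' @examples
#' junctional_conductance(I_b = 40, V_a = -100, V_b = -60)  # 1 nS
#' @export
junctional_conductance <- function(I_b, V_a, V_b = -60) {
  dv <- V_a - V_b
  if (any(dv == 0))
    stop("undefined conductance: V_a equals V_b", call. = FALSE)
  -I_b / dv
}

#' Construct a single-channel current trace
#'
#' @param samples current samples (pA).
#' @param sampling_rate sampling rate (Hz).
#' @param holding_voltage holding/command voltage (mV).
#' @param protocol free-text protocol tag, e.g. `"step +60 mV 40 s"` or
#'   `"ramp -80..+80 mV 9 s"`.
#' @return A `channel_trace` list.
#' @export
channel_trace <- function(samples, sampling_rate, holding_voltage = 60,
                          protocol = "step +60 mV 40 s") {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (!all(is.finite(samples))) stop("non-finite samples", call. = FALSE)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 holding_voltage = holding_voltage,
                 protocol = protocol),
            class = "channel_trace")
}

# deterministic two-level split: Lloyd iteration seeded at the 1% and 99%
# quantiles
.two_levels <- function(x) {
  c1 <- unname(stats::quantile(x, 0.01)); c2 <- unname(stats::quantile(x, 0.99))
  if (c1 == c2) return(c(c1, c2))
  for (it in 1:100) {
    mid <- (c1 + c2) / 2
    lo <- x <= mid
    n1 <- mean(x[lo]); n2 <- mean(x[!lo])
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) break
    c1 <- n1; c2 <- n2
  }
  c(c1, c2)
}

# merge runs shorter than min_len into their neighbors, shortest first;
# works on the run-length encoding so long traces stay cheap
.merge_short_runs <- function(state, min_len) {
  r <- rle(state)
  len <- r$lengths; val <- r$values
  repeat {
    if (length(len) <= 1L) break
    short <- which(len < min_len)
    if (!length(short)) break
    j <- short[which.min(len[short])]
    val[j] <- if (j == 1L) val[j + 1L] else val[j - 1L]
    keep <- c(TRUE, val[-1L] != val[-length(val)])
    grp <- cumsum(keep)
    len <- as.vector(tapply(len, grp, sum))
    val <- val[keep]
  }
  rep.int(val, len)
}

# 10-90% crossing time (ms) around sample index `at` for a step from level
# `from` to level `to`; linear interpolation between bracketing samples
.transition_time <- function(x, at, from, to, rate) {
  amp <- to - from
  lo <- from + 0.10 * amp; hi <- from + 0.90 * amp
  win <- max(1L, at - 50L):min(length(x), at + 50L)
  xx <- x[win]
  cross <- function(level) {
    s <- sign(amp)
    below <- s * xx < s * level
    k <- which(below[-length(xx)] & !below[-1L])
    k <- k[which.min(abs(win[k] - at))]
    if (!length(k)) return(NA_real_)
    frac <- (level - xx[k]) / (xx[k + 1L] - xx[k])
    win[k] + frac
  }
  t_lo <- cross(lo); t_hi <- cross(hi)
  if (is.na(t_lo) || is.na(t_hi)) return(1000 / rate)  # within one sample
  abs(t_hi - t_lo) / rate * 1000
}

#' Idealize single-channel events by half-amplitude threshold
#'
#' Estimates closed and open current levels by a deterministic two-level
#' split, assigns each sample open or closed by crossing of the
#' `threshold_frac` (default half) amplitude point, merges dwells shorter
#' than `min_dwell_ms`, and reports per-event amplitude (mean open current
#' minus baseline) and 10-90% transition durations. The closed level is the
#' level nearest 0 pA (leak-subtracted convention); a single-level trace is
#' all open when its level is significantly nonzero, otherwise eventless.
#'
#' @param trace a [channel_trace()].
#' @param baseline_window optional numeric length-2 time range (s) known to
#'   be closed; its median overrides the automatic baseline.
#' @param threshold_frac threshold position between levels (default 0.5).
#' @param min_dwell_ms minimum dwell time retained (default 2 ms).
#' @return A data frame of class `event_list` with columns `start`, `end`
#'   (s), `state` (`"open"`/`"closed"`), `amplitude` (pA), `rise_ms`,
#'   `fall_ms`; attributes `baseline`, `open_level`, `sampling_rate`,
#'   `duration`.
#' @export
detect_events <- function(trace, baseline_window = NULL,
                          threshold_frac = 0.5, min_dwell_ms = 2) {
  stopifnot(inherits(trace, "channel_trace"))
  x <- trace$samples
  rate <- trace$sampling_rate
  n <- length(x)
  empty <- function(baseline = 0) {
    structure(data.frame(start = numeric(0), end = numeric(0),
                         state = character(0), amplitude = numeric(0),
                         rise_ms = numeric(0), fall_ms = numeric(0),
                         stringsAsFactors = FALSE),
              baseline = baseline, open_level = NA_real_,
              sampling_rate = rate, duration = n / rate,
              class = c("event_list", "data.frame"))
  }
  if (n == 0L) return(empty())
  lev <- .two_levels(x)
  sep <- lev[2L] - lev[1L]
  resid_scale <- stats::mad(x - ifelse(x <= mean(lev), lev[1L], lev[2L]))
  if (sep <= max(3 * resid_scale, .Machine$double.eps)) {
    # single-level trace: open when the level is clearly nonzero
    level <- stats::median(x)
    s <- max(resid_scale, stats::mad(x))
    if (abs(level) > max(5 * s, 0)) {
      ev <- data.frame(start = 0, end = n / rate, state = "open",
                       amplitude = level, rise_ms = NA_real_,
                       fall_ms = NA_real_, stringsAsFactors = FALSE)
      return(structure(ev, baseline = 0, open_level = level,
                       sampling_rate = rate, duration = n / rate,
                       class = c("event_list", "data.frame")))
    }
    return(empty(baseline = level))
  }
  # closed = level nearest 0 pA
  closed_level <- lev[which.min(abs(lev))]
  open_level <- lev[which.max(abs(lev))]
  if (!is.null(baseline_window)) {
    idx <- which((seq_len(n) - 1) / rate >= baseline_window[1] &
                   (seq_len(n) - 1) / rate <= baseline_window[2])
    if (!length(idx)) stop("baseline window outside the trace", call. = FALSE)
    closed_level <- stats::median(x[idx])
  }
  thr <- closed_level + threshold_frac * (open_level - closed_level)
  s <- sign(open_level - closed_level)
  state <- ifelse(s * x >= s * thr, "open", "closed")
  min_len <- max(1L, as.integer(round(min_dwell_ms / 1000 * rate)))
  state <- .merge_short_runs(state, min_len)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  baseline <- stats::median(x[state == "closed"])
  ev <- data.frame(
    start = (starts - 1L) / rate, end = ends / rate, state = r$values,
    amplitude = vapply(seq_along(starts), function(i)
      mean(x[starts[i]:ends[i]]) - baseline, numeric(1)),
    rise_ms = NA_real_, fall_ms = NA_real_, stringsAsFactors = FALSE)
  open_i <- which(ev$state == "open")
  for (i in open_i) {
    if (starts[i] > 1L)
      ev$rise_ms[i] <- .transition_time(x, starts[i] - 1L, baseline,
                                        baseline + ev$amplitude[i], rate)
    if (ends[i] < n)
      ev$fall_ms[i] <- .transition_time(x, ends[i], baseline + ev$amplitude[i],
                                        baseline, rate)
  }
  structure(ev, baseline = baseline, open_level = open_level,
            sampling_rate = rate, duration = n / rate,
            class = c("event_list", "data.frame"))
}

#' Unitary conductance and open probability from idealized events
#'
#' Per-event conductance is `amplitude / (V - V_rev) * 1000` (pA/mV to pS);
#' the modal conductance is the center of the highest histogram bin (bins
#' centered on multiples of `bin_width`, mirroring the 75 +/- 5 pS
#' reporting granularity). Open probability is total open time over total
#' trace time.
#'
#' @param events an `event_list` from [detect_events()].
#' @param V membrane voltage (mV).
#' @param V_rev reversal potential (mV; default 0, the observed zero-current
#'   potential).
#' @param bin_width histogram bin width (pS, default 5).
#' @return A `channel_estimate` list: `modal_conductance` (pS),
#'   `conductances` (per open event), `histogram` (data frame of bin
#'   centers and counts), `open_probability`, `mean_rise_ms`,
#'   `mean_fall_ms`, `n_open_events`.
#' @export
conductance_estimate <- function(events, V, V_rev = 0, bin_width = 5) {
  stopifnot(inherits(events, "event_list"))
  if (V == V_rev) stop("V equals V_rev: conductance undefined", call. = FALSE)
  open <- events[events$state == "open", , drop = FALSE]
  if (nrow(open) == 0L) stop("no open events", call. = FALSE)
  g <- open$amplitude / (V - V_rev) * 1000
  centers <- seq(round(min(g) / bin_width) * bin_width,
                 round(max(g) / bin_width) * bin_width, by = bin_width)
  breaks <- c(centers - bin_width / 2, centers[length(centers)] + bin_width / 2)
  counts <- as.integer(table(cut(g, breaks = breaks, include.lowest = TRUE)))
  modal <- centers[which.max(counts)]
  duration <- attr(events, "duration")
  open_time <- sum(open$end - open$start)
  structure(list(
    modal_conductance = modal,
    conductances = g,
    histogram = data.frame(center = centers, count = counts),
    open_probability = open_time / duration,
    mean_rise_ms = mean(open$rise_ms, na.rm = TRUE),
    mean_fall_ms = mean(open$fall_ms, na.rm = TRUE),
    n_open_events = nrow(open)
  ), class = "channel_estimate")
}

#' Construct a dye-uptake trace
#'
#' @param time sample times (min), strictly increasing.
#' @param fluorescence fluorescence values (AU).
#' @param phases data frame with columns `label`, `t_start`, `t_end` (min)
#'   annotating non-overlapping recording phases (e.g. control, divalent
#'   cation free solution, blocker).
#' @return An `uptake_trace` list.
#' @export
uptake_trace <- function(time, fluorescence, phases) {
  stopifnot(length(time) == length(fluorescence))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing",
                                 call. = FALSE)
  stopifnot(is.data.frame(phases),
            all(c("label", "t_start", "t_end") %in% names(phases)))
  # each sample in at most one phase
  hits <- vapply(time, function(t)
    sum(t >= phases$t_start & t < phases$t_end), integer(1))
  if (any(hits > 1L)) stop("overlapping phase annotations", call. = FALSE)
  structure(list(time = time, fluorescence = fluorescence, phases = phases),
            class = "uptake_trace")
}

#' Dye-uptake rates per phase
#'
#' Ordinary least-squares slope of fluorescence versus time within each
#' annotated phase (all in-phase samples, no outlier rejection). Also
#' reports each phase's fold change relative to the first phase, and, when
#' three or more phases are present, the percent block of the final phase
#' relative to the preceding one (the blocker-after-trigger layout).
#' Phases with fewer than 3 samples are skipped with a warning.
#'
#' @param trace an [uptake_trace()].
#' @return A data frame with columns `label`, `slope` (AU/min),
#'   `n_samples`, `fold_vs_first`; attribute `percent_block` when defined.
#' @export
uptake_rate <- function(trace) {
  stopifnot(inherits(trace, "uptake_trace"))
  ph <- trace$phases
  res <- lapply(seq_len(nrow(ph)), function(i) {
    inph <- trace$time >= ph$t_start[i] & trace$time < ph$t_end[i]
    if (sum(inph) < 3L) {
      warning("phase '", ph$label[i], "' has fewer than 3 samples; skipped",
              call. = FALSE)
      return(NULL)
    }
    fit <- stats::lm(f ~ t, data = data.frame(t = trace$time[inph],
                                              f = trace$fluorescence[inph]))
    data.frame(label = ph$label[i],
               slope = unname(stats::coef(fit)[2L]),
               n_samples = sum(inph), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L)
    stop("no phase with >= 3 samples", call. = FALSE)
  out$fold_vs_first <- out$slope / out$slope[1L]
  pb <- NA_real_
  if (nrow(out) >= 3L) {
    k <- nrow(out)
    pb <- 100 * (1 - out$slope[k] / out$slope[k - 1L])
  }
  structure(out, percent_block = pb)
}

#' Ratiometric calcium signal
#'
#' Elementwise Fura-2 ratio `F340 / F380`.
#'
#' @param F340,F380 fluorescence at 340 and 380 nm excitation (equal
#'   lengths; `F380` must be positive).
#' @return Numeric vector of ratios.
#' @export
ca_ratio <- function(F340, F380) {
  if (length(F340) != length(F380))
    stop("F340 and F380 must have equal lengths", call. = FALSE)
  if (any(F380 <= 0)) stop("F380 must be positive elementwise", call. = FALSE)
  F340 / F380
}
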