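# Seeded generators emulating every input the pipeline consumes: two-class
# descriptor matrices with a few separating columns among many noise columns,
# two-state channel current traces with set conductance / open probability /
# noise, phase-structured dye-uptake time courses, and cylindrical
# pseudo-atom pore geometries with known constrictions. Every generator is a
# pure function of its arguments plus seed.

#' Generate a planted two-class descriptor dataset
#'
#' Informative columns are drawn `Normal(+effect_size/2, 1)` for permeant
#' and `Normal(-effect_size/2, 1)` for non-permeant molecules; noise columns
#' are `Normal(0, 1)` regardless of class. Optionally injects missing
#' values, missing-heavy columns and an all-but-one-zero column (converted
#' noise columns) to exercise the non-informative filter.
#'
#' @param n_permeant,n_nonpermeant molecules per class (both >= 1).
#' @param n_informative,n_noise numbers of class-separating and noise
#'   descriptors (total >= 1).
#' @param effect_size class-mean separation in standard-deviation units.
#' @param missing_fraction fraction of cells set missing at random
#'   (in `[0, 1)`).
#' @param n_missing_heavy noise columns converted to be missing for 2
#'   molecules (dropped by [filter_noninformative()]).
#' @param n_zero_degenerate noise columns converted to zero for all but one
#'   molecule.
#' @param seed integer seed.
#' @return List with `matrix` (labelled [descriptor_matrix()]) and
#'   `informative` (character vector of planted descriptor names).
#' @export
gen_descriptor_dataset <- function(n_permeant, n_nonpermeant,
                                   n_informative, n_noise,
                                   effect_size = 3,
                                   missing_fraction = 0,
                                   n_missing_heavy = 0L,
                                   n_zero_degenerate = 0L,
                                   seed = 1L) {
  if (n_permeant < 1L || n_nonpermeant < 1L)
    stop("both classes must be non-empty", call. = FALSE)
  if (n_informative + n_noise < 1L)
    stop("need at least one descriptor", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)", call. = FALSE)
  if (n_missing_heavy + n_zero_degenerate > n_noise)
    stop("degenerate columns exceed n_noise", call. = FALSE)
  n <- n_permeant + n_nonpermeant
  p <- n_informative + n_noise
  labels <- c(rep("permeant", n_permeant),
              rep("non_permeant", n_nonpermeant))
  withr::with_seed(as.integer(seed), {
    v <- matrix(stats::rnorm(n * p), n, p)
    if (n_informative > 0L) {
      shift <- ifelse(labels == "permeant", effect_size / 2, -effect_size / 2)
      v[, seq_len(n_informative)] <- v[, seq_len(n_informative)] + shift
    }
    if (missing_fraction > 0) {
      holes <- stats::runif(n * p) < missing_fraction
      v[holes] <- NA_real_
    }
    noise_cols <- if (n_noise > 0L) n_informative + seq_len(n_noise) else
      integer(0)
    if (n_missing_heavy > 0L)
      for (j in noise_cols[seq_len(n_missing_heavy)])
        v[sample.int(n, 2L), j] <- NA_real_
    if (n_zero_degenerate > 0L) {
      cols <- noise_cols[n_missing_heavy + seq_len(n_zero_degenerate)]
      for (j in cols) {
        v[, j] <- 0
        v[sample.int(n, 1L), j] <- stats::rnorm(1L) + 5
      }
    }
  })
  rownames(v) <- sprintf("M%02d", seq_len(n))
  inf_names <- if (n_informative > 0L)
    sprintf("INF%03d", seq_len(n_informative)) else character(0)
  colnames(v) <- c(inf_names,
                   if (n_noise > 0L) sprintf("NOISE%03d", seq_len(n_noise)))
  list(matrix = descriptor_matrix(v, labels = labels),
       informative = inf_names)
}

#' Simulate a two-state single-channel current trace
#'
#' Two-state (closed/open) Markov gating with exponential dwell times. The
#' user sets the open probability and the mean open dwell; the mean closed
#' dwell follows as `open * (1 - P_o) / P_o`, so the specification is never
#' over-determined. Open current is `g * V / 1000` pA plus Gaussian noise;
#' closed current is 0 plus noise. The initial state is drawn from the
#' stationary distribution.
#'
#' @param g unitary conductance (pS).
#' @param P_o open probability in `[0, 1]`.
#' @param V membrane voltage (mV).
#' @param noise_sd Gaussian current noise (pA).
#' @param mean_dwell_open_ms mean open dwell (ms).
#' @param duration_s trace duration (s).
#' @param rate_hz sampling rate (Hz).
#' @param seed integer seed.
#' @return A [channel_trace()] with the generating truth attached as
#'   `attr(, "truth")` (list: `g`, `P_o`, `V`, `states` 0/1 per sample).
#' @examples
#' tr <- gen_channel_trace(g = 75, P_o = 1, V = 60, noise_sd = 0)
#' unique(tr$samples)  # 4.5 pA
#' @export
gen_channel_trace <- function(g = 75, P_o = 0.3, V = 60, noise_sd = 0.5,
                              mean_dwell_open_ms = 100, duration_s = 40,
                              rate_hz = 5000, seed = 1L) {
  if (P_o < 0 || P_o > 1) stop("P_o must be in [0, 1]", call. = FALSE)
  if (duration_s <= 0 || rate_hz <= 0)
    stop("duration and rate must be > 0", call. = FALSE)
  if (mean_dwell_open_ms <= 0)
    stop("mean_dwell_open_ms must be > 0", call. = FALSE)
  n <- as.integer(round(duration_s * rate_hz))
  open_current <- g * V / 1000
  withr::with_seed(as.integer(seed), {
    if (P_o %in% c(0, 1)) {
      states <- rep(as.integer(P_o), n)
    } else {
      mean_open_s <- mean_dwell_open_ms / 1000
      mean_closed_s <- mean_open_s * (1 - P_o) / P_o
      state <- stats::rbinom(1L, 1L, P_o)
      states <- integer(0)
      while (length(states) < n) {
        dwell <- stats::rexp(1L, rate = 1 / if (state == 1L) mean_open_s
                             else mean_closed_s)
        k <- as.integer(round(dwell * rate_hz))
        if (k > 0L) states <- c(states, rep(state, k))
        state <- 1L - state
      }
      states <- states[seq_len(n)]
    }
    samples <- states * open_current +
      if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  })
  tr <- channel_trace(samples, sampling_rate = rate_hz,
                      holding_voltage = V,
                      protocol = sprintf("step %+g mV %g s", V, duration_s))
  attr(tr, "truth") <- list(g = g, P_o = P_o, V = V, states = states)
  tr
}

#' Simulate a phase-structured dye-uptake trace
#'
#' Piecewise-linear mean fluorescence, continuous at phase breakpoints
#' (e.g. control, then a hemichannel-opening trigger, then a blocker), plus
#' Gaussian noise, sampled at fixed intervals (the published assay imaged
#' every 30 s).
#'
#' @param phases data frame with columns `label`, `slope` (AU/min) and
#'   `duration` (min); at least one row.
#' @param noise_sd Gaussian noise (AU).
#' @param sample_interval sampling interval (min, default 0.5).
#' @param f0 starting fluorescence (AU).
#' @param seed integer seed.
#' @return An [uptake_trace()] with phase annotations attached.
#' @export
gen_uptake_trace <- function(phases, noise_sd = 0, sample_interval = 0.5,
                             f0 = 0, seed = 1L) {
  stopifnot(is.data.frame(phases),
            all(c("label", "slope", "duration") %in% names(phases)))
  if (nrow(phases) == 0L) stop("empty phase list", call. = FALSE)
  if (any(phases$duration <= 0)) stop("durations must be > 0", call. = FALSE)
  t_end <- cumsum(phases$duration)
  t_start <- c(0, utils::head(t_end, -1L))
  total <- t_end[length(t_end)]
  time <- seq(0, total, by = sample_interval)
  mean_f <- numeric(length(time))
  level <- f0
  for (i in seq_len(nrow(phases))) {
    inph <- time >= t_start[i] & time <= t_end[i]
    mean_f[inph] <- level + phases$slope[i] * (time[inph] - t_start[i])
    level <- level + phases$slope[i] * phases$duration[i]
  }
  f <- if (noise_sd > 0)
    withr::with_seed(as.integer(seed),
                     mean_f + stats::rnorm(length(time), 0, noise_sd))
  else mean_f
  uptake_trace(time, f,
               data.frame(label = phases$label, t_start = t_start,
                          t_end = t_end, stringsAsFactors = FALSE))
}

#' Generate a pseudo-atom ring pore geometry with known radius oracle
#'
#' Places `n_atoms` pseudo-atoms uniformly on a circle of radius
#' `ring_radius` in the plane z for each ring. With zero jitter the pore
#' radius at a ring plane is exactly `ring_radius - vdw` (closed form),
#' giving an analytic oracle for the profiler.
#'
#' @param rings data frame with columns `z` (Angstrom), `ring_radius`
#'   (Angstrom), `n_atoms` (>= 3) and `vdw` (Angstrom, `< ring_radius`).
#' @param jitter_sd Gaussian positional jitter (Angstrom, default 0).
#' @param seed integer seed (used only when `jitter_sd > 0`).
#' @param pdb_path optional path; when given the geometry is also written
#'   as a PDB file (carbon pseudo-atom records; per-atom radii stay on the
#'   returned [atom_set()]).
#' @return List with `atoms` (an [atom_set()] carrying the exact per-atom
#'   radii) and `oracle` (data frame `z`, `radius` of the analytic radius
#'   at each ring plane, jitter 0).
#' @examples
#' geom <- gen_pore_geometry(data.frame(z = 5, ring_radius = 10,
#'                                      n_atoms = 12, vdw = 1.7))
#' geom$oracle  # radius 8.3 at z = 5
#' @export
gen_pore_geometry <- function(rings, jitter_sd = 0, seed = 1L,
                              pdb_path = NULL) {
  stopifnot(is.data.frame(rings),
            all(c("z", "ring_radius", "n_atoms", "vdw") %in% names(rings)))
  if (nrow(rings) == 0L) stop("need at least one ring", call. = FALSE)
  if (any(rings$vdw < 0) || any(rings$ring_radius <= rings$vdw))
    stop("ring_radius must exceed vdw >= 0", call. = FALSE)
  if (any(rings$n_atoms < 3L)) stop("n_atoms must be >= 3", call. = FALSE)
  build <- function() {
    parts <- lapply(seq_len(nrow(rings)), function(i) {
      k <- rings$n_atoms[i]
      theta <- 2 * pi * (seq_len(k) - 1L) / k
      data.frame(x = rings$ring_radius[i] * cos(theta),
                 y = rings$ring_radius[i] * sin(theta),
                 z = rep(rings$z[i], k),
                 vdw = rep(rings$vdw[i], k))
    })
    do.call(rbind, parts)
  }
  coords <- build()
  if (jitter_sd > 0) {
    coords[, c("x", "y", "z")] <- withr::with_seed(
      as.integer(seed),
      coords[, c("x", "y", "z")] +
        matrix(stats::rnorm(3L * nrow(coords), 0, jitter_sd),
               ncol = 3L))
  }
  atoms <- atom_set(coords$x, coords$y, coords$z, element = "C",
                    vdw = coords$vdw, resid = "RNG")
  if (!is.null(pdb_path)) write_pdb(atoms, pdb_path)
  list(atoms = atoms,
       oracle = data.frame(z = rings$z,
                           radius = rings$ring_radius - rings$vdw))
}
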