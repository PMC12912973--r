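#' Parameters for a synthetic two-state end trajectory
#'
#' A rodlet end alternates between a pause ("dwell") state, during which its
#' position is constant, and a growth ("step") state, during which it advances
#' linearly. Dwell durations, step durations and step length gains are drawn
#' independently from exponential distributions, the renewal-process reading of
#' stop-and-go single-fibril elongation. The track is sampled at the AFM frame
#' interval and i.i.d. Gaussian position noise is added last.
#'
#' @param tau_dwell Mean pause duration (s).
#' @param tau_step Mean growth-phase duration (s).
#' @param mean_step_size Mean length gain per growth phase (nm).
#' @param frame_interval Sampling period (s). Default 12.75 s, the
#'   high-speed-AFM frame time.
#' @param duration Total simulated time (s). Default 1785 s (141 frames,
#'   about 30 min of imaging).
#' @param noise_sigma SD of additive Gaussian position noise (nm). Default
#'   0.3 nm, the order of AFM height/edge noise.
#' @param start_in_dwell Logical; does the trajectory start in a pause phase?
#' @param seed Integer RNG seed or `NULL` to use the current RNG stream.
#' @return An object of class `trajectory_params`.
#' @seealso [gen_end_trajectory()]
#' @export
trajectory_params <- function(tau_dwell, tau_step, mean_step_size,
                              frame_interval = 12.75, duration = 1785,
                              noise_sigma = 0.3, start_in_dwell = TRUE,
                              seed = NULL) {
  check_number(tau_dwell, "tau_dwell", 0, allow_lower = FALSE)
  check_number(tau_step, "tau_step", 0, allow_lower = FALSE)
  check_number(mean_step_size, "mean_step_size", 0, allow_lower = FALSE)
  check_number(frame_interval, "frame_interval", 0, allow_lower = FALSE)
  check_number(duration, "duration", 0, allow_lower = FALSE)
  check_number(noise_sigma, "noise_sigma", 0)
  check_flag(start_in_dwell, "start_in_dwell")
  structure(list(tau_dwell = tau_dwell, tau_step = tau_step,
                 mean_step_size = mean_step_size,
                 frame_interval = frame_interval, duration = duration,
                 noise_sigma = noise_sigma, start_in_dwell = start_in_dwell,
                 seed = check_seed(seed)),
            class = "trajectory_params")
}

#' Parameters for synthetic precursor-height traces
#'
#' Spherical precursors that convert into rodlets show a gradual height
#' increase that plateaus (here a logistic rise); non-converting spheres keep a
#' constant height. Defaults follow the measured values: converting precursors
#' plateau near 2.3 nm, non-converting spheres sit near 3.1 nm.
#'
#' @param plateau_height Upper plateau of converting traces (nm).
#' @param midpoint_time Time of half-rise (s).
#' @param rise_width Logistic rise timescale (s).
#' @param noise_sigma Additive Gaussian noise SD (nm).
#' @param converts Logical; fibril-forming (`TRUE`) or not.
#' @param constant_height Height of non-converting traces (nm).
#' @param n_traces Number of traces to generate.
#' @param duration,frame_interval Time grid: `seq(0, duration, frame_interval)`.
#' @param seed Integer RNG seed or `NULL`.
#' @return An object of class `precursor_params`.
#' @export
precursor_params <- function(plateau_height = 2.3, midpoint_time = 600,
                             rise_width = 120, noise_sigma = 0.2,
                             converts = TRUE, constant_height = 3.1,
                             n_traces = 1, duration = 1800,
                             frame_interval = 12.75, seed = NULL) {
  check_number(plateau_height, "plateau_height", 0, allow_lower = FALSE)
  check_number(midpoint_time, "midpoint_time")
  check_number(rise_width, "rise_width", 0, allow_lower = FALSE)
  check_number(noise_sigma, "noise_sigma", 0)
  check_flag(converts, "converts")
  check_number(constant_height, "constant_height", 0, allow_lower = FALSE)
  check_number(n_traces, "n_traces", 1)
  check_number(duration, "duration", 0, allow_lower = FALSE)
  check_number(frame_interval, "frame_interval", 0, allow_lower = FALSE)
  if (n_traces != round(n_traces)) stop_rk("'n_traces' must be an integer")
  structure(list(plateau_height = plateau_height,
                 midpoint_time = midpoint_time, rise_width = rise_width,
                 noise_sigma = noise_sigma, converts = converts,
                 constant_height = constant_height,
                 n_traces = as.integer(n_traces), duration = duration,
                 frame_interval = frame_interval, seed = check_seed(seed)),
            class = "precursor_params")
}

# draw the latent alternating dwell/step phase sequence up to `duration`;
# the last phase is truncated at `duration` (step deltas prorated)
draw_latent_phases <- function(p) {
  kind <- character(0); dur <- numeric(0); delta <- numeric(0)
  total <- 0; in_dwell <- p$start_in_dwell
  while (total < p$duration) {
    if (in_dwell) {
      d <- rexp(1L, 1 / p$tau_dwell)
      kind <- c(kind, "dwell"); dur <- c(dur, d); delta <- c(delta, 0)
    } else {
      d <- rexp(1L, 1 / p$tau_step)
      s <- rexp(1L, 1 / p$mean_step_size)
      kind <- c(kind, "step"); dur <- c(dur, d); delta <- c(delta, s)
    }
    total <- total + d
    in_dwell <- !in_dwell
  }
  start <- cumsum(c(0, dur[-length(dur)]))
  k <- length(dur)
  truncated <- start[k] + dur[k] > p$duration
  if (truncated) {
    frac <- (p$duration - start[k]) / dur[k]
    delta[k] <- delta[k] * frac
    dur[k] <- p$duration - start[k]
  }
  structure(data.frame(kind = kind, start = start, duration = dur,
                       delta = delta, stringsAsFactors = FALSE),
            truncated_last = truncated)
}

# noiseless piecewise-linear position at arbitrary times
latent_position <- function(latent, tt) {
  cumdelta <- cumsum(c(0, latent$delta))
  idx <- findInterval(tt, latent$start)
  idx[idx < 1L] <- 1L
  frac <- pmin(pmax((tt - latent$start[idx]) / latent$duration[idx], 0), 1)
  cumdelta[idx] + latent$delta[idx] * frac
}

#' Generate a synthetic rodlet-end trajectory
#'
#' Simulates a stop-and-go end-position track: alternating pause and growth
#' phases with exponentially distributed durations and step sizes, sampled at
#' the frame interval, with Gaussian measurement noise added last. The latent
#' ground-truth phase sequence is returned alongside the sampled track so that
#' segmentation and fitting can be validated against it.
#'
#' @param params A [trajectory_params()] object.
#' @param rodlet_id,end_label,category,context Metadata labels attached to the
#'   trajectory (`end_label` one of `"fast"`, `"slow"`, `"unassigned"`;
#'   `category` `"preexisting"` or `"de_novo"`; `context` `"single"` or
#'   `"bundled"`).
#' @return An object of class `end_trajectory` with elements `times`,
#'   `positions`, `latent` (data frame `kind`, `start`, `duration`, `delta`;
#'   attribute `truncated_last` flags a phase cut off at `duration`),
#'   `params` and the metadata labels.
#' @examples
#' p <- trajectory_params(61, 29.7, 26.5, noise_sigma = 0, seed = 1)
#' tr <- gen_end_trajectory(p)
#' all(diff(tr$positions) >= 0)  # noiseless tracks are nondecreasing
#' @export
gen_end_trajectory <- function(params, rodlet_id = "r1",
                               end_label = c("unassigned", "fast", "slow"),
                               category = c("preexisting", "de_novo"),
                               context = c("single", "bundled")) {
  if (!inherits(params, "trajectory_params"))
    stop_rk("'params' must be created by trajectory_params()")
  end_label <- match.arg(end_label)
  category <- match.arg(category)
  context <- match.arg(context)
  with_seed(params$seed, {
    latent <- draw_latent_phases(params)
    times <- seq(0, params$duration, by = params$frame_interval)
    pos <- latent_position(latent, times)
    if (params$noise_sigma > 0)
      pos <- pos + rnorm(length(pos), 0, params$noise_sigma)
    structure(list(times = times, positions = pos, latent = latent,
                   params = params, rodlet_id = rodlet_id,
                   end_label = end_label, category = category,
                   context = context),
              class = "end_trajectory")
  })
}

#' @export
print.end_trajectory <- function(x, ...) {
  cat(sprintf("<end_trajectory> %s/%s (%s, %s): %d frames over %.4g s, %d latent phases\n",
              x$rodlet_id, x$end_label, x$category, x$context,
              length(x$times), max(x$times), nrow(x$latent)))
  invisible(x)
}

#' Generate synthetic precursor-height traces
#'
#' Converting precursors follow a logistic rise
#' `plateau / (1 + exp(-(t - midpoint) / rise_width))` plus noise;
#' non-converting spheres are `constant_height` plus noise.
#'
#' @param params A [precursor_params()] object.
#' @return A list of `height_trace` objects, each with `times`, `heights`
#'   and `converts`.
#' @export
gen_precursor_traces <- function(params) {
  if (!inherits(params, "precursor_params"))
    stop_rk("'params' must be created by precursor_params()")
  with_seed(params$seed, {
    times <- seq(0, params$duration, by = params$frame_interval)
    lapply(seq_len(params$n_traces), function(i) {
      h <- if (params$converts) {
        params$plateau_height /
          (1 + exp(-(times - params$midpoint_time) / params$rise_width))
      } else {
        rep(params$constant_height, length(times))
      }
      if (params$noise_sigma > 0)
        h <- h + rnorm(length(h), 0, params$noise_sigma)
      structure(list(times = times, heights = h, converts = params$converts),
                class = "height_trace")
    })
  })
}

#' Generate a synthetic thioflavin-T fluorescence curve
#'
#' Integrates the dock-lock elongation model and maps rodlet mass affinely to
#' fluorescence, `F(t) = alpha * M(t) + beta + noise`. Without an air-water
#' interface no new open ends are nucleated, so an unseeded reaction stays
#' flat until `interface_on_at`; a seeded reaction (`M0 > 0`) grows from its
#' preformed ends regardless of the interface.
#'
#' @param model A [dock_lock_model()] object.
#' @param times Strictly increasing time grid.
#' @param interface_on_at Time at which the air-water interface is introduced;
#'   `0` for present from the start (default), `Inf` for never.
#' @param noise_sigma SD of additive Gaussian fluorescence noise.
#' @param seed Integer RNG seed or `NULL`.
#' @return An object of class `tht_curve` with `times`, `fluorescence`,
#'   `interface_on_at`, `seeded` and the latent `M` series.
#' @export
gen_tht_curve <- function(model, times, interface_on_at = 0,
                          noise_sigma = 0, seed = NULL) {
  if (!inherits(model, "dock_lock_model"))
    stop_rk("'model' must be created by dock_lock_model()")
  check_times(times)
  check_number(noise_sigma, "noise_sigma", 0)
  M <- simulate_interface_switch(model, interface_on_at, times)
  with_seed(check_seed(seed), {
    fl <- model$alpha * M + model$beta
    if (noise_sigma > 0) fl <- fl + rnorm(length(fl), 0, noise_sigma)
    structure(list(times = times, fluorescence = fl,
                   interface_on_at = interface_on_at,
                   seeded = model$M0 > 0, M = M),
              class = "tht_curve")
  })
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 2L || any(!is.finite(times)) ||
      any(diff(times) <= 0))
    stop_rk("'times' must be a strictly increasing numeric vector")
  times
}

#' Printed kinetic parameter sets for rodlet categories
#'
#' Mean dwell time, step time and step size for the six reported rodlet
#' groups, usable as generator presets (times in s, sizes in nm).
#'
#' @return A data frame with columns `preset`, `tau_dwell`, `tau_step`,
#'   `mean_step_size`.
#' @export
rodlet_presets <- function() {
  data.frame(
    preset = c("preexisting", "de_novo", "fast", "slow", "bundled", "single"),
    tau_dwell = c(61.0, 75.6, 57.6, 95.7, 43.6, 67.1),
    tau_step = c(29.7, 27.3, 27.6, 25.9, 20.6, 31.2),
    mean_step_size = c(26.5, 19.2, 21.7, 18.8, 36.4, 22.2),
    stringsAsFactors = FALSE
  )
}
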