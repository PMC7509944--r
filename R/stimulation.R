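#' Serotonin-binding-protein release kernel R(t)
#'
#' During a stimulation of length `duration` seconds, SBP-serotonin
#' complexes are dumped into the extracellular space at a constant rate and
#' dissociate with first-order rate `b` (/s).  The resulting rate of
#' appearance of free serotonin is
#' `R(t) = 1 - exp(-b t)` for `t <= duration` and
#' `R(t) = exp(-b (t - duration)) - exp(-b t)` afterwards; it is continuous,
#' zero at `t = 0`, and integrates to `duration` (all complex eventually
#' dissociates).
#'
#' @param t time since stimulation onset, in seconds (vectorized); negative
#'   times return 0.
#' @param duration stimulation length in seconds (default 2).
#' @param b SBP dissociation rate in /s (default 1).
#' @return dimensionless kernel values.
#' @examples
#' release_kernel_R(2)            # 1 - exp(-2)
#' integrate(release_kernel_R, 0, 60)$value  # ~2
#' @export
release_kernel_R <- function(t, duration = 2, b = 1) {
  if (duration <= 0) stop("duration must be positive")
  if (b <= 0) stop("b must be positive")
  ifelse(t <= 0, 0,
         ifelse(t <= duration, 1 - exp(-b * t),
                exp(-b * (t - duration)) - exp(-b * t)))
}

#' Stimulation protocol
#'
#' Describes a single square-pulse stimulation: onset and duration on the
#' seconds clock, strength `r` (dimensionless multiple of the release
#' kernel), SBP dissociation rate `b`, and the basal firing rate.
#'
#' @param onset_s stimulation onset, seconds from recording start.
#' @param duration_s stimulation length in seconds.
#' @param r stimulation strength (0 = no stimulation).
#' @param b SBP dissociation rate (/s).
#' @param f_basal basal firing rate (/h).
#' @return list of class `stim_protocol`.
#' @export
stim_protocol <- function(onset_s = 5, duration_s = 2, r = 0, b = 1,
                          f_basal = 1) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (b <= 0) stop("b must be positive")
  if (r < 0) stop("r must be non-negative")
  structure(list(onset_s = onset_s, duration_s = duration_s, r = r, b = b,
                 f_basal = f_basal), class = "stim_protocol")
}

#' Firing rate fire(t)
#'
#' `fire(t) = f_basal + r * R(t - onset)`: basal firing plus the
#' SBP-shaped release transient.  Continuous in `t` (the kernel vanishes at
#' onset).
#'
#' @param t_s time in seconds from recording start (vectorized).
#' @param protocol a [stim_protocol()].
#' @return firing rate in /h.
#' @export
fire_rate <- function(t_s, protocol) {
  protocol$f_basal + protocol$r *
    release_kernel_R(t_s - protocol$onset_s, protocol$duration_s, protocol$b)
}

#' Meal-driven blood tryptophan forcing
#'
#' Blood tryptophan is doubled (relative to the daily mean) for a fixed
#' window after each meal (2 h after breakfast and lunch, 3 h after dinner
#' by default) and is correspondingly lower between meals, with the
#' between-meal level chosen so that the 24 h mean equals `mean_btrp`
#' exactly: `high = 2 * mean`,
#' `low = (24 - 2 * sum(durations)) * mean / (24 - sum(durations))`.
#'
#' @param meal_times_h meal onsets within one 24 h day (hours).
#' @param durations_h elevated-window lengths (hours), same length as
#'   `meal_times_h`.
#' @param mean_btrp the 24 h mean blood tryptophan (uM).
#' @param days number of days the forcing should cover (for the breakpoint
#'   list; the function itself is 24 h-periodic).
#' @return function of time (h) returning btrp (uM), 24 h-periodic, with a
#'   `breaks` attribute listing its discontinuities over `days` days.
#' @examples
#' f <- meal_btrp()
#' mean(f(seq(0, 24, by = 1 / 64)[-1]))  # ~96
#' @export
meal_btrp <- function(meal_times_h = c(7, 12, 18), durations_h = c(2, 2, 3),
                      mean_btrp = 96, days = 2) {
  if (length(meal_times_h) != length(durations_h))
    stop("meal_times_h and durations_h must have the same length")
  if (any(meal_times_h < 0) || any(meal_times_h + durations_h > 24))
    stop("meal windows must lie within one 24 h day")
  o <- order(meal_times_h)
  meal_times_h <- meal_times_h[o]; durations_h <- durations_h[o]
  ends <- meal_times_h + durations_h
  if (any(meal_times_h[-1] < ends[-length(ends)]))
    stop("meal windows overlap")
  high <- 2 * mean_btrp
  low <- (24 * mean_btrp - sum(durations_h) * high) / (24 - sum(durations_h))
  f <- function(t) {
    td <- t %% 24
    elevated <- rep(FALSE, length(td))
    for (i in seq_along(meal_times_h))
      elevated <- elevated | (td >= meal_times_h[i] & td < ends[i])
    ifelse(elevated, high, low)
  }
  attr(f, "breaks") <- sort(as.vector(outer(c(meal_times_h, ends),
                                            24 * (seq_len(days) - 1), "+")))
  attr(f, "levels") <- c(low = low, high = high)
  f
}

#' Extracellular histamine pulse forcing
#'
#' The histamine time course accompanying a stimulation is not part of the
#' model; this parameterized stand-in adds a step-and-exponential-decay bump
#' to the constant baseline (integral above baseline =
#' `amplitude * decay_s`), or interpolates a user-supplied tabulated curve.
#'
#' @param baseline constant baseline eha (uM).
#' @param amplitude pulse height (uM); 0 gives the constant baseline.
#' @param onset_s pulse onset (s).
#' @param decay_s exponential decay constant (s).
#' @param table optional data.frame with columns `t_s`, `eha` tabulating the
#'   curve; when supplied it overrides the parametric family (linear
#'   interpolation, constant extrapolation).
#' @return function of time (h) returning eha (uM).
#' @export
eha_pulse <- function(baseline = 1.39, amplitude = 0, onset_s = 5,
                      decay_s = 5, table = NULL) {
  if (!is.null(table)) {
    af <- stats::approxfun(table$t_s, table$eha, rule = 2)
    return(function(t) af(t * 3600))
  }
  function(t) {
    ts <- t * 3600 - onset_s
    baseline + ifelse(ts < 0, 0, amplitude * exp(-ts / decay_s))
  }
}

#' Named response presets
#'
#' Parameter overrides reproducing the fitted average stimulation responses:
#' `male`/`female` (hippocampus CA2) and `fast`/`hybrid`/`slow`
#' (substantia nigra pars reticulata).  Presets are stored as JSON under
#' `inst/extdata/presets/` and mirror the published preset tables
#' cell-for-cell; each contains parameter overrides plus the protocol
#' strength `r`.
#'
#' @param name preset name, or `"custom"` with explicit `overrides`/`r`.
#' @param overrides named list of parameter overrides (custom presets).
#' @param r stimulation strength (custom presets).
#' @return list of class `sero_preset` with fields `name`, `overrides`, `r`.
#' @export
sero_preset <- function(name = c("male", "female", "fast", "hybrid", "slow",
                                 "custom"),
                        overrides = list(), r = 0) {
  name <- match.arg(name)
  if (name == "custom")
    return(structure(list(name = name, overrides = overrides, r = r),
                     class = "sero_preset"))
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "serosim")
  if (path == "") stop("preset file not found for '", name, "'")
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(name = name, overrides = as.list(spec$overrides),
                 r = spec$r), class = "sero_preset")
}

#' Simulate a stimulation response curve
#'
#' Equilibrates the model under the preset's parameters (self-anchored
#' steady state), then integrates the stimulated system over the recording
#' window and reports extracellular serotonin relative to the pre-stimulus
#' baseline, in nM, on the seconds clock.
#'
#' @param preset a [sero_preset()] (or a parameter-override list).
#' @param protocol a [stim_protocol()]; its `r` defaults to the preset's.
#' @param params base parameter set the preset overrides are applied to.
#' @param record_window_s length of the recording (s).
#' @param dt_s output resolution (s).
#' @param forcings optional [sero_forcings()] (e.g. a histamine pulse); by
#'   default both forcings are constant at the preset's baseline values.
#' @param keep_state if `TRUE` the returned object also carries the full
#'   state trajectory (receptor species included).
#' @return data.frame of class `sero_response` with columns `t_s`,
#'   `delta_eht_nM`; attributes `baseline_eht_nM`, `preset`, `protocol`,
#'   and optionally `trajectory`.
#' @examples
#' \donttest{
#' resp <- simulate_response(sero_preset("male"))
#' max(resp$delta_eht_nM)
#' }
#' @export
simulate_response <- function(preset, protocol = NULL,
                              params = sero_params(), record_window_s = 30,
                              dt_s = 0.05, forcings = NULL,
                              keep_state = FALSE) {
  if (!inherits(preset, "sero_preset"))
    preset <- sero_preset("custom", overrides = as.list(preset))
  p <- do.call(sero_params, utils::modifyList(unclass(params),
                                              preset$overrides))
  if (is.null(protocol))
    protocol <- stim_protocol(r = preset$r, f_basal = p$f_basal,
                              b = p$b_sbp)
  eq <- compute_equilibrium(p)
  if (is.null(forcings)) forcings <- sero_forcings(p)
  fire_fun <- function(t_h) fire_rate(t_h * 3600, protocol)
  times <- seq(0, record_window_s, by = dt_s) / 3600
  tr <- sero_simulate(eq$state, p, eq$anchors, forcings, fire_fun, times)
  baseline_nm <- 1000 * eq$state[["eht"]]
  out <- data.frame(t_s = tr$time_h * 3600,
                    delta_eht_nM = 1000 * tr$eht - baseline_nm)
  attr(out, "baseline_eht_nM") <- baseline_nm
  attr(out, "preset") <- preset
  attr(out, "protocol") <- protocol
  if (keep_state) attr(out, "trajectory") <- tr
  class(out) <- c("sero_response", "data.frame")
  out
}
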