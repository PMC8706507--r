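#' Configuration of the intravaginal probe firmware
#'
#' Parameters of the trigger logic: after activation the probe stays
#' suspended (performing no checks) for `suspension_minutes`; it then
#' monitors for light above `light_threshold` — the photodetector responds
#' even at dusk-level brightness, so the default threshold is low — or a
#' temperature change of at least `temp_gradient_threshold` degrees C per
#' minute in either direction (expulsion from the vagina exposes the probe
#' to ambient temperature). The electronics are rated for
#' `operating_range`; readings outside it are flagged with a warning but do
#' not halt the simulation.
#'
#' @param suspension_minutes Countdown after activation during which no
#'   checks are performed (default 60).
#' @param light_threshold Illumination level (arbitrary units) above which
#'   light is detected.
#' @param temp_gradient_threshold Absolute temperature slope (degrees C per
#'   minute) counting as a sudden change.
#' @param operating_range Rated temperature interval, degrees C.
#' @return A `probe_config` object.
#' @export
probe_config <- function(suspension_minutes = 60, light_threshold = 5,
                         temp_gradient_threshold = 1,
                         operating_range = c(-20, 55)) {
  stopifnot(suspension_minutes > 0, light_threshold > 0,
            temp_gradient_threshold > 0, length(operating_range) == 2L,
            operating_range[1] < operating_range[2])
  structure(list(suspension_minutes = suspension_minutes,
                 light_threshold = light_threshold,
                 temp_gradient_threshold = temp_gradient_threshold,
                 operating_range = operating_range),
            class = "probe_config")
}

#' Central unit managing up to six probes
#'
#' The base station registers probes (assigning each a progressive number),
#' receives their radio expulsion signals and converts them into SMS and
#' phone-call alerts through the GSM network. It can manage at most six
#' probes simultaneously. All state is carried functionally: operations
#' return an updated copy of the unit.
#'
#' @param gsm_available Logical: is the GSM network reachable? Dispatching
#'   with GSM down produces an undelivered alert (the failure mode behind
#'   missed alarms in the field).
#' @param contacts Character vector of user contacts.
#' @return A `central_unit` object.
#' @export
central_unit <- function(gsm_available = TRUE,
                         contacts = c("farmer")) {
  structure(list(probes = list(), gsm_available = isTRUE(gsm_available),
                 contacts = contacts, next_number = 1L),
            class = "central_unit")
}

#' @export
print.central_unit <- function(x, ...) {
  cat(sprintf("Central unit: %d/6 probes registered, GSM %s\n",
              length(x$probes),
              if (x$gsm_available) "available" else "unavailable"))
  for (p in x$probes) {
    cat(sprintf("  #%d %s: %s\n", p$number, p$id, p$state))
  }
  invisible(x)
}

#' Activate and register an intravaginal probe
#'
#' Registers the probe with the central unit, assigns the next progressive
#' number and starts the suspension countdown at `t0`. A unit already
#' holding six probes, or a duplicate probe id, is an error.
#'
#' @param unit A [central_unit()].
#' @param probe_id Unique probe identifier.
#' @param config A [probe_config()].
#' @param t0 Activation time, minutes.
#' @return The updated `central_unit`; the new probe is in state
#'   `"suspended"`.
#' @export
activate_probe <- function(unit, probe_id, config = probe_config(), t0 = 0) {
  stopifnot(inherits(unit, "central_unit"))
  if (length(unit$probes) >= 6L) {
    stop("central unit capacity exceeded: can manage at most 6 probes",
         call. = FALSE)
  }
  if (probe_id %in% names(unit$probes)) {
    stop("probe '", probe_id, "' is already registered", call. = FALSE)
  }
  probe <- structure(
    list(id = probe_id, number = unit$next_number, state = "suspended",
         config = config, t0 = t0, last_time = NULL, last_temp = NULL,
         signalled = FALSE),
    class = "probe"
  )
  unit$probes[[probe_id]] <- probe
  unit$next_number <- unit$next_number + 1L
  unit
}

#' Advance a probe by one sensor reading
#'
#' Implements the firmware transition rules. During the suspension
#' countdown the probe performs no checks regardless of the readings. Once
#' monitoring, a light level above the threshold or an absolute temperature
#' slope (first difference over the previous reading) at or above the
#' gradient threshold ejects the probe, which emits exactly one expulsion
#' signal and then turns off autonomously; `"off"` is absorbing. Reading
#' times must be strictly increasing.
#'
#' @param probe A probe as stored in a [central_unit()].
#' @param time Reading time, minutes (>` previous reading time).
#' @param light Illumination level.
#' @param temperature Temperature, degrees C.
#' @return List with `probe` (updated) and `signal` (`NULL`, or a list with
#'   `probe_id` and `time` when the probe ejects).
#' @export
probe_step <- function(probe, time, light, temperature) {
  stopifnot(inherits(probe, "probe"))
  if (!is.null(probe$last_time) && time <= probe$last_time) {
    stop("reading times must be strictly increasing (", time, " after ",
         probe$last_time, ")", call. = FALSE)
  }
  cfg <- probe$config
  if (temperature < cfg$operating_range[1] ||
        temperature > cfg$operating_range[2]) {
    warning("temperature ", temperature,
            " degrees C outside rated operating range", call. = FALSE)
  }
  signal <- NULL
  if (probe$state == "ejected") {
    probe$state <- "off"                    # turns off after signalling
  } else if (probe$state == "suspended") {
    if (time >= probe$t0 + cfg$suspension_minutes) {
      probe$state <- "monitoring"
    }
  }
  if (probe$state == "monitoring") {
    slope <- if (is.null(probe$last_temp)) 0 else
      (temperature - probe$last_temp) / (time - probe$last_time)
    if (light > cfg$light_threshold ||
          abs(slope) >= cfg$temp_gradient_threshold) {
      if (!probe$signalled) {
        probe$state <- "ejected"
        probe$signalled <- TRUE
        signal <- list(probe_id = probe$id, time = time)
      }
    }
  }
  probe$last_time <- time
  probe$last_temp <- temperature
  list(probe = probe, signal = signal)
}

#' Dispatch a probe expulsion signal as a phone alert
#'
#' Converts a radio expulsion signal into an alert to the user contacts.
#' With GSM available the alert goes out on both channels (SMS and phone
#' call); with GSM unavailable the alert is recorded as undelivered — the
#' mechanism behind alarms missed in the field despite correct probe
#' triggering.
#'
#' @param unit A [central_unit()].
#' @param signal Signal list from [probe_step()]/[simulate_probe()].
#' @return An `alert_event`: list with `probe_id`, `time`, `channels`
#'   (subset of `c("SMS", "call")`) and `delivered` (logical).
#' @export
dispatch_alert <- function(unit, signal) {
  stopifnot(inherits(unit, "central_unit"))
  if (!signal$probe_id %in% names(unit$probes)) {
    stop("signal from unregistered probe '", signal$probe_id, "'",
         call. = FALSE)
  }
  delivered <- unit$gsm_available
  structure(
    list(probe_id = signal$probe_id, time = signal$time,
         channels = if (delivered) c("SMS", "call") else character(0),
         delivered = delivered),
    class = "alert_event"
  )
}

#' @export
print.alert_event <- function(x, ...) {
  if (x$delivered) {
    cat(sprintf("Alert from probe %s at %.1f min via %s\n", x$probe_id,
                x$time, paste(x$channels, collapse = "+")))
  } else {
    cat(sprintf("Alert from probe %s at %.1f min NOT delivered (GSM down)\n",
                x$probe_id, x$time))
  }
  invisible(x)
}

#' Simulate a probe over a full signal trace
#'
#' Folds the [probe_step()] transition rules over an ordered signal trace
#' and dispatches at most one alert per probe. Implemented vectorised for
#' speed; the semantics are identical to stepping sample by sample (the
#' test suite asserts this equivalence on random traces).
#'
#' @param trace Data frame with columns `time_min`, `light`, `temp_c`,
#'   strictly increasing in time.
#' @param config A [probe_config()].
#' @param unit A [central_unit()]; defaults to a fresh unit with GSM up.
#' @param probe_id Probe identifier to register.
#' @param t0 Activation time, minutes.
#' @return An `alert_event` (see [dispatch_alert()]) if the probe ejected,
#'   otherwise `NULL`.
#' @export
simulate_probe <- function(trace, config = probe_config(), unit = NULL,
                           probe_id = "probe-1", t0 = 0) {
  req <- c("time_min", "light", "temp_c")
  if (!is.data.frame(trace) || !all(req %in% names(trace))) {
    stop("trace must be a data frame with columns time_min, light, temp_c",
         call. = FALSE)
  }
  t <- trace$time_min
  if (nrow(trace) && (any(diff(t) <= 0))) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  if (is.null(unit)) unit <- central_unit()
  unit <- activate_probe(unit, probe_id, config, t0)
  if (!nrow(trace)) return(NULL)
  if (any(trace$temp_c < config$operating_range[1] |
            trace$temp_c > config$operating_range[2])) {
    warning("trace contains temperatures outside the rated operating range",
            call. = FALSE)
  }
  monitoring <- t >= t0 + config$suspension_minutes
  slope <- c(0, diff(trace$temp_c) / diff(t))
  trigger <- monitoring & (trace$light > config$light_threshold |
                             abs(slope) >= config$temp_gradient_threshold)
  hit <- which(trigger)
  if (!length(hit)) return(NULL)
  dispatch_alert(unit, list(probe_id = probe_id, time = t[hit[1]]))
}
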