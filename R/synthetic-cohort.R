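# --- truncated-normal machinery ---------------------------------------------

# Mean and sd of a normal(mu, sigma) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  if (Z <= 0) return(c(mean = NA_real_, sd = NA_real_))
  d <- (stats::dnorm(al) - stats::dnorm(be)) / Z
  m <- mu + sigma * d
  v <- sigma^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z -
                    d^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Moment-matched truncated normal parameters
#'
#' Finds underlying normal parameters `(mu, sigma)` such that the
#' distribution truncated to `[lower, upper]` has (as nearly as possible)
#' the requested mean and standard deviation. Matching the *truncated*
#' moments matters whenever the truncation bounds bite: parameterising a
#' truncated normal naively at the target mean/sd shifts the realised mean
#' by several units for the interval distributions used here. Some targets
#' are infeasible — no truncated normal on `[a, b]` has sd above the uniform
#' limit `(b - a)/sqrt(12)` — in which case the least-squares optimum is
#' returned together with the achieved moments.
#'
#' @param mean,sd Target truncated mean and standard deviation.
#' @param lower,upper Truncation bounds.
#' @return List with `mu`, `sigma`, `achieved_mean`, `achieved_sd`.
#' @export
match_truncnorm <- function(mean, sd, lower, upper) {
  stopifnot(lower < upper, sd > 0, mean > lower, mean < upper)
  range <- upper - lower
  obj <- function(par) {
    m <- truncnorm_moments(par[1], exp(par[2]), lower, upper)
    if (anyNA(m)) return(1e12)
    (m[["mean"]] - mean)^2 + (m[["sd"]] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "L-BFGS-B",
                      lower = c(lower - 20 * range, log(sd) - 8),
                      upper = c(upper + 20 * range, log(20 * range)))
  ach <- truncnorm_moments(fit$par[1], exp(fit$par[2]), lower, upper)
  list(mu = fit$par[1], sigma = exp(fit$par[2]),
       achieved_mean = unname(ach[["mean"]]),
       achieved_sd = unname(ach[["sd"]]))
}

# Inverse-CDF sampler for the truncated normal.
rtruncnorm <- function(n, mu, sigma, a, b) {
  lo <- stats::pnorm((a - mu) / sigma)
  hi <- stats::pnorm((b - mu) / sigma)
  mu + sigma * stats::qnorm(stats::runif(n, lo, hi))
}

# Truncated lognormal sampler with moments matched on the log scale only
# approximately; provided as an alternative family.
rtrunclnorm <- function(n, mean, sd, a, b) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  lo <- stats::plnorm(max(a, .Machine$double.eps), meanlog, sdlog)
  hi <- stats::plnorm(b, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, lo, hi), meanlog, sdlog)
}

# --- cohort configuration ----------------------------------------------------

interval_spec <- function(mean, sd, min, max) {
  stopifnot(min < max, sd > 0, mean > min, mean < max)
  list(mean = mean, sd = sd, min = min, max = max)
}

#' Configuration of the synthetic calving cohort generator
#'
#' Defaults reproduce the statistical structure observed in the field
#' evaluation of the sensor: alarms succeed with probability 0.863 (misses
#' are attributed to GSM dispatch failures, not trigger failures); 19/63 of
#' alarmed deliveries show dystocia, split 10:5:4 over severity scores 1-3
#' with no score-4 cases; alarm-to-expulsion intervals are truncated normal
#' with (truncated) mean 57, sd 33 on 15-146 min for eutocia and mean 80,
#' sd 30 on 24-126 min for dystocia; application-to-calving spans mean 5.10,
#' sd 3.58, 0-18 days; and 33.8% of alerts fall in the 22:00-06:00 night
#' window (uniform within windows).
#'
#' @param n_cows Number of monitored deliveries.
#' @param seed Integer seed; mandatory, every draw is reproducible.
#' @param p_alarm Probability an alarm is received.
#' @param p_dystocia_given_alarm Dystocia probability (any score >= 1).
#' @param score_split_given_dystocia Proportions over scores 1-4 given
#'   dystocia; must sum to 1.
#' @param eutocia_interval,dystocia_interval,days_to_calving Lists with
#'   `mean`, `sd`, `min`, `max` (minutes for intervals, days for spans);
#'   targets refer to the truncated distribution.
#' @param night_share_22_06 Share of alert times in 22:00-06:00.
#' @param parity_primiparous Share of primiparous dams.
#' @param p_sorted_primi,p_beef_pluri Semen-type probabilities by parity.
#' @param gsm_failure_prob Probability GSM dispatch fails, used by the
#'   end-to-end probe simulation; defaults to `1 - p_alarm`.
#' @param interval_family `"truncnorm"` (moment-matched, default) or
#'   `"lognormal"`.
#' @return A `cohort_config` object with the moment-matched sampler
#'   parameters precomputed.
#' @export
cohort_config <- function(n_cows,
                          seed,
                          p_alarm = 0.863,
                          p_dystocia_given_alarm = 19 / 63,
                          score_split_given_dystocia =
                            c(10 / 19, 5 / 19, 4 / 19, 0),
                          eutocia_interval = interval_spec(57, 33, 15, 146),
                          dystocia_interval = interval_spec(80, 30, 24, 126),
                          days_to_calving = interval_spec(5.10, 3.58, 0, 18),
                          night_share_22_06 = 0.338,
                          parity_primiparous = 0.35,
                          p_sorted_primi = 0.85,
                          p_beef_pluri = 0.15,
                          gsm_failure_prob = NULL,
                          interval_family = c("truncnorm", "lognormal")) {
  if (missing(seed)) stop("an explicit integer seed is required",
                          call. = FALSE)
  interval_family <- match.arg(interval_family)
  stopifnot(n_cows >= 1, seed == round(seed))
  fracs <- list(p_alarm = p_alarm,
                p_dystocia_given_alarm = p_dystocia_given_alarm,
                night_share_22_06 = night_share_22_06,
                parity_primiparous = parity_primiparous,
                p_sorted_primi = p_sorted_primi, p_beef_pluri = p_beef_pluri)
  for (nm in names(fracs)) {
    v <- fracs[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop("'", nm, "' must be a fraction in [0, 1]", call. = FALSE)
    }
  }
  if (length(score_split_given_dystocia) != 4L ||
        any(score_split_given_dystocia < 0) ||
        abs(sum(score_split_given_dystocia) - 1) > 1e-9) {
    stop("'score_split_given_dystocia' must be 4 proportions over scores ",
         "1-4 summing to 1", call. = FALSE)
  }
  eutocia_interval <- do.call(interval_spec, eutocia_interval[c(
    "mean", "sd", "min", "max")])
  dystocia_interval <- do.call(interval_spec, dystocia_interval[c(
    "mean", "sd", "min", "max")])
  days_to_calving <- do.call(interval_spec, days_to_calving[c(
    "mean", "sd", "min", "max")])
  if (is.null(gsm_failure_prob)) gsm_failure_prob <- 1 - p_alarm
  if (gsm_failure_prob < 0 || gsm_failure_prob > 1) {
    stop("'gsm_failure_prob' must be a fraction in [0, 1]", call. = FALSE)
  }
  cfg <- list(n_cows = as.integer(n_cows), seed = as.integer(seed),
              p_alarm = p_alarm,
              p_dystocia_given_alarm = p_dystocia_given_alarm,
              score_split_given_dystocia = score_split_given_dystocia,
              eutocia_interval = eutocia_interval,
              dystocia_interval = dystocia_interval,
              days_to_calving = days_to_calving,
              night_share_22_06 = night_share_22_06,
              parity_primiparous = parity_primiparous,
              p_sorted_primi = p_sorted_primi, p_beef_pluri = p_beef_pluri,
              gsm_failure_prob = gsm_failure_prob,
              interval_family = interval_family)
  if (interval_family == "truncnorm") {
    cfg$matched <- lapply(
      list(eutocia = eutocia_interval, dystocia = dystocia_interval,
           days = days_to_calving),
      function(s) match_truncnorm(s$mean, s$sd, s$min, s$max))
  }
  structure(cfg, class = "cohort_config")
}

# Draw n interval values for one spec under the configured family.
draw_interval <- function(n, spec, matched, family) {
  if (n == 0L) return(numeric(0))
  if (family == "truncnorm") {
    rtruncnorm(n, matched$mu, matched$sigma, spec$min, spec$max)
  } else {
    rtrunclnorm(n, spec$mean, spec$sd, spec$min, spec$max)
  }
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# APGAR component probabilities by dystocia score: eutocic calves are almost
# all fully vital; severity shifts mass from 2 toward 1 and 0.
apgar_probs <- function(score) {
  p2 <- max(0.25, 0.95 - 0.15 * score)
  p1 <- min(0.6, 0.04 + 0.12 * score)
  c(`0` = 1 - p2 - p1, `1` = p1, `2` = p2)
}

#' Generate a synthetic calving cohort
#'
#' Draws `n_cows` monitored deliveries under a [cohort_config()]:
#' alarms are Bernoulli(`p_alarm`); dystocia occurs at
#' `p_dystocia_given_alarm` with the configured severity split (score 0 is
#' eutocia by definition); alarm-to-expulsion intervals come from the
#' configured truncated distribution of the matching severity group and are
#' present only for alarmed deliveries; application-to-calving spans and
#' alert clock times (two-window night/day mixture) follow the config.
#' APGAR components degrade stochastically with dystocia severity. The
#' output is fully reproducible from the seed.
#'
#' @param config A [cohort_config()].
#' @return A `calving_cohort` data frame, one row per delivery, with columns
#'   `cow_id`, `parity`, `semen_type`, `calf_sex`, `alarm`,
#'   `dystocia_score`, `days_to_calving`, `alarm_to_expulsion_min`,
#'   `alert_time` (decimal hours) and the five `apgar_*` components.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_cows = 73, seed = 1))
#' mean(cohort$alarm)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_cows
  with_seed(config$seed, {
    parity <- ifelse(stats::runif(n) < config$parity_primiparous,
                     "primiparous", "pluriparous")
    semen <- ifelse(parity == "primiparous",
                    ifelse(stats::runif(n) < config$p_sorted_primi,
                           "sorted", "conventional_dairy"),
                    ifelse(stats::runif(n) < config$p_beef_pluri,
                           "beef", "conventional_dairy"))
    p_female <- ifelse(semen == "sorted", 1, 0.516 / 1.001)
    calf_sex <- ifelse(stats::runif(n) < p_female, "female", "male")
    alarm <- stats::runif(n) < config$p_alarm
    dystocia <- stats::runif(n) < config$p_dystocia_given_alarm
    score <- integer(n)
    nd <- sum(dystocia)
    if (nd > 0) {
      score[dystocia] <- sample(1:4, nd, replace = TRUE,
                                prob = config$score_split_given_dystocia)
    }
    days <- round(draw_interval(n, config$days_to_calving,
                                config$matched$days,
                                config$interval_family), 2)
    expulsion <- rep(NA_real_, n)
    idx_e <- which(alarm & score == 0L)
    idx_d <- which(alarm & score > 0L)
    expulsion[idx_e] <- round(draw_interval(
      length(idx_e), config$eutocia_interval, config$matched$eutocia,
      config$interval_family), 2)
    expulsion[idx_d] <- round(draw_interval(
      length(idx_d), config$dystocia_interval, config$matched$dystocia,
      config$interval_family), 2)
    night <- stats::runif(n) < config$night_share_22_06
    u <- stats::runif(n)
    alert <- ifelse(night,
                    ifelse(u * 8 < 2, 22 + u * 8, u * 8 - 2),  # 22:00-06:00
                    6 + u * 16)                                 # 06:00-22:00
    alert <- round(alert, 4)
    alert[!alarm] <- NA_real_
    ap <- vapply(score, function(s) {
      pr <- apgar_probs(s)
      sample(0:2, 5L, replace = TRUE, prob = pr)
    }, integer(5))
    out <- data.frame(
      cow_id = sprintf("cow-%04d", seq_len(n)),
      parity = parity, semen_type = semen, calf_sex = calf_sex,
      alarm = alarm, dystocia_score = score, days_to_calving = days,
      alarm_to_expulsion_min = expulsion, alert_time = alert,
      apgar_mucous_membranes = ap[1, ], apgar_heart_rate = ap[2, ],
      apgar_muscle_tone = ap[3, ], apgar_activity = ap[4, ],
      apgar_respiration = ap[5, ],
      stringsAsFactors = FALSE
    )
    class(out) <- c("calving_cohort", "data.frame")
    out
  })
}

#' Generate a signal trace re-enacting one monitored delivery
#'
#' Builds the per-minute light/temperature series an intravaginal probe
#' would record for a delivery: darkness and stable body temperature
#' (~38.5 degrees C) until the probe is expelled at the start of stage II of
#' labor, then a light step above the detection threshold and a temperature
#' ramp toward ambient. The multi-day application-to-calving span is
#' compressed to a minutes-scale re-enactment; by default expulsion falls at
#' `suspension + U(15, 180)` minutes after activation so the probe is out of
#' its countdown when the event occurs. Non-alarmed deliveries still contain
#' the physical event — in the field those alarms were lost at GSM dispatch,
#' not at the trigger — so failure is injected in [dispatch_alert()], never
#' in the trace.
#'
#' @param record One-row slice of a [generate_cohort()] data frame (or any
#'   list with the same fields).
#' @param config A [probe_config()].
#' @param seed Integer seed.
#' @param expulsion_min Minutes from activation to probe expulsion; default
#'   drawn as described above.
#' @param ambient_temp Ambient temperature the probe cools toward, deg C.
#' @return A `signal_trace` data frame with columns `time_min`, `light`,
#'   `temp_c`, sampled once per minute from activation to 10 min past
#'   expulsion.
#' @export
generate_trace <- function(record, config = probe_config(), seed,
                           expulsion_min = NULL, ambient_temp = 20) {
  if (missing(seed)) stop("an explicit integer seed is required",
                          call. = FALSE)
  with_seed(seed, {
    if (is.null(expulsion_min)) {
      expulsion_min <- config$suspension_minutes + stats::runif(1, 15, 180)
    }
    times <- seq(0, ceiling(expulsion_min) + 10)
    n <- length(times)
    dark <- stats::runif(n, 0, 0.1 * config$light_threshold)
    light <- ifelse(times >= expulsion_min, 10 * config$light_threshold +
                      stats::runif(n, 0, config$light_threshold), dark)
    body <- 38.5 + stats::rnorm(n, 0, 0.05)
    cooled <- pmax(ambient_temp,
                   38.5 - 3 * (times - expulsion_min))
    temp <- ifelse(times >= expulsion_min, cooled, body)
    out <- data.frame(time_min = times, light = round(light, 3),
                      temp_c = round(temp, 3))
    class(out) <- c("signal_trace", "data.frame")
    out
  })
}

cohort_columns <- c(
  "cow_id", "parity", "semen_type", "calf_sex", "alarm", "dystocia_score",
  "days_to_calving", "alarm_to_expulsion_min", "alert_time",
  "apgar_mucous_membranes", "apgar_heart_rate", "apgar_muscle_tone",
  "apgar_activity", "apgar_respiration"
)

#' Write and read a calving cohort as CSV
#'
#' Fixed-header UTF-8 CSV round trip: `read_cohort_csv(write_cohort_csv(x))`
#' returns a data frame identical to `x`. Reading validates each row —
#' negative intervals or spans, out-of-range scores, an expulsion interval
#' on a non-alarmed delivery — and rejects the file naming the offending
#' line.
#'
#' @param records A `calving_cohort` data frame (may have zero rows).
#' @param path Output/input file path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a `calving_cohort` data frame.
#' @export
write_cohort_csv <- function(records, path) {
  if (!all(cohort_columns %in% names(records))) {
    stop("records is missing cohort columns: ",
         paste(setdiff(cohort_columns, names(records)), collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(as.data.frame(records)[, cohort_columns], path,
                   row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8",
                        colClasses = c(cow_id = "character"))
  if (!identical(names(df), cohort_columns)) {
    stop("unexpected CSV header in ", path, "; expected: ",
         paste(cohort_columns, collapse = ","), call. = FALSE)
  }
  for (col in c("days_to_calving", "alarm_to_expulsion_min", "alert_time")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$dystocia_score <- as.integer(df$dystocia_score)
  if (nrow(df)) {
    df$alarm <- as.logical(df$alarm)
    for (i in seq_len(nrow(df))) {
      line <- i + 1L                    # header is line 1
      bad <- function(msg) stop("malformed row at line ", line, ": ", msg,
                                call. = FALSE)
      if (is.na(df$alarm[i])) bad("alarm must be TRUE/FALSE")
      if (is.na(df$dystocia_score[i]) ||
            !df$dystocia_score[i] %in% 0:4) bad("dystocia_score not in 0..4")
      if (is.na(df$days_to_calving[i]) || df$days_to_calving[i] < 0) {
        bad("negative or missing days_to_calving")
      }
      if (df$alarm[i]) {
        if (is.na(df$alarm_to_expulsion_min[i]) ||
              df$alarm_to_expulsion_min[i] < 0) {
          bad("alarmed delivery needs a non-negative alarm_to_expulsion_min")
        }
      } else if (!is.na(df$alarm_to_expulsion_min[i])) {
        bad("alarm_to_expulsion_min present without an alarm")
      }
    }
  }
  class(df) <- c("calving_cohort", "data.frame")
  df
}
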