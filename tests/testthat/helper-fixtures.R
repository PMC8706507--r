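# Fixtures built in code: the field cohort reconstructed from its published
# category counts, and a seeded random-tree generator for oracle tests.

# Expand cohort counts into per-delivery records. Difficulty scores were
# recorded for the alarmed (monitored) deliveries only, so they sum to
# n_alarm; the missed-alarm rows carry NA scores, matching how the field
# data were tabulated (score rates against the full cohort size).
cohort_from_counts <- function(n_total = 73, n_alarm = 63,
                               scores = c(`0` = 44, `1` = 10, `2` = 5,
                                          `3` = 4, `4` = 0)) {
  stopifnot(sum(scores) == n_alarm, n_alarm <= n_total)
  score <- c(rep(0:4, times = scores), rep(NA_integer_, n_total - n_alarm))
  alarm <- c(rep(TRUE, n_alarm), rep(FALSE, n_total - n_alarm))
  data.frame(cow_id = sprintf("cow-%02d", seq_len(n_total)),
             alarm = alarm, dystocia_score = score,
             stringsAsFactors = FALSE)
}

# Random decision tree with bounded depth/branching; terminal payoffs in
# [-100, 250]. kinds are drawn with terminal probability growing with depth
# so trees stay small.
random_tree <- function(depth = 0L, max_depth = 5L, max_branches = 4L,
                        p_decision = 0.25) {
  if (depth >= max_depth || runif(1) < 0.25 + 0.15 * depth) {
    return(dt_terminal(paste0("t", sample.int(1e6, 1)),
                       runif(1, -100, 250)))
  }
  nb <- sample(2:max_branches, 1)
  children <- lapply(seq_len(nb), function(i) {
    random_tree(depth + 1L, max_depth, max_branches, p_decision)
  })
  if (runif(1) < p_decision) {
    dt_decision(paste0("d", depth, "_", sample.int(1e6, 1)),
                lapply(seq_len(nb), function(i) {
                  dt_branch(paste0("opt", i), children[[i]])
                }))
  } else {
    p <- runif(nb)
    p <- p / sum(p)
    dt_chance(paste0("c", depth, "_", sample.int(1e6, 1)),
              lapply(seq_len(nb), function(i) {
                dt_branch(paste0("b", i), children[[i]], p = p[i])
              }))
  }
}

# Flat signal trace (dark, body temperature) with optional light step.
flat_trace <- function(n = 30L, step = 5, light_at = NA, light_level = 100) {
  t <- seq(0, by = step, length.out = n)
  light <- rep(0.1, n)
  if (!is.na(light_at)) light[t >= light_at] <- light_level
  data.frame(time_min = t, light = light, temp_c = rep(38.5, n))
}
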