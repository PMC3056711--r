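#' Perievent time histogram
#'
#' Bins one unit's spikes in a window around each behavioral event (by
#' default the 4 s leading up to a lever press, in 100 ms bins) and
#' averages across trials. Bins are half-open `[edge, edge + w)` relative
#' to the event, so a spike exactly at the event time of a `[-4, 0)` window
#' is excluded.
#'
#' @param raster a [spike_raster()].
#' @param events event times in seconds (e.g. lever presses).
#' @param unit unit index within the raster.
#' @param window two-element window relative to the event, seconds.
#' @param bin_width bin width in seconds.
#' @return an object of class `peth`: `list(bin_centers, mean_rate,
#'   per_trial_counts, n_trials, bin_width)` with `mean_rate` in Hz.
#'   Events whose window starts before the recording are dropped with a
#'   warning.
#' @export
perievent_histogram <- function(raster, events, unit = 1,
                                window = c(-4, 0), bin_width = 0.1) {
  stopifnot(inherits(raster, "spike_raster"), length(window) == 2,
            window[2] > window[1], bin_width > 0)
  keep <- events + window[1] >= raster$t_start - 1e-9
  if (any(!keep)) {
    warning(sum(!keep), " event(s) too close to the recording start dropped")
    events <- events[keep]
  }
  nb <- round((window[2] - window[1]) / bin_width)
  edges <- window[1] + bin_width * (0:nb)
  s <- raster$spikes[[unit]]
  counts <- t(vapply(events, function(ev) {
    rel <- s - ev
    rel <- rel[rel >= edges[1] & rel < edges[nb + 1]]
    tabulate(findInterval(rel, edges), nbins = nb)
  }, numeric(nb)))
  structure(list(bin_centers = edges[-1] - bin_width / 2,
                 mean_rate = colMeans(counts) / bin_width,
                 per_trial_counts = counts,
                 n_trials = length(events), bin_width = bin_width),
            class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> %d trials x %d bins, mean rate %.2f Hz\n",
              x$n_trials, length(x$bin_centers), mean(x$mean_rate)))
  invisible(x)
}

# Pooled per-trial bin counts of one unit in [t + win[1], t + win[2])
# around each event time.
pooled_counts <- function(raster, unit, events, win, bin_width) {
  perievent_histogram(raster, events, unit = unit, window = win,
                      bin_width = bin_width)$per_trial_counts
}

#' Categorize an NAcc unit by its goal-approach response
#'
#' For each target side, compares the unit's baseline activity (the 2 s
#' before the cue) with its activity during the 2 s before the lever press
#' using a two-sample Kolmogorov-Smirnov test on the pooled 100 ms bin
#' counts across trials. A side is responsive when `p < alpha`; the
#' direction (excited / inhibited) is the sign of the approach-minus-
#' baseline mean difference, since the KS statistic itself is sign-blind.
#' The per-side responses determine the label:
#' both sides responsive with the same sign - `dual-nonselective`;
#' opposite signs - `dual-selective`; exactly one side - `uni-selective`;
#' neither - `nonresponsive`.
#'
#' @param raster a [spike_raster()].
#' @param unit unit index.
#' @param left_events,right_events lever-press times per side (>= 5 trials
#'   each).
#' @param left_cues,right_cues matching cue times.
#' @param alpha significance level (uncorrected).
#' @param window_dur length of the baseline / approach windows, seconds.
#' @param bin_width bin width for pooling, seconds.
#' @return an object of class `neuron_category`: `list(label, left, right,
#'   p_values)` where `left`/`right` are `"excited"`, `"inhibited"` or
#'   `"none"`.
#' @export
categorize_neuron <- function(raster, unit, left_events, right_events,
                              left_cues, right_cues, alpha = 0.05,
                              window_dur = 2, bin_width = 0.1) {
  for (side in list(c("left", length(left_events)),
                    c("right", length(right_events))))
    if (as.integer(side[2]) < 5)
      stop("need at least 5 trials on the ", side[1], " side")
  win <- c(-window_dur, 0)
  side_test <- function(cues, presses) {
    base <- as.vector(pooled_counts(raster, unit, cues, win, bin_width))
    appr <- as.vector(pooled_counts(raster, unit, presses, win, bin_width))
    p <- suppressWarnings(ks.test(base, appr)$p.value)
    if (p < alpha) {
      list(resp = if (mean(appr) >= mean(base)) "excited" else "inhibited",
           p = p)
    } else list(resp = "none", p = p)
  }
  L <- side_test(left_cues, left_events)
  R <- side_test(right_cues, right_events)
  label <- if (L$resp != "none" && R$resp != "none") {
    if (L$resp == R$resp) "dual-nonselective" else "dual-selective"
  } else if (L$resp != "none" || R$resp != "none") {
    "uni-selective"
  } else "nonresponsive"
  structure(list(label = label, left = L$resp, right = R$resp,
                 p_values = c(left = L$p, right = R$p)),
            class = "neuron_category")
}

#' @export
print.neuron_category <- function(x, ...) {
  cat(sprintf("<neuron_category> %s (left: %s, right: %s)\n",
              x$label, x$left, x$right))
  invisible(x)
}

#' Population summary of response categories
#'
#' @param categories list of [categorize_neuron()] results (or a character
#'   vector of labels).
#' @return `list(n, responsive_fraction, category_fractions)` where
#'   `category_fractions` are fractions among the responsive units.
#' @export
population_summary <- function(categories) {
  labels <- if (is.character(categories)) categories
            else vapply(categories, `[[`, character(1), "label")
  if (length(labels) == 0) stop("no categories supplied")
  resp <- labels != "nonresponsive"
  lv <- c("dual-nonselective", "dual-selective", "uni-selective")
  fr <- if (any(resp)) table(factor(labels[resp], levels = lv)) / sum(resp)
        else setNames(rep(0, 3), lv)
  list(n = length(labels),
       responsive_fraction = mean(resp),
       category_fractions = as.numeric(fr) |> setNames(lv))
}

#' Categorize a whole synthetic session
#'
#' Convenience wrapper running [categorize_neuron()] over every unit of a
#' [synth_nacc_session()]-style recording.
#'
#' @param raster a [spike_raster()].
#' @param events data frame with columns `side`, `cue_time`, `press_time`.
#' @param alpha significance level.
#' @return list of `neuron_category` objects, one per unit.
#' @export
categorize_session <- function(raster, events, alpha = 0.05) {
  le <- events$press_time[events$side == "left"]
  re <- events$press_time[events$side == "right"]
  lc <- events$cue_time[events$side == "left"]
  rc <- events$cue_time[events$side == "right"]
  lapply(seq_along(raster$spikes), function(u)
    categorize_neuron(raster, u, le, re, lc, rc, alpha = alpha))
}
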