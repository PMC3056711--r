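#' Spike raster container
#'
#' A `spike_raster` holds sorted spike times (seconds) for a set of units
#' over a recording span. It is the raw currency of the synthetic M1/NAcc
#' generators, of the binning utilities and of the perievent analysis.
#'
#' @param spikes list of numeric vectors, one per unit, each strictly
#'   increasing spike times in seconds.
#' @param unit_ids character or integer identifiers, one per unit. Defaults
#'   to the names of `spikes` or `1:n`.
#' @param t_start,t_end recording span in seconds; all spike times must lie
#'   within `[t_start, t_end]`. `t_end` defaults to the latest spike (or
#'   `t_start` for an empty raster).
#' @return an object of class `spike_raster`.
#' @examples
#' r <- spike_raster(list(a = c(0.05, 0.12, 0.19)), t_end = 0.2)
#' bin_spikes(r, 0.1)
#' @export
spike_raster <- function(spikes, unit_ids = NULL, t_start = 0, t_end = NULL) {
  stopifnot(is.list(spikes))
  if (is.null(unit_ids)) unit_ids <- names(spikes) %||% seq_along(spikes)
  if (length(unit_ids) != length(spikes))
    stop("unit_ids must have one entry per unit")
  spikes <- lapply(spikes, as.numeric)
  if (is.null(t_end)) {
    mx <- suppressWarnings(max(unlist(spikes), -Inf))
    t_end <- max(t_start, if (is.finite(mx)) mx else t_start)
  }
  for (i in seq_along(spikes)) {
    s <- spikes[[i]]
    if (any(diff(s) <= 0))
      stop("spike times of unit ", unit_ids[i], " are not strictly increasing")
    if (length(s) && (s[1] < t_start || s[length(s)] > t_end))
      stop("spike times of unit ", unit_ids[i], " fall outside [t_start, t_end]")
  }
  structure(list(spikes = spikes, unit_ids = as.character(unit_ids),
                 t_start = t_start, t_end = t_end),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d units, %d spikes, span [%.3f, %.3f] s\n",
              length(x$spikes), sum(lengths(x$spikes)), x$t_start, x$t_end))
  invisible(x)
}

#' Number of units in a raster
#' @param raster a [spike_raster()].
#' @return integer count of units.
#' @export
n_units <- function(raster) length(raster$spikes)

#' Bin spike trains into a rate matrix
#'
#' Counts spikes of every unit in non-overlapping bins of `bin_width`
#' seconds (default 100 ms, the windowing used throughout the decoder).
#' Bins are half-open `[edge, edge + w)`; the number of bins is
#' `floor((t_end - t_start) / bin_width)`, so a trailing remainder shorter
#' than one bin is not covered.
#'
#' @param raster a [spike_raster()].
#' @param bin_width bin width in seconds (> 0).
#' @return a [rate_matrix()] of counts (units x bins).
#' @export
bin_spikes <- function(raster, bin_width = 0.1) {
  stopifnot(inherits(raster, "spike_raster"), bin_width > 0)
  span <- raster$t_end - raster$t_start
  nb <- max(0L, floor(span / bin_width + 1e-9))
  vals <- matrix(0L, nrow = length(raster$spikes), ncol = nb,
                 dimnames = list(raster$unit_ids, NULL))
  if (nb > 0) {
    edges <- raster$t_start + bin_width * (0:nb)
    for (i in seq_along(raster$spikes)) {
      s <- raster$spikes[[i]]
      s <- s[s >= raster$t_start & s < edges[nb + 1]]
      if (length(s))
        vals[i, ] <- tabulate(findInterval(s, edges, left.open = FALSE),
                              nbins = nb)
    }
  }
  rate_matrix(vals, bin_width = bin_width, t0 = raster$t_start)
}

#' Binned firing-count matrix
#'
#' @param values units x bins matrix of non-negative spike counts.
#' @param bin_width bin width in seconds.
#' @param t0 time (seconds) of the left edge of the first bin.
#' @return an object of class `rate_matrix`.
#' @export
rate_matrix <- function(values, bin_width = 0.1, t0 = 0) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("rate_matrix entries must be >= 0")
  structure(list(values = values, bin_width = bin_width, t0 = t0),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("<rate_matrix> %d units x %d bins, bin_width %.3f s, t0 %.3f s\n",
              nrow(x$values), ncol(x$values), x$bin_width, x$t0))
  invisible(x)
}

#' @export
dim.rate_matrix <- function(x) dim(x$values)

#' Read / write spike rasters as two-column CSV
#'
#' The on-disk format is a plain CSV with columns `unit_id` and `time_s`,
#' sorted by unit then time. The reader validates per-unit monotonicity.
#'
#' @param raster a [spike_raster()].
#' @param path file path.
#' @param unit_ids optional unit ids to force into the raster even when a
#'   unit emitted no spikes in the file.
#' @param t_start,t_end span override for the reader (defaults: 0 and the
#'   latest spike time).
#' @return `read_spike_csv` returns a [spike_raster()];
#'   `write_spike_csv` returns `path` invisibly.
#' @export
write_spike_csv <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  df <- data.frame(
    unit_id = rep(raster$unit_ids, lengths(raster$spikes)),
    time_s = unlist(raster$spikes, use.names = FALSE)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path, unit_ids = NULL, t_start = 0, t_end = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "time_s") %in% names(df)))
    stop("spike CSV must have columns unit_id and time_s")
  ids <- unit_ids %||% unique(df$unit_id)
  spikes <- lapply(ids, function(id) sort(df$time_s[df$unit_id == id]))
  names(spikes) <- ids
  spike_raster(spikes, unit_ids = ids, t_start = t_start, t_end = t_end)
}

#' Read / write rate matrices as CSV
#'
#' Columns are bins; a header row carries the left bin edges (seconds), and
#' the first column carries unit ids.
#'
#' @param rm a [rate_matrix()].
#' @param path file path.
#' @return `read_rate_csv` returns a [rate_matrix()];
#'   `write_rate_csv` returns `path` invisibly.
#' @export
write_rate_csv <- function(rm, path) {
  stopifnot(inherits(rm, "rate_matrix"))
  edges <- rm$t0 + rm$bin_width * (seq_len(ncol(rm$values)) - 1)
  df <- data.frame(unit_id = rownames(rm$values) %||% seq_len(nrow(rm$values)),
                   rm$values, check.names = FALSE)
  names(df) <- c("unit_id", sprintf("%.6f", edges))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rate_csv
#' @export
read_rate_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  edges <- as.numeric(names(df)[-1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  colnames(vals) <- NULL
  w <- if (length(edges) > 1) edges[2] - edges[1] else 0.1
  rate_matrix(vals, bin_width = w, t0 = edges[1])
}
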