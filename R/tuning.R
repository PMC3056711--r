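#' Direction tuning map of a synthetic cortical ensemble
#'
#' Assigns every unit one preferred movement direction out of the action
#' alphabet, plus a drive gain. The `block` scheme splits the ensemble into
#' contiguous equal-size subsets, one per direction (the layout used for the
#' grid task: with 12 units and the 2D alphabet, units 1-3 are tuned left,
#' 4-6 right, 7-9 up and 10-12 down). The `shuffled` scheme permutes the
#' preferred directions of the corresponding block map, modelling a
#' reorganization of the neural representation. `custom` takes `preferred`
#' as given.
#'
#' @param n_units number of units; must be divisible by the number of
#'   directions under the `block` scheme.
#' @param directions character vector, the action alphabet.
#' @param scheme `"block"`, `"shuffled"` or `"custom"`.
#' @param preferred per-unit preferred directions, for `scheme = "custom"`.
#' @param gain per-unit drive gain (recycled); scales the command drive the
#'   unit receives when its preferred direction is part of the motor command.
#' @param seed optional RNG seed for the `shuffled` scheme.
#' @return an object of class `tuning_map` with fields `preferred`,
#'   `gain` and `directions`.
#' @examples
#' make_tuning_map(12, c("left", "right", "up", "down"))
#' @export
make_tuning_map <- function(n_units,
                            directions = c("left", "right", "up", "down"),
                            scheme = c("block", "shuffled", "custom"),
                            preferred = NULL, gain = 1, seed = NULL) {
  scheme <- match.arg(scheme)
  directions <- as.character(directions)
  if (scheme == "custom") {
    if (is.null(preferred) || length(preferred) != n_units)
      stop("custom scheme requires one preferred direction per unit")
    if (!all(preferred %in% directions))
      stop("preferred directions outside the action alphabet")
  } else {
    if (n_units %% length(directions) != 0)
      stop("n_units (", n_units, ") is not divisible by the number of ",
           "directions (", length(directions), ") under the block scheme")
    preferred <- rep(directions, each = n_units / length(directions))
    if (scheme == "shuffled") {
      if (!is.null(seed)) set.seed(seed)
      preferred <- sample(preferred)
    }
  }
  structure(list(preferred = preferred,
                 gain = rep_len(gain, n_units),
                 directions = directions),
            class = "tuning_map")
}

#' Shuffle an existing tuning map
#'
#' Permutes the per-unit preferred directions with the current (or supplied)
#' RNG stream, preserving the multiset of directions. Used at the
#' reorganization event of the tuning-remapping experiment.
#'
#' @param map a `tuning_map`.
#' @param seed optional RNG seed.
#' @return a shuffled `tuning_map`.
#' @export
shuffle_tuning_map <- function(map, seed = NULL) {
  stopifnot(inherits(map, "tuning_map"))
  if (!is.null(seed)) set.seed(seed)
  map$preferred <- sample(map$preferred)
  map
}

#' @export
print.tuning_map <- function(x, ...) {
  cat("<tuning_map>", length(x$preferred), "units over {",
      paste(x$directions, collapse = ", "), "}\n")
  print(setNames(x$preferred, seq_along(x$preferred)))
  invisible(x)
}
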