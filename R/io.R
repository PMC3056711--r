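#' Load an experiment configuration
#'
#' Reads a YAML config file, validates every key against the schema of
#' [default_config()] (unknown keys are rejected by name) and fills in the
#' defaults for everything unspecified. An empty file yields the full
#' default configuration.
#'
#' @param path YAML file path.
#' @return a validated `bmirl_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_config(default_config(), user)
}

#' @rdname load_config
#' @param config a config list to save.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

merge_config <- function(defaults, user, prefix = "") {
  if (!is.list(user))
    stop("config section '", sub("\\.$", "", prefix), "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key: ", paste0(prefix, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    prefix = paste0(prefix, k, "."))
    } else {
      v <- user[[k]]
      if (is.numeric(defaults[[k]]) && !is.numeric(v))
        stop("config key ", prefix, k, " must be numeric")
      if (is.character(defaults[[k]]) && !is.character(v))
        stop("config key ", prefix, k, " must be a string")
      defaults[[k]] <- v
    }
  }
  defaults
}

#' Write / read experiment logs as JSON lines
#'
#' One JSON record per line: a `header` record with the log metadata, one
#' `trial` record per trial and one `step` record per decoder step (with
#' the per-action values). Integer and flag fields round-trip exactly;
#' floats to full serialized precision.
#'
#' @param log an `experiment_log`.
#' @param path file path (conventionally `.jsonl`).
#' @return `write_log` returns `path` invisibly; `read_log` returns the
#'   reconstructed `experiment_log`. A malformed line aborts with its line
#'   number.
#' @export
write_log <- function(log, path) {
  stopifnot(inherits(log, "experiment_log"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  emit <- function(x) writeLines(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), con)
  emit(list(kind = "header", meta = log$meta,
            n_trials = nrow(log$trials), n_steps = nrow(log$steps),
            has_values = !is.null(log$values),
            has_snapshots = !is.null(log$snapshots)))
  for (i in seq_len(nrow(log$trials))) {
    rec <- c(kind = "trial", as.list(log$trials[i, ]))
    if (!is.null(log$snapshots)) rec$snapshot <- unname(log$snapshots[i, ])
    emit(rec)
  }
  for (i in seq_len(nrow(log$steps))) {
    rec <- c(kind = "step", as.list(log$steps[i, ]))
    if (!is.null(log$values)) rec$values <- unname(log$values[i, ])
    emit(rec)
  }
  invisible(path)
}

#' @rdname write_log
#' @export
read_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty log file: ", path)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    recs[[i]] <- tryCatch(jsonlite::fromJSON(lines[i]),
                          error = function(e)
                            stop("malformed log record at line ", i, ": ",
                                 conditionMessage(e), call. = FALSE))
  }
  kinds <- vapply(recs, `[[`, character(1), "kind")
  if (kinds[1] != "header") stop("log must start with a header record")
  hdr <- recs[[1]]
  log <- empty_log()
  log$meta <- hdr$meta
  tr <- recs[kinds == "trial"]
  if (length(tr)) {
    log$trials <- do.call(rbind, lapply(tr, function(r)
      data.frame(trial = as.integer(r$trial), target = as.integer(r$target),
                 success = as.logical(r$success), steps = as.integer(r$steps),
                 eta = as.numeric(r$eta))))
    if (isTRUE(hdr$has_snapshots))
      log$snapshots <- do.call(rbind, lapply(tr, function(r) r$snapshot))
  }
  sp <- recs[kinds == "step"]
  if (length(sp)) {
    log$steps <- do.call(rbind, lapply(sp, function(r)
      data.frame(trial = as.integer(r$trial), step = as.integer(r$step),
                 action = as.integer(r$action),
                 feedback = as.numeric(r$feedback), eta = as.numeric(r$eta))))
    if (isTRUE(hdr$has_values))
      log$values <- do.call(rbind, lapply(sp, function(r) r$values))
  }
  log
}

#' Save / load models as JSON
#'
#' Serializes Actor or Critic models (weights plus architecture metadata)
#' to a single portable JSON file.
#'
#' @param model an `actor_model` or `critic_model`.
#' @param path file path.
#' @return `read_model` returns the model; `write_model` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  cls <- class(model)[1]
  if (!cls %in% c("actor_model", "critic_model"))
    stop("write_model handles actor_model and critic_model objects")
  payload <- lapply(unclass(model), function(x)
    if (is.matrix(x)) list(dim = dim(x), data = as.vector(x)) else x)
  jsonlite::write_json(list(class = cls, fields = payload), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  fields <- lapply(obj$fields, function(x) {
    if (is.list(x) && !is.null(x$dim)) matrix(x$data, x$dim[1], x$dim[2])
    else x
  })
  structure(fields, class = obj$class)
}
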