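#' 2D grid-world navigation task
#'
#' A square grid of `n x n` nodes with `spacing` between adjacent nodes.
#' The agent occupies a node (integer coordinates `0 .. n-1`) and moves one
#' node per action along `left/right/up/down`; moves that would exit the
#' grid clamp to the boundary. Targets sit at the four corners and are
#' numbered 1 upper-right, 2 lower-left, 3 upper-left, 4 lower-right; each
#' trial starts from the center of the grid.
#'
#' @param n nodes per side.
#' @param spacing node distance in world units.
#' @param start starting node (integer coordinates); default the center.
#' @param active_target index into `targets`.
#' @return an object of class `grid_world_2d`.
#' @export
grid_world <- function(n = 20, spacing = 0.1, start = NULL,
                       active_target = 1L) {
  start <- start %||% c(floor(n / 2), floor(n / 2))
  targets <- list(c(n - 1, n - 1), c(0, 0), c(0, n - 1), c(n - 1, 0))
  names(targets) <- c("upper-right", "lower-left", "upper-left", "lower-right")
  structure(list(n = n, spacing = spacing, start = start, position = start,
                 targets = targets, active_target = as.integer(active_target),
                 actions = list(left = c(-1, 0), right = c(1, 0),
                                up = c(0, 1), down = c(0, -1))),
            class = "grid_world_2d")
}

#' 3D two-lever reaching task
#'
#' Continuous 3D workspace with an alphabet of 12 unit movement directions:
#' the 6 axial directions (forward/back, left/right, up/down) plus 6 corner
#' diagonals spanning the front and upper reaching envelope (all `(+-1, +-1,
#' +-1)/sqrt(3)` corners except the two back-down ones, which point outside
#' the workspace in front of and above the actuator base). The alphabet is
#' fully overridable via `actions`.
#'
#' @param step_size distance moved per action.
#' @param target,nontarget 3D lever positions; defaults put the target 10
#'   steps along the forward-right-up diagonal and the non-target mirrored
#'   to the left.
#' @param start starting position.
#' @param extent half-width of the cubic workspace; positions clamp to
#'   `[-extent, extent]` per coordinate.
#' @param actions optional 3 x 12 matrix of unit direction columns.
#' @return an object of class `reach_world_3d`.
#' @export
reach_world <- function(step_size = 0.1, target = NULL, nontarget = NULL,
                        start = c(0, 0, 0), extent = 2, actions = NULL) {
  if (is.null(actions)) {
    ax <- cbind(forward = c(1, 0, 0), back = c(-1, 0, 0),
                left = c(0, -1, 0), right = c(0, 1, 0),
                up = c(0, 0, 1), down = c(0, 0, -1))
    dg <- cbind("forward-right-up" = c(1, 1, 1),
                "forward-left-up" = c(1, -1, 1),
                "forward-right-down" = c(1, 1, -1),
                "forward-left-down" = c(1, -1, -1),
                "back-right-up" = c(-1, 1, 1),
                "back-left-up" = c(-1, -1, 1))
    actions <- cbind(ax, dg / sqrt(3))
  }
  if (ncol(actions) != 12) stop("the reach alphabet must have 12 directions")
  target <- target %||% (10 * step_size * c(1, 1, 1) / sqrt(3))
  nontarget <- nontarget %||% (10 * step_size * c(1, -1, 1) / sqrt(3))
  if (isTRUE(all.equal(target, nontarget)))
    stop("target and non-target levers must differ")
  structure(list(step_size = step_size, start = start, position = start,
                 targets = list(target = target, nontarget = nontarget),
                 active_target = 1L, extent = extent, actions = actions),
            class = "reach_world_3d")
}

#' Position and target of a world in workspace coordinates
#' @param world a `grid_world_2d` or `reach_world_3d`.
#' @return numeric coordinate vector.
#' @export
world_position <- function(world) {
  if (inherits(world, "grid_world_2d")) world$position * world$spacing
  else world$position
}

#' @rdname world_position
#' @export
target_position <- function(world) {
  tg <- world$targets[[world$active_target]]
  if (inherits(world, "grid_world_2d")) tg * world$spacing else tg
}

#' Apply one action to a world
#'
#' Moves the agent one step along the named action's direction; moves that
#' would leave the workspace clamp to the boundary (possibly leaving the
#' position unchanged).
#'
#' @param world a `grid_world_2d` or `reach_world_3d`.
#' @param action action name from the world's alphabet.
#' @return the updated world.
#' @export
apply_action <- function(world, action) UseMethod("apply_action")

#' @export
apply_action.grid_world_2d <- function(world, action) {
  if (!action %in% names(world$actions)) stop("unknown action: ", action)
  p <- world$position + world$actions[[action]]
  world$position <- pmin(pmax(p, 0), world$n - 1)
  world
}

#' @export
apply_action.reach_world_3d <- function(world, action) {
  if (!action %in% colnames(world$actions)) stop("unknown action: ", action)
  p <- world$position + world$step_size * world$actions[, action]
  world$position <- pmin(pmax(p, -world$extent), world$extent)
  world
}

#' Intended motor command toward the active target
#'
#' The simulated user always intends to move toward the active target. In
#' 2D the intent is quantized to the sign structure of the displacement (a
#' diagonal intent lists both component directions, which excites both
#' tuned subsets); in 3D it is quantized to the alphabet direction with the
#' largest cosine to the displacement.
#'
#' @param world a world object.
#' @return character vector of 0-2 direction labels (empty at the target).
#' @export
intended_command <- function(world) {
  if (inherits(world, "grid_world_2d")) {
    dv <- world$targets[[world$active_target]] - world$position
    cmd <- character(0)
    if (dv[1] > 0) cmd <- c(cmd, "right") else if (dv[1] < 0) cmd <- c(cmd, "left")
    if (dv[2] > 0) cmd <- c(cmd, "up") else if (dv[2] < 0) cmd <- c(cmd, "down")
    cmd
  } else {
    dv <- target_position(world) - world$position
    if (sqrt(sum(dv^2)) < 1e-12) return(character(0))
    cosines <- as.numeric(dv %*% world$actions) / sqrt(sum(dv^2))
    colnames(world$actions)[which.max(cosines)]
  }
}

#' Outcome of one trial
#'
#' A trial succeeds if some position of the trajectory comes within
#' `success_radius` of the target at a step index not exceeding
#' `max_steps`; `steps_used` is the first such step (the starting position
#' counts as step 0) or `max_steps` for a failed trial.
#'
#' @param trajectory numeric matrix of positions, one row per step,
#'   including the starting position as the first row.
#' @param target numeric target position (same frame).
#' @param max_steps trial step budget.
#' @param success_radius capture distance.
#' @return `list(success = <logical>, steps_used = <integer>)`.
#' @export
trial_outcome <- function(trajectory, target, max_steps = 50,
                          success_radius = 0.1) {
  trajectory <- as.matrix(trajectory)
  if (nrow(trajectory) == 0) stop("empty trajectory")
  d <- sqrt(rowSums(sweep(trajectory, 2, target)^2))
  hit <- which(d <= success_radius + 1e-12) - 1L # step index, start = 0
  hit <- hit[hit <= max_steps]
  if (length(hit)) list(success = TRUE, steps_used = unname(hit[1]))
  else list(success = FALSE, steps_used = as.integer(max_steps))
}

#' Per-trial target schedule
#'
#' Expands an epoch plan into a per-trial vector of target indices. Each
#' plan entry is a pair `(target, n_trials)` where `target` is a target
#' index or `"random"`; random trials draw uniformly over `1:n_targets`
#' with the current RNG stream.
#'
#' @param plan a list of `list(target =, n =)` entries (or a 2-column
#'   data frame with columns `target` and `n`).
#' @param n_targets number of targets the `"random"` phase draws from.
#' @return integer vector of per-trial target indices.
#' @examples
#' set.seed(1)
#' sequential_target_schedule(list(list(target = 1, n = 3),
#'                                 list(target = "random", n = 4)))
#' @export
sequential_target_schedule <- function(plan, n_targets = 4) {
  if (is.data.frame(plan)) plan <- lapply(seq_len(nrow(plan)), function(i)
    list(target = plan$target[i], n = plan$n[i]))
  if (length(plan) == 0) stop("empty epoch plan")
  out <- lapply(plan, function(p) {
    if (identical(p$target, "random"))
      sample.int(n_targets, p$n, replace = TRUE)
    else rep(as.integer(p$target), p$n)
  })
  unlist(out, use.names = FALSE)
}
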