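#' Synchronous update step
#'
#' All non-input nodes are updated simultaneously from the current state;
#' input nodes take their clamp value.
#'
#' @param net A \code{boolean_network}.
#' @param state Named 0/1 vector over all nodes.
#' @param clamps Named 0/1 vector covering the input nodes (inputs with a
#'   declared initial value default to it).
#' @return The successor state (named integer vector).
#' @export
step_synchronous <- function(net, state, clamps = NULL) {
  check_state(net, state)
  cl <- check_clamps(net, clamps)
  env <- state_env(state)
  new <- state
  for (nm in setdiff(net$nodes, net$inputs))
    new[[nm]] <- as.integer(eval(net$rules[[nm]], env))
  if (length(cl)) new[names(cl)] <- cl
  new
}

#' Asynchronous update step
#'
#' Exactly one uniformly chosen non-input node is updated; the choice is
#' driven by the current R random number stream (seed it via
#' [simulate_network()] for reproducible trajectories).
#'
#' @inheritParams step_synchronous
#' @return The successor state, with attribute \code{"updated"} naming the
#'   node that was recomputed.
#' @export
step_asynchronous <- function(net, state, clamps = NULL) {
  check_state(net, state)
  cl <- check_clamps(net, clamps)
  free <- setdiff(net$nodes, net$inputs)
  if (length(free) == 0L) stop("network has no free node to update",
                               call. = FALSE)
  pick <- free[sample.int(length(free), 1L)]
  new <- state
  new[[pick]] <- as.integer(eval(net$rules[[pick]], state_env(state)))
  if (length(cl)) new[names(cl)] <- cl
  attr(new, "updated") <- pick
  new
}

state_env <- function(state) {
  list2env(as.list(stats::setNames(as.logical(state), names(state))),
           parent = baseenv())
}

#' Simulate a Boolean network trajectory
#'
#' @param net A \code{boolean_network}.
#' @param init Initial state; defaults to [initial_state()] of the model
#'   file. Input nodes are forced to their clamp value at time 0.
#' @param clamps Named 0/1 vector for the inputs (see [step_synchronous()]).
#' @param n_steps Number of update steps (trajectory has
#'   \code{n_steps + 1} columns). Defaults to \code{min(2^k + 1, 64)} for
#'   \code{k} free nodes, enough to close any cycle in the small models
#'   used here.
#' @param mode \code{"synchronous"} (deterministic; default) or
#'   \code{"asynchronous"} (one random node per step; requires \code{seed}).
#' @param seed Integer seed, mandatory in asynchronous mode, ignored in
#'   synchronous mode. The global RNG state is restored on exit.
#' @return A \code{bn_trajectory}: node-by-time 0/1 matrix with attributes
#'   \code{mode}, \code{seed} and \code{clamps}.
#' @examples
#' net <- parse_rules(c("ERK* = not DUSP", "DUSP* = ERK",
#'                      "ERK = True", "DUSP = True"))
#' simulate_network(net, n_steps = 6)
#' @export
simulate_network <- function(net, init = NULL, clamps = NULL, n_steps = NULL,
                             mode = c("synchronous", "asynchronous"),
                             seed = NULL) {
  mode <- match.arg(mode)
  cl <- check_clamps(net, clamps)
  if (is.null(init)) init <- initial_state(net)
  check_state(net, init)
  if (length(cl)) init[names(cl)] <- cl
  if (is.null(n_steps)) {
    k <- length(setdiff(net$nodes, net$inputs))
    n_steps <- min(2^k + 1, 64L)
  }
  if (n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)

  if (mode == "asynchronous") {
    if (is.null(seed)) stop("asynchronous simulation requires a seed",
                            call. = FALSE)
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(seed)
  }

  traj <- matrix(NA_integer_, nrow = length(net$nodes), ncol = n_steps + 1L,
                 dimnames = list(net$nodes,
                                 paste0("t", 0:n_steps)))
  state <- init[net$nodes]
  traj[, 1L] <- state
  for (s in seq_len(n_steps)) {
    state <- if (mode == "synchronous") step_synchronous(net, state, cl)
             else step_asynchronous(net, state, cl)
    traj[, s + 1L] <- state
  }
  structure(traj, mode = mode,
            seed = if (mode == "asynchronous") seed else NULL,
            clamps = cl, class = c("bn_trajectory", "matrix", "array"))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' Find the synchronous attractor from a given initial state
#'
#' Iterates synchronous updates until a state repeats, which is guaranteed
#' within \code{2^k + 1} steps for \code{k} free nodes, and splits the run
#' into transient and cycle.
#'
#' @inheritParams simulate_network
#' @return A \code{bn_attractor}: list with \code{transient} (node x time
#'   matrix of the pre-cycle states, possibly zero columns),
#'   \code{cycle} (node x time matrix, one synchronous step maps its last
#'   column to its first), \code{transient_length} and \code{cycle_length}.
#' @examples
#' net <- parse_rules(c("ERK* = not DUSP", "DUSP* = ERK",
#'                      "ERK = True", "DUSP = True"))
#' find_attractor(net)$cycle_length  # period-4 negative feedback loop
#' @export
find_attractor <- function(net, init = NULL, clamps = NULL) {
  cl <- check_clamps(net, clamps)
  if (is.null(init)) init <- initial_state(net)
  check_state(net, init)
  if (length(cl)) init[names(cl)] <- cl

  state <- init[net$nodes]
  states <- list(state)
  keys <- paste(state, collapse = "")
  repeat {
    state <- step_synchronous(net, state, cl)
    key <- paste(state, collapse = "")
    hit <- match(key, keys)
    if (!is.na(hit)) {
      all_states <- do.call(cbind, states)
      rownames(all_states) <- net$nodes
      n <- ncol(all_states)
      transient <- all_states[, seq_len(hit - 1L), drop = FALSE]
      cycle <- all_states[, hit:n, drop = FALSE]
      colnames(transient) <- if (hit > 1L) paste0("t", 0:(hit - 2L)) else NULL
      colnames(cycle) <- paste0("t", (hit - 1L):(n - 1L))
      return(structure(list(transient = transient, cycle = cycle,
                            transient_length = hit - 1L,
                            cycle_length = ncol(cycle),
                            clamps = cl),
                       class = "bn_attractor"))
    }
    states[[length(states) + 1L]] <- state
    keys <- c(keys, key)
  }
}

#' @export
print.bn_attractor <- function(x, ...) {
  cat(sprintf("Attractor: transient %d, cycle length %d%s\n",
              x$transient_length, x$cycle_length,
              if (x$cycle_length == 1L) " (fixed point)" else ""))
  print(cbind(x$transient, x$cycle))
  invisible(x)
}

node_values <- function(x, node) {
  if (inherits(x, "bn_attractor")) {
    if (!node %in% rownames(x$cycle))
      stop(sprintf("unknown node '%s'", node), call. = FALSE)
    list(transient = as.integer(x$transient[node, ]),
         cycle = as.integer(x$cycle[node, ]))
  } else if (inherits(x, "bn_trajectory") || is.matrix(x)) {
    if (!node %in% rownames(x))
      stop(sprintf("unknown node '%s'", node), call. = FALSE)
    list(transient = as.integer(x[node, ]), cycle = NULL)
  } else stop("expected a bn_attractor or bn_trajectory", call. = FALSE)
}

#' Qualitative pattern class of a node's long-run behaviour
#'
#' Classifies a node, given its attractor, into one of
#' \code{CONSTANT_ON}, \code{CONSTANT_OFF}, \code{OSCILLATING},
#' \code{ON_THEN_OFF}, \code{OFF_THEN_ON}:
#' oscillating iff the node is non-constant within the cycle; constant iff it
#' holds the same value through transient and cycle; otherwise the node
#' settles to a constant cycle value after being in the opposite state during
#' the transient (\code{ON_THEN_OFF} when it was active and settles OFF, and
#' symmetrically). The label is invariant to extending the simulation beyond
#' one full cycle.
#'
#' @param x A \code{bn_attractor} (from [find_attractor()]), or a
#'   \code{boolean_network} (the attractor is computed first, forwarding
#'   \code{...} to [find_attractor()]).
#' @param node Node name.
#' @param ... Passed to [find_attractor()] when \code{x} is a network.
#' @return A single string, the pattern label.
#' @export
classify_node_pattern <- function(x, node, ...) {
  if (inherits(x, "boolean_network")) x <- find_attractor(x, ...)
  if (!inherits(x, "bn_attractor"))
    stop("classify_node_pattern needs an attractor or a network",
         call. = FALSE)
  v <- node_values(x, node)
  cyc <- v$cycle
  all_v <- c(v$transient, cyc)
  if (any(cyc != cyc[1L])) return("OSCILLATING")
  c0 <- cyc[1L]
  if (all(all_v == c0)) return(if (c0 == 1L) "CONSTANT_ON" else "CONSTANT_OFF")
  if (c0 == 0L) "ON_THEN_OFF" else "OFF_THEN_ON"
}

#' Direction-symbol string of a node's simulated time course
#'
#' Reads the node's values over transient plus one full cycle and encodes
#' each consecutive change as \code{"+"} (0 to 1), \code{"-"} (1 to 0) or
#' \code{"0"} (no change). This is the qualitative simulated pattern
#' compared against experimental patterns, since Boolean time units are
#' arbitrary and only the order of events is meaningful.
#'
#' @inheritParams classify_node_pattern
#' @return A single string over \code{+ - 0}.
#' @export
node_symbols <- function(x, node, ...) {
  if (inherits(x, "boolean_network")) x <- find_attractor(x, ...)
  v <- node_values(x, node)
  vals <- c(v$transient, v$cycle)
  diff_symbols(vals)
}

diff_symbols <- function(vals) {
  if (length(vals) < 2L) return("0")  # a fixed point with no transient
  d <- diff(vals)
  paste(c("-", "0", "+")[sign(d) + 2L], collapse = "")
}

#' Export a trajectory as a TSV matrix and a two-colour heatmap
#'
#' Writes \code{<prefix>.tsv}, a node-by-time 0/1 matrix in declaration
#' order, and (where PNG devices are available) \code{<prefix>.png}, a
#' raster with green for ON and red for OFF.
#'
#' @param traj A \code{bn_trajectory} or a node x time 0/1 matrix.
#' @param prefix Output path prefix (without extension).
#' @return Invisibly, a character vector of the files written.
#' @export
export_heatmap <- function(traj, prefix) {
  if (!is.matrix(traj) || ncol(traj) < 1L)
    stop("trajectory must be a non-empty node x time matrix", call. = FALSE)
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(as.data.frame(unclass(traj)), tsv, sep = "\t",
                     quote = FALSE, col.names = NA)
  written <- tsv
  if (isTRUE(capabilities("png"))) {
    png_path <- paste0(prefix, ".png")
    grDevices::png(png_path, width = 140 + 40 * ncol(traj),
                   height = 120 + 28 * nrow(traj), res = 96)
    op <- graphics::par(mar = c(3.5, 7, 2, 1))
    on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
    m <- traj[rev(seq_len(nrow(traj))), , drop = FALSE]
    graphics::image(x = seq_len(ncol(m)) - 1, y = seq_len(nrow(m)),
                    z = t(m), zlim = c(0, 1),
                    col = c("red3", "green3"), axes = FALSE,
                    xlab = "", ylab = "")
    graphics::axis(1, at = seq_len(ncol(m)) - 1,
                   labels = sub("^t", "", colnames(m) %||%
                                  as.character(seq_len(ncol(m)) - 1)))
    graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                   tick = FALSE)
    graphics::mtext("time step", side = 1, line = 2.2)
    written <- c(written, png_path)
  }
  invisible(written)
}

#' Read back a trajectory matrix written by [export_heatmap()]
#'
#' @param path Path to the TSV file.
#' @return Integer node x time matrix.
#' @export
read_trajectory_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
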