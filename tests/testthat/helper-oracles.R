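# Independent oracles used across the suite.

# Exhaustive transition-graph attractor finder: enumerates all 2^k states
# of the free nodes, tabulates the full synchronous transition map, then
# walks it from the initial state marking visit times. Independent of
# find_attractor's incremental hash detection.
exhaustive_attractor <- function(net, init = NULL, clamps = NULL) {
  cl <- duspboolnet:::check_clamps(net, clamps)
  if (is.null(init)) init <- initial_state(net)
  if (length(cl)) init[names(cl)] <- cl
  free <- setdiff(net$nodes, net$inputs)
  k <- length(free)
  grid <- as.matrix(expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- free
  key_of <- function(v) paste(v, collapse = "")
  keys <- apply(grid, 1L, key_of)

  succ <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    st <- init
    st[free] <- grid[i, free]
    if (length(cl)) st[names(cl)] <- cl
    nx <- step_synchronous(net, st, cl)
    succ[i] <- match(key_of(nx[free]), keys)
  }

  start <- match(key_of(init[free]), keys)
  visit_time <- rep(NA_integer_, nrow(grid))
  cur <- start
  t <- 0L
  while (is.na(visit_time[cur])) {
    visit_time[cur] <- t
    cur <- succ[cur]
    t <- t + 1L
  }
  cycle_start_time <- visit_time[cur]
  cycle_states <- which(!is.na(visit_time) & visit_time >= cycle_start_time)
  ord <- order(visit_time[cycle_states])
  list(transient_length = cycle_start_time,
       cycle_length = length(cycle_states),
       cycle_keys = keys[cycle_states][ord])
}

# Exhaustive asynchronous reachability: BFS over every single-free-node
# update from the initial state.
async_reachable <- function(net, init = NULL, clamps = NULL) {
  cl <- duspboolnet:::check_clamps(net, clamps)
  if (is.null(init)) init <- initial_state(net)
  if (length(cl)) init[names(cl)] <- cl
  free <- setdiff(net$nodes, net$inputs)
  key_of <- function(v) paste(v, collapse = "")
  seen <- new.env(parent = emptyenv())
  frontier <- list(init)
  assign(key_of(init), TRUE, envir = seen)
  while (length(frontier)) {
    nxt <- list()
    for (st in frontier) {
      env <- duspboolnet:::state_env(st)
      for (nm in free) {
        new <- st
        new[[nm]] <- as.integer(eval(net$rules[[nm]], env))
        if (length(cl)) new[names(cl)] <- cl
        kk <- key_of(new)
        if (!exists(kk, envir = seen, inherits = FALSE)) {
          assign(kk, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- new
        }
      }
    }
    frontier <- nxt
  }
  sort(ls(seen))
}

# Random Boolean network in the text dialect: k nodes, each rule a random
# expression over <= 3 parents combined with and/or/not.
random_network_text <- function(k, rng) {
  nodes <- paste0("N", seq_len(k))
  lines <- character(0)
  for (n in nodes) {
    np <- sample(1:min(3, k), 1)
    parents <- sample(nodes, np)
    lits <- ifelse(stats::runif(np) < 0.4, paste("not", parents), parents)
    ops <- sample(c("and", "or"), max(0, np - 1), replace = TRUE)
    expr <- lits[1]
    for (j in seq_along(ops)) expr <- paste(expr, ops[j], lits[j + 1])
    lines <- c(lines, sprintf("%s* = %s", n, expr))
  }
  inits <- sprintf("%s = %s", nodes,
                   ifelse(stats::runif(k) < 0.5, "True", "False"))
  c(lines, inits)
}

# Adjusted Rand index between two gene -> cluster maps, treating each
# UNCLUSTERED gene as its own singleton class.
cluster_agreement <- function(truth, recovered) {
  stopifnot(setequal(names(truth), names(recovered)))
  g <- names(truth)
  t1 <- ifelse(truth[g] == "UNCLUSTERED", paste0("s_", g), truth[g])
  r1 <- ifelse(recovered[g] == "UNCLUSTERED", paste0("s_", g), recovered[g])
  mclust::adjustedRandIndex(t1, r1)
}

# Small shared fixture: the two-node negative feedback loop.
negative_feedback_net <- function() {
  parse_rules(c("ERK* = not DUSP", "DUSP* = ERK",
                "ERK = True", "DUSP = True"))
}
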