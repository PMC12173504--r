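#' Bounded reservoir of visited active states
#'
#' The quasi-stationary method keeps the dynamics in the active region: when
#' the system absorbs (a homogeneous configuration), it is teleported back
#' to a previously visited active state sampled with probability
#' proportional to the time the system spent there. The reservoir stores a
#' bounded number of state snapshots with dwell weights; when full, a new
#' record replaces a uniformly chosen stored snapshot with probability
#' `capacity / n_records` (classic reservoir sampling), so the long-run
#' inclusion probability of any visited state stays proportional to its
#' dwell time over the reservoir's memory horizon.
#'
#' Two replacement policies are available once the reservoir is full.
#' `memory = "recent"` (the default, and the standard quasi-stationary
#' simulation practice) always overwrites a uniformly chosen stored snapshot,
#' so the reservoir is an exponentially forgetting sample of roughly the last
#' `capacity * cadence` time units — teleports then return the system near
#' its current quasi-stationary region instead of replaying the initial
#' transient. `memory = "full"` uses classic reservoir sampling (replace with
#' probability `capacity / n_records`), making inclusion uniform over the
#' whole visited history; it is provided for sensitivity analysis but
#' converges much more slowly because early transient states are never
#' forgotten.
#'
#' @param capacity maximum number of stored snapshots (default 100).
#' @param memory replacement policy, `"recent"` or `"full"`.
#' @return A mutable object of class `qs_reservoir` (an environment with
#'   `states`, `weights`, `n_records`, `capacity`, `memory`).
#' @export
qs_reservoir <- function(capacity = 100L, memory = c("recent", "full")) {
  stopifnot(capacity >= 1L)
  res <- new.env(parent = emptyenv())
  res$capacity <- as.integer(capacity)
  res$memory <- match.arg(memory)
  res$states <- list()
  res$weights <- numeric(0)
  res$n_records <- 0L
  class(res) <- "qs_reservoir"
  res
}

#' @export
print.qs_reservoir <- function(x, ...) {
  cat(sprintf("<qs_reservoir> %d/%d snapshots (%d recorded, total weight %g)\n",
              length(x$states), x$capacity, x$n_records, sum(x$weights)))
  invisible(x)
}

#' Record an active state into the reservoir
#'
#' @param reservoir a [qs_reservoir()]; modified in place.
#' @param state a non-absorbing [strategy_state()].
#' @param dwell dwell weight of the snapshot (time units, e.g. the recording
#'   cadence in MCS); must be positive.
#' @param cfg the [dynamics_config()] whose absorbing trigger guards the
#'   reservoir (absorbing states are refused with an error).
#' @return The reservoir, invisibly.
#' @export
qs_record <- function(reservoir, state, dwell, cfg) {
  stopifnot(inherits(reservoir, "qs_reservoir"), dwell > 0)
  if (is_absorbing(state, cfg))
    stop("refusing to record an absorbing state into the reservoir")
  reservoir$n_records <- reservoir$n_records + 1L
  k <- length(reservoir$states)
  if (k < reservoir$capacity) {
    reservoir$states[[k + 1L]] <- state
    reservoir$weights <- c(reservoir$weights, dwell)
  } else {
    keep <- if (reservoir$memory == "full")
      runif(1) < reservoir$capacity / reservoir$n_records
    else TRUE
    if (keep) {
      i <- min(floor(runif(1) * k), k - 1) + 1L
      reservoir$states[[i]] <- state
      reservoir$weights[i] <- dwell
    }
  }
  invisible(reservoir)
}

#' Teleport: sample a stored state proportionally to dwell weight
#'
#' @param reservoir a non-empty [qs_reservoir()].
#' @return A [strategy_state()] copy of a stored snapshot, drawn with
#'   probability `dwell_weight / total_weight`. Errors on an empty
#'   reservoir (absorption happened before any active state was recorded;
#'   the caller should restart the run).
#' @export
qs_teleport <- function(reservoir) {
  stopifnot(inherits(reservoir, "qs_reservoir"))
  k <- length(reservoir$states)
  if (k == 0L)
    stop("empty reservoir: the run absorbed before any active state was recorded")
  i <- if (k == 1L) 1L else
    sample.int(k, 1L, prob = reservoir$weights)
  reservoir$states[[i]]
}

#' Evolve the dynamics with the quasi-stationary method
#'
#' Runs `n_mcs` Monte Carlo steps. After every MCS the absorbing condition
#' (`cfg$absorbing_trigger`) is checked; upon absorption the state is
#' replaced by a reservoir teleport before continuing, so the reported
#' trajectory always consists of active states. Active states are recorded
#' into the reservoir every `cadence` MCS (with the cadence as dwell
#' weight); the initial state seeds the reservoir so an early absorption
#' teleports back to the start.
#'
#' @param h a [hypergraph()].
#' @param state initial [strategy_state()]; must not be absorbing.
#' @param scheme a [make_scheme()] payoff scheme.
#' @param cfg a [dynamics_config()].
#' @param n_mcs number of Monte Carlo steps.
#' @param capacity reservoir capacity (snapshots).
#' @param cadence recording cadence in MCS.
#' @param memory reservoir replacement policy, see [qs_reservoir()].
#' @return List: `trajectory` (data frame with one row per MCS: `mcs`,
#'   `rho_pair`, `rho_tri`, `rho`), `state` (final state), `n_teleports`,
#'   and the `reservoir`.
#' @export
evolve_quasistationary <- function(h, state, scheme, cfg, n_mcs,
                                   capacity = 100L, cadence = 1L,
                                   memory = c("recent", "full")) {
  stopifnot(inherits(h, "hypergraph"), state$mode == cfg$mode, n_mcs >= 1)
  if (is_absorbing(state, cfg))
    stop("initial state is absorbing; start from a mixed configuration")
  n <- h$n_nodes
  vec <- cfg$mode == "vector"
  pk <- pack_hypergraph(h)
  res <- qs_reservoir(capacity, memory = match.arg(memory))
  qs_record(res, state, cadence, cfg)
  sp <- if (vec) state$pair else state$slot
  st <- if (vec) state$tri else state$slot
  n_up <- if (vec) 2L * n else n
  rho_pair <- numeric(n_mcs)
  rho_tri <- numeric(n_mcs)
  n_teleports <- 0L
  for (t in seq_len(n_mcs)) {
    out <- run_updates_packed(pk, sp, st, scheme, cfg, n_up)
    sp <- out$pair
    st <- out$tri
    cur <- if (vec) strategy_state(pair = sp, tri = st)
           else strategy_state(slot = sp)
    if (is_absorbing(cur, cfg)) {
      cur <- qs_teleport(res)
      sp <- if (vec) cur$pair else cur$slot
      st <- if (vec) cur$tri else cur$slot
      n_teleports <- n_teleports + 1L
    } else if (t %% cadence == 0L) {
      qs_record(res, cur, cadence, cfg)
    }
    rho_pair[t] <- mean(sp)
    rho_tri[t] <- if (vec) mean(st) else rho_pair[t]
  }
  list(trajectory = data.frame(mcs = seq_len(n_mcs), rho_pair = rho_pair,
                               rho_tri = rho_tri,
                               rho = (rho_pair + rho_tri) / 2),
       state = cur, n_teleports = n_teleports, reservoir = res)
}
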