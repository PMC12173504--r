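#' Configuration of a stationary-state ensemble experiment
#'
#' Bundles the structural, game, dynamical and sampling parameters of one
#' parameter point. Defaults are the model's study conditions: `N = 1500`
#' players with pairwise degree 4 and two triangles per node, noise
#' `w = 1 / (k_pair + k_tri)`, initial cooperator density 0.5 in both slot
#' types, `1e5` MCS with the last `1e4` as the stationary window, and
#' `M = 400` independent runs. Scaled-down values (e.g. `n_nodes = 300`,
#' `n_mcs = 2e4`, `stationary_window = 2e3`, `n_runs = 20`) reproduce the
#' same phenomenology at desk scale.
#'
#' @param alpha higher-order dilemma strength (see [make_scheme()]).
#' @param pswitch inter-order coupling probability.
#' @param omega_target topological overlap to rewire the structure to.
#' @param n_nodes,k_pair,k_tri structure parameters.
#' @param w Fermi noise; `NULL` means `1 / (k_pair + k_tri)`.
#' @param rho0_pair,rho0_tri initial cooperator densities per slot type
#'   (scalar mode uses `rho0_pair`).
#' @param n_mcs,stationary_window run length and averaging window (MCS).
#' @param n_runs ensemble size M.
#' @param mode `"vector"` or `"scalar"`.
#' @param master_seed integer seed from which per-run seeds are derived.
#' @param omega_tol,max_swaps rewiring tolerance and attempt budget.
#' @param qs_capacity,qs_cadence,qs_memory reservoir parameters (see
#'   [qs_reservoir()]).
#' @param neighbour_rule,absorbing_trigger see [dynamics_config()].
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(alpha, pswitch, omega_target,
                              n_nodes = 1500L, k_pair = 4L, k_tri = 2L,
                              w = NULL, rho0_pair = 0.5, rho0_tri = 0.5,
                              n_mcs = 1e5, stationary_window = 1e4,
                              n_runs = 400L, mode = c("vector", "scalar"),
                              master_seed = 1L, omega_tol = 0.01,
                              max_swaps = NULL, qs_capacity = 100L,
                              qs_cadence = 1L,
                              qs_memory = c("recent", "full"),
                              neighbour_rule = "union_unique",
                              absorbing_trigger = "either_layer") {
  mode <- match.arg(mode)
  qs_memory <- match.arg(qs_memory)
  if (is.null(w)) w <- 1 / (k_pair + k_tri)
  stopifnot(rho0_pair >= 0, rho0_pair <= 1, rho0_tri >= 0, rho0_tri <= 1,
            stationary_window <= n_mcs, n_runs >= 1)
  cfg <- list(alpha = alpha, pswitch = pswitch, omega_target = omega_target,
              n_nodes = as.integer(n_nodes), k_pair = as.integer(k_pair),
              k_tri = as.integer(k_tri), w = w, rho0_pair = rho0_pair,
              rho0_tri = rho0_tri, n_mcs = as.integer(n_mcs),
              stationary_window = as.integer(stationary_window),
              n_runs = as.integer(n_runs), mode = mode,
              master_seed = as.integer(master_seed), omega_tol = omega_tol,
              max_swaps = max_swaps, qs_capacity = as.integer(qs_capacity),
              qs_cadence = as.integer(qs_cadence), qs_memory = qs_memory,
              neighbour_rule = neighbour_rule,
              absorbing_trigger = absorbing_trigger)
  class(cfg) <- "experiment_config"
  cfg
}

#' Initial strategy state with exact cooperator counts
#'
#' Places exactly `round(rho0 * n_nodes)` cooperators per slot type at
#' uniformly random positions without replacement (independently per slot
#' type in vector mode) — an "equal number of cooperators and defectors"
#' start at the default densities of 0.5, not a Bernoulli draw.
#'
#' @param n_nodes number of players.
#' @param rho0_pair,rho0_tri initial cooperator densities.
#' @param mode `"vector"` or `"scalar"` (scalar uses `rho0_pair`).
#' @return A [strategy_state()].
#' @export
initialize_state <- function(n_nodes, rho0_pair = 0.5, rho0_tri = rho0_pair,
                             mode = c("vector", "scalar")) {
  mode <- match.arg(mode)
  draw <- function(rho) {
    v <- integer(n_nodes)
    v[sample.int(n_nodes, round(rho * n_nodes))] <- 1L
    v
  }
  if (mode == "scalar") strategy_state(slot = draw(rho0_pair))
  else strategy_state(pair = draw(rho0_pair), tri = draw(rho0_tri))
}

run_dynamics_config <- function(cfg) {
  dynamics_config(w = cfg$w, pswitch = cfg$pswitch, mode = cfg$mode,
                  neighbour_rule = cfg$neighbour_rule,
                  absorbing_trigger = cfg$absorbing_trigger)
}

#' One independent run: build, rewire, evolve, average
#'
#' Seeds the RNG with `run_seed`, builds a fresh full-overlap structure,
#' rewires it to the configured overlap, draws the initial state, evolves it
#' with [evolve_quasistationary()], and returns the time averages of the
#' cooperation densities over the stationary window (the last
#' `cfg$stationary_window` MCS).
#'
#' @param cfg an [experiment_config()].
#' @param run_seed integer seed for this run (structure and dynamics).
#' @return Named list: `rho_pair`, `rho_tri`, `rho` (stationary means),
#'   `omega` (achieved overlap), `n_teleports`.
#' @export
run_single <- function(cfg, run_seed) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(run_seed)
  h <- build_full_overlap(cfg$n_nodes, cfg$k_pair, cfg$k_tri)
  if (cfg$omega_target < 1)
    h <- rewire_to_overlap(h, cfg$omega_target, tolerance = cfg$omega_tol,
                           max_swaps = cfg$max_swaps)
  state <- initialize_state(cfg$n_nodes, cfg$rho0_pair, cfg$rho0_tri,
                            mode = cfg$mode)
  dyn <- run_dynamics_config(cfg)
  ev <- evolve_quasistationary(h, state, make_scheme(cfg$alpha), dyn,
                               n_mcs = cfg$n_mcs, capacity = cfg$qs_capacity,
                               cadence = cfg$qs_cadence,
                               memory = cfg$qs_memory)
  win <- ev$trajectory[ev$trajectory$mcs > cfg$n_mcs - cfg$stationary_window, ]
  list(rho_pair = mean(win$rho_pair), rho_tri = mean(win$rho_tri),
       rho = mean(win$rho), omega = compute_overlap(h)$omega,
       n_teleports = ev$n_teleports)
}

#' Ensemble of independent runs at one parameter point
#'
#' Executes `cfg$n_runs` independent [run_single()] calls. Per-run seeds are
#' spawned deterministically from `cfg$master_seed` (a `sample.int` stream
#' seeded with the master seed), so identical configurations reproduce
#' byte-identical results. Each run regenerates and rewires its own
#' structure, averaging over structural as well as dynamical randomness.
#'
#' @param cfg an [experiment_config()].
#' @return Object of class `ensemble_result`: `per_run` (data frame with one
#'   row per run), ensemble means `mean_rho`, `mean_rho_pair`,
#'   `mean_rho_tri`, the standard error `se_rho`, and the full `config`.
#' @export
run_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(cfg$master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_runs)
  rows <- lapply(seq_len(cfg$n_runs), function(i) {
    r <- run_single(cfg, seeds[i])
    data.frame(run = i, seed = seeds[i], rho_pair = r$rho_pair,
               rho_tri = r$rho_tri, rho = r$rho, omega = r$omega,
               n_teleports = r$n_teleports)
  })
  per_run <- do.call(rbind, rows)
  structure(list(
    per_run = per_run,
    mean_rho = mean(per_run$rho),
    mean_rho_pair = mean(per_run$rho_pair),
    mean_rho_tri = mean(per_run$rho_tri),
    se_rho = stats::sd(per_run$rho) / sqrt(nrow(per_run)),
    config = cfg), class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<ensemble_result> M=%d runs | alpha=%g pswitch=%g omega=%g N=%d\n",
    "  <rho> = %.4f (se %.4f)   <rho_pair> = %.4f   <rho_tri> = %.4f\n"),
    nrow(x$per_run), x$config$alpha, x$config$pswitch,
    x$config$omega_target, x$config$n_nodes,
    x$mean_rho, x$se_rho, x$mean_rho_pair, x$mean_rho_tri))
  invisible(x)
}

#' Parameter sweep over pswitch, overlap and dilemma strength
#'
#' Runs [run_ensemble()] on the Cartesian product of the supplied grids
#' (any of `pswitch`, `omega`, `alpha`; missing grids stay at the base
#' configuration's value) and returns a long-format table, one row per grid
#' point, in deterministic row order. Each point uses master seed
#' `base$master_seed + point_index - 1`.
#'
#' @param base an [experiment_config()] providing all non-swept parameters.
#' @param pswitch,omega,alpha numeric vectors of grid values (optional).
#' @return Data frame with the grid columns plus `mean_rho`,
#'   `mean_rho_pair`, `mean_rho_tri` and `se_rho`.
#' @export
run_sweep <- function(base, pswitch = NULL, omega = NULL, alpha = NULL) {
  stopifnot(inherits(base, "experiment_config"))
  grid <- expand.grid(
    pswitch = if (is.null(pswitch)) base$pswitch else pswitch,
    omega = if (is.null(omega)) base$omega_target else omega,
    alpha = if (is.null(alpha)) base$alpha else alpha,
    KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base
    cfg$pswitch <- grid$pswitch[i]
    cfg$omega_target <- grid$omega[i]
    cfg$alpha <- grid$alpha[i]
    cfg$master_seed <- base$master_seed + i - 1L
    res <- run_ensemble(cfg)
    data.frame(pswitch = cfg$pswitch, omega = cfg$omega_target,
               alpha = cfg$alpha, n_nodes = cfg$n_nodes,
               n_runs = cfg$n_runs, mode = cfg$mode,
               mean_rho = res$mean_rho, mean_rho_pair = res$mean_rho_pair,
               mean_rho_tri = res$mean_rho_tri, se_rho = res$se_rho)
  })
  do.call(rbind, rows)
}

# enumeration helpers for the exact chain: a state index encodes all slots
# as bits (vector mode: bit j = pair slot of node j, bit N+j = tri slot)
decode_state <- function(idx, n_slots) {
  as.integer(bitwAnd(bitwShiftR(idx, 0:(n_slots - 1L)), 1L))
}
encode_state <- function(bits) {
  sum(bitwShiftL(as.integer(bits), 0:(length(bits) - 1L)))
}

#' Exact Markov chain solver for small systems
#'
#' Enumerates every joint strategy configuration of a small hypergraph
#' (at most 12 slots, i.e. 4096 states), builds the exact one-step
#' transition matrix of the elementary-update chain — focal uniform, model
#' per `cfg$neighbour_rule`, the five-outcome distribution of
#' [outcome_probabilities()] — and solves for the absorption probabilities
#' from every transient state by linear algebra. This is the independent
#' oracle the simulation is validated against.
#'
#' @param h a small [hypergraph()].
#' @param scheme a [make_scheme()] payoff scheme (any object with the same
#'   payoff fields works, e.g. a degenerate equal-payoff scheme).
#' @param cfg a [dynamics_config()].
#' @return List: `transition` (dense transition matrix over all states),
#'   `absorbing` (0-based state indices with `P[s,s] = 1`), and `absorption`
#'   (matrix of absorption probabilities, transient states x absorbing
#'   states, with dimnames giving the 0-based state indices).
#' @export
exact_small_system_oracle <- function(h, scheme, cfg) {
  stopifnot(inherits(h, "hypergraph"))
  n <- h$n_nodes
  vec <- cfg$mode == "vector"
  n_slots <- if (vec) 2L * n else n
  if (n_slots > 12L)
    stop("state space too large: ", n_slots, " slots (limit 12)")
  n_states <- 2L^n_slots
  P <- matrix(0, n_states, n_states)
  model_dist <- lapply(seq_len(n) - 1L, function(f) {
    cp <- co_players(h, f)
    if (cfg$neighbour_rule == "union_unique") {
      u <- cp$union
      stats::setNames(rep(1 / length(u), length(u)), u)
    } else {
      pw <- h$pair_adj[[f + 1L]]
      tp <- cp$triangle
      pr <- c(stats::setNames(rep(0.5 / length(pw), length(pw)), pw),
              stats::setNames(rep(0.5 / length(tp), length(tp)), tp))
      tapply(pr, names(pr), sum)
    }
  })
  for (s in 0:(n_states - 1L)) {
    bits <- decode_state(s, n_slots)
    state <- if (vec) strategy_state(pair = bits[1:n], tri = bits[n + 1:n])
             else strategy_state(slot = bits)
    pay <- vapply(seq_len(n) - 1L, function(i) total_payoff(h, state, i, scheme),
                  numeric(1))
    for (f in seq_len(n)) {
      md <- model_dist[[f]]
      for (mi in seq_along(md)) {
        m <- as.integer(names(md)[mi])
        pi_t <- fermi_probability(pay[m + 1L], pay[f], cfg$w)
        if (vec) {
          probs <- outcome_probabilities(pi_t, cfg$pswitch)
          targets <- list(
            pair_from_pair = c(f, bits[m + 1L]),
            pair_from_tri  = c(f, bits[n + m + 1L]),
            tri_from_tri   = c(n + f, bits[n + m + 1L]),
            tri_from_pair  = c(n + f, bits[m + 1L]))
          for (o in names(targets)) {
            nb <- bits
            nb[targets[[o]][1L]] <- targets[[o]][2L]
            s2 <- encode_state(nb)
            P[s + 1L, s2 + 1L] <- P[s + 1L, s2 + 1L] +
              md[mi] * probs[[o]] / n
          }
          P[s + 1L, s + 1L] <- P[s + 1L, s + 1L] +
            md[mi] * probs[["no_change"]] / n
        } else {
          nb <- bits
          nb[f] <- bits[m + 1L]
          s2 <- encode_state(nb)
          P[s + 1L, s2 + 1L] <- P[s + 1L, s2 + 1L] + md[mi] * pi_t / n
          P[s + 1L, s + 1L] <- P[s + 1L, s + 1L] + md[mi] * (1 - pi_t) / n
        }
      }
    }
  }
  absorbing <- which(abs(diag(P) - 1) < 1e-12) - 1L
  transient <- setdiff(0:(n_states - 1L), absorbing)
  Q <- P[transient + 1L, transient + 1L, drop = FALSE]
  R <- P[transient + 1L, absorbing + 1L, drop = FALSE]
  B <- solve(diag(length(transient)) - Q, R)
  dimnames(B) <- list(transient, absorbing)
  list(transition = P, absorbing = absorbing, absorption = B)
}

#' Simulate one run to fixation (no quasi-stationary teleports)
#'
#' Evolves the plain dynamics until no elementary update can change the
#' state (the `"joint"` absorbing condition) and reports where it fixated.
#' Used to validate the compiled simulation against
#' [exact_small_system_oracle()].
#'
#' @param h a [hypergraph()].
#' @param state initial [strategy_state()].
#' @param scheme a payoff scheme.
#' @param cfg a [dynamics_config()].
#' @param max_mcs bail-out bound on the number of MCS.
#' @return List: `state` (the absorbing state), `state_index` (its 0-based
#'   encoding, bit `j` = pair slot of node `j`, bit `N + j` = triangle
#'   slot), `n_mcs` used.
#' @export
simulate_fixation <- function(h, state, scheme, cfg, max_mcs = 1e5) {
  stopifnot(inherits(h, "hypergraph"), state$mode == cfg$mode)
  joint_cfg <- cfg
  joint_cfg$absorbing_trigger <- "joint"
  pk <- pack_hypergraph(h)
  vec <- cfg$mode == "vector"
  sp <- if (vec) state$pair else state$slot
  st <- if (vec) state$tri else state$slot
  n_up <- if (vec) 2L * h$n_nodes else h$n_nodes
  for (t in seq_len(max_mcs)) {
    cur <- if (vec) strategy_state(pair = sp, tri = st)
           else strategy_state(slot = sp)
    if (is_absorbing(cur, joint_cfg))
      return(list(state = cur,
                  state_index = encode_state(if (vec) c(sp, st) else sp),
                  n_mcs = t - 1L))
    out <- run_updates_packed(pk, sp, st, scheme, cfg, n_up)
    sp <- out$pair
    st <- out$tri
  }
  stop("no fixation within ", max_mcs, " MCS")
}
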