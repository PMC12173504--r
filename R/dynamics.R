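#' Per-node strategy state
#'
#' In vector mode every node holds two strategy slots, one used in pairwise
#' games and one in three-player games; in scalar mode a single slot is used
#' at both orders (the uni-dimensional baseline). Strategies are stored as
#' integers, 1 = cooperate, 0 = defect; `"C"`/`"D"` character vectors are
#' accepted.
#'
#' @param pair,tri per-node slot vectors (vector mode).
#' @param slot per-node slot vector (scalar mode).
#' @return Object of class `strategy_state` with fields `mode`
#'   (`"vector"`/`"scalar"`), `n_nodes`, and `pair`/`tri` or `slot`.
#' @export
strategy_state <- function(pair = NULL, tri = NULL, slot = NULL) {
  if (!is.null(slot)) {
    if (!is.null(pair) || !is.null(tri))
      stop("supply either slot (scalar mode) or pair+tri (vector mode)")
    s <- list(mode = "scalar", n_nodes = length(slot),
              slot = as_strategy_int(slot))
  } else {
    if (is.null(pair) || is.null(tri) || length(pair) != length(tri))
      stop("vector mode needs pair and tri slot vectors of equal length")
    s <- list(mode = "vector", n_nodes = length(pair),
              pair = as_strategy_int(pair), tri = as_strategy_int(tri))
  }
  class(s) <- "strategy_state"
  s
}

#' @export
print.strategy_state <- function(x, ...) {
  d <- densities(x)
  cat(sprintf("<strategy_state> %s mode, %d nodes: rho_pair=%.3f rho_tri=%.3f rho=%.3f\n",
              x$mode, x$n_nodes, d[["rho_pair"]], d[["rho_tri"]], d[["rho"]]))
  invisible(x)
}

#' Cooperator densities of a state
#'
#' `rho_pair` and `rho_tri` are the cooperator fractions in the pairwise and
#' triangle slots; the overall cooperation level is their mean,
#' `rho = (rho_pair + rho_tri) / 2`. In scalar mode all three coincide.
#'
#' @param state a [strategy_state()].
#' @return Named numeric vector `c(rho_pair, rho_tri, rho)`.
#' @export
densities <- function(state) {
  stopifnot(inherits(state, "strategy_state"))
  if (state$mode == "scalar") {
    r <- mean(state$slot)
    c(rho_pair = r, rho_tri = r, rho = r)
  } else {
    rp <- mean(state$pair); rt <- mean(state$tri)
    c(rho_pair = rp, rho_tri = rt, rho = (rp + rt) / 2)
  }
}

#' Configuration of the imitation dynamics
#'
#' @param w selection noise of the Fermi rule (inverse payoff scale),
#'   `w >= 0`. The model's convention is `w = 1 / (k_pair + k_tri)`;
#'   [experiment_config()] fills that in from the configured degrees.
#' @param pswitch probability that an imitation event copies the model
#'   player's strategy from the *other* interaction order (inter-order
#'   dynamical coupling), in `[0, 1]`. Meaningless in scalar mode.
#' @param mode `"vector"` (two strategy slots per node) or `"scalar"`.
#' @param neighbour_rule how the model player is drawn: `"union_unique"`
#'   (uniform over the de-duplicated union of co-players across both layers;
#'   the default) or `"layer_then_neighbour"` (a layer with probability 1/2,
#'   then a uniform co-player within it).
#' @param absorbing_trigger `"either_layer"` (absorbing as soon as either
#'   slot type is homogeneous; the model's literal rule) or `"joint"`
#'   (absorbing only when no elementary update can change the state).
#' @return Object of class `dynamics_config`.
#' @export
dynamics_config <- function(w, pswitch = 0, mode = c("vector", "scalar"),
                            neighbour_rule = c("union_unique",
                                               "layer_then_neighbour"),
                            absorbing_trigger = c("either_layer", "joint")) {
  mode <- match.arg(mode)
  neighbour_rule <- match.arg(neighbour_rule)
  absorbing_trigger <- match.arg(absorbing_trigger)
  if (w < 0) stop("w must be >= 0")
  if (pswitch < 0 || pswitch > 1) stop("pswitch must be in [0, 1]")
  structure(list(w = w, pswitch = pswitch, mode = mode,
                 neighbour_rule = neighbour_rule,
                 absorbing_trigger = absorbing_trigger),
            class = "dynamics_config")
}

#' Fermi imitation probability
#'
#' Probability that the focal player adopts the model player's strategy,
#' `1 / (1 + exp(-w (payoff_model - payoff_focal)))`: a sigmoid in the payoff
#' difference. As `w -> Inf` it approaches a step function (better payoff is
#' always copied); at `w = 0` it is exactly 1/2 regardless of payoffs
#' (neutral drift). Overflow-safe for any `w * delta`.
#'
#' @param payoff_model,payoff_focal total payoffs of model and focal player.
#' @param w selection noise, `w >= 0`.
#' @return Probability in `[0, 1]`; vectorized over its arguments.
#' @export
fermi_probability <- function(payoff_model, payoff_focal, w) {
  if (any(w < 0)) stop("w must be >= 0")
  1 / (1 + exp(-w * (payoff_model - payoff_focal)))
}

#' Outcome distribution of one elementary update
#'
#' Given the Fermi probability of the chosen focal/model pair, an elementary
#' update in vector mode realizes exactly one of five outcomes: copy the
#' model's pairwise slot into the focal pairwise slot (probability
#' `0.5 (1 - pswitch) fermi_prob`), copy the model's triangle slot into the
#' focal pairwise slot (`0.5 pswitch fermi_prob`), and the two mirrored
#' triangle-slot updates; otherwise nothing changes (`1 - fermi_prob`). At
#' most one focal slot changes per update.
#'
#' @param fermi_prob imitation probability from [fermi_probability()].
#' @param pswitch inter-order coupling probability.
#' @return Named numeric vector of the five outcome probabilities
#'   (`pair_from_pair`, `pair_from_tri`, `tri_from_tri`, `tri_from_pair`,
#'   `no_change`); sums to 1.
#' @export
outcome_probabilities <- function(fermi_prob, pswitch) {
  c(pair_from_pair = 0.5 * (1 - pswitch) * fermi_prob,
    pair_from_tri  = 0.5 * pswitch * fermi_prob,
    tri_from_tri   = 0.5 * (1 - pswitch) * fermi_prob,
    tri_from_pair  = 0.5 * pswitch * fermi_prob,
    no_change      = 1 - fermi_prob)
}

#' Draw a focal player and a model player
#'
#' The focal player is uniform over all nodes; the model player is one of
#' its co-players, drawn according to `cfg$neighbour_rule`. Consumes random
#' draws in the documented order (focal, then model; the layer rule uses a
#' layer draw followed by a neighbour draw), so runs are reproducible from a
#' seed and bit-compatible with the compiled update loop.
#'
#' @param h a [hypergraph()].
#' @param cfg a [dynamics_config()].
#' @return Integer vector `c(focal, model)` of 0-based node ids.
#' @export
pick_focal_and_model <- function(h, cfg) {
  stopifnot(inherits(h, "hypergraph"))
  n <- h$n_nodes
  f <- min(floor(runif(1) * n), n - 1)
  cp <- co_players(h, f)
  pool <- if (cfg$neighbour_rule == "union_unique") {
    cp$union
  } else if (runif(1) < 0.5) h$pair_adj[[f + 1L]] else cp$triangle
  if (!length(pool))
    stop("node ", f, " has no co-players in the drawn layer")
  m <- pool[min(floor(runif(1) * length(pool)), length(pool) - 1) + 1L]
  c(focal = as.integer(f), model = as.integer(m))
}

#' One elementary update of the imitation dynamics (vector mode)
#'
#' Draws a focal and a model player, computes both players' total payoffs
#' fresh over all their games in both layers, evaluates the Fermi
#' probability once from the totals, and realizes one of the five outcomes
#' of [outcome_probabilities()] by sequential draws: target slot (pairwise
#' with probability 1/2), source order (the other order with probability
#' `pswitch`), acceptance (with the Fermi probability). A copy whose source
#' value equals the current target value is counted as an accepted no-op.
#'
#' This is the pure-R reference path; [monte_carlo_step()] and the
#' quasi-stationary driver run the same update (identical draw order and
#' summation order, hence bit-identical trajectories for a given seed) in
#' compiled code.
#'
#' @param h a [hypergraph()].
#' @param state a [strategy_state()] in vector mode.
#' @param scheme a [make_scheme()] payoff scheme.
#' @param cfg a [dynamics_config()] with `mode = "vector"`.
#' @return List with `state` (the updated state) and `event` (focal, model,
#'   `target_slot`, `source_slot`, `fermi_prob`, `accepted`).
#' @export
elementary_update <- function(h, state, scheme, cfg) {
  stopifnot(state$mode == "vector", cfg$mode == "vector")
  fm <- pick_focal_and_model(h, cfg)
  pi_t <- fermi_probability(total_payoff(h, state, fm[["model"]], scheme),
                            total_payoff(h, state, fm[["focal"]], scheme),
                            cfg$w)
  target_pair <- runif(1) < 0.5
  cross <- runif(1) < cfg$pswitch
  accepted <- runif(1) < pi_t
  target_slot <- if (target_pair) "pair" else "tri"
  source_slot <- if (target_pair == cross) "tri" else "pair"
  if (accepted) {
    src <- if (source_slot == "pair") state$pair else state$tri
    if (target_pair) state$pair[fm[["focal"]] + 1L] <- src[fm[["model"]] + 1L]
    else             state$tri[fm[["focal"]] + 1L] <- src[fm[["model"]] + 1L]
  }
  list(state = state,
       event = list(focal = fm[["focal"]], model = fm[["model"]],
                    target_slot = target_slot, source_slot = source_slot,
                    fermi_prob = pi_t, accepted = accepted))
}

#' One elementary update of the scalar-strategy baseline
#'
#' In the uni-dimensional baseline each node has a single strategy used at
#' both orders; the focal player copies the model's strategy with the Fermi
#' probability computed from total payoffs. No slot or source distinction
#' exists, so the inter-order coupling is meaningless here.
#'
#' @inheritParams elementary_update
#' @param state a [strategy_state()] in scalar mode.
#' @return List with `state` and `event` as in [elementary_update()] (slots
#'   reported as `"scalar"`).
#' @export
scalar_update <- function(h, state, scheme, cfg) {
  stopifnot(state$mode == "scalar", cfg$mode == "scalar")
  fm <- pick_focal_and_model(h, cfg)
  pi_t <- fermi_probability(total_payoff(h, state, fm[["model"]], scheme),
                            total_payoff(h, state, fm[["focal"]], scheme),
                            cfg$w)
  accepted <- runif(1) < pi_t
  if (accepted)
    state$slot[fm[["focal"]] + 1L] <- state$slot[fm[["model"]] + 1L]
  list(state = state,
       event = list(focal = fm[["focal"]], model = fm[["model"]],
                    target_slot = "scalar", source_slot = "scalar",
                    fermi_prob = pi_t, accepted = accepted))
}

# scheme packed for the compiled loop: R,S,T,P (pair), R,G,S (coop tri),
# T,W,P (defect tri)
pack_scheme <- function(scheme) {
  c(scheme$R_pair, scheme$S_pair, scheme$T_pair, scheme$P_pair,
    scheme$R_tri, scheme$G_tri, scheme$S_tri,
    scheme$T_tri, scheme$W_tri, scheme$P_tri)
}

# flat (CSR) adjacency arrays consumed by the compiled update loop; layer
# orders match the R reference: pair_adj insertion order, triangle partners
# sorted within each triangle, union / de-duplicated lists sorted
pack_hypergraph <- function(h) {
  n <- h$n_nodes
  tpart <- vector("list", n)
  tdadj <- vector("list", n)
  uadj <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- h$tri_of_node[[i]]
    if (length(rows)) {
      pm <- lapply(rows, function(r) setdiff(h$triangles[r, ], i - 1L))
      tpart[[i]] <- unlist(pm)
      tdadj[[i]] <- sort(unique(tpart[[i]]))
    } else {
      tpart[[i]] <- integer(0)
      tdadj[[i]] <- integer(0)
    }
    uadj[[i]] <- sort(unique(c(h$pair_adj[[i]], tdadj[[i]])))
  }
  list(n = n,
       padj = as.integer(unlist(h$pair_adj)),
       poff = c(0L, cumsum(lengths(h$pair_adj))),
       tpart = as.integer(unlist(tpart)),
       toff = c(0L, cumsum(lengths(tpart))),
       uadj = as.integer(unlist(uadj)),
       uoff = c(0L, cumsum(lengths(uadj))),
       tdadj = as.integer(unlist(tdadj)),
       tdoff = c(0L, cumsum(lengths(tdadj))))
}

# run n_updates compiled elementary updates on packed arrays; returns new
# slot vectors plus acceptance counters
run_updates_packed <- function(pk, sp, st, scheme, cfg, n_updates) {
  hc_run_updates(as.integer(n_updates), sp, st,
                 pk$padj, pk$poff, pk$tpart, pk$toff,
                 pk$uadj, pk$uoff, pk$tdadj, pk$tdoff,
                 pack_scheme(scheme), cfg$w, cfg$pswitch,
                 as.integer(cfg$mode == "vector"),
                 as.integer(cfg$neighbour_rule == "layer_then_neighbour"))
}

#' One full Monte Carlo step
#'
#' A Monte Carlo step (MCS) consists of `2 N` elementary updates in vector
#' mode — each player gets the opportunity to update both of its strategy
#' slots once on average — and `N` updates in scalar mode. Runs in compiled
#' code; equivalent to applying [elementary_update()] (or [scalar_update()])
#' that many times.
#'
#' @inheritParams elementary_update
#' @param state a [strategy_state()] matching `cfg$mode`.
#' @return The updated [strategy_state()].
#' @export
monte_carlo_step <- function(h, state, scheme, cfg) {
  stopifnot(inherits(h, "hypergraph"), state$mode == cfg$mode)
  pk <- pack_hypergraph(h)
  vec <- cfg$mode == "vector"
  out <- run_updates_packed(pk,
                            if (vec) state$pair else state$slot,
                            if (vec) state$tri else state$slot,
                            scheme, cfg,
                            if (vec) 2L * h$n_nodes else h$n_nodes)
  if (vec) strategy_state(pair = out$pair, tri = out$tri)
  else strategy_state(slot = out$pair)
}

slot_homogeneous <- function(v) all(v == v[1L])

#' Is a state absorbing?
#'
#' Under the `"either_layer"` trigger (the model's literal rule) a vector
#' state is absorbing as soon as the pairwise slots are homogeneous *or* the
#' triangle slots are homogeneous — full cooperation or defection in either
#' interaction order. Under `"joint"` the state is absorbing only when no
#' elementary update can change it: with `pswitch > 0` cross-order copies
#' couple the layers, so all `2 N` slot values must coincide; at
#' `pswitch = 0` each layer must be homogeneous on its own. Scalar states
#' are absorbing when the single slot is homogeneous.
#'
#' @param state a [strategy_state()].
#' @param cfg a [dynamics_config()].
#' @return Logical flag.
#' @export
is_absorbing <- function(state, cfg) {
  stopifnot(inherits(state, "strategy_state"))
  if (state$mode == "scalar") return(slot_homogeneous(state$slot))
  if (cfg$absorbing_trigger == "either_layer") {
    slot_homogeneous(state$pair) || slot_homogeneous(state$tri)
  } else if (cfg$pswitch > 0) {
    slot_homogeneous(c(state$pair, state$tri))
  } else {
    slot_homogeneous(state$pair) && slot_homogeneous(state$tri)
  }
}
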