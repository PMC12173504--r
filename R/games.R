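#' Comparability-constrained payoff scheme for two- and three-player dilemmas
#'
#' Builds the full payoff scheme of the model: a pairwise prisoner's dilemma
#' matrix with entries T > R > P > S (temptation, reward, punishment,
#' sucker), a three-player payoff cube whose diagonal-profile entries are the
#' pairwise ones doubled (so one triangle of unanimous partners is worth
#' exactly two pair games: the comparability constraint), and the two payoffs
#' with no pairwise counterpart: `G_tri`, earned by each cooperator in a
#' mixed \{C, C, D\} group, and `W_tri`, earned by each defector in a mixed
#' \{D, D, C\} group. The dilemma strength is `alpha = W_tri - G_tri`:
#' positive alpha gives a strong social dilemma (defection is always the
#' rational switch), negative alpha a relaxed one (a lone defector among
#' cooperators is a second Nash equilibrium).
#'
#' @param alpha dilemma strength; `G_tri` is set to `W_tri - alpha`. The
#'   model's explored range is `[-1.4, 0.3]`, but any value is accepted (the
#'   violated dilemma conditions are reported by [classify_dilemma()]).
#' @param T_pair,R_pair,P_pair,S_pair pairwise payoffs; defaults 1.1, 1, 0,
#'   -0.1. Must satisfy `T > R > P > S`.
#' @param W_tri each defector's payoff in a mixed \{D, D, C\} group;
#'   default 0.7.
#' @return Object of class `payoff_scheme`: all eight base payoffs plus
#'   `G_tri`, `W_tri` and `alpha`.
#' @export
make_scheme <- function(alpha, T_pair = 1.1, R_pair = 1, P_pair = 0,
                        S_pair = -0.1, W_tri = 0.7) {
  ord <- c(T = T_pair, R = R_pair, P = P_pair, S = S_pair)
  bad <- which(diff(ord) >= 0)
  if (length(bad))
    stop("pairwise ordering violated: ", names(ord)[bad[1L]], " (",
         ord[bad[1L]], ") must exceed ", names(ord)[bad[1L] + 1L], " (",
         ord[bad[1L] + 1L], ")")
  s <- list(
    T_pair = T_pair, R_pair = R_pair, P_pair = P_pair, S_pair = S_pair,
    T_tri = 2 * T_pair, R_tri = 2 * R_pair, P_tri = 2 * P_pair,
    S_tri = 2 * S_pair, W_tri = W_tri, G_tri = W_tri - alpha, alpha = alpha)
  class(s) <- "payoff_scheme"
  s
}

#' @export
print.payoff_scheme <- function(x, ...) {
  cat(sprintf("<payoff_scheme> alpha = %g (%s dilemma)\n", x$alpha,
              if (x$alpha > 0) "strong" else if (x$alpha < 0) "relaxed"
              else "boundary"))
  cat(sprintf("  pairwise  T=%g R=%g P=%g S=%g\n",
              x$T_pair, x$R_pair, x$P_pair, x$S_pair))
  cat(sprintf("  triangle  T=%g R=%g P=%g S=%g G=%g W=%g\n",
              x$T_tri, x$R_tri, x$P_tri, x$S_tri, x$G_tri, x$W_tri))
  invisible(x)
}

as_strategy_int <- function(s) {
  if (is.character(s)) {
    v <- match(s, c("D", "C")) - 1L
    if (anyNA(v)) stop("strategies must be \"C\" or \"D\"")
    v
  } else {
    v <- as.integer(s)
    if (anyNA(v) || any(v < 0L | v > 1L))
      stop("integer strategies must be 0 (defect) or 1 (cooperate)")
    v
  }
}

#' Payoffs of a two-player game
#'
#' @param s1,s2 strategies, `"C"`/`"D"` (or 1/0).
#' @param scheme a [make_scheme()] payoff scheme.
#' @return Numeric vector `c(payoff_1, payoff_2)`; symmetric under swapping
#'   the players and the outputs.
#' @export
pair_payoffs <- function(s1, s2, scheme) {
  a <- as_strategy_int(s1); b <- as_strategy_int(s2)
  one <- function(me, other) {
    if (me == 1L) { if (other == 1L) scheme$R_pair else scheme$S_pair }
    else          { if (other == 1L) scheme$T_pair else scheme$P_pair }
  }
  c(one(a, b), one(b, a))
}

# focal payoff in one triangle given own strategy (0/1) and partner
# cooperator count; single source for R and the tests' intuition:
# C faces (2,1,0) cooperators -> R, G, S ; D faces (2,1,0) -> T, W, P
tri_focal_payoff <- function(me, n_coop_partners, scheme) {
  if (me == 1L) {
    switch(n_coop_partners + 1L, scheme$S_tri, scheme$G_tri, scheme$R_tri)
  } else {
    switch(n_coop_partners + 1L, scheme$P_tri, scheme$W_tri, scheme$T_tri)
  }
}

#' Payoffs of a three-player game
#'
#' Evaluates the payoff cube: all cooperators earn `R_tri` each; with one
#' defector the defector takes `T_tri` and each cooperator `G_tri`; with two
#' defectors each defector takes `W_tri` and the cooperator `S_tri`; all
#' defectors earn `P_tri`. Invariant under simultaneous permutation of
#' players and payoffs.
#'
#' @param s1,s2,s3 strategies, `"C"`/`"D"` (or 1/0).
#' @param scheme a [make_scheme()] payoff scheme.
#' @return Numeric vector `c(payoff_1, payoff_2, payoff_3)`.
#' @export
triple_payoffs <- function(s1, s2, s3, scheme) {
  s <- c(as_strategy_int(s1), as_strategy_int(s2), as_strategy_int(s3))
  nc <- sum(s)
  vapply(1:3, function(i) tri_focal_payoff(s[i], nc - s[i], scheme),
         numeric(1))
}

#' Nash social-dilemma classification of a payoff scheme
#'
#' Evaluates the eight inequalities that make the three-player game a social
#' dilemma in Nash's sense: (a) a focal player benefits when others
#' cooperate (`R_tri >= G_tri >= S_tri` and `T_tri >= W_tri >= P_tri`);
#' (b) mutual cooperation beats mutual defection (`R_tri > P_tri`);
#' (c) within any group defectors out-earn cooperators (`T_tri > G_tri`,
#' `W_tri > S_tri`); (d) switching to defection always pays
#' (`T_tri > R_tri`, `W_tri > G_tri`, `P_tri > S_tri`). When
#' `G_tri < W_tri` (alpha > 0) all conditions hold and the dilemma is
#' *strong* (full defection is the only Nash equilibrium); when
#' `G_tri > W_tri` (alpha < 0) the mixed-group switch condition fails and the
#' dilemma is *relaxed* (one defector among two cooperators is also a Nash
#' equilibrium).
#'
#' @param scheme a [make_scheme()] payoff scheme.
#' @return Object of class `dilemma_report`: `category` (`"strong"`,
#'   `"relaxed"` or `"boundary"` when `G_tri == W_tri`),
#'   `violated_conditions` (character vector of condition names), a logical
#'   `conditions` vector, and `nash_note`.
#' @export
classify_dilemma <- function(scheme) {
  s <- scheme
  conditions <- c(
    coop_ranking            = s$R_tri >= s$G_tri && s$G_tri >= s$S_tri,
    defect_ranking          = s$T_tri >= s$W_tri && s$W_tri >= s$P_tri,
    mutual_coop_beats_defect = s$R_tri > s$P_tri,
    defector_tops_lone      = s$T_tri > s$G_tri,
    defector_tops_majority  = s$W_tri > s$S_tri,
    switch_gain_all_coop    = s$T_tri > s$R_tri,
    switch_gain_mixed       = s$W_tri > s$G_tri,
    switch_gain_all_defect  = s$P_tri > s$S_tri)
  category <- if (s$G_tri < s$W_tri) "strong"
              else if (s$G_tri > s$W_tri) "relaxed"
              else "boundary"
  note <- switch(category,
    strong = "only full defection {D,D,D} is a Nash equilibrium",
    relaxed = "besides {D,D,D}, a lone defector {C,C,D} is a Nash equilibrium",
    boundary = paste("G_tri equals W_tri exactly: neither strictly strong",
                     "nor relaxed"))
  structure(list(category = category,
                 violated_conditions = names(conditions)[!conditions],
                 conditions = conditions, nash_note = note),
            class = "dilemma_report")
}

#' @export
print.dilemma_report <- function(x, ...) {
  cat(sprintf("<dilemma_report> %s social dilemma\n", x$category))
  if (length(x$violated_conditions))
    cat("  violated:", paste(x$violated_conditions, collapse = ", "), "\n")
  cat(" ", x$nash_note, "\n")
  invisible(x)
}

#' Total payoff of a node over all its games in both layers
#'
#' Sums the node's pairwise payoffs over its pair edges (each participant
#' plays its pairwise-slot strategy) and its triangle payoffs over its
#' 3-hyperedges (triangle-slot strategies). In scalar mode the single slot is
#' used at both orders. This is the pure-R reference used by the tests; the
#' compiled dynamics loop recomputes the same quantity (with identical
#' summation order) at every elementary update.
#'
#' @param h a [hypergraph()].
#' @param state a [strategy_state()] covering all nodes.
#' @param node 0-based node id.
#' @param scheme a [make_scheme()] payoff scheme.
#' @return The node's total payoff (numeric scalar).
#' @export
total_payoff <- function(h, state, node, scheme) {
  stopifnot(inherits(h, "hypergraph"), inherits(state, "strategy_state"))
  node <- as.integer(node)
  if (node < 0L || node >= h$n_nodes) stop("unknown node id: ", node)
  sp <- if (state$mode == "vector") state$pair else state$slot
  st <- if (state$mode == "vector") state$tri else state$slot
  tot <- 0
  me_p <- sp[node + 1L]
  for (j in h$pair_adj[[node + 1L]]) {  # plain loop: mirrors compiled order
    tot <- tot + if (me_p == 1L) {
      if (sp[j + 1L] == 1L) scheme$R_pair else scheme$S_pair
    } else {
      if (sp[j + 1L] == 1L) scheme$T_pair else scheme$P_pair
    }
  }
  me_t <- st[node + 1L]
  for (tr in h$tri_of_node[[node + 1L]]) {
    partners <- setdiff(h$triangles[tr, ], node)
    tot <- tot + tri_focal_payoff(me_t, st[partners[1L] + 1L] +
                                    st[partners[2L] + 1L], scheme)
  }
  tot
}
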