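#' Build a random-regular hypergraph with full layer overlap
#'
#' Configuration-model construction of a three-regular simplicial complex:
#' each node contributes `k_tri` stubs, the stub list is shuffled and grouped
#' into triples to form the triangle layer, and the pairwise layer is set to
#' the projection of the triangles. A matching is rejected (and redrawn) if a
#' triple repeats a node, a triangle is duplicated, two triangles share two
#' nodes, or either layer is disconnected. The result has every node in
#' exactly `k_tri` triangles and `k_pair = 2 k_tri` pairwise edges, and
#' topological overlap exactly 1.
#'
#' @param n_nodes number of players; `n_nodes * k_tri` must be divisible by 3
#'   and `n_nodes >= 3 * k_tri + 1`.
#' @param k_pair pairwise degree; must equal `2 * k_tri` (the projection of a
#'   node's triangles supplies exactly `2 * k_tri` distinct neighbours).
#' @param k_tri number of triangles per node.
#' @param seed optional integer seed (`set.seed` is called when supplied;
#'   otherwise the current RNG stream is used).
#' @param max_restarts configuration-model restarts before giving up.
#' @return A connected [hypergraph()] with `n_nodes * k_tri / 3` triangles,
#'   `n_nodes * k_pair / 2` pairwise edges and overlap omega = 1.
#' @export
build_full_overlap <- function(n_nodes, k_pair, k_tri, seed = NULL,
                               max_restarts = 1000L) {
  n_nodes <- as.integer(n_nodes)
  k_pair <- as.integer(k_pair)
  k_tri <- as.integer(k_tri)
  if ((n_nodes * k_tri) %% 3L != 0L)
    stop("n_nodes * k_tri = ", n_nodes * k_tri,
         " is not divisible by 3: no exact triangle matching exists")
  if (k_pair != 2L * k_tri)
    stop("full overlap requires k_pair = 2 * k_tri (got k_pair = ", k_pair,
         ", k_tri = ", k_tri, ")")
  if (n_nodes < 3L * k_tri + 1L)
    stop("n_nodes must be at least 3 * k_tri + 1 = ", 3L * k_tri + 1L)
  if (!is.null(seed)) set.seed(seed)

  n_tri <- (n_nodes * k_tri) %/% 3L
  stubs <- rep.int(0:(n_nodes - 1L), k_tri)
  for (attempt in seq_len(max_restarts)) {
    tri <- matrix(stubs[sample.int(length(stubs))], ncol = 3L, byrow = TRUE)
    if (any(tri[, 1L] == tri[, 2L] | tri[, 1L] == tri[, 3L] |
            tri[, 2L] == tri[, 3L])) next
    tri <- t(apply(tri, 1L, sort))
    proj <- project_rows(tri)
    if (anyDuplicated(edge_key(proj, n_nodes))) next  # shared pair or dup tri
    h <- hypergraph(n_nodes, proj, tri, validate = FALSE)
    if (!pair_layer_connected(h)) next  # projection == triangle layer here
    stopifnot(nrow(h$triangles) == n_tri)
    return(h)
  }
  stop("no valid stub matching found in ", max_restarts,
       " restarts (n_nodes = ", n_nodes, ", k_tri = ", k_tri, ")")
}

#' Criss-cross (double) edge swap on the pairwise layer
#'
#' Replaces pairwise edges A-B and C-D by A-D and B-C, preserving every
#' node's pairwise degree and leaving the triangle layer untouched. The swap
#' is only legal when A, B, C, D are four distinct nodes, both edges exist,
#' and the four-node pairwise subgraph contains exactly those two edges (no
#' links from A or B to C or D). An illegal candidate returns `NULL` (a
#' rejection signal for the caller to redraw), not an error.
#'
#' @param h a [hypergraph()].
#' @param edge_ab,edge_cd length-2 vectors of 0-based node ids, in the
#'   orientation (A, B) and (C, D) that defines the rewiring A-D, B-C.
#' @return The rewired [hypergraph()], or `NULL` if the candidate is
#'   rejected.
#' @export
crisscross_swap <- function(h, edge_ab, edge_cd) {
  stopifnot(inherits(h, "hypergraph"))
  a <- as.integer(edge_ab[1L]); b <- as.integer(edge_ab[2L])
  cc <- as.integer(edge_cd[1L]); d <- as.integer(edge_cd[2L])
  if (length(unique(c(a, b, cc, d))) != 4L) return(NULL)
  if (!(b %in% h$pair_adj[[a + 1L]]) || !(d %in% h$pair_adj[[cc + 1L]]))
    return(NULL)
  # subgraph on {A,B,C,D} must be exactly the two swapped edges
  if (cc %in% h$pair_adj[[a + 1L]] || d %in% h$pair_adj[[a + 1L]] ||
      cc %in% h$pair_adj[[b + 1L]] || d %in% h$pair_adj[[b + 1L]])
    return(NULL)
  apply_swap(h, a, b, cc, d)
}

# unconditional swap A-B, C-D -> A-D, B-C (preconditions already checked)
apply_swap <- function(h, a, b, cc, d) {
  n <- h$n_nodes
  keys <- edge_key(h$pair_edges, n)
  i1 <- match(edge_key(rbind(sort(c(a, b))), n), keys)
  i2 <- match(edge_key(rbind(sort(c(cc, d))), n), keys)
  h$pair_edges[i1, ] <- sort(c(a, d))
  h$pair_edges[i2, ] <- sort(c(b, cc))
  drop1 <- function(v, x) v[-match(x, v)]
  h$pair_adj[[a + 1L]] <- c(drop1(h$pair_adj[[a + 1L]], b), d)
  h$pair_adj[[b + 1L]] <- c(drop1(h$pair_adj[[b + 1L]], a), cc)
  h$pair_adj[[cc + 1L]] <- c(drop1(h$pair_adj[[cc + 1L]], d), b)
  h$pair_adj[[d + 1L]] <- c(drop1(h$pair_adj[[d + 1L]], cc), a)
  h
}

#' Tune the topological overlap by degree-preserving rewiring
#'
#' Starting from a structure at or above the target overlap (typically the
#' full-overlap simplicial complex), repeatedly draws two random pairwise
#' edges with random endpoint orientation, tests the criss-cross
#' preconditions, and commits the swap only when it strictly reduces the
#' number of shared (projected) edges without undershooting
#' `target_omega - tolerance` and keeps the pairwise layer connected
#' (disconnecting swaps are reverted, never committed). Triangle memberships
#' are never modified; the triangle layer's connectivity is re-verified once
#' on the result.
#'
#' @param h a [hypergraph()], both layers connected.
#' @param target_omega requested overlap, `0 <= target_omega <=` current
#'   omega (only decreasing rewiring is supported).
#' @param tolerance acceptance band around the target; default one-edge
#'   resolution `1 / |E_pair|` (the finest achievable).
#' @param max_swaps attempt budget; default `100 * |E_pair|`.
#' @param seed optional integer seed.
#' @return A [hypergraph()] with `|omega - target_omega| <= tolerance`, all
#'   pairwise degrees preserved and both layers connected.
#' @export
rewire_to_overlap <- function(h, target_omega, tolerance = NULL,
                              max_swaps = NULL, seed = NULL) {
  stopifnot(inherits(h, "hypergraph"))
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(h$pair_edges)
  if (m == 0L) stop("pairwise layer is empty")
  if (is.null(tolerance)) tolerance <- 1 / m
  if (tolerance < 1 / m)
    stop("tolerance below the overlap granularity 1/|E_pair| = ", 1 / m)
  if (is.null(max_swaps)) max_swaps <- 100L * m
  if (target_omega < 0 || target_omega > 1) stop("target_omega must be in [0, 1]")

  n <- h$n_nodes
  proj_keys <- sort(edge_key(project_triangles(h), n))
  in_proj <- function(i, j) {
    k <- if (i < j) as.double(i) * n + j else as.double(j) * n + i
    pos <- findInterval(k, proj_keys)
    pos > 0L && proj_keys[pos] == k
  }
  shared <- sum(edge_key(h$pair_edges, n) %in% proj_keys)
  lo <- ceiling((target_omega - tolerance) * m)
  hi <- floor((target_omega + tolerance) * m)
  if (shared >= lo && shared <= hi) return(h)
  if (shared / m < target_omega)
    stop("current overlap ", shared / m, " is below target ", target_omega,
         ": only decreasing rewiring is supported")

  best <- shared
  for (attempt in seq_len(max_swaps)) {
    e <- sample.int(m, 2L)
    ab <- h$pair_edges[e[1L], ]
    cd <- h$pair_edges[e[2L], ]
    if (runif(1) < 0.5) ab <- rev(ab)
    if (runif(1) < 0.5) cd <- rev(cd)
    a <- ab[1L]; b <- ab[2L]; cc <- cd[1L]; d <- cd[2L]
    if (length(unique(c(a, b, cc, d))) != 4L) next
    if (cc %in% h$pair_adj[[a + 1L]] || d %in% h$pair_adj[[a + 1L]] ||
        cc %in% h$pair_adj[[b + 1L]] || d %in% h$pair_adj[[b + 1L]]) next
    delta <- in_proj(a, d) + in_proj(b, cc) - in_proj(a, b) - in_proj(cc, d)
    new_shared <- shared + delta
    if (new_shared >= shared || new_shared < lo) next  # must move down, no overshoot
    h2 <- apply_swap(h, a, b, cc, d)
    if (!pair_layer_connected(h2)) next  # revert by discarding h2
    h <- h2
    shared <- new_shared
    best <- min(best, shared)
    if (shared <= hi) break
  }
  if (shared > hi)
    stop(sprintf(
      "target omega %.4f +/- %.4f not reached within %d attempts (best omega %.4f)",
      target_omega, tolerance, max_swaps, best / m))
  if (!tri_layer_connected(h))
    stop("triangle layer is disconnected (input structure was invalid)")
  h
}
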