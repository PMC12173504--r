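#' Two-layer hypergraph of pairwise edges and triangles
#'
#' Constructs a hypergraph on `n_nodes` players holding a pairwise-edge layer
#' and a triangle (3-hyperedge) layer, with per-node adjacency indices for
#' both layers. Node identifiers are 0-based (`0 .. n_nodes - 1`), matching
#' the plain-text interchange format of [write_hypergraph()].
#'
#' Validated invariants: ids in range, no self-loops, no repeated nodes
#' within a triangle, no duplicate edges or triangles, and any two triangles
#' share at most one node (so the triangle projection has no duplicate
#' pairs). Regularity and connectivity are properties of the generators
#' ([build_full_overlap()], [rewire_to_overlap()]), not of the container:
#' irregular or disconnected toy structures are valid hypergraphs.
#'
#' @param n_nodes number of players N.
#' @param pair_edges integer matrix with two columns (or anything coercible
#'   to one), one row per pairwise edge, 0-based node ids.
#' @param triangles integer matrix with three columns, one row per
#'   3-hyperedge, 0-based node ids. May have zero rows.
#' @param validate check all invariants (disable only for internally
#'   constructed objects known to be valid).
#' @return An object of class `hypergraph`: a list with `n_nodes`,
#'   `pair_edges` (m x 2, rows sorted ascending), `triangles` (t x 3, rows
#'   sorted ascending), `pair_adj` (per-node integer vectors of pairwise
#'   neighbours) and `tri_of_node` (per-node integer vectors of triangle row
#'   indices, 1-based into `triangles`).
#' @export
hypergraph <- function(n_nodes, pair_edges, triangles = NULL, validate = TRUE) {
  n_nodes <- as.integer(n_nodes)
  pair_edges <- as_edge_matrix(pair_edges, 2L)
  triangles <- as_edge_matrix(triangles, 3L)
  if (validate) {
    if (n_nodes < 1L) stop("n_nodes must be >= 1")
    ids <- c(pair_edges, triangles)
    if (length(ids) && (min(ids) < 0L || max(ids) >= n_nodes))
      stop("node ids must lie in 0 .. n_nodes - 1")
    if (nrow(pair_edges) && any(pair_edges[, 1L] == pair_edges[, 2L]))
      stop("self-loops are not allowed in pair_edges")
    if (nrow(triangles) &&
        any(triangles[, 1L] == triangles[, 2L] |
            triangles[, 2L] == triangles[, 3L]))
      stop("triangles must contain three distinct nodes")
    if (anyDuplicated(edge_key(pair_edges, n_nodes)))
      stop("duplicate pair edges")
    if (nrow(triangles)) {
      tkey <- (as.double(triangles[, 1L]) * n_nodes + triangles[, 2L]) *
        n_nodes + triangles[, 3L]
      if (anyDuplicated(tkey)) stop("duplicate triangles")
      # two triangles sharing >= 2 nodes would duplicate a projected pair
      if (anyDuplicated(edge_key(project_rows(triangles), n_nodes)))
        stop("two triangles share more than one node")
    }
  }
  h <- list(
    n_nodes = n_nodes,
    pair_edges = pair_edges,
    triangles = triangles,
    pair_adj = adjacency_from_edges(pair_edges, n_nodes),
    tri_of_node = membership_from_triangles(triangles, n_nodes)
  )
  class(h) <- "hypergraph"
  h
}

# coerce to a sorted-row integer matrix with k columns
as_edge_matrix <- function(x, k) {
  if (is.null(x) || length(x) == 0L)
    return(matrix(integer(0), ncol = k))
  if (!is.matrix(x)) x <- matrix(as.integer(unlist(x)), ncol = k, byrow = TRUE)
  storage.mode(x) <- "integer"
  t(apply(x, 1L, sort))
}

# unique numeric key for an unordered pair (i < j); double to avoid overflow
edge_key <- function(edges, n) {
  if (!nrow(edges)) return(numeric(0))
  as.double(edges[, 1L]) * n + edges[, 2L]
}

key_to_edge <- function(key, n) {
  i <- floor(key / n)
  cbind(as.integer(i), as.integer(key - i * n))
}

# all three projected pairs of every triangle row (not de-duplicated)
project_rows <- function(triangles) {
  if (!nrow(triangles)) return(matrix(integer(0), ncol = 2L))
  rbind(triangles[, c(1L, 2L), drop = FALSE],
        triangles[, c(1L, 3L), drop = FALSE],
        triangles[, c(2L, 3L), drop = FALSE])
}

adjacency_from_edges <- function(edges, n) {
  adj <- rep(list(integer(0)), n)
  if (nrow(edges)) {
    ends <- c(edges[, 1L], edges[, 2L]) + 1L
    other <- c(edges[, 2L], edges[, 1L])
    sp <- split(other, ends)
    adj[as.integer(names(sp))] <- sp
  }
  adj
}

membership_from_triangles <- function(triangles, n) {
  mem <- rep(list(integer(0)), n)
  if (nrow(triangles)) {
    idx <- rep(seq_len(nrow(triangles)), 3L)
    sp <- split(idx, c(triangles) + 1L)
    mem[as.integer(names(sp))] <- sp
  }
  mem
}

#' @export
print.hypergraph <- function(x, ...) {
  om <- if (nrow(x$pair_edges)) {
    sprintf("%.4f", compute_overlap(x)$omega)
  } else "NA (no pair edges)"
  cat(sprintf(
    "<hypergraph> %d nodes, %d pair edges, %d triangles, overlap omega = %s\n",
    x$n_nodes, nrow(x$pair_edges), nrow(x$triangles), om))
  invisible(x)
}

#' Project the triangle layer onto pairwise edges
#'
#' Every 3-hyperedge \{l, m, n\} contributes the three unordered pairs
#' (l,m), (l,n), (m,n); the result is de-duplicated (triangles may share one
#' node, never a pair).
#'
#' @param h a [hypergraph()].
#' @return Integer matrix with two columns, one row per projected pair.
#' @export
project_triangles <- function(h) {
  stopifnot(inherits(h, "hypergraph"))
  pr <- project_rows(h$triangles)
  pr[!duplicated(edge_key(pr, h$n_nodes)), , drop = FALSE]
}

#' Topological overlap between the pairwise and triangle layers
#'
#' The overlap is the fraction of pairwise edges that also occur as
#' projected edges of triangles:
#' \deqn{\omega = |E_{pair} \cap E_{proj}| / |E_{pair}|.}
#' `omega = 1` means every pairwise edge is supported by a triangle (a
#' three-regular simplicial complex when the layers are regular and
#' `k_pair = 2 k_tri`); `omega = 0` means the two layers share no pair.
#'
#' @param h a [hypergraph()] with at least one pairwise edge.
#' @return A list of class `overlap_report`: `omega`, `n_shared_edges`,
#'   `n_pair_edges`, and `granularity` (`1 / n_pair_edges`, the resolution at
#'   which omega can be tuned).
#' @export
compute_overlap <- function(h) {
  stopifnot(inherits(h, "hypergraph"))
  m <- nrow(h$pair_edges)
  if (m == 0L) stop("overlap undefined: pairwise layer is empty")
  proj <- edge_key(project_triangles(h), h$n_nodes)
  shared <- sum(edge_key(h$pair_edges, h$n_nodes) %in% proj)
  structure(
    list(omega = shared / m, n_shared_edges = as.integer(shared),
         n_pair_edges = m, granularity = 1 / m),
    class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("omega = %.4f  (%d / %d pair edges shared; granularity %.2e)\n",
              x$omega, x$n_shared_edges, x$n_pair_edges, x$granularity))
  invisible(x)
}

#' Co-players of a node in each layer
#'
#' @param h a [hypergraph()].
#' @param node 0-based node id.
#' @return List with sorted 0-based id vectors `pairwise` (neighbours via
#'   pair edges), `triangle` (partners sharing a 3-hyperedge) and `union`
#'   (de-duplicated union of the two). On a full-overlap regular structure
#'   with `k_pair = 2 k_tri` the union has `k_pair` members; at zero overlap
#'   it has up to `k_pair + 2 k_tri` distinct members.
#' @export
co_players <- function(h, node) {
  stopifnot(inherits(h, "hypergraph"))
  node <- as.integer(node)
  if (is.na(node) || node < 0L || node >= h$n_nodes)
    stop("unknown node id: ", node)
  pw <- sort(h$pair_adj[[node + 1L]])
  tri_rows <- h$tri_of_node[[node + 1L]]
  tp <- if (length(tri_rows)) {
    sort(unique(setdiff(c(h$triangles[tri_rows, , drop = FALSE]), node)))
  } else integer(0)
  list(pairwise = pw, triangle = tp, union = sort(unique(c(pw, tp))))
}

# breadth-first reachability over an adjacency list (0-based ids)
adj_connected <- function(adj, n) {
  if (n == 1L) return(TRUE)
  visited <- logical(n)
  visited[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- unlist(adj[frontier], use.names = FALSE) + 1L
    nb <- unique(nb[!visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  all(visited)
}

pair_layer_connected <- function(h) adj_connected(h$pair_adj, h$n_nodes)

tri_layer_connected <- function(h) {
  proj <- project_triangles(h)
  adj_connected(adjacency_from_edges(proj, h$n_nodes), h$n_nodes)
}

#' Read / write the plain-text hypergraph format
#'
#' Format: a header line `# nodes <N>`, then one line `E i j` per pairwise
#' edge and one line `T i j k` per triangle, whitespace-separated 0-based
#' ids. The writer emits edges and triangles sorted lexicographically so
#' files diff reproducibly; the reader validates all hypergraph invariants.
#'
#' @param h a [hypergraph()].
#' @param path file path.
#' @return `write_hypergraph` returns `path` invisibly; `read_hypergraph`
#'   returns a validated [hypergraph()].
#' @export
write_hypergraph <- function(h, path) {
  stopifnot(inherits(h, "hypergraph"))
  lines <- sprintf("# nodes %d", h$n_nodes)
  if (nrow(h$pair_edges)) {
    pe <- h$pair_edges[order(h$pair_edges[, 1L], h$pair_edges[, 2L]), ,
                       drop = FALSE]
    lines <- c(lines, sprintf("E %d %d", pe[, 1L], pe[, 2L]))
  }
  if (nrow(h$triangles)) {
    tr <- h$triangles[order(h$triangles[, 1L], h$triangles[, 2L],
                            h$triangles[, 3L]), , drop = FALSE]
    lines <- c(lines, sprintf("T %d %d %d", tr[, 1L], tr[, 2L], tr[, 3L]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hypergraph
#' @export
read_hypergraph <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^#\\s*nodes\\s+\\d+$", lines)
  if (!any(hdr)) stop("missing '# nodes <N>' header")
  n <- as.integer(sub("^#\\s*nodes\\s+", "", lines[which(hdr)[1L]]))
  body <- lines[!grepl("^#", lines)]
  parse_rows <- function(tag, k) {
    rows <- body[startsWith(body, tag)]
    if (!length(rows)) return(NULL)
    vals <- lapply(strsplit(rows, "\\s+"), function(f) {
      if (length(f) != k + 1L) stop("malformed line: ", paste(f, collapse = " "))
      as.integer(f[-1L])
    })
    do.call(rbind, vals)
  }
  hypergraph(n, parse_rows("E", 2L), parse_rows("T", 3L))
}
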