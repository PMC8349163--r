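#' Density of a node set within a network
#'
#' The density of a cluster is the ratio of the number of edges among its
#' members to the maximum possible number of edges,
#' \eqn{d_k = |E_k| / (|N_k|(|N_k|-1)/2)}.
#'
#' @param members character vector of at least two network nodes.
#' @param network a \code{gene_network}.
#' @return density in [0, 1].
#' @export
cluster_density <- function(members, network) {
  members <- unique(as.character(members))
  if (length(members) < 2) stop("density needs at least two members")
  if (!all(members %in% network$nodes)) {
    stop("members must be network nodes")
  }
  inside <- network$edges$from %in% members & network$edges$to %in% members
  m <- length(members)
  sum(inside) / (m * (m - 1) / 2)
}

#' Cluster property of an outside node with respect to a cluster
#'
#' \eqn{cp_{nk} = |E_{nk}| / (d_k |N_k|)}, where \eqn{|E_{nk}|} is the
#' number of network edges joining the node to cluster members, \eqn{d_k}
#' the cluster's density and \eqn{|N_k|} its size. Measures how strongly a
#' periphery node is wired into the cluster relative to the cluster's own
#' connectivity.
#'
#' @param node a gene identifier not in \code{members}.
#' @param members cluster member identifiers.
#' @param network a \code{gene_network}.
#' @return non-negative real.
#' @export
cluster_property <- function(node, members, network) {
  members <- unique(as.character(members))
  if (node %in% members) stop("node must lie outside the cluster")
  d_k <- cluster_density(members, network)
  if (d_k == 0) stop("cluster property undefined for an edgeless cluster")
  touches <- (network$edges$from == node & network$edges$to %in% members) |
    (network$edges$to == node & network$edges$from %in% members)
  sum(touches) / (d_k * length(members))
}

#' Overlapping density-constrained clustering
#'
#' Extracts overlapping, highly interconnected clusters from an undirected
#' gene network. The procedure is deterministic:
#' \enumerate{
#'   \item All nodes start unassigned.
#'   \item While an unassigned node with degree >= 1 remains, seed a new
#'     cluster at the unassigned node of highest network degree
#'     (ties broken toward the lexicographically smallest identifier).
#'   \item Grow the cluster greedily: among all nodes (assigned or not)
#'     adjacent to the cluster, the preferred candidate has the most edges
#'     into the cluster (ties: higher network degree, then lexicographically
#'     smallest). It joins iff the enlarged cluster's density stays at or
#'     above \code{d_min} and its cluster property with respect to the
#'     current cluster is at least \code{cp_min}. For a singleton cluster
#'     the density term of the cluster property is taken as 1.
#'   \item When no candidate is acceptable, the cluster is emitted if it
#'     has at least two members; its members become assigned.
#' }
#' Overlap arises because clusters grown from later seeds may re-absorb
#' already-assigned nodes.
#'
#' @param network a \code{gene_network} with at least one edge.
#' @param d_min minimum cluster density, in (0, 1].
#' @param cp_min minimum cluster property for accepting a candidate
#'   (default 0.5, the recommended setting).
#' @return A \code{cluster_set}: list with \code{d_min}, \code{cp_min} and
#'   \code{clusters}, an ordered list where each element has \code{members}
#'   (sorted character), \code{internal_edges} and \code{density}. Cluster
#'   ids are 1-based positions in emission order.
#' @export
cluster_graph <- function(network, d_min, cp_min = 0.5) {
  if (nrow(network$edges) == 0) stop("cannot cluster an edgeless network")
  if (!(d_min > 0 && d_min <= 1)) stop("d_min must be in (0, 1]")
  if (cp_min < 0) stop("cp_min must be >= 0")
  ai <- adjacency_index(network)
  n <- ai$n
  deg <- ai$deg
  adj <- ai$adj
  # seeds scanned in (-degree, identifier) order; ids are sorted already so
  # index order is the lexicographic tie-break
  seed_order <- order(-deg, seq_len(n))
  assigned <- rep(FALSE, n)
  clusters <- list()

  for (seed in seed_order) {
    if (assigned[seed] || deg[seed] == 0) next
    member <- rep(FALSE, n)
    member[seed] <- TRUE
    sz <- 1L
    ec <- 0L  # internal edge count
    conn <- integer(n)  # edges from each node into the current cluster
    conn[adj[[seed]]] <- 1L
    repeat {
      cand <- which(conn > 0L & !member)
      if (length(cand) == 0) break
      # preferred candidate: max edges-in, then max degree, then smallest id
      o <- order(-conn[cand], -deg[cand], cand)
      picked <- FALSE
      for (v in cand[o]) {
        new_ec <- ec + conn[v]
        new_sz <- sz + 1L
        dens_new <- new_ec / (new_sz * (new_sz - 1L) / 2)
        d_cur <- if (sz == 1L) 1 else ec / (sz * (sz - 1L) / 2)
        cp <- conn[v] / (d_cur * sz)
        if (dens_new >= d_min && cp >= cp_min) {
          member[v] <- TRUE
          sz <- new_sz
          ec <- new_ec
          conn[adj[[v]]] <- conn[adj[[v]]] + 1L
          picked <- TRUE
          break
        }
      }
      if (!picked) break
    }
    if (sz >= 2L) {
      mem <- ai$ids[member]
      clusters[[length(clusters) + 1L]] <- list(
        members = mem,
        internal_edges = as.integer(ec),
        density = ec / (sz * (sz - 1L) / 2)
      )
      assigned[member] <- TRUE
    }
    # a seed whose cluster stayed a singleton can never grow later either;
    # mark it so the outer loop terminates
    assigned[seed] <- TRUE
  }
  structure(list(d_min = d_min, cp_min = cp_min, clusters = clusters),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), integer(1))
  cat(sprintf("cluster_set: %d clusters (d_min=%.2f, cp_min=%.2f)\n",
              length(x$clusters), x$d_min, x$cp_min))
  if (length(sizes)) {
    cat(sprintf("  sizes: min %d, median %g, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  }
  invisible(x)
}

#' Write a cluster set as TSV
#'
#' Columns: cluster_id (1-based emission order), size, internal_edges,
#' density, comma-joined sorted member list.
#'
#' @param clusterset a \code{cluster_set}.
#' @param path output path.
#' @export
write_clusters_tsv <- function(clusterset, path) {
  cl <- clusterset$clusters
  df <- data.frame(
    cluster_id = seq_along(cl),
    size = vapply(cl, function(x) length(x$members), integer(1)),
    internal_edges = vapply(cl, function(x) x$internal_edges, integer(1)),
    density = vapply(cl, function(x) x$density, numeric(1)),
    members = vapply(cl, function(x) paste(x$members, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
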