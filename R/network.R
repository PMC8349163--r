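# canonicalize a two-column character matrix of edges: trim whitespace,
# drop self-pairs, orient lexicographically (from < to), deduplicate.
canonical_edges <- function(from, to) {
  from <- trimws(from)
  to <- trimws(to)
  keep <- from != to
  n_self <- sum(!keep)
  from <- from[keep]
  to <- to[keep]
  swap <- from > to
  tmp <- from[swap]
  from[swap] <- to[swap]
  to[swap] <- tmp
  key <- paste(from, to, sep = "\r")
  dup <- duplicated(key)
  ed <- data.frame(from = from[!dup], to = to[!dup], stringsAsFactors = FALSE)
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL
  attr(ed, "n_self_dropped") <- n_self
  ed
}

#' Construct a gene network from an edge table
#'
#' A \code{gene_network} is a simple undirected graph over opaque gene
#' identifiers: a sorted node vector plus a canonical edge table in which
#' every edge is stored once with \code{from < to} lexicographically.
#' Self-loops and duplicate edges are removed on construction.
#'
#' @param edges data.frame (or 2-column matrix) with character columns
#'   \code{from} and \code{to}.
#' @return An object of class \code{gene_network} with elements
#'   \code{nodes} (character) and \code{edges} (data.frame).
#' @export
gene_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("edges must have two columns")
  ed <- canonical_edges(as.character(edges[[1]]), as.character(edges[[2]]))
  attr(ed, "n_self_dropped") <- NULL
  net <- list(
    nodes = sort(unique(c(ed$from, ed$to))),
    edges = ed
  )
  class(net) <- "gene_network"
  net
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a single-source edge list
#'
#' Reads one co-expression edge list in either two-column TSV or SIF
#' dialect and returns the per-source network with edges in canonical
#' orientation (lexicographically smaller identifier first), self-pairs
#' dropped, and duplicates collapsed. A third TSV column (edge weight or
#' confidence), if present, is ignored: the downstream clustering and
#' enrichment operate on unweighted edge counts.
#'
#' @param path file path.
#' @param dialect \code{"tsv2col"} (tab-delimited source/target, optional
#'   \code{source<TAB>target} header auto-detected) or \code{"sif"}
#'   (whitespace-delimited \code{source type target ...}; the interaction
#'   type is ignored and multiple targets are expanded pairwise).
#' @param source_name short label for the source; defaults to the file name.
#' @return A \code{source_edge_list}: list with \code{source_name} and a
#'   canonical \code{edges} data.frame. The number of dropped self-pairs is
#'   reported via \code{message()}.
#' @export
read_edge_list <- function(path, dialect = c("tsv2col", "sif"),
                           source_name = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  from <- character(0)
  to <- character(0)
  if (dialect == "tsv2col") {
    first_data <- TRUE
    for (i in idx) {
      parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      parts <- trimws(parts)
      if (length(parts) < 2 || !nzchar(parts[1]) || !nzchar(parts[2])) {
        stop(sprintf("malformed row at line %d of %s", i, path))
      }
      if (first_data &&
          tolower(parts[1]) %in% c("source", "from", "gene1", "node1") &&
          tolower(parts[2]) %in% c("target", "to", "gene2", "node2")) {
        first_data <- FALSE
        next  # header row
      }
      first_data <- FALSE
      from <- c(from, parts[1])
      to <- c(to, parts[2])
    }
  } else {
    for (i in idx) {
      parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      if (length(parts) == 1) {
        stop(sprintf("malformed SIF row at line %d of %s (lone node)", i, path))
      }
      if (length(parts) < 3) {
        stop(sprintf("malformed SIF row at line %d of %s", i, path))
      }
      src <- parts[1]
      targets <- parts[-(1:2)]  # drop interaction type
      from <- c(from, rep(src, length(targets)))
      to <- c(to, targets)
    }
  }
  ed <- canonical_edges(from, to)
  n_self <- attr(ed, "n_self_dropped")
  attr(ed, "n_self_dropped") <- NULL
  if (n_self > 0) {
    message(sprintf("%s: dropped %d self-pair(s)", source_name, n_self))
  }
  if (nrow(ed) == 0) stop("no edges left after filtering in ", path)
  structure(list(source_name = source_name, edges = ed),
            class = "source_edge_list")
}

#' Merge per-source edge lists into one integrated network
#'
#' Takes the union of the canonical edge sets of all sources: an edge
#' present in several sources appears once in the merged network. The
#' merged network records, for every edge, which sources contributed it
#' (attribute \code{"provenance"}: comma-joined source names, aligned with
#' the edge table rows).
#'
#' @param sources non-empty list of \code{source_edge_list} objects (a
#'   single \code{source_edge_list} is accepted).
#' @return A \code{gene_network}.
#' @export
merge_networks <- function(sources) {
  if (inherits(sources, "source_edge_list")) sources <- list(sources)
  if (length(sources) == 0) stop("merge_networks: empty source list")
  from <- character(0)
  to <- character(0)
  lab <- character(0)
  for (s in sources) {
    from <- c(from, s$edges$from)
    to <- c(to, s$edges$to)
    lab <- c(lab, rep(s$source_name, nrow(s$edges)))
  }
  key <- paste(from, to, sep = "\r")
  prov <- tapply(lab, key, function(x) paste(sort(unique(x)), collapse = ","))
  net <- gene_network(data.frame(from = from, to = to,
                                 stringsAsFactors = FALSE))
  mkey <- paste(net$edges$from, net$edges$to, sep = "\r")
  attr(net, "provenance") <- unname(prov[mkey])
  net
}

#' Load the bait (known) gene set
#'
#' One gene identifier per line; blank lines and lines starting with
#' \code{#} are ignored; duplicates are collapsed. Identifiers are exact,
#' case-sensitive strings (no alias resolution).
#'
#' @param path file path.
#' @return Sorted character vector of class \code{known_gene_set}.
#' @export
load_known_genes <- function(path) {
  if (!file.exists(path)) stop("cannot read known-gene list: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genes <- sort(unique(lines))
  if (length(genes) == 0) stop("empty known-gene set after parsing ", path)
  structure(genes, class = "known_gene_set")
}

#' Intersect a known set with a network, with a coverage message
#'
#' @param known character vector of known genes.
#' @param network a \code{gene_network}.
#' @return Character vector of known genes present in the network.
#' @export
known_in_network <- function(known, network) {
  present <- intersect(as.character(known), network$nodes)
  absent <- length(known) - length(present)
  if (absent > 0) {
    message(sprintf("%d known gene(s) absent from the network", absent))
  }
  present
}

#' Write a network as canonical two-column TSV
#'
#' @param network a \code{gene_network}.
#' @param path output path.
#' @export
write_network_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("source", "target"))
  invisible(path)
}

#' Summarize a merged network
#'
#' @param network a \code{gene_network} (ideally from
#'   \code{\link{merge_networks}} so provenance is available).
#' @return list with \code{nodes}, \code{edges} and, when provenance is
#'   present, per-source edge counts (an edge shared by k sources counts
#'   toward each).
#' @export
network_summary <- function(network) {
  out <- list(nodes = length(network$nodes), edges = nrow(network$edges))
  prov <- attr(network, "provenance")
  if (!is.null(prov)) {
    srcs <- unlist(strsplit(prov, ",", fixed = TRUE))
    out$per_source <- as.list(table(srcs))
  }
  out
}

# integer-indexed adjacency for the clustering engine
adjacency_index <- function(network) {
  ids <- network$nodes
  n <- length(ids)
  fi <- match(network$edges$from, ids)
  ti <- match(network$edges$to, ids)
  adj <- vector("list", n)
  both <- c(fi, ti)
  other <- c(ti, fi)
  split_adj <- split(other, factor(both, levels = seq_len(n)))
  for (i in seq_len(n)) adj[[i]] <- sort(split_adj[[i]])
  list(ids = ids, adj = adj, deg = lengths(adj), n = n)
}
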