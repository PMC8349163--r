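#' Build the 2x2 contingency table for one cluster
#'
#' The universe of the test is the network, not the genome:
#' \code{a} = known genes in the cluster, \code{b} = other cluster members,
#' \code{c} = known genes elsewhere in the network, \code{d} = remaining
#' network genes. \code{a + c} counts only known genes actually present in
#' the network.
#'
#' @param members cluster member identifiers (subset of network nodes).
#' @param known character vector of known (bait) genes.
#' @param network a \code{gene_network}.
#' @return named integer vector \code{c(a, b, c, d)}.
#' @export
contingency <- function(members, known, network) {
  members <- unique(as.character(members))
  if (!all(members %in% network$nodes)) {
    stop("cluster members must be network nodes")
  }
  known_net <- intersect(as.character(known), network$nodes)
  a <- length(intersect(members, known_net))
  b <- length(members) - a
  cc <- length(known_net) - a
  d <- length(network$nodes) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' One-sided Fisher's exact test (enrichment direction)
#'
#' Returns \eqn{P(X \ge a)} for hypergeometric \eqn{X} with population
#' \eqn{a+b+c+d}, success count \eqn{a+c}, and \eqn{a+b} draws — the upper
#' tail of the 2x2 table, i.e. the probability of observing at least as
#' many known genes in the cluster under the null of no association.
#' Computed through the hypergeometric tail in log space, so p-values of
#' order 1e-17 and far below are exact to double precision.
#'
#' @param a,b,c,d non-negative cell counts (or a single length-4 vector
#'   passed as \code{a}).
#' @return p-value in (0, 1].
#' @export
fisher_greater <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) {
    stopifnot(length(a) == 4)
    d <- a[4]; c <- a[3]; b <- a[2]; a <- a[1]
  }
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  if (a == 0) return(1)
  exp(stats::phyper(a - 1, a + c, b + d, a + b,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Score every cluster's enrichment for the known gene set
#'
#' Applies \code{\link{contingency}} and \code{\link{fisher_greater}} to
#' each cluster of a cluster set, preserving cluster order and ids.
#'
#' @param clusterset a \code{cluster_set} produced from \code{network}.
#' @param known known (bait) gene identifiers.
#' @param network the \code{gene_network} the clusters were drawn from.
#' @param adjust optionally \code{"BH"} to add a Benjamini-Hochberg
#'   adjusted column \code{p_adj}; no correction by default (significance
#'   downstream uses the raw p, matching the raw p < alpha convention).
#' @return data.frame with one row per cluster: \code{cluster_id},
#'   \code{size}, \code{n_known} (a), \code{n_other} (b), \code{p_value},
#'   and a \code{members} list-column carrying each cluster's sorted
#'   member vector.
#' @export
evaluate_clusters <- function(clusterset, known, network, adjust = NULL) {
  cl <- clusterset$clusters
  known_net <- intersect(as.character(known), network$nodes)
  if (length(known_net) == 0 && length(cl) > 0) {
    warning("known gene set is disjoint from the network; all p-values are 1")
  }
  n_cl <- length(cl)
  res <- data.frame(
    cluster_id = seq_len(n_cl),
    size = vapply(cl, function(x) length(x$members), integer(1)),
    n_known = integer(n_cl),
    n_other = integer(n_cl),
    p_value = numeric(n_cl),
    stringsAsFactors = FALSE
  )
  members <- vector("list", n_cl)
  for (i in seq_len(n_cl)) {
    tab <- contingency(cl[[i]]$members, known_net, network)
    res$n_known[i] <- tab[["a"]]
    res$n_other[i] <- tab[["b"]]
    res$p_value[i] <- fisher_greater(tab)
    members[[i]] <- cl[[i]]$members
  }
  res$members <- members
  if (!is.null(adjust)) {
    adjust <- match.arg(adjust, "BH")
    res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  }
  res
}

#' Write cluster enrichment results as TSV
#'
#' @param enriched data.frame from \code{\link{evaluate_clusters}}.
#' @param path output path.
#' @export
write_enrichment_tsv <- function(enriched, path) {
  out <- enriched[setdiff(names(enriched), "members")]
  out$p_value <- formatC(out$p_value, format = "e", digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
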