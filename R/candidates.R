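#' Filter clusters significant at level alpha
#'
#' Strict inequality (p < alpha), matching the raw-p significance call
#' used to declare bait-enriched clusters; input row order is preserved.
#'
#' @param enriched data.frame from \code{\link{evaluate_clusters}}.
#' @param alpha significance level in (0, 1], default 0.05.
#' @return the significant subset of \code{enriched}.
#' @export
significant_clusters <- function(enriched, alpha = 0.05) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  out <- enriched[enriched$p_value < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k clusters by ascending p-value
#'
#' @param enriched data.frame from \code{\link{evaluate_clusters}}.
#' @param k number of clusters to keep (default 6); if fewer clusters
#'   exist, all are returned with a warning.
#' @return rows of \code{enriched} with the k smallest p-values, sorted
#'   ascending (ties toward the smaller cluster_id).
#' @export
top_k_clusters <- function(enriched, k = 6) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(enriched)) {
    warning(sprintf("only %d clusters available; returning all",
                    nrow(enriched)))
    k <- nrow(enriched)
  }
  o <- order(enriched$p_value, enriched$cluster_id)
  out <- enriched[o[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract candidate ("potential") genes from enriched clusters
#'
#' Candidates are the non-bait members of the supplied clusters
#' (typically the significant or top-k subset): the union of cluster
#' members minus the known set, each annotated with its SScore, the
#' cluster attaining its best p-value, and the number of supplied
#' clusters containing it. Ranked by SScore descending (ties broken
#' lexicographically by gene identifier).
#'
#' @param clusters data.frame of enriched clusters (rows of
#'   \code{\link{evaluate_clusters}} output, with the \code{members}
#'   list-column).
#' @param known known (bait) gene identifiers to exclude.
#' @param scores data.frame from \code{\link{sscore_table}}.
#' @return data.frame with columns \code{gene}, \code{sscore},
#'   \code{best_cluster_id}, \code{n_significant_clusters}.
#' @export
potential_genes <- function(clusters, known, scores) {
  if (nrow(clusters) == 0) {
    return(data.frame(gene = character(0), sscore = numeric(0),
                      best_cluster_id = integer(0),
                      n_significant_clusters = integer(0),
                      stringsAsFactors = FALSE))
  }
  all_members <- unlist(clusters$members, use.names = FALSE)
  cand <- setdiff(unique(all_members), as.character(known))
  n_in <- vapply(cand, function(g)
    sum(vapply(clusters$members, function(m) g %in% m, logical(1))),
    integer(1))
  idx <- match(cand, scores$gene)
  out <- data.frame(
    gene = cand,
    sscore = scores$sscore[idx],
    best_cluster_id = scores$best_cluster_id[idx],
    n_significant_clusters = n_in,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$sscore, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full candidate report at one density
#'
#' Convenience wrapper: significant clusters at \code{alpha}, the top-k
#' among them, and the candidate genes drawn from all significant
#' clusters.
#'
#' @param enriched data.frame from \code{\link{evaluate_clusters}}.
#' @param known known (bait) gene identifiers.
#' @param scores data.frame from \code{\link{sscore_table}}.
#' @param alpha significance level (default 0.05).
#' @param top_k size of the highlighted top-cluster report (default 6).
#' @return list of class \code{candidate_report}: \code{alpha},
#'   \code{significant} (data.frame), \code{top} (data.frame),
#'   \code{candidates} (data.frame), \code{top_candidates} (candidates
#'   restricted to the top-k clusters).
#' @export
candidate_report <- function(enriched, known, scores, alpha = 0.05,
                             top_k = 6) {
  sig <- significant_clusters(enriched, alpha)
  top <- if (nrow(sig)) top_k_clusters(sig, min(top_k, nrow(sig))) else sig
  structure(list(
    alpha = alpha,
    significant = sig,
    top = top,
    candidates = potential_genes(sig, known, scores),
    top_candidates = potential_genes(top, known, scores)
  ), class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("candidate_report: %d significant clusters (p < %g), %d candidate genes\n",
              nrow(x$significant), x$alpha, nrow(x$candidates)))
  cat(sprintf("  top %d clusters yield %d candidates\n",
              nrow(x$top), nrow(x$top_candidates)))
  invisible(x)
}

#' Write candidate tables as TSV
#'
#' Emits the candidate gene table and a top-cluster report (cluster_id,
#' size, candidate genes, p-value).
#'
#' @param report a \code{candidate_report}.
#' @param candidates_path,topk_path output paths.
#' @export
write_candidates_tsv <- function(report, candidates_path, topk_path) {
  cand <- report$candidates
  cand$sscore <- sprintf("%.4f", cand$sscore)
  utils::write.table(cand, candidates_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  top <- report$top
  known_excl <- setdiff(unlist(top$members), report$candidates$gene)
  topdf <- data.frame(
    cluster_id = top$cluster_id,
    size = top$size,
    candidate_genes = vapply(top$members, function(m)
      paste(setdiff(m, known_excl), collapse = ","), character(1)),
    p_value = formatC(top$p_value, format = "e", digits = 6),
    stringsAsFactors = FALSE
  )
  utils::write.table(topdf, topk_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}
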