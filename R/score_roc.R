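#' Per-gene significance scores from cluster enrichment
#'
#' Each gene's SScore is \eqn{-\log_{10}} of the smallest enrichment
#' p-value among the clusters containing it (clusters overlap, so a gene
#' can carry several p-values). Genes belonging to no cluster score 0, so
#' every network gene appears in the table and later ROC negatives include
#' unclustered genes. Log base 10 is a reporting convention only: AUC and
#' density selection are invariant under any strictly increasing rescaling
#' of the scores.
#'
#' @param enriched data.frame from \code{\link{evaluate_clusters}}
#'   (needs \code{cluster_id}, \code{p_value} and the \code{members}
#'   list-column).
#' @param network the \code{gene_network}.
#' @return data.frame with columns \code{gene}, \code{sscore},
#'   \code{best_cluster_id} (cluster attaining the minimal p; NA for
#'   unclustered genes; ties resolved toward the smaller id).
#' @export
sscore_table <- function(enriched, network) {
  genes <- network$nodes
  sscore <- numeric(length(genes))
  best <- rep(NA_integer_, length(genes))
  best_p <- rep(Inf, length(genes))
  for (i in seq_len(nrow(enriched))) {
    idx <- match(enriched$members[[i]], genes)
    p <- enriched$p_value[i]
    upd <- p < best_p[idx]  # strict: ties keep the smaller cluster_id
    best_p[idx[upd]] <- p
    best[idx[upd]] <- enriched$cluster_id[i]
  }
  clustered <- is.finite(best_p)
  sscore[clustered] <- -log10(best_p[clustered])
  data.frame(gene = genes, sscore = sscore, best_cluster_id = best,
             stringsAsFactors = FALSE)
}

#' ROC curve of SScores against the known gene labels
#'
#' Sweeps a threshold over the unique observed scores in descending
#' order; at each threshold th, TP = known genes with score >= th,
#' FP = non-known genes with score >= th, TPR = TP/(TP+FN),
#' FPR = FP/(FP+TN). The point list is anchored at (0,0) and (1,1) and
#' the AUC is the trapezoidal area — equivalent to the Mann-Whitney
#' statistic with half credit for tied positive/negative pairs.
#'
#' @param scores data.frame with \code{gene} and \code{sscore} columns
#'   (as from \code{\link{sscore_table}}), or a named numeric vector.
#' @param known character vector of positive-label genes; genes of
#'   \code{scores} not in it are negatives.
#' @return list of class \code{roc_result}: \code{points} data.frame
#'   (threshold, tp, fp, tn, fn, tpr, fpr; threshold NA on the two
#'   anchors), \code{auc}, \code{thresholds}.
#' @export
roc_curve <- function(scores, known) {
  if (is.data.frame(scores)) {
    s <- stats::setNames(scores$sscore, scores$gene)
  } else {
    s <- scores
  }
  pos <- names(s) %in% as.character(known)
  if (!any(pos)) stop("no positive (known) genes among the scored genes")
  if (all(pos)) stop("no negative genes among the scored genes")
  np <- sum(pos)
  nn <- sum(!pos)
  th <- sort(unique(unname(s)), decreasing = TRUE)
  tp <- vapply(th, function(t) sum(s[pos] >= t), numeric(1))
  fp <- vapply(th, function(t) sum(s[!pos] >= t), numeric(1))
  pts <- data.frame(
    threshold = c(NA, th, NA),
    tp = c(0, tp, np), fp = c(0, fp, nn),
    tn = nn - c(0, fp, nn), fn = np - c(0, tp, np)
  )
  pts$tpr <- pts$tp / np
  pts$fpr <- pts$fp / nn
  # drop duplicate anchor rows if the sweep already reaches them
  dup <- duplicated(pts[c("tpr", "fpr")])
  pts <- pts[!dup, , drop = FALSE]
  rownames(pts) <- NULL
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, thresholds = th),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f over %d thresholds\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Scan clustering densities and select the one maximizing AUC
#'
#' For each density, runs the full chain
#' \code{\link{cluster_graph}} -> \code{\link{evaluate_clusters}} ->
#' \code{\link{sscore_table}} -> \code{\link{roc_curve}} and records the
#' AUC with the known genes as positives. The selected density attains
#' the maximal AUC; exact ties go to the larger density.
#'
#' @param network a \code{gene_network}.
#' @param known known (bait) gene identifiers.
#' @param densities numeric vector of minimum densities to scan
#'   (default \code{c(0.5, 0.6, 0.7, 0.8, 0.9)}).
#' @param cp_min cluster-property threshold (default 0.5).
#' @param roc_known optional separate positive set for the ROC (e.g.
#'   held-out known genes in recovery experiments); enrichment always
#'   uses \code{known}.
#' @return list of class \code{density_scan}: \code{per_density} (one
#'   record per density with \code{d_min}, \code{clusters},
#'   \code{enriched}, \code{scores}, \code{roc}), \code{auc} (named
#'   numeric), \code{selected_density}.
#' @export
scan_densities <- function(network, known,
                           densities = c(0.5, 0.6, 0.7, 0.8, 0.9),
                           cp_min = 0.5, roc_known = NULL) {
  if (length(densities) == 0) stop("no densities to scan")
  if (any(densities <= 0 | densities > 1)) stop("densities must be in (0, 1]")
  if (is.null(roc_known)) roc_known <- known
  per <- vector("list", length(densities))
  auc <- numeric(length(densities))
  for (i in seq_along(densities)) {
    d <- densities[i]
    cs <- cluster_graph(network, d_min = d, cp_min = cp_min)
    enr <- evaluate_clusters(cs, known, network)
    sc <- sscore_table(enr, network)
    roc <- roc_curve(sc, roc_known)
    per[[i]] <- list(d_min = d, clusters = cs, enriched = enr,
                     scores = sc, roc = roc)
    auc[i] <- roc$auc
  }
  names(auc) <- formatC(densities, format = "g")
  # argmax with ties toward the larger density
  best <- which(auc == max(auc))
  sel <- densities[best[which.max(densities[best])]]
  structure(list(per_density = per, auc = auc, selected_density = sel),
            class = "density_scan")
}

#' @export
print.density_scan <- function(x, ...) {
  cat("density_scan:\n")
  for (i in seq_along(x$per_density)) {
    cat(sprintf("  d_min %.2f: %3d clusters, AUC %.4f%s\n",
                x$per_density[[i]]$d_min,
                length(x$per_density[[i]]$clusters$clusters),
                x$auc[i],
                if (x$per_density[[i]]$d_min == x$selected_density)
                  "  <- selected" else ""))
  }
  invisible(x)
}

#' Write the per-gene score table as TSV
#'
#' @param scores data.frame from \code{\link{sscore_table}}.
#' @param known known genes, used to flag each row.
#' @param path output path.
#' @export
write_scores_tsv <- function(scores, known, path) {
  out <- scores
  out$sscore <- sprintf("%.4f", out$sscore)
  out$is_known <- out$gene %in% as.character(known)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ROC point table as TSV
#'
#' @param roc a \code{roc_result}.
#' @param path output path.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
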