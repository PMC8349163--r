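#' Label-holdout recovery experiment
#'
#' Benchmarks the whole pipeline on a synthetic dataset by hiding a
#' fraction of the known labels: the visible knowns drive clustering
#' enrichment and density selection, and the hidden knowns act as
#' recovery targets. The recovery ROC is computed over the genes not
#' used as queries (visible knowns are excluded from both positives and
#' negatives — they are the input, not predictions), with hidden knowns
#' as positives. Candidate recall is the fraction of hidden knowns and
#' of planted candidates that surface in the significant-cluster
#' candidate list at the selected density.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param fraction fraction of known labels to hide (default 0.3).
#' @param seed seed for the holdout draw.
#' @param densities densities to scan (default
#'   \code{c(0.5, 0.6, 0.7, 0.8, 0.9)}).
#' @param cp_min cluster-property threshold (default 0.5).
#' @param alpha cluster significance level (default 0.05).
#' @return list: \code{auc_hidden} (recovery AUC at the selected
#'   density), \code{selected_density}, \code{hidden_recall} and
#'   \code{planted_recall} (fractions recovered in the candidate list),
#'   \code{candidates} (the candidate table), \code{scan}.
#' @export
holdout_recovery <- function(dataset, fraction = 0.3, seed = 1,
                             densities = c(0.5, 0.6, 0.7, 0.8, 0.9),
                             cp_min = 0.5, alpha = 0.05) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  split <- holdout_known(dataset$known, fraction, seed)
  net <- dataset$network
  visible <- intersect(split$visible, net$nodes)
  hidden <- intersect(split$hidden, net$nodes)
  scan <- scan_densities(net, visible, densities = densities,
                         cp_min = cp_min, roc_known = hidden)
  sel <- which(vapply(scan$per_density, function(r) r$d_min,
                      numeric(1)) == scan$selected_density)
  best <- scan$per_density[[sel]]
  eligible <- best$scores[!(best$scores$gene %in% visible), , drop = FALSE]
  roc <- roc_curve(eligible, hidden)
  report <- candidate_report(best$enriched, visible, best$scores,
                             alpha = alpha)
  cand <- report$candidates$gene
  planted <- intersect(dataset$planted_candidates, net$nodes)
  list(
    auc_hidden = roc$auc,
    selected_density = scan$selected_density,
    hidden_recall = if (length(hidden)) mean(hidden %in% cand) else NA_real_,
    planted_recall = if (length(planted)) mean(planted %in% cand) else NA_real_,
    candidates = report$candidates,
    visible = visible, hidden = hidden,
    scan = scan
  )
}

#' Precision of SScore ranking for planted candidates
#'
#' With the full known labels in play, ranks the non-known genes by
#' SScore at the selected density and measures the fraction of the top
#' \code{|planted|} that are true planted candidates.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param densities,cp_min as in \code{\link{scan_densities}}.
#' @return list: \code{precision}, \code{selected_density}.
#' @export
planted_precision <- function(dataset,
                              densities = c(0.5, 0.6, 0.7, 0.8, 0.9),
                              cp_min = 0.5) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  net <- dataset$network
  known <- intersect(dataset$known, net$nodes)
  scan <- scan_densities(net, known, densities = densities, cp_min = cp_min)
  sel <- which(vapply(scan$per_density, function(r) r$d_min,
                      numeric(1)) == scan$selected_density)
  sc <- scan$per_density[[sel]]$scores
  nonknown <- sc[!(sc$gene %in% known), , drop = FALSE]
  nonknown <- nonknown[order(-nonknown$sscore, nonknown$gene), , drop = FALSE]
  planted <- intersect(dataset$planted_candidates, net$nodes)
  top <- utils::head(nonknown$gene, length(planted))
  list(precision = mean(top %in% planted),
       selected_density = scan$selected_density)
}
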