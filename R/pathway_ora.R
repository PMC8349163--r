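#' Read pathway gene sets in GMT format
#'
#' GMT rows are tab-separated: set name, description, then one or more
#' member genes. Duplicate genes within a row are collapsed; the universe
#' defaults to the union of all pathway genes.
#'
#' @param path file path.
#' @return list of class \code{pathway_db}: \code{pathways} (named list
#'   of character vectors), \code{universe} (character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pw <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    genes <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
    if (length(parts) < 3 || !nzchar(parts[1]) || length(genes) == 0) {
      stop(sprintf("malformed GMT row at line %d of %s", i, path))
    }
    pw[[parts[1]]] <- sort(genes)
  }
  structure(list(pathways = pw,
                 universe = sort(unique(unlist(pw, use.names = FALSE)))),
            class = "pathway_db")
}

#' Pathway over-representation analysis
#'
#' Upper-tail hypergeometric test per pathway: with population size
#' |universe|, |pathway| successes and |query ∩ universe| draws, the
#' p-value is P(overlap >= observed). Bonferroni correction multiplies by
#' the number of pathways tested (capped at 1).
#'
#' @param query character vector of genes (e.g. candidate genes).
#' @param db a \code{pathway_db} from \code{\link{read_gmt}}.
#' @return data.frame sorted by p ascending: \code{pathway},
#'   \code{pathway_size}, \code{overlap}, \code{p_hyper},
#'   \code{p_bonferroni}.
#' @export
ora <- function(query, db) {
  universe <- db$universe
  q <- intersect(unique(as.character(query)), universe)
  if (length(q) == 0) stop("query has no genes in the pathway universe")
  n_pw <- length(db$pathways)
  res <- data.frame(
    pathway = names(db$pathways),
    pathway_size = vapply(db$pathways, length, integer(1)),
    overlap = vapply(db$pathways, function(p)
      length(intersect(p, q)), integer(1)),
    stringsAsFactors = FALSE
  )
  res$p_hyper <- vapply(seq_len(n_pw), function(i) {
    k <- res$overlap[i]
    if (k == 0) return(1)
    exp(stats::phyper(k - 1, res$pathway_size[i],
                      length(universe) - res$pathway_size[i],
                      length(q), lower.tail = FALSE, log.p = TRUE))
  }, numeric(1))
  res$p_bonferroni <- pmin(1, res$p_hyper * n_pw)
  res <- res[order(res$p_hyper, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cohen's kappa between two gene sets
#'
#' Chance-corrected agreement of the two binary membership vectors over
#' the universe: \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with observed
#' agreement \eqn{p_o} and marginal chance agreement \eqn{p_e}. Returns 0
#' when \eqn{p_e = 1} (both sets empty or both equal to the universe).
#'
#' @param p1,p2 gene sets (subsets of \code{universe}).
#' @param universe the reference gene universe.
#' @return kappa in [-1, 1].
#' @export
kappa_score <- function(p1, p2, universe) {
  universe <- unique(as.character(universe))
  n <- length(universe)
  if (n == 0) stop("empty universe")
  in1 <- universe %in% as.character(p1)
  in2 <- universe %in% as.character(p2)
  both <- sum(in1 & in2)
  neither <- sum(!in1 & !in2)
  po <- (both + neither) / n
  pe <- (sum(in1) * sum(in2) + sum(!in1) * sum(!in2)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Kappa-linked graph of significant pathways
#'
#' Nodes are the pathways with Bonferroni-corrected p at or below
#' \code{alpha}; an edge links every pair whose membership kappa over
#' the database universe is at least \code{kappa_min} (the conventional
#' grouping cutoff is 0.5).
#'
#' @param results data.frame from \code{\link{ora}}.
#' @param db the \code{pathway_db}.
#' @param kappa_min minimum kappa for an edge, in [0, 1] (default 0.5).
#' @param alpha significance cutoff on \code{p_bonferroni} (default 0.05,
#'   inclusive).
#' @return data.frame edge list: \code{pathway1}, \code{pathway2},
#'   \code{kappa} (pathway1 < pathway2 lexicographically).
#' @export
pathway_graph <- function(results, db, kappa_min = 0.5, alpha = 0.05) {
  if (!(kappa_min >= 0 && kappa_min <= 1)) stop("kappa_min must be in [0, 1]")
  sig <- sort(results$pathway[results$p_bonferroni <= alpha])
  out <- data.frame(pathway1 = character(0), pathway2 = character(0),
                    kappa = numeric(0), stringsAsFactors = FALSE)
  if (length(sig) < 2) return(out)
  for (i in seq_len(length(sig) - 1)) {
    for (j in seq(i + 1, length(sig))) {
      k <- kappa_score(db$pathways[[sig[i]]], db$pathways[[sig[j]]],
                       db$universe)
      if (k >= kappa_min) {
        out[nrow(out) + 1, ] <- list(sig[i], sig[j], k)
      }
    }
  }
  out
}
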