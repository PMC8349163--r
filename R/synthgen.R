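# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a planted-module synthetic network
#'
#' Describes a stochastic-block-style benchmark emulating a bait-gene
#' co-expression network: a handful of near-clique modules in which most
#' members carry the known (bait) label, embedded in a sparse background.
#' The defaults plant 4 modules of 30-50 nodes at within-module edge
#' probability 0.9, with 90\% of module members labeled known, over a
#' background sized and labeled so that roughly 41\% of all nodes are
#' known — the composition of the motivating real network.
#'
#' @param n_background number of background nodes (default 220).
#' @param n_modules number of planted modules (default 4).
#' @param module_size single integer or \code{c(min, max)} range from
#'   which each module size is drawn uniformly (default \code{c(30, 50)}).
#' @param p_within within-module edge probability (default 0.9).
#' @param p_background background-pair edge probability (default 0.02).
#' @param p_attach module-to-background edge probability (default 0.01).
#' @param known_frac_module fraction of each module labeled known
#'   (default 0.9).
#' @param known_frac_background fraction of background nodes labeled
#'   known (default 0.05).
#' @param seed integer seed governing all draws (default 1).
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_background = 220, n_modules = 4,
                           module_size = c(30, 50), p_within = 0.9,
                           p_background = 0.02, p_attach = 0.01,
                           known_frac_module = 0.9,
                           known_frac_background = 0.05, seed = 1) {
  probs <- c(p_within, p_background, p_attach,
             known_frac_module, known_frac_background)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities and fractions must lie in [0, 1]")
  }
  if (n_background < 0 || n_modules < 0 || any(module_size < 2)) {
    stop("invalid sizes")
  }
  if (p_within <= p_background) {
    stop("p_within must exceed p_background for meaningful planting")
  }
  structure(list(
    n_background = as.integer(n_background),
    n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    p_within = p_within, p_background = p_background, p_attach = p_attach,
    known_frac_module = known_frac_module,
    known_frac_background = known_frac_background,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# all unordered pairs of a node id vector, Bernoulli-thinned at prob p;
# draw order is fixed (row-major over the upper triangle)
sample_pairs <- function(ids, p) {
  n <- length(ids)
  if (n < 2 || p == 0) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(from = pairs[1, keep], to = pairs[2, keep],
             stringsAsFactors = FALSE)
}

#' Generate a planted-module synthetic dataset
#'
#' Deterministic given the spec's seed. Generation order: module sizes,
#' then within-module edges (module by module), background edges,
#' module-background attachment edges, then known labels (per module,
#' then background), each label count rounded to the nearest integer and
#' drawn without replacement. Module nodes are named \code{g0001...},
#' background nodes follow.
#'
#' @param spec a \code{synthetic_spec}.
#' @return list of class \code{synthetic_dataset}: \code{network}
#'   (\code{gene_network}), \code{known} (character), \code{modules}
#'   (list of character vectors, the ground truth), and
#'   \code{planted_candidates} (unlabeled module members — the genes a
#'   successful run should surface).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    sizes <- if (length(spec$module_size) == 1) {
      rep(spec$module_size, spec$n_modules)
    } else {
      sample(seq(spec$module_size[1], spec$module_size[2]),
             spec$n_modules, replace = TRUE)
    }
    n_mod_nodes <- sum(sizes)
    n_total <- n_mod_nodes + spec$n_background
    ids <- sprintf("g%04d", seq_len(n_total))
    modules <- list()
    offset <- 0
    edges <- list()
    for (m in seq_len(spec$n_modules)) {
      mem <- ids[offset + seq_len(sizes[m])]
      modules[[m]] <- mem
      edges[[length(edges) + 1]] <- sample_pairs(mem, spec$p_within)
      offset <- offset + sizes[m]
    }
    bg <- ids[n_mod_nodes + seq_len(spec$n_background)]
    edges[[length(edges) + 1]] <- sample_pairs(bg, spec$p_background)
    if (length(bg) > 0 && n_mod_nodes > 0 && spec$p_attach > 0) {
      mod_nodes <- ids[seq_len(n_mod_nodes)]
      grid <- expand.grid(from = mod_nodes, to = bg,
                          stringsAsFactors = FALSE)
      keep <- stats::runif(nrow(grid)) < spec$p_attach
      edges[[length(edges) + 1]] <- grid[keep, , drop = FALSE]
    }
    edf <- do.call(rbind, edges)
    known <- character(0)
    for (m in seq_len(spec$n_modules)) {
      k <- round(spec$known_frac_module * sizes[m])
      known <- c(known, sample(modules[[m]], k))
    }
    kb <- round(spec$known_frac_background * spec$n_background)
    if (kb > 0) known <- c(known, sample(bg, kb))
    known <- sort(known)
    net <- gene_network(edf)
    structure(list(
      network = net,
      known = known,
      modules = modules,
      planted_candidates = sort(setdiff(unlist(modules), known)),
      spec = spec
    ), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d nodes, %d edges, %d known (%.2f), %d planted candidates\n",
    length(x$network$nodes), nrow(x$network$edges), length(x$known),
    length(x$known) / length(x$network$nodes), length(x$planted_candidates)))
  invisible(x)
}

#' Randomly hide a fraction of the known labels
#'
#' Splits the known set into a visible part (fed to the pipeline) and a
#' hidden part (used as recovery targets): \code{round(fraction * n)}
#' genes are hidden, drawn without replacement under the seed.
#'
#' @param known character vector of known genes.
#' @param fraction fraction to hide, in (0, 1).
#' @param seed integer seed.
#' @return list with \code{visible} and \code{hidden} (disjoint, sorted).
#' @export
holdout_known <- function(known, fraction, seed) {
  known <- unique(as.character(known))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  n_hide <- round(fraction * length(known))
  if (n_hide == 0 || n_hide == length(known)) {
    stop("holdout leaves an empty visible or hidden set")
  }
  with_seed(seed, {
    hidden <- sort(sample(known, n_hide))
    list(visible = sort(setdiff(known, hidden)), hidden = hidden)
  })
}

#' Write a synthetic dataset to pipeline-ready files
#'
#' Emits the edge list as two-column TSV, the known genes one per line,
#' and the ground truth (modules, planted candidates, spec) as JSON, so
#' downstream stages consume the dataset exactly like real inputs.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param dir output directory (created if missing).
#' @return named character vector of the three file paths.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    edges = file.path(dir, "network.tsv"),
    known = file.path(dir, "known_genes.txt"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_network_tsv(dataset$network, paths[["edges"]])
  writeLines(dataset$known, paths[["known"]])
  jsonlite::write_json(
    list(modules = dataset$modules,
         planted_candidates = dataset$planted_candidates,
         spec = unclass(dataset$spec)),
    paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  paths
}
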