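# shared fixtures and independent oracles for the suite

net_from_pairs <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  gene_network(data.frame(from = m[, 1], to = m[, 2],
                          stringsAsFactors = FALSE))
}

two_triangles <- function() {
  net_from_pairs("A", "B", "A", "C", "B", "C", "D", "E", "D", "F", "E", "F")
}

star4 <- function() net_from_pairs("c", "l1", "c", "l2", "c", "l3")

complete_net <- function(n, prefix = "n") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  gene_network(as.data.frame(t(utils::combn(ids, 2)),
                             stringsAsFactors = FALSE))
}

# Erdos-Renyi graph over named nodes, self-contained RNG
random_net <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("v%03d", seq_len(n))
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  gene_network(data.frame(from = pairs[1, keep], to = pairs[2, keep],
                          stringsAsFactors = FALSE))
}

# oracle: count edges with both endpoints in a member set, by scanning
oracle_internal_edges <- function(members, network) {
  sum(network$edges$from %in% members & network$edges$to %in% members)
}

# oracle: upper-tail hypergeometric by direct binomial-coefficient
# summation (safe in double precision for N <= ~60)
oracle_fisher_upper <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  ks <- seq(a, min(K, n))
  if (length(ks) == 0 || a == 0) return(1)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# oracle: AUC by exhaustive positive-negative pair enumeration,
# half credit for ties (Mann-Whitney)
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# fixture mirroring the published top-cluster table: six enriched
# clusters whose non-bait members union to 13 unique candidates
table3_fixture <- function() {
  known <- sprintf("K%03d", 1:112)
  cand <- c("IMDH3", "MVP1", "T19K24.17", "MRSA2", "SIR", "ASP4", "CGS1",
            "At1g21440", "HMT3", "At3g47420", "PS1", "SAL1", "At3g14220")
  members <- list(
    c(known[1:47], c("IMDH3", "MVP1", "T19K24.17", "MRSA2")),
    c(known[10:42], "MRSA2"),
    c(known[1:38], c("T19K24.17", "SIR", "MRSA2", "ASP4", "CGS1", "At1g21440")),
    c(known[1:39], c("T19K24.17", "SIR", "MRSA2", "ASP4", "CGS1", "At1g21440", "HMT3")),
    c(known[5:39], c("At3g47420", "PS1", "SIR", "T19K24.17", "SAL1", "CGS1")),
    c(known[1:35], c("At3g14220", "T19K24.17", "SIR", "MRSA2", "ASP4", "CGS1", "At1g21440"))
  )
  p <- c(5.79e-17, 2.27e-13, 2.75e-11, 4.65e-11, 4.77e-10, 1.93e-09)
  nodes <- unique(c(known, unlist(members), sprintf("U%03d", 1:45)))
  net <- gene_network(data.frame(from = nodes[-length(nodes)],
                                 to = nodes[-1]))
  enr <- make_enriched(members, p, known, net)
  list(enr = enr, known = known, cand = cand, net = net)
}

# enriched-cluster data.frame built directly from member lists + p-values
make_enriched <- function(members, p_values, known, network) {
  df <- data.frame(
    cluster_id = seq_along(members),
    size = vapply(members, length, integer(1)),
    n_known = vapply(members, function(m)
      length(intersect(m, known)), integer(1)),
    p_value = p_values,
    stringsAsFactors = FALSE
  )
  df$n_other <- df$size - df$n_known
  df$members <- members
  df
}
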