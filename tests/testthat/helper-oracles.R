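# Independent oracles used to cross-check the package's own algorithms.
# All are deliberately implemented through different routes (igraph MST,
# direct likelihood optimisation, exhaustive enumeration) than the code
# they validate.

# locale-independent pattern key ('+' before '-') and canonical unordered
# edge keys, for comparing edge sets between implementation and oracle
pkey <- function(x) chartr("+-", "01", x)
edge_keys <- function(a, b) {
  sw <- pkey(a) > pkey(b)
  k1 <- ifelse(sw, b, a)
  k2 <- ifelse(sw, a, b)
  paste(k1, k2, sep = "|")
}

# complete weighted graph over compact patterns
complete_graph <- function(patterns) {
  n <- length(patterns)
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- patterns
  w <- numeric(0)
  ends <- igraph::ends(g, igraph::E(g))
  for (k in seq_len(nrow(ends))) {
    a <- strsplit(ends[k, 1], "")[[1]]
    b <- strsplit(ends[k, 2], "")[[1]]
    w <- c(w, sum(a != b))
  }
  igraph::E(g)$weight <- w
  g
}

# total weight of a minimum spanning tree (igraph)
oracle_mst_weight <- function(patterns) {
  if (length(patterns) < 2) return(0)
  g <- complete_graph(patterns)
  sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
}

# set of edges belonging to at least one MST, via the perturbation trick:
# shrinking an edge by a tiny amount lowers the MST weight by exactly that
# amount iff the edge lies in some MST. Returns "a|b" keys with a < b.
oracle_all_mst_edges <- function(patterns) {
  g <- complete_graph(patterns)
  W <- oracle_mst_weight(patterns)
  keys <- character(0)
  eps <- 1e-6
  for (k in seq_along(igraph::E(g))) {
    w2 <- igraph::E(g)$weight
    w2[k] <- w2[k] - eps
    igraph::E(g)$w2 <- w2
    tree <- igraph::mst(g, weights = igraph::E(g)$w2)
    W2 <- sum(igraph::E(tree)$w2)
    if (isTRUE(all.equal(W2, W - eps))) {
      ab <- igraph::ends(g, igraph::E(g)[k])
      keys <- c(keys, edge_keys(ab[1], ab[2]))
    }
  }
  keys
}

# brute-force minimal Steiner-tree weight: minimum MST weight over the
# input augmented with every subset of candidate binary vectors of size
# <= max_extra (exhaustive; only for tiny L)
oracle_steiner_weight <- function(patterns, max_extra = 2) {
  L <- nchar(patterns[1])
  all_vec <- do.call(paste0, expand.grid(rep(list(c("-", "+")), L)))
  extras <- setdiff(all_vec, patterns)
  best <- oracle_mst_weight(patterns)
  for (k in seq_len(max_extra)) {
    combos <- utils::combn(extras, k, simplify = FALSE)
    for (cm in combos) {
      w <- oracle_mst_weight(c(patterns, cm))
      if (w < best) best <- w
    }
  }
  best
}

# minimal cost of connecting all sampled nodes inside the network graph
# (graph Steiner weight), by exhaustion over median-vector subsets
steiner_in_graph <- function(net, max_medians = 12) {
  smp <- net$nodes$pattern[net$nodes$sampled]
  meds <- net$nodes$pattern[!net$nodes$sampled]
  if (length(meds) > max_medians) return(NA_real_)
  g <- hapnet::as_igraph(net)
  best <- Inf
  for (mask in 0:(2^length(meds) - 1)) {
    keep <- c(smp, meds[bitwAnd(mask, 2^(seq_along(meds) - 1)) > 0])
    sub <- igraph::induced_subgraph(g, keep)
    if (!igraph::is_connected(sub)) next
    tree <- igraph::mst(sub, weights = igraph::E(sub)$length)
    w <- sum(igraph::E(tree)$length)
    if (w < best) best <- w
  }
  best
}

# direct likelihood maximisation over the frequency simplex through a
# softmax parameterisation and multi-start BFGS; independent of the EM path
oracle_max_loglik <- function(genotypes, support, starts = 25, seed = 99) {
  nll <- function(theta) {
    p <- exp(theta - max(theta))
    p <- p / sum(p)
    names(p) <- support
    ll <- hapnet::log_likelihood(p, genotypes)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  set.seed(seed)
  best <- -Inf
  K <- length(support)
  for (s in seq_len(starts)) {
    th0 <- if (s == 1) rep(0, K) else stats::rnorm(K, sd = 2)
    fit <- try(stats::optim(th0, nll, method = "BFGS",
                            control = list(maxit = 500)), silent = TRUE)
    if (!inherits(fit, "try-error") && -fit$value > best) best <- -fit$value
  }
  best
}

# random haplotype pattern set
random_patterns <- function(n, L) {
  unique(vapply(seq_len(n), function(i)
    paste(sample(c("-", "+"), L, replace = TRUE), collapse = ""),
    character(1)))
}

# small generic site maps used throughout
sm <- function(L) beta_globin_sites(paste0("s", seq_len(L)))
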