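test_that("the median vector is the site-wise majority", {
  expect_equal(median_vector(c(0, 0, 0), c(0, 1, 1), c(1, 1, 0)),
               c(0L, 1L, 0L))
  set.seed(8)
  for (rep in 1:20) {
    x <- sample(0:1, 5, replace = TRUE)
    y <- sample(0:1, 5, replace = TRUE)
    expect_equal(median_vector(x, x, y), x)  # duplicate wins every site
  }
  # majority of three published patterns
  m <- median_vector(parse_haplotype("-------"), parse_haplotype("+----++"),
                     parse_haplotype("------+"))
  expect_equal(format_haplotype(m), "------+")
  expect_error(median_vector(c(0, 1), c(0, 1, 1), c(1, 1, 0)), "lengths")
})

test_that("the minimum spanning network is the union of all MSTs", {
  p2 <- network_params(site_map = sm(2))
  # {00, 01, 11}: a path, the long diagonal is in no MST
  net <- minimum_spanning_network(c("--", "-+", "++"), p2)
  keys <- edge_keys(net$edges$from, net$edges$to)
  expect_setequal(keys, c(edge_keys("--", "-+"), edge_keys("-+", "++")))
  # {00, 11}: one link of length 2
  net <- minimum_spanning_network(c("--", "++"), p2)
  expect_equal(net$edges$length, 2)
  # {000, 011, 110}: all three length-2 links are co-minimal
  p3 <- network_params(site_map = sm(3))
  net <- minimum_spanning_network(c("---", "-++", "++-"), p3)
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$edges$length, rep(2, 3))
  expect_error(minimum_spanning_network(character(0), p2), "empty")

  # randomized agreement with the all-MST oracle (epsilon = 0)
  set.seed(21)
  for (rep in 1:30) {
    L <- sample(3:6, 1)
    pats <- random_patterns(sample(3:7, 1), L)
    if (length(pats) < 2) next
    net <- minimum_spanning_network(pats, network_params(site_map = sm(L)))
    expect_setequal(edge_keys(net$edges$from, net$edges$to),
                    oracle_all_mst_edges(pats))
  }
})

test_that("epsilon-0 backbones are subgraphs of epsilon-1 backbones", {
  set.seed(33)
  for (rep in 1:20) {
    L <- sample(3:6, 1)
    pats <- random_patterns(sample(3:6, 1), L)
    if (length(pats) < 2) next
    e0 <- minimum_spanning_network(pats, network_params(0, site_map = sm(L)))
    e1 <- minimum_spanning_network(pats, network_params(1, site_map = sm(L)))
    k0 <- paste(e0$edges$from, e0$edges$to, sep = "|")
    k1 <- paste(e1$edges$from, e1$edges$to, sep = "|")
    expect_true(all(k0 %in% k1))
  }
})

test_that("median joining resolves the classic triangle into a Steiner star", {
  p3 <- network_params(site_map = sm(3))
  net <- mj_construct(c("---", "-++", "++-"), p3)
  expect_equal(nrow(net$nodes), 4)
  expect_equal(net$nodes$pattern[!net$nodes$sampled], "-+-")
  expect_equal(nrow(net$edges), 3)
  expect_equal(sum(net$edges$length), 3)
  expect_true(all(net$edges$length == 1))
  # brute-force Steiner search certifies 3 as the unique optimum (MST = 4)
  expect_equal(oracle_steiner_weight(c("---", "-++", "++-")), 3)
  expect_equal(oracle_mst_weight(c("---", "-++", "++-")), 4)
})

test_that("degenerate and tree-like inputs stay trees", {
  p3 <- network_params(site_map = sm(3))
  net <- mj_construct("-++", p3)
  expect_equal(nrow(net$nodes), 1)
  expect_equal(nrow(net$edges), 0)
  # a chain of single-step neighbours needs no medians: |E| = |V| - 1
  p4 <- network_params(site_map = sm(4))
  chain <- c("----", "+---", "++--", "+++-", "++++")
  net <- mj_construct(chain, p4)
  expect_equal(nrow(net$nodes), 5)
  expect_equal(nrow(net$edges), 4)
  expect_true(all(net$edges$length == 1))
})

test_that("networks connect the sample at no more than MST cost", {
  set.seed(55)
  for (rep in 1:25) {
    L <- sample(3:5, 1)
    pats <- random_patterns(sample(2:5, 1), L)
    net <- mj_construct(pats, network_params(site_map = sm(L)))
    g <- as_igraph(net)
    expect_true(igraph::is_connected(g))
    # the cheapest subnetwork connecting the sampled haplotypes is
    # bracketed by the true Steiner minimum (<= 3 branch points suffice
    # for <= 5 terminals) and their MST weight
    w_net <- steiner_in_graph(net)
    expect_lte(w_net, oracle_mst_weight(pats))
    expect_gte(w_net, oracle_steiner_weight(pats, max_extra = 3))
    # every edge length equals the Hamming distance of its endpoints
    for (k in seq_len(nrow(net$edges))) {
      expect_equal(net$edges$length[k],
                   hamming_distance(
                     unname(parse_haplotype(net$edges$from[k], sm(L))),
                     unname(parse_haplotype(net$edges$to[k], sm(L)))))
    }
    # surviving medians have degree >= 3 or sit on a sampled geodesic
    deg <- igraph::degree(g)
    D <- igraph::distances(g, weights = igraph::E(g)$length)
    smp <- net$nodes$pattern[net$nodes$sampled]
    for (m in net$nodes$pattern[!net$nodes$sampled]) {
      if (deg[m] >= 3) next
      on_geo <- FALSE
      for (s in smp) for (t in smp[smp > s]) {
        if (isTRUE(all.equal(D[s, m] + D[m, t], D[s, t]))) on_geo <- TRUE
      }
      expect_true(on_geo)
    }
  }
})

test_that("network export produces edge lists, DOT and GraphML", {
  p2 <- network_params(site_map = sm(2))
  net <- minimum_spanning_network(
    data.frame(label = c("A", "B", "C"), pattern = c("--", "-+", "++"),
               weight = c(0.5, 0.25, 0.25)), p2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  el <- read.delim(tsv)
  expect_equal(nrow(el), 2)
  expect_equal(names(el), c("node_a", "node_b", "length", "sites_changed"))

  dot <- withr::local_tempfile(fileext = ".dot")
  export_network(net, dot, "dot")
  lines <- readLines(dot)
  expect_match(lines[1], "^graph ")
  expect_equal(sum(grepl("\\{", lines)), sum(grepl("\\}", lines)))
  # circle diameters proportional to frequency: widths in ratio 2:1:1
  circ <- grep("shape=circle", lines, value = TRUE)
  ids <- sub("^\\s*\"([^\"]+)\".*", "\\1", circ)
  widths <- setNames(as.numeric(sub(".*width=([0-9.]+).*", "\\1", circ)), ids)
  expect_equal(unname(widths[c("A", "B", "C")] / widths["B"]), c(2, 1, 1))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), 3)
  expect_equal(igraph::ecount(g2), 2)
  expect_setequal(igraph::V(g2)$weight, c(0.5, 0.25, 0.25))

  expect_error(export_network(net, tsv, "pdf"))
})

test_that("the pooled world haplotype set yields a connected 21-node network", {
  ft <- table1_fixture()
  pooled <- pool_populations(ft)
  net <- mj_construct(data.frame(label = pooled$label,
                                 pattern = pooled$pattern,
                                 weight = pooled$count))
  expect_equal(sum(net$nodes$sampled), 21)
  expect_true(igraph::is_connected(as_igraph(net)))
  dot <- withr::local_tempfile(fileext = ".dot")
  export_network(net, dot, "dot")
  expect_equal(sum(grepl("shape=circle", readLines(dot))), 21)
})
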