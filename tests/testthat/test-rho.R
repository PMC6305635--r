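test_that("age conversion multiplies by the calibration rate", {
  expect_equal(convert_age(4), 80720)
  expect_equal(convert_age(3), 60540)
  expect_equal(convert_age(2), 40360)
  expect_equal(convert_age(0.5), 10090)
  expect_equal(convert_age(0.8), 16144)
  expect_equal(convert_age(0, calibration_rate(12345)), 0)
  expect_equal(convert_age(1, calibration_rate(100.04)), 100)  # 0.1-year rounding
  expect_error(convert_age(-1), "non-negative")
  expect_error(calibration_rate(0))
})

test_that("expansion time follows t = tau / 2u with generation scaling", {
  expect_equal(expansion_time(2, 1), 1)
  expect_equal(expansion_time(1, 0.5), 1)
  expect_equal(expansion_time(4.2, 0.05), 42)
  expect_equal(expansion_time(4.2, 0.05, generation_years = 25), 1050)
  expect_error(expansion_time(1, 0), "positive")
  expect_error(expansion_time(-1, 1), "non-negative")
})

test_that("rho on a three-lineage star reproduces the hand calculation", {
  # chromosomes at 2, 3 and 4 mutations from the root: rho is their mean;
  # every branch subtends one chromosome, so sigma^2 = (2+3+4)/9 = 1
  sim <- simulate_star("-------", n = 3, counts = c(2, 3, 4), seed = 1)
  expect_equal(sim$mutations, c(2L, 3L, 4L))
  tree <- star_genealogy("-------", sim$haplotypes)
  est <- rho_estimate(tree, "-------")
  expect_equal(est$rho, 3)
  expect_equal(est$sigma, 1)
  expect_equal(est$years, 60540)
  expect_equal(est$years_sd, 20180)
  expect_equal(est$n, 3)
})

test_that("a sample identical to the root dates to zero", {
  tree <- star_genealogy("-------", "-------")
  est <- rho_estimate(tree, "-------")
  expect_equal(est$rho, 0)
  expect_equal(est$years, 0)
  expect_equal(est$sigma, 0)
})

test_that("sigma^2 equals rho/n exactly on constructed stars", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(2:12, 1)
    counts <- sample(0:5, n, replace = TRUE)
    sim <- simulate_star(paste(rep("-", 30), collapse = ""), n = n,
                         counts = counts, seed = rep)
    tree <- star_genealogy(sim$root, sim$haplotypes)
    est <- rho_estimate(tree, sim$root)
    expect_equal(est$rho, mean(counts))
    expect_equal(est$sigma^2, est$rho / n, tolerance = 1e-12)
  }
})

test_that("rho at the root equals the multiplicity-weighted mean leaf depth", {
  # non-star genealogy with internal structure and multiplicities
  nodes <- data.frame(
    id = c("R", "A", "B", "C", "D"),
    pattern = c("-----", "+----", "++---", "+++--", "---+-"),
    parent = c(NA, "R", "A", "B", "R"),
    edge_length = c(0, 1, 1, 1, 1),
    multiplicity = c(2, 1, 0, 3, 5),
    sampled = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  tree <- rooted_genealogy(nodes)
  est <- rho_estimate(tree, "R")
  # direct recomputation from depths and multiplicities
  expected <- sum(tree$multiplicity * tree$depth) / sum(tree$multiplicity)
  expect_equal(est$rho, expected)
  # branch formula by hand: n_A-branch = 4, n_B = 3, n_C = 3, n_D = 5
  expect_equal(est$sigma^2, (16 + 9 + 9 + 25) / 11^2)
  expect_error(rho_estimate(tree, "Z"), "not in genealogy")
})

test_that("clades without sampled chromosomes are rejected by name", {
  nodes <- data.frame(
    id = c("R", "m"), pattern = c("--", "-+"),
    parent = c(NA, "R"), edge_length = c(0, 1),
    multiplicity = c(1, 0), sampled = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  tree <- rooted_genealogy(nodes)
  expect_error(rho_estimate(tree, "m"), "'m'")
})

test_that("shortest-path trees root the network deterministically", {
  p2 <- network_params(site_map = sm(2))
  # path A-B-C
  net <- minimum_spanning_network(c("--", "-+", "++"), p2)
  tree <- extract_tree(net, "--")
  expect_equal(tree$depth[match(c("--", "-+", "++"), tree$pattern)],
               c(0, 1, 2))
  expect_equal(tree$parent[tree$pattern == "++"], "-+")
  # square of unit edges: the opposite corner is at depth 2 in both modes
  sq <- c("--", "-+", "+-", "++")
  netq <- minimum_spanning_network(sq, p2)
  for (mode in c("shortest-path", "all-shortest-paths-average")) {
    tr <- extract_tree(netq, "--", mode)
    expect_equal(tr$depth[tr$pattern == "++"], 2)
  }
  # diamond with competing 2- and 3-step routes: shortest wins
  p4 <- network_params(site_map = sm(4))
  dia <- c("----", "+---", "++--", "+++-", "++++", "---+")
  netd <- mj_construct(dia, p4)
  trd <- extract_tree(netd, "----")
  expect_equal(trd$depth[trd$pattern == "++++"], 4)
  expect_error(extract_tree(netq, "##"), "not a node")
})

test_that("per-node dating supports both clade-rho and root-path readings", {
  # root with two sampled children at distances 1 and 2
  nodes <- data.frame(
    id = c("R", "A", "B"), pattern = c("---", "+--", "-++"),
    parent = c(NA, "R", "R"), edge_length = c(0, 1, 2),
    multiplicity = c(0, 1, 1), sampled = c(FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  tree <- rooted_genealogy(nodes)
  rp <- date_all_nodes(tree, mode = "root-path")
  expect_equal(rp$years[match(c("A", "B"), rp$haplotype)], c(20180, 40360))
  dr <- date_all_nodes(tree, mode = "descendant-rho")
  expect_equal(dr$rho, c(0, 0))  # leaves are their own clades

  # chain root - A(1 mutation, 1 chromosome) - B(1 mutation, 1 chromosome)
  chain <- data.frame(
    id = c("R", "A", "B"), pattern = c("---", "+--", "++-"),
    parent = c(NA, "R", "A"), edge_length = c(0, 1, 1),
    multiplicity = c(1, 1, 1), sampled = c(TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  trc <- rooted_genealogy(chain)
  estA <- rho_estimate(trc, "A")
  expect_equal(estA$rho, 0.5)  # mean of 0 (own chromosome) and 1 (B)
  tab <- date_all_nodes(trc)
  expect_equal(names(tab),
               c("haplotype", "pattern", "years", "years_sd", "rho", "sigma", "n"))
  # years always equals rho x rate up to the 0.1-year print rounding
  expect_true(all(abs(tab$years - tab$rho * 20180) <= 0.5))
})

test_that("simulated star samples recover the expected rho", {
  # 200 replicates of n = 20 chromosomes with 3 expected mutations each;
  # rho is unbiased for the true mean, so the replicate mean sits near 3
  rhos <- vapply(1:200, function(r) {
    sim <- simulate_star(paste(rep("-", 50), collapse = ""), n = 20,
                         lambda = 3, seed = 1000 + r)
    tree <- star_genealogy(sim$root, sim$haplotypes)
    rho_estimate(tree, sim$root)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 3), 0.1)
})
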