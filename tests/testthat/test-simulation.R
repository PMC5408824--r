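test_that("fixture network is deterministic, connected and heavy-tailed", {
  a <- generate_fixture_network(100, 2, seed = 5)
  b <- generate_fixture_network(100, 2, seed = 5)
  expect_identical(igraph::as_edgelist(a), igraph::as_edgelist(b))
  expect_true(igraph::is_connected(a))
  expect_gte(igraph::ecount(a), 99)

  for (s in 1:20) {
    g <- generate_fixture_network(500, 3, seed = s)
    d <- igraph::degree(g)
    expect_gte(max(d), 3 * stats::median(d))
  }

  # triadic closure produces clustering; plain PA essentially none
  clustered <- generate_fixture_network(500, 3, seed = 1)
  plain <- generate_fixture_network(500, 3, seed = 1, triad_prob = 0)
  expect_gt(igraph::transitivity(clustered), igraph::transitivity(plain))

  expect_error(generate_fixture_network(3, 3), "exceed")
})

test_that("frontier growth returns connected subsets of the right size", {
  net <- generate_fixture_network(300, 2, seed = 8)
  withr::with_seed(12, {
    for (i in 1:300) {
      mem <- sample_connected_subnetwork(net, 10)
      expect_length(mem, 10)
      expect_true(igraph::is_connected(igraph::induced_subgraph(net, mem)))
    }
    expect_length(sample_connected_subnetwork(net, 1), 1)
    expect_setequal(sample_connected_subnetwork(net, 300),
                    igraph::V(net)$name)
  })
})

test_that("radius-conditioned sampling verifies and bounds the radius", {
  net <- generate_fixture_network(500, 3, seed = 14)
  withr::with_seed(15, {
    mem <- sample_subnetwork_with_radius(net, 15, 3)
    expect_equal(graph_radius(net, mem), 3)
    expect_gte(attr(mem, "tries"), 1)
  })
  expect_error(sample_subnetwork_with_radius(net, 5, 6), "impossible")
  # a hub neighborhood subset can realize radius 1
  withr::with_seed(16, {
    star_like <- sample_subnetwork_with_radius(net, 4, 1)
    expect_equal(graph_radius(net, star_like), 1)
  })
})

test_that("planted deregulation follows the redraw model", {
  net <- generate_fixture_network(400, 3, seed = 20)

  null_cfg <- simulation_config(2, 15, p_enr = 0, p_scale = 0.1, seed = 1)
  null_sim <- plant_deregulation(net, null_cfg)
  expect_length(null_sim$redrawn, 0)
  expect_length(null_sim$pathway_genes, 30)

  forced <- plant_deregulation(net, simulation_config(2, 15, p_enr = 1,
                                                      p_scale = 0.1, seed = 2))
  expect_true(all(forced$scores[forced$pathway_genes] <= 0.1))
  expect_setequal(forced$redrawn, forced$pathway_genes)

  # redraw fraction ~ Binomial(n_pathway_genes, 0.5) across instances
  redrawn <- vapply(1:10, function(s) {
    sim <- plant_deregulation(net, simulation_config(2, 15, 0.5, 0.1,
                                                     seed = 100 + s))
    length(sim$redrawn)
  }, numeric(1))
  n_total <- 10 * 30
  ci <- stats::qbinom(c(0.0005, 0.9995), n_total, 0.5)
  expect_gte(sum(redrawn), ci[1])
  expect_lte(sum(redrawn), ci[2])
})

test_that("planted pathways are disjoint, connected and reproducible", {
  net <- generate_fixture_network(400, 3, seed = 21)
  cfg <- simulation_config(3, 20, 0.5, 0.1, seed = 9)
  sim <- plant_deregulation(net, cfg)
  expect_length(sim$pathway_genes, 60) # disjoint
  for (pw in sim$pathways) {
    expect_true(igraph::is_connected(igraph::induced_subgraph(net,
                                                              pw$members)))
    expect_equal(graph_radius(net, pw$members), pw$radius)
  }
  expect_setequal(unlist(lapply(sim$pathways, `[[`, "members")),
                  sim$pathway_genes)
  expect_true(all(as.numeric(sim$scores) > 0 & as.numeric(sim$scores) <= 1))

  sim2 <- plant_deregulation(net, cfg)
  expect_identical(as.numeric(sim$scores), as.numeric(sim2$scores))
  expect_identical(sim$pathways, sim2$pathways)

  radius_cfg <- simulation_config(1, 12, 0.5, 0.1, target_radius = 3,
                                  seed = 4)
  rsim <- plant_deregulation(net, radius_cfg)
  expect_equal(rsim$pathways[[1]]$radius, 3)

  expect_error(
    plant_deregulation(net, simulation_config(10, 50, 0.5, 0.1, seed = 1)),
    "node budget")
})

test_that("rewiring preserves edge count and perturbs the requested share", {
  net <- generate_fixture_network(500, 3, seed = 22)
  expect_identical(rewire_network(net, 0), net)

  rw <- rewire_network(net, 0.3, seed = 5)
  expect_equal(igraph::ecount(rw), igraph::ecount(net))
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  ji <- jaccard_index(canon(net), canon(rw))
  expect_equal(ji, 0.7 / 1.3, tolerance = 0.08)

  deg_rw <- rewire_network(net, 0.2, seed = 6, keep_degree = TRUE)
  expect_identical(igraph::degree(deg_rw)[igraph::V(net)$name],
                   igraph::degree(net)[igraph::V(net)$name])
})
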