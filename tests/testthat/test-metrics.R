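star <- function(n) {            # ego at the hub
  adj <- matrix(0, n, n)
  adj[1, 2:n] <- adj[2:n, 1] <- 1
  adj
}
complete <- function(n) matrix(1, n, n) - diag(n)
path4 <- {
  adj <- matrix(0, 4, 4)
  adj[cbind(1:3, 2:4)] <- adj[cbind(2:4, 1:3)] <- 1
  adj
}

test_that("degree centrality is the tie share on a 0-100 scale", {
  net <- graph_net(complete(9))
  expect_equal(degree_centrality(net), 100)
  iso <- complete(9); iso[1, ] <- iso[, 1] <- 0
  expect_equal(degree_centrality(graph_net(iso)), 0)
  four <- matrix(0, 9, 9); four[1, 2:5] <- four[2:5, 1] <- 1
  expect_equal(degree_centrality(graph_net(four)), 50)
  expect_error(degree_centrality(graph_net(matrix(0, 1, 1))), "singleton")
})

test_that("the most central professional is found with deterministic tie-breaks", {
  # GP tied to everything.
  adj <- complete(5)
  net <- graph_net(adj, disciplines = c("gp", "practice_nurse",
                                        "practice_assistant", "pharmacist"))
  mc <- most_central_professional(net)
  expect_equal(mc$degree, 100)
  # Two professionals with equal degree, one a GP: the GP wins.
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- 1
  adj[1, 3] <- adj[3, 1] <- 1
  net <- graph_net(adj, disciplines = c("practice_nurse", "gp",
                                        "practice_assistant"))
  mc <- most_central_professional(net)
  expect_equal(mc$discipline, "gp")
  # In-practice beats external at equal degree and discipline rank.
  net <- graph_net(adj, disciplines = c("medical_specialist",
                                        "practice_nurse", "gp"))
  expect_equal(most_central_professional(net)$discipline, "practice_nurse")
  # n = 3, single tie: 50%.
  adj <- matrix(0, 3, 3); adj[1, 2] <- adj[2, 1] <- 1
  expect_equal(most_central_professional(graph_net(adj))$degree, 50)
})

test_that("Freeman centralization: 100 iff star, 0 iff regular", {
  expect_equal(network_centralization(graph_net(star(5))), 100)
  expect_equal(network_centralization(graph_net(complete(6))), 0)
  expect_equal(network_centralization(graph_net(path4)), 100 * 2 / 6)
  expect_error(network_centralization(graph_net(complete(2))), "fewer than 3")

  # Exhaustive over all graphs on 5 labelled nodes.
  for (k in 0:(2^10 - 1)) {
    adj <- graph_from_index(5, k)
    net <- graph_net(adj)
    cz <- network_centralization(net)
    d <- rowSums(adj)
    is_star <- all(sort(d) == c(1, 1, 1, 1, 4))
    is_regular <- length(unique(d)) == 1
    expect_equal(cz == 100, is_star)
    expect_equal(cz == 0, is_regular)
  }
})

test_that("density counts present dyads over all dyads including the ego", {
  expect_equal(net_density(graph_net(complete(7))), 1)
  expect_equal(net_density(graph_net(matrix(0, 5, 5))), 0)
  set.seed(77)
  adj <- rand_adj(9)
  expect_equal(net_density(graph_net(adj)), sum(adj) / 2 / 36)
  net19 <- graph_net(star(9))
  net19$adjacency[2, 3:9] <- net19$adjacency[3:9, 2] <- 1
  net19$adjacency[3, 4:8] <- net19$adjacency[4:8, 3] <- 1
  expect_equal(sum(net19$adjacency) / 2, 20)
  expect_equal(net_density(net19), 20 / 36)
})

test_that("overlap is the simple matching coefficient over dyads", {
  a <- graph_net(complete(4))
  expect_equal(overlap(a, a)$coefficient, 1)
  b <- graph_net(matrix(0, 4, 4))
  b$adjacency <- 1 - diag(4) - a$adjacency  # complement
  b$adjacency[b$adjacency < 0] <- 0
  expect_equal(overlap(a, b)$coefficient, 0)

  # Differ in 2 of 6 dyads.
  c1 <- graph_net(complete(4)); c2 <- graph_net(complete(4))
  c2$adjacency[3, 4] <- c2$adjacency[4, 3] <- 0
  c2$adjacency[2, 4] <- c2$adjacency[4, 2] <- 0
  expect_equal(overlap(c1, c2)$coefficient, 4 / 6)

  expect_equal(overlap(c1, c2)$coefficient, overlap(c2, c1)$coefficient)
  other <- graph_net(complete(4), patient_id = "py")
  expect_error(overlap(c1, other), "same patient")
})

test_that("reciprocity counts mutually agreeing dyads among responders", {
  roster6 <- mk_roster("pr1", c(gp = 2L, practice_nurse = 2L,
                                practice_assistant = 2L))
  ids <- roster6$professional_id
  # All reports symmetric (nobody reports anything): perfect agreement.
  pv <- mk_providers(roster6)
  expect_equal(reciprocity(pv), 1)
  # Every dyad one-sided for every activity: zero agreement.
  roster_pair <- mk_roster("pr1", c(gp = 1L, practice_nurse = 1L))
  one_sided <- stats::setNames(
    rep(list("practice_nurse"), length(ACTIVITIES)), ACTIVITIES)
  pv <- mk_providers(roster_pair,
                     yes = list(`HP:pr1:gp:1` = one_sided))
  expect_equal(reciprocity(pv), 0)
  expect_error(reciprocity(mk_providers(roster6, responders = ids[1])),
               "2 responding")
})

test_that("reciprocity matches hand-counted agreement on a 6-responder practice", {
  roster6 <- mk_roster("pr1", c(gp = 2L, practice_nurse = 2L,
                                practice_assistant = 2L))
  ids <- roster6$professional_id
  # One activity; gp1 and gp2 mutually report each other's disciplines,
  # gp1 additionally reports the nurses (unreciprocated).
  pv <- mk_providers(roster6, yes = list(
    `HP:pr1:gp:1` = list(treatment = c("gp", "practice_nurse")),
    `HP:pr1:gp:2` = list(treatment = "gp")))
  pv <- pv[pv$activity == "treatment", ]
  # 15 dyads: agreeing = all except gp1-pn1 and gp1-pn2 -> 13/15.
  expect_equal(reciprocity(pv), 13 / 15)
})

test_that("the parameter set agrees with the individual metrics", {
  # Star with the patient at the center, 4 professionals.
  net <- graph_net(star(5))
  ps <- parameter_set(net)
  expect_equal(ps$size, 4)
  expect_equal(ps$density, 0.4)
  expect_equal(ps$centralization, 100)
  expect_equal(ps$patient_degree, 100)

  net <- graph_net(complete(4), disciplines = c("gp", "practice_nurse",
                                                "dietician"))
  ps <- parameter_set(net)
  expect_equal(ps$diversity, 3)
  expect_equal(ps$size, 3)
  expect_equal(ps$density, 1)

  set.seed(7)
  for (rep in 1:10) {
    adj <- rand_adj(9)
    net <- graph_net(adj)
    ps <- parameter_set(net)
    expect_equal(ps$density, net_density(net))
    expect_equal(ps$centralization, network_centralization(net))
    expect_equal(ps$patient_degree, degree_centrality(net))
    expect_equal(ps$central_prof_degree,
                 most_central_professional(net)$degree)
    expect_equal(ps$n_connections, sum(adj) / 2)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(55)
  adj <- rand_adj(7)
  net <- graph_net(adj)
  perm <- c(1, 1 + sample(6))   # keep the ego first
  net2 <- graph_net(adj[perm, perm],
                    disciplines = net$nodes$discipline[-1][perm[-1] - 1])
  expect_equal(net_density(net2), net_density(net))
  expect_equal(network_centralization(net2), network_centralization(net))
  expect_equal(degree_centrality(net2), degree_centrality(net))
})

test_that("metrics agree with igraph on random graphs", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(3:10, 1)
    adj <- rand_adj(n)
    net <- graph_net(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(net_density(net), igraph::edge_density(g))
    # igraph normalizes undirected degree centralization by n(n-1);
    # Freeman's denominator is (n-1)(n-2).
    expect_equal(network_centralization(net),
                 100 * igraph::centr_degree(g)$centralization * n / (n - 2))
    expect_equal(degree_centrality(net),
                 100 * igraph::degree(g)[1] / (n - 1),
                 ignore_attr = TRUE)
  }
})
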