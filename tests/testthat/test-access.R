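test_that("points snap to the nearest node with deterministic ties", {
  net <- line_network(6L, step = 1000)
  # coincident point: that node
  expect_equal(snap_to_node(data.frame(x = 2000, y = 0), net), 3L)
  # exact midpoint between nodes 1 and 2: smallest id wins
  expect_equal(snap_to_node(data.frame(x = 500, y = 0), net), 1L)
  # brute-force nearest scan on random points
  set.seed(17)
  pts <- data.frame(x = runif(40, -500, 5500), y = runif(40, -200, 200))
  got <- snap_to_node(pts, net)
  for (i in seq_len(40)) {
    d <- sqrt((net$nodes$x - pts$x[i])^2 + (net$nodes$y - pts$y[i])^2)
    expect_equal(got[i], which.min(d))
  }
  expect_error(snap_to_node(pts, list(nodes = net$nodes[0, ])), "empty")
})

test_that("linear-decay scores follow hand-computed shortest paths", {
  net <- line_network(6L, step = 1000) # nodes at 0..5000 m
  query <- data.frame(x = 0, y = 0)

  # center at the query node: decay at zero distance is 1
  expect_equal(access_score(query, data.frame(x = 0, y = 0), net), 1.0)
  # center exactly at the radius: contribution 0
  expect_equal(access_score(query, data.frame(x = 5000, y = 0), net), 0)
  # centers at 1000 m and 4000 m on a 5000 m radius: 0.8 + 0.2
  two <- data.frame(x = c(1000, 4000), y = c(0, 0))
  expect_equal(access_score(query, two, net), 1.0)
  # no active center within radius: zero
  expect_equal(access_score(data.frame(x = 5000, y = 0),
                            data.frame(x = 0, y = 0), net), 0)
})

test_that("scores are additive over centers and monotone in radius", {
  canton <- tiny_canton()
  net <- canton$network
  pts <- canton$neighborhoods[1:10, .(x, y)]
  A <- canton$centers[1:3, .(x, y)]
  B <- canton$centers[4:6, .(x, y)]
  sA <- access_score(pts, A, net)
  sB <- access_score(pts, B, net)
  sAB <- access_score(pts, rbind(A, B), net)
  expect_equal(sAB, sA + sB, tolerance = 1e-12)

  s3 <- access_score(pts, A, net, radius = 3000)
  s6 <- access_score(pts, A, net, radius = 6000)
  expect_true(all(s6 >= s3 - 1e-12))
})

test_that("network distances dominate Euclidean and match plain Dijkstra", {
  set.seed(23)
  # 30-node toy: a jittered 6x5 grid
  nodes <- data.frame(node_id = 1:30,
                      x = rep(1:6, 5) * 100 + runif(30, -20, 20),
                      y = rep(1:5, each = 6) * 100 + runif(30, -20, 20))
  idx <- function(i, j) (j - 1L) * 6L + i
  e <- rbind(cbind(idx(rep(1:5, 5), rep(1:5, each = 5)),
                   idx(rep(2:6, 5), rep(1:5, each = 5))),
             cbind(idx(rep(1:6, 4), rep(1:4, each = 6)),
                   idx(rep(1:6, 4), rep(2:5, each = 6))))
  edges <- data.frame(from = e[, 1], to = e[, 2],
                      length = sqrt((nodes$x[e[, 1]] - nodes$x[e[, 2]])^2 +
                                    (nodes$y[e[, 1]] - nodes$y[e[, 2]])^2))
  net <- list(nodes = nodes, edges = edges)
  g <- build_network_graph(net)
  D <- igraph::distances(g, v = as.character(1:30), to = as.character(1:30))
  for (s in c(1L, 14L, 30L)) {
    expect_equal(unname(D[s, ]), oracle_dijkstra(nodes, edges, s),
                 tolerance = 1e-9)
  }
  euclid <- as.matrix(dist(nodes[, c("x", "y")]))
  expect_true(all(D >= euclid - 1e-9))
})

test_that("center activity intervals gate period contributions", {
  net <- line_network(6L, step = 1000)
  centers <- data.frame(x = 1000, y = 0,
                        first_active_period = 2008L,
                        last_active_period = 2012L)
  periods <- seq(2004L, 2016L, 2L)
  acc <- access_panel(data.frame(id = 1L, x = 0, y = 0), centers, net,
                      periods)
  expect_equal(as.vector(acc),
               c(0, 0, 0.8, 0.8, 0.8, 0, 0))

  # adding a center never decreases any score
  centers2 <- rbind(centers,
                    data.frame(x = 3000, y = 0,
                               first_active_period = 2004L,
                               last_active_period = 2016L))
  acc2 <- access_panel(data.frame(id = 1L, x = 0, y = 0), centers2, net,
                       periods)
  expect_true(all(acc2 >= acc))

  bad <- data.frame(x = 0, y = 0, first_active_period = 2010L,
                    last_active_period = 2008L)
  expect_error(access_panel(data.frame(id = 1L, x = 0, y = 0), bad, net,
                            periods), "validation error")
})
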