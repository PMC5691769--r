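# Correlation network: sex-weighted Spearman, spanning-tree pruning,
# module detection, and per-module PC scores.

test_that("edge weights are the sex-fraction-weighted Spearman average", {
  set.seed(41)
  n_f <- 60; n_m <- 40
  sex <- c(rep("female", n_f), rep("male", n_m))
  x <- rnorm(n_f + n_m)
  y <- c(0.6 * x[1:n_f] + 0.8 * rnorm(n_f), rnorm(n_m))  # correlated in women only
  data <- cbind(a = x, b = y)
  net <- sex_weighted_spearman(data, sex)
  rho_f <- cor(x[1:n_f], y[1:n_f], method = "spearman")
  rho_m <- cor(x[-(1:n_f)], y[-(1:n_f)], method = "spearman")
  expect_equal(net$edges$weight, 0.6 * rho_f + 0.4 * rho_m, tolerance = 1e-12)
  expect_true(all(abs(net$edges$weight) <= 1))

  # single-sex input reduces to the plain Spearman matrix
  net_f <- sex_weighted_spearman(data[1:n_f, ], rep("female", n_f))
  expect_equal(net_f$edges$weight, rho_f, tolerance = 1e-12)

  # a monotone copy correlates perfectly in both sexes
  net_m <- sex_weighted_spearman(cbind(a = x, mono = exp(x)), sex)
  expect_equal(net_m$edges$weight, 1)
})

test_that("constant variables get zero edges with a warning", {
  data <- cbind(a = rnorm(20), flat = rep(1, 20))
  expect_warning(net <- sex_weighted_spearman(data, rep("female", 20)),
                 "constant within sex")
  expect_equal(net$edges$weight, 0)
})

test_that("pruning keeps the maximum spanning tree", {
  tri <- new_net(c("a", "b", "c"),
                 data.frame(u = c("a", "a", "b"), v = c("b", "c", "c"),
                            weight = c(0.9, -0.8, 0.1)))
  pruned <- prune_spanning_tree(tri)
  expect_true(pruned$pruned)
  kept <- paste(pruned$edges$u, pruned$edges$v)
  expect_setequal(kept, c("a b", "a c"))  # |0.9| and |-0.8| survive

  # an input that is already a tree passes through unchanged
  tree <- prune_spanning_tree(pruned)
  expect_equal(tree$edges[order(tree$edges$u), ],
               pruned$edges[order(pruned$edges$u), ])

  # empty graph
  empty <- prune_spanning_tree(new_net(character(0),
                                       data.frame(u = character(0), v = character(0),
                                                  weight = numeric(0))))
  expect_equal(nrow(empty$edges), 0)
})

test_that("pruned weight equals the enumeration oracle on random graphs", {
  set.seed(77)
  for (rep_ in 1:50) {
    n <- sample(4:8, 1)
    g <- random_connected_graph(n)
    nodes <- sort(unique(c(g$u, g$v)))
    pruned <- prune_spanning_tree(new_net(nodes, g))
    expect_equal(nrow(pruned$edges), length(nodes) - 1)
    expect_equal(sum(abs(pruned$edges$weight)),
                 enum_mst_weight(nodes, g), tolerance = 1e-9)
    # sign-flip invariance of the retained edge set
    flipped <- g; flipped$weight <- -flipped$weight
    pruned2 <- prune_spanning_tree(new_net(nodes, flipped))
    expect_equal(paste(pruned$edges$u, pruned$edges$v),
                 paste(pruned2$edges$u, pruned2$edges$v))
  }
})

test_that("retained edge count is nodes minus components", {
  # two disconnected triangles
  e <- data.frame(u = c("a", "a", "b", "x", "x", "y"),
                  v = c("b", "c", "c", "y", "z", "z"),
                  weight = c(0.5, 0.4, 0.3, 0.9, 0.8, 0.7))
  pruned <- prune_spanning_tree(new_net(c("a", "b", "c", "x", "y", "z"), e))
  expect_equal(nrow(pruned$edges), 6 - 2)
})

test_that("module detection splits at the weak bridge and maximizes modularity", {
  nodes <- c("a1", "a2", "a3", "b1", "b2", "b3")
  e <- data.frame(
    u = c("a1", "a1", "b1", "b1", "a1"),
    v = c("a2", "a3", "b2", "b3", "b1"),
    weight = c(0.8, 0.7, 0.8, 0.7, 0.05))
  net <- new_net(nodes, e, pruned = TRUE)
  mods <- detect_modules(net)
  expect_equal(unname(mods$assignment[c("a1", "a2", "a3")]), rep(1L, 3))
  expect_equal(unname(mods$assignment[c("b1", "b2", "b3")]), rep(2L, 3))
  # equals the globally best partition by exhaustive search over all 203
  q_best <- max(vapply(all_partitions(6), function(p)
    partition_modularity(setNames(p, nodes), e, nodes), 0))
  expect_equal(partition_modularity(mods$assignment, e, nodes), q_best,
               tolerance = 1e-12)
})

test_that("module detection handles degenerate graphs deterministically", {
  lone <- new_net("a", data.frame(u = character(0), v = character(0),
                                  weight = numeric(0)), pruned = TRUE)
  expect_equal(unname(detect_modules(lone)$assignment), 1L)

  iso <- new_net(c("a", "b", "c"),
                 data.frame(u = character(0), v = character(0), weight = numeric(0)),
                 pruned = TRUE)
  expect_equal(unname(detect_modules(iso)$assignment), 1:3)

  # chain of identical weights: returned modularity equals the best over
  # all contiguous partitions (the full agglomerative reachable set)
  n <- 7
  nodes <- paste0("v", 1:n)
  chain <- data.frame(u = nodes[-n], v = nodes[-1], weight = rep(0.5, n - 1))
  mods <- detect_modules(new_net(nodes, chain, pruned = TRUE))
  contiguous_best <- max(vapply(all_partitions(n), function(p) {
    # contiguous partitions only (all that agglomeration on a chain can reach)
    blocks <- rle(p)$values
    if (anyDuplicated(blocks)) return(-Inf)
    partition_modularity(setNames(p, nodes), chain, nodes)
  }, 0))
  expect_equal(partition_modularity(mods$assignment, chain, nodes),
               contiguous_best, tolerance = 1e-12)
  expect_identical(detect_modules(new_net(nodes, chain, pruned = TRUE))$assignment,
                   mods$assignment)
})

test_that("module PC scores match the closed-form eigensolver oracle", {
  set.seed(55)
  n <- 40
  base <- rnorm(n)
  data <- cbind(p = base + 0.4 * rnorm(n),
                q = base + 0.4 * rnorm(n),
                r = -base + 0.6 * rnorm(n))
  rownames(data) <- sprintf("P%02d", 1:n)
  mods <- new_module_set(setNames(c(1L, 1L, 1L), c("p", "q", "r")))
  scored <- module_scores(data, mods)
  R <- cor(data)
  ev_oracle <- eigen3_closed_form(R)
  expect_equal(unlist(scored$explained_variance[["1"]])[1], ev_oracle[1] / 3,
               tolerance = 1e-6)
  # PC1 variance equals the top eigenvalue of the correlation matrix
  expect_equal(var(scored$scores[, "M1.PC1"]), ev_oracle[1], tolerance = 1e-6)
  expect_lt(abs(mean(scored$scores[, "M1.PC1"])), 1e-8)
  expect_lt(abs(mean(scored$scores[, "M1.PC2"])), 1e-8)
  # sign convention: positive loading on the alphabetically first variable
  expect_gte(cor(scored$scores[, "M1.PC1"], data[, "p"]), 0)
})

test_that("single-variable and degenerate modules are handled", {
  set.seed(56)
  data <- cbind(a = rnorm(30), b = rnorm(30), flat = rep(2, 30))
  rownames(data) <- sprintf("P%02d", 1:30)
  mods <- new_module_set(setNames(c(1L, 2L, 2L), c("a", "b", "flat")))
  expect_warning(scored <- module_scores(data, mods), "zero-variance")
  expect_equal(scored$scores[, "M1.PC1"], scale(data[, "a"])[, 1],
               ignore_attr = TRUE)
  expect_true(all(scored$scores[, "M1.PC2"] == 0))

  # two perfectly correlated variables: PC1 explains everything
  dd <- cbind(x = 1:20 + 0.0, y = 2 * (1:20) + 3)
  rownames(dd) <- sprintf("P%02d", 1:20)
  m2 <- module_scores(dd, new_module_set(setNames(c(1L, 1L), c("x", "y"))))
  expect_equal(unlist(m2$explained_variance[["1"]])[1], 1, tolerance = 1e-12)
})

test_that("the pipeline recovers two independent correlated blocks", {
  set.seed(60)
  hits <- vapply(1:20, function(s) {
    set.seed(s + 300)
    n <- 200
    f1 <- rnorm(n); f2 <- rnorm(n)
    block <- function(f) sapply(1:4, function(i) sqrt(0.8) * f + sqrt(0.2) * rnorm(n))
    data <- cbind(block(f1), block(f2))
    colnames(data) <- c(paste0("a", 1:4), paste0("b", 1:4))
    sex <- rep(c("female", "male"), n / 2)
    mods <- detect_modules(prune_spanning_tree(sex_weighted_spearman(data, sex)))
    a_mods <- unique(mods$assignment[paste0("a", 1:4)])
    b_mods <- unique(mods$assignment[paste0("b", 1:4)])
    length(a_mods) == 1 && length(b_mods) == 1 && a_mods != b_mods
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("projection reproduces in-sample scores", {
  set.seed(61)
  data <- matrix(rnorm(80), 20, 4,
                 dimnames = list(sprintf("P%02d", 1:20), c("a", "b", "c", "d")))
  mods <- module_scores(data, new_module_set(setNames(c(1L, 1L, 2L, 2L),
                                                      c("a", "b", "c", "d"))))
  proj <- project_module_scores(mods, data)
  expect_equal(proj, mods$scores, tolerance = 1e-10)
})
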