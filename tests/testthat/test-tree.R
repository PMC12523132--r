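grid_fixture <- function(n = 200, seed = 1) {
  set.seed(seed)
  X <- data.frame(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2),
                  x6 = rbinom(n, 1, 0.5))
  X
}

test_that("cutpoint grids: deciles for continuous, 0.5 for binary, frozen", {
  X <- grid_fixture()
  g <- build_cutpoint_grid(X)
  expect_length(g$x1, 9L)
  expect_equal(g$x6, 0.5)
  expect_equal(g$x1, unname(quantile(X$x1, probs = 1:9 / 10)))
  X$const <- 1
  expect_warning(g2 <- build_cutpoint_grid(X), "constant")
  expect_false("const" %in% names(g2))
})

test_that("tree prior: structural term, depth penalty, selection terms", {
  g <- build_cutpoint_grid(grid_fixture())
  pr <- tree_prior(g)
  t0 <- root_tree()
  expect_equal(log_tree_prior(t0, pr), log(1 - 0.95))

  ## one split: log p_split(0) + 2 log(1 - p_split(1)) - var/cut selection
  t1 <- slopehte:::grow_leaf(t0, 1L, 1L, g$x1[5])
  ps1 <- 0.95 * 2^(-2)
  expect_equal(log_tree_prior(t1, pr),
               log(0.95) + 2 * log(1 - ps1) - log(3) - log(9))

  ## the split probability decays with depth (deeper splits are penalized)
  expect_gt(slopehte:::p_split(0, pr), slopehte:::p_split(1, pr))
  expect_gt(slopehte:::p_split(1, pr), slopehte:::p_split(3, pr))

  ## with d0 = 0 the split probability is depth-independent
  pr0 <- tree_prior(g, d0 = 0)
  t1b <- slopehte:::grow_leaf(t0, 1L, 2L, g$x2[5])
  expect_equal(log_tree_prior(t1, pr0), log_tree_prior(t1b, pr0))
})

test_that("leaf routing is deterministic with ties going left", {
  ## split at (transformed) baseline eGFR 34.32: 44.23 routes right,
  ## 23.97 routes left
  t0 <- root_tree()
  tr <- slopehte:::grow_leaf(t0, 1L, 1L, 34.32)
  attr(tr, "var_names") <- "eGFR"
  expect_equal(leaf_assign(tr, data.frame(eGFR = 44.23)), 2L)
  expect_equal(leaf_assign(tr, data.frame(eGFR = 23.97)), 1L)
  expect_equal(leaf_assign(tr, data.frame(eGFR = 34.32)), 1L)  # tie -> left
  expect_equal(leaf_assign(t0, data.frame(eGFR = 1)), 1L)
  expect_error(leaf_assign(tr, data.frame(AGE = 50)), "missing split variable")

  ## routing partitions any sample
  X <- grid_fixture()
  g <- build_cutpoint_grid(X)
  t2 <- slopehte:::grow_leaf(root_tree(), 1L, 1L, g$x1[3])
  t2 <- slopehte:::grow_leaf(t2, 2L, 3L, 0.5)
  attr(t2, "var_names") <- names(g)
  a <- leaf_assign(t2, X)
  expect_equal(sum(table(a)), nrow(X))
  expect_equal(sort(unique(a)), 1:3)
})

test_that("surfaces: piecewise-constant effect and within-leaf linear forms", {
  ## toy example: treatment slope -3 / -1 and control slope -4 / -1.5 split
  ## at baseline GFR 75 give effect 1 below and 0.5 above
  tr <- slopehte:::grow_leaf(root_tree(), 1L, 1L, 75)
  attr(tr, "var_names") <- "GFR"
  trt_slope <- c(-3, -1); ctl_slope <- c(-4, -1.5)
  theta <- trt_slope - ctl_slope
  X <- data.frame(GFR = c(60, 74, 80, 100))
  expect_equal(predict_surface(tr, theta, X, kind = "tau0"),
               c(1, 1, 0.5, 0.5))
  ## a root tree's effect is constant
  expect_equal(predict_surface(root_tree(), 0.1, X, kind = "tau0"),
               rep(0.1, 4))
  ## tau0 takes at most J distinct values on any input
  expect_lte(length(unique(predict_surface(tr, theta, X, "tau0"))),
             num_leaves(tr))

  ## within-leaf linear: equal coefficients reduce to one global form
  mu <- cbind(c(40, -2), c(40, -2))
  Xl <- cbind(1, X$GFR)
  expect_equal(predict_surface(tr, mu, X, kind = "alpha0", Xlin = Xl),
               drop(Xl %*% c(40, -2)))
  expect_error(predict_surface(tr, mu[, 1, drop = FALSE], X, "alpha0", Xl))
})

test_that("birth/death proposals respect constraints and invert each other", {
  X <- grid_fixture(n = 120, seed = 3)
  trt <- rbinom(nrow(X), 1, 0.5)
  g <- build_cutpoint_grid(X)
  pr <- tree_prior(g)
  t0 <- root_tree(); attr(t0, "var_names") <- names(g)
  set.seed(4)
  b <- birth_proposal(t0, pr, X, min_leaf = 10, trt = trt)
  expect_true(b$ok)
  expect_equal(num_leaves(b$tree), 2L)
  a <- leaf_assign(b$tree, X)
  expect_true(all(table(a) >= 10))
  ## both arms in each child
  expect_true(all(tapply(trt, a, function(z) length(unique(z))) == 2))

  d <- death_proposal(b$tree, pr, X, min_leaf = 10, trt = trt)
  expect_true(d$ok)
  expect_equal(num_leaves(d$tree), 1L)
  expect_equal(tree_string(d$tree), tree_string(t0))

  ## death is unavailable at the root; birth fails with an impossible min_leaf
  expect_false(death_proposal(t0, pr, X, 10)$ok)
  expect_false(birth_proposal(t0, pr, X, min_leaf = 100, trt = trt)$ok)
})

test_that("prior-only chain matches the enumerated prior (detailed balance)", {
  ## 4 subjects on a 2x2 grid of two binary variables with min_leaf 2:
  ## the only reachable trees are the root and the two single-split trees,
  ## with prior weights 1-c0 and c0/2 * (1-p1)^2 each
  X <- data.frame(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  g <- build_cutpoint_grid(X)
  pr <- tree_prior(g, require_both_arms = FALSE)
  c0 <- 0.95; d0 <- 2
  p1 <- c0 * 2^(-d0)
  wts <- c(root = 1 - c0,
           split = c0 * 0.5 * (1 - p1)^2,   # per variable
           split2 = c0 * 0.5 * (1 - p1)^2)

  tr <- root_tree(); attr(tr, "var_names") <- names(g)
  set.seed(5)
  counts <- c(0, 0, 0)
  for (it in 1:6000) {
    J <- num_leaves(tr)
    move <- if (J == 1L) "birth" else if (runif(1) < 0.5) "birth" else "death"
    prop <- if (move == "birth") birth_proposal(tr, pr, X, 2) else death_proposal(tr, pr, X, 2)
    if (prop$ok) {
      lr <- log_tree_prior(prop$tree, pr) - log_tree_prior(tr, pr) + prop$log_ratio
      if (log(runif(1)) < lr) tr <- prop$tree
    }
    key <- if (num_leaves(tr) == 1L) 1L else if (tr$var[1] == 1L) 2L else 3L
    counts[key] <- counts[key] + 1L
  }
  ## compare long-run frequencies to the enumerated prior (thinned for a
  ## rough independence approximation)
  freq <- counts / sum(counts)
  expect_equal(freq, unname(wts / sum(wts)), tolerance = 0.08)
})

test_that("serialization is canonical and round-trips through JSON", {
  g <- build_cutpoint_grid(grid_fixture())
  t1 <- slopehte:::grow_leaf(root_tree(), 1L, 1L, g$x1[5])
  t1 <- slopehte:::grow_leaf(t1, 3L, 3L, 0.5)
  attr(t1, "var_names") <- names(g)
  s <- tree_string(t1)
  expect_match(s, "^\\(x1<=")
  j <- tree_to_json(t1)
  t2 <- tree_from_json(j, split_vars = names(g))
  expect_equal(tree_string(t2), s)
  expect_equal(num_leaves(t2), 3L)
})
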