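fake_draw <- function(tree, theta2, surface) {
  list(trees = list(root_tree(), root_tree(), tree),
       coefs = list(theta2 = theta2), tau_surface = surface)
}

test_that("most representative tree minimizes distance to the mean surface", {
  t_root <- root_tree()
  tA <- slopehte:::grow_leaf(root_tree(), 1L, 1L, 0)
  ## three draws with known surfaces over 4 subjects
  s1 <- c(1, 1, 0, 0); s2 <- c(0.9, 0.9, 0.1, 0.1); s3 <- c(0, 0, 0, 0)
  draws <- list(fake_draw(tA, c(1, 0), s1),
                fake_draw(tA, c(0.9, 0.1), s2),
                fake_draw(t_root, 0, s3))
  ## brute-force oracle scan
  tau_bar <- colMeans(rbind(s1, s2, s3))
  dists <- sapply(list(s1, s2, s3), function(s) sum((s - tau_bar)^2))
  rep <- most_representative_tree(draws)
  expect_equal(rep$index, which.min(dists))
  expect_equal(rep$distance, min(dists))

  ## single draw returns itself with distance zero
  one <- most_representative_tree(draws[1])
  expect_equal(one$index, 1L)
  expect_equal(one$distance, 0)

  ## identical draws: distance zero, first index under canonical tie-break
  same <- most_representative_tree(list(draws[[1]], draws[[1]]))
  expect_equal(same$distance, 0)
})

test_that("super-representative tree is the modal tree with documented ties", {
  tA <- slopehte:::grow_leaf(root_tree(), 1L, 1L, 0.3)
  tB <- slopehte:::grow_leaf(root_tree(), 1L, 1L, -0.7)
  tC <- root_tree()
  ## frequencies 48 / 43 / 9 out of 100
  reps <- c(replicate(48, tA, simplify = FALSE),
            replicate(43, tB, simplify = FALSE),
            replicate(9, tC, simplify = FALSE))
  sup <- super_representative_tree(reps)
  expect_equal(sup$frequency, 0.48)
  expect_equal(tree_string(sup$tree), tree_string(tA))
  expect_length(sup$matches, 48L)

  ## all equal -> frequency 1
  expect_equal(super_representative_tree(replicate(5, tA, simplify = FALSE))$frequency, 1)

  ## two-way tie -> the smaller tree wins
  tBig <- slopehte:::grow_leaf(tA, 2L, 1L, 0.9)
  sup2 <- super_representative_tree(list(tBig, tC, tBig, tC))
  expect_equal(num_leaves(sup2$tree), 1L)
})

test_that("intersection partition refines the three trees", {
  X <- data.frame(AGE = c(30, 30, 70, 70), eGFR = c(20, 50, 20, 50))
  tAGE <- slopehte:::grow_leaf(root_tree(), 1L, 1L, 50)
  attr(tAGE, "var_names") <- c("AGE", "eGFR")
  tEGFR <- slopehte:::grow_leaf(root_tree(), 1L, 2L, 34.32)
  attr(tEGFR, "var_names") <- c("AGE", "eGFR")
  t0 <- root_tree()

  ## all root-only: a single cell
  all_root <- intersection_tree(t0, t0, t0, X)
  expect_equal(length(unique(all_root$cell)), 1L)

  ## only the effect tree splits: cells equal its leaves
  one <- intersection_tree(t0, t0, tEGFR, X)
  expect_equal(one$cell, leaf_assign(tEGFR, X))

  ## AGE x eGFR: four occupied cells, each wholly inside one leaf per tree
  two <- intersection_tree(tAGE, t0, tEGFR, X)
  expect_equal(length(unique(two$cell)), 4L)
  for (cell in unique(two$cell)) {
    sel <- two$cell == cell
    expect_length(unique(leaf_assign(tAGE, X[sel, , drop = FALSE])), 1L)
    expect_length(unique(leaf_assign(tEGFR, X[sel, , drop = FALSE])), 1L)
  }
})

test_that("ordering probability behaves at its reference points", {
  expect_equal(ordering_probability(c(2, 3, 4), c(0, 1, 1.5)), 1)
  expect_equal(ordering_probability(1:100, 1:100), 0)  # strict inequality
  set.seed(1)
  a <- rnorm(4000); b <- rnorm(4000)
  expect_equal(ordering_probability(a, b), 0.5, tolerance = 0.03)
  ## unit mean gap, unit variances: P(A > B) = Phi(1/sqrt(2))
  a2 <- rnorm(4000, 1); b2 <- rnorm(4000, 0)
  expect_equal(ordering_probability(a2, b2), pnorm(1 / sqrt(2)),
               tolerance = 0.03)
  expect_error(ordering_probability(numeric(0), 1), "no posterior draws")
})

test_that("concordance tertiles are coherent", {
  ## validation estimates equal to discovery: nondecreasing tertile means
  set.seed(2)
  disc <- rnorm(60)
  out <- concordance_summary(list(list(disc_cate = disc, valid_cate = disc)))
  expect_true(all(diff(out[1, ]) >= 0))
  ## constant estimates: all tertile means equal
  out2 <- concordance_summary(list(list(disc_cate = rep(1, 30),
                                        valid_cate = rep(0.4, 30))))
  expect_equal(unname(out2[1, ]), rep(0.4, 3))
})

test_that("honest refit yields calibrated per-leaf effects on planted data", {
  ## strong two-group truth; trees frozen at the true split
  sc <- scenario("setting1", n = 500)
  d <- gen_trial(sc, seed = 14)
  cfg <- sampler_config(B1 = 30, B2 = 20, seed = 8)
  grids <- build_cutpoint_grid(d$covariates[, d$spec$split_vars])
  ## build the generating split at the grid cut nearest 0
  cut0 <- grids$x1[which.min(abs(grids$x1))]
  tr <- slopehte:::grow_leaf(root_tree(), 1L, 1L, cut0)
  attr(tr, "var_names") <- names(grids)
  draw <- list(trees = list(root_tree(), root_tree(), tr),
               coefs = NULL, sigma2 = 9, Sigma = diag(c(0.44, 0.25, 0.25)),
               psi = NULL)
  for (k in 1:2) attr(draw$trees[[k]], "var_names") <- names(grids)
  sp <- split_dataset(d, 0.6, seed = 3)
  rf <- honest_refit(sp$validation, draw, cfg, grids, scaling = NULL,
                     n_warm = 300, n_draws = 500)
  expect_true(all(rf$estimable))
  est <- colMeans(rf$theta_draws)
  truth <- c(-1, 1)
  ci <- apply(rf$theta_draws, 2, quantile, probs = c(0.025, 0.975))
  expect_true(all(truth >= ci[1, ] & truth <= ci[2, ]))
  expect_equal(est, truth, tolerance = 0.5)
  ## leaf bookkeeping covers the validation set
  expect_equal(sum(rf$leaf_n), sp$validation$n)
  expect_true(all(rf$leaf_p >= 0 & rf$leaf_p <= 1))
})

test_that("honest refit handles parameter-less frozen-tree initialization", {
  d <- tiny_trial(n = 60, "setting13", seed = 15)
  cfg <- sampler_config(B1 = 10, B2 = 5, seed = 9, min_leaf = 5)
  grids <- build_cutpoint_grid(d$covariates[, d$spec$split_vars])
  draw <- list(trees = replicate(3, {
    tr <- root_tree(); attr(tr, "var_names") <- names(grids); tr
  }, simplify = FALSE), coefs = NULL, sigma2 = 9,
  Sigma = diag(c(0.4, 0.2, 0.2)), psi = NULL)
  rf <- honest_refit(d, draw, cfg, grids, scaling = NULL,
                     n_warm = 50, n_draws = 50)
  expect_equal(ncol(rf$theta_draws), 1L)
  expect_true(is.finite(mean(rf$theta_draws)))
})
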