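## Decision trees are stored flat: parallel vectors indexed by node id, with
## node 1 the root. Internal nodes carry (var, cut); leaves have var = NA.
## Routing sends x left iff x[var] <= cut (ties go left). Leaf indices
## j = 1..J follow preorder traversal, which also defines the canonical
## serialization used for tree equality and frequency counting.

#' A root-only decision tree
#'
#' @return A `bdt_tree` with a single leaf.
#' @export
root_tree <- function() {
  structure(
    list(var = NA_integer_, cut = NA_real_,
         left = NA_integer_, right = NA_integer_,
         parent = NA_integer_, depth = 0L),
    class = "bdt_tree"
  )
}

is_leaf <- function(tree) is.na(tree$var)

#' Number of leaves of a decision tree
#' @param tree A `bdt_tree`.
#' @return Integer leaf count `J`.
#' @export
num_leaves <- function(tree) sum(is_leaf(tree))

## Node ids in preorder (root, left subtree, right subtree).
preorder <- function(tree) {
  out <- integer(0)
  stack <- 1L
  while (length(stack)) {
    nd <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, nd)
    if (!is.na(tree$var[nd])) {
      stack <- c(tree$left[nd], tree$right[nd], stack)
    }
  }
  out
}

## Leaf node ids in preorder; position in this vector is the leaf index j.
leaf_nodes <- function(tree) {
  po <- preorder(tree)
  po[is.na(tree$var[po])]
}

## Internal nodes whose children are both leaves (candidates for a death move).
prunable_nodes <- function(tree) {
  internal <- which(!is.na(tree$var))
  internal[vapply(internal, function(nd) {
    is.na(tree$var[tree$left[nd]]) && is.na(tree$var[tree$right[nd]])
  }, logical(1))]
}

#' Prior and proposal settings for Bayesian decision trees
#'
#' The depth prior splits a node at depth `d` with probability
#' `c0 * (1 + d)^(-d0)`; split variables are uniform over the eligible set and
#' cutpoints uniform over the variable's frozen grid, so the tree space is
#' finite and tree frequencies are well defined.
#'
#' @param cutpoint_grid Named list of ordered candidate cutpoints per split
#'   variable (see [build_cutpoint_grid()]).
#' @param c0 Base parameter in (0,1), default 0.95.
#' @param d0 Power parameter >= 0, default 2.
#' @param min_leaf Minimum subjects per leaf in the discovery data; default
#'   `NULL` means `max(25, ceiling(0.02 * n))` is chosen at fit time.
#' @param require_both_arms Require every leaf to contain both treatment
#'   arms so within-leaf effects stay estimable. Default `TRUE`.
#' @return An object of class `tree_prior`.
#' @export
tree_prior <- function(cutpoint_grid, c0 = 0.95, d0 = 2,
                       min_leaf = NULL, require_both_arms = TRUE) {
  stopifnot(is.list(cutpoint_grid), length(cutpoint_grid) >= 1L,
            !is.null(names(cutpoint_grid)),
            c0 > 0, c0 < 1, d0 >= 0)
  if (any(vapply(cutpoint_grid, length, 1L) == 0L)) {
    stop("every split-eligible variable needs a nonempty cutpoint grid")
  }
  structure(
    list(cutpoint_grid = cutpoint_grid, c0 = c0, d0 = d0,
         min_leaf = min_leaf, require_both_arms = require_both_arms),
    class = "tree_prior"
  )
}

p_split <- function(depth, prior) prior$c0 * (1 + depth)^(-prior$d0)

#' Frozen cutpoint grids for tree splits
#'
#' Continuous variables get interior quantiles of the discovery-set
#' distribution (deciles by default); binary variables get the single
#' cutpoint 0.5. Grids are computed once per run and frozen, making the tree
#' space finite. Constant columns are excluded with a warning.
#'
#' @param X Covariate matrix or data.frame (columns named).
#' @param variables Columns eligible for splitting (default all).
#' @param n_cuts Number of quantile bins for continuous variables (default 10,
#'   i.e. 9 interior cutpoints).
#' @return Named list of numeric cutpoint vectors.
#' @export
build_cutpoint_grid <- function(X, variables = colnames(X), n_cuts = 10) {
  X <- as.data.frame(X)
  grids <- list()
  for (v in variables) {
    vals <- X[[v]]
    u <- unique(vals[is.finite(vals)])
    if (length(u) <= 1L) {
      warning(sprintf("split variable '%s' is constant; excluded", v))
      next
    }
    if (length(u) == 2L) {
      grids[[v]] <- mean(sort(u))
    } else {
      q <- unique(stats::quantile(vals, probs = seq_len(n_cuts - 1L) / n_cuts,
                                  names = FALSE, type = 7))
      grids[[v]] <- q
    }
  }
  if (!length(grids)) stop("no usable split variables")
  grids
}

#' Log prior probability of a tree
#'
#' Structural term (split/stop probabilities by depth) plus, for each internal
#' node, the uniform log-probability of its split variable and cutpoint.
#'
#' @param tree A `bdt_tree`.
#' @param prior A [tree_prior()].
#' @return Scalar log prior.
#' @export
log_tree_prior <- function(tree, prior) {
  m <- length(prior$cutpoint_grid)
  lp <- 0
  for (nd in seq_along(tree$var)) {
    ps <- p_split(tree$depth[nd], prior)
    if (is.na(tree$var[nd])) {
      lp <- lp + log(1 - ps)
    } else {
      g <- length(prior$cutpoint_grid[[tree$var[nd]]])
      lp <- lp + log(ps) - log(m) - log(g)
    }
  }
  lp
}

#' Route covariate vectors to leaf indices
#'
#' @param tree A `bdt_tree`.
#' @param X Matrix or data.frame of covariates containing every split
#'   variable as a named column. A single vector is accepted for one subject.
#' @return Integer vector of leaf indices in `1..num_leaves(tree)`.
#' @export
leaf_assign <- function(tree, X) {
  if (is.null(dim(X))) X <- t(as.matrix(X))
  X <- as.data.frame(X)
  node <- rep(1L, nrow(X))
  repeat {
    v <- tree$var[node]
    active <- !is.na(v)
    if (!any(active)) break
    for (nd in unique(node[active])) {
      sel <- active & node == nd
      var_name <- attr(tree, "var_names")[tree$var[nd]]
      if (is.null(var_name) || is.na(var_name)) var_name <- tree$var[nd]
      xv <- X[[var_name]]
      if (is.null(xv)) stop(sprintf("missing split variable '%s'", var_name))
      goes_left <- xv[sel] <= tree$cut[nd]
      node[sel] <- ifelse(goes_left, tree$left[nd], tree$right[nd])
    }
  }
  ln <- leaf_nodes(tree)
  match(node, ln)
}

#' Evaluate a tree-structured surface
#'
#' The total-effect surface `tau0` is piecewise constant: the leaf scalar
#' `theta_j`. The baseline (`alpha0`) and chronic-slope (`gamma0`) surfaces
#' are within-leaf linear: `x' mu_j` with one coefficient vector per leaf.
#'
#' @param tree A `bdt_tree`.
#' @param leaf_params For `kind = "tau0"` a numeric vector of length `J`;
#'   otherwise a `p x J` matrix of within-leaf coefficients.
#' @param X Covariates (rows = subjects). For the linear kinds, `Xlin` must
#'   supply the design (with intercept); defaults to `X`.
#' @param kind One of `"alpha0"`, `"gamma0"`, `"tau0"`.
#' @param Xlin Optional design matrix for the within-leaf regressions.
#' @return Numeric vector of surface values.
#' @export
predict_surface <- function(tree, leaf_params, X, kind = c("tau0", "alpha0", "gamma0"),
                            Xlin = NULL) {
  kind <- match.arg(kind)
  j <- leaf_assign(tree, X)
  if (kind == "tau0") {
    theta <- as.numeric(leaf_params)
    if (length(theta) != num_leaves(tree)) stop("leaf parameter length != J")
    return(theta[j])
  }
  if (is.null(Xlin)) Xlin <- cbind(1, as.matrix(X))
  if (!is.matrix(leaf_params) || ncol(leaf_params) != num_leaves(tree) ||
      nrow(leaf_params) != ncol(Xlin)) {
    stop("leaf coefficient matrix must be p x J matching the design")
  }
  rowSums(Xlin * t(leaf_params)[j, , drop = FALSE])
}

## Eligible (variable index, cutpoint index) pairs for splitting a leaf whose
## member rows (indices into X) are given. Enforces min_leaf per child and,
## optionally, both arms in each child.
eligible_pairs <- function(members, X, prior, min_leaf, trt = NULL) {
  vars <- names(prior$cutpoint_grid)
  out <- NULL
  for (vi in seq_along(vars)) {
    xv <- X[[vars[vi]]][members]
    grid <- prior$cutpoint_grid[[vi]]
    for (ci in seq_along(grid)) {
      left <- xv <= grid[ci]
      nl <- sum(left); nr <- length(xv) - nl
      if (nl < min_leaf || nr < min_leaf) next
      if (!is.null(trt) && prior$require_both_arms) {
        tl <- trt[members][left]; tr <- trt[members][!left]
        if (length(unique(tl)) < 2L || length(unique(tr)) < 2L) next
      }
      out <- rbind(out, c(vi, ci))
    }
  }
  out
}

#' Birth proposal for the tree sampler
#'
#' Picks a leaf uniformly, then an eligible (variable, cutpoint) pair
#' uniformly, and splits the leaf. Returns the proposed tree together with the
#' Hastings log-ratio `log q(T | T') - log q(T' | T)` that accounts for the
#' reverse death move. If the chosen leaf admits no eligible split the move is
#' unavailable (`ok = FALSE`) and counts as a rejected (null) iteration.
#'
#' @param tree A `bdt_tree`.
#' @param prior A [tree_prior()].
#' @param X Discovery-set covariates (data.frame with split variables).
#' @param min_leaf Minimum subjects per child leaf.
#' @param trt Optional treatment vector for the both-arms constraint.
#' @return List with `tree`, `log_ratio`, `ok`.
#' @export
birth_proposal <- function(tree, prior, X, min_leaf, trt = NULL) {
  X <- as.data.frame(X)
  ln <- leaf_nodes(tree)
  J <- length(ln)
  assign <- leaf_assign(tree, X)
  leaf_pick <- if (J == 1L) 1L else sample.int(J, 1L)
  members <- which(assign == leaf_pick)
  pairs <- eligible_pairs(members, X, prior, min_leaf, trt)
  if (is.null(pairs)) {
    return(list(tree = tree, log_ratio = -Inf, ok = FALSE))
  }
  pick <- pairs[sample.int(nrow(pairs), 1L), ]
  newt <- grow_leaf(tree, ln[leaf_pick], pick[1L], prior$cutpoint_grid[[pick[1L]]][pick[2L]])
  attr(newt, "var_names") <- names(prior$cutpoint_grid)

  p_birth_T <- if (J == 1L) 1 else 0.5
  ## forward: choose birth, leaf, pair; reverse: choose death, prunable node
  log_fwd <- log(p_birth_T) - log(J) - log(nrow(pairs))
  log_rev <- log(0.5) - log(length(prunable_nodes(newt)))
  list(tree = newt, log_ratio = log_rev - log_fwd, ok = TRUE)
}

#' Death proposal for the tree sampler
#'
#' Collapses a uniformly chosen internal node whose children are both leaves;
#' the Hastings ratio is the reciprocal of the matching birth.
#'
#' @inheritParams birth_proposal
#' @return List with `tree`, `log_ratio`, `ok` (`FALSE` for a root-only tree).
#' @export
death_proposal <- function(tree, prior, X, min_leaf, trt = NULL) {
  X <- as.data.frame(X)
  pn <- prunable_nodes(tree)
  if (!length(pn)) return(list(tree = tree, log_ratio = -Inf, ok = FALSE))
  pick <- if (length(pn) == 1L) pn else pn[sample.int(length(pn), 1L)]
  newt <- prune_node(tree, pick)
  attr(newt, "var_names") <- names(prior$cutpoint_grid)

  ## reverse birth from the pruned tree
  ln_new <- leaf_nodes(newt)
  J_new <- length(ln_new)
  assign_new <- leaf_assign(newt, X)
  collapsed_leaf <- which(ln_new == attr(newt, "collapsed_node"))
  members <- which(assign_new == collapsed_leaf)
  pairs <- eligible_pairs(members, X, prior, min_leaf, trt)
  n_pairs <- if (is.null(pairs)) 1L else nrow(pairs)  # contains the old split
  p_birth_new <- if (J_new == 1L) 1 else 0.5
  log_fwd <- log(0.5) - log(length(pn))
  log_rev <- log(p_birth_new) - log(J_new) - log(n_pairs)
  list(tree = newt, log_ratio = log_rev - log_fwd, ok = TRUE)
}

## Split leaf node `nd` on (variable index, cut value); appends two leaves.
grow_leaf <- function(tree, nd, vi, cutval) {
  k <- length(tree$var)
  tree$var[nd] <- vi
  tree$cut[nd] <- cutval
  tree$left[nd] <- k + 1L
  tree$right[nd] <- k + 2L
  d <- tree$depth[nd] + 1L
  tree$var <- c(tree$var, NA_integer_, NA_integer_)
  tree$cut <- c(tree$cut, NA_real_, NA_real_)
  tree$left <- c(tree$left, NA_integer_, NA_integer_)
  tree$right <- c(tree$right, NA_integer_, NA_integer_)
  tree$parent <- c(tree$parent, nd, nd)
  tree$depth <- c(tree$depth, d, d)
  tree
}

## Collapse internal node `nd` (children must be leaves) back into a leaf and
## renumber nodes compactly.
prune_node <- function(tree, nd) {
  drop <- c(tree$left[nd], tree$right[nd])
  tree$var[nd] <- NA_integer_
  tree$cut[nd] <- NA_real_
  tree$left[nd] <- NA_integer_
  tree$right[nd] <- NA_integer_
  keep <- setdiff(seq_along(tree$var), drop)
  remap <- match(seq_along(tree$var), keep)
  out <- structure(
    list(var = tree$var[keep], cut = tree$cut[keep],
         left = remap[tree$left[keep]], right = remap[tree$right[keep]],
         parent = remap[tree$parent[keep]], depth = tree$depth[keep]),
    class = "bdt_tree"
  )
  attr(out, "collapsed_node") <- remap[nd]
  out
}

#' Canonical serialization of a tree
#'
#' Deterministic preorder string, e.g. `"(x1<=0.5 * *)"`; equal strings define
#' tree equality for representative-tree frequency counting (the cutpoint
#' grids are frozen, so the space of strings is finite).
#'
#' @param tree A `bdt_tree`.
#' @param var_names Optional names of the split variables.
#' @return Character scalar.
#' @export
tree_string <- function(tree, var_names = attr(tree, "var_names")) {
  rec <- function(nd) {
    if (is.na(tree$var[nd])) return("*")
    v <- if (!is.null(var_names)) var_names[tree$var[nd]] else paste0("v", tree$var[nd])
    sprintf("(%s<=%.10g %s %s)", v, tree$cut[nd],
            rec(tree$left[nd]), rec(tree$right[nd]))
  }
  rec(1L)
}

#' @export
print.bdt_tree <- function(x, ...) {
  cat("<bdt_tree> J =", num_leaves(x), "leaves:", tree_string(x), "\n")
  invisible(x)
}

#' Serialize / deserialize a tree (JSON)
#'
#' Nested records with fields `var`, `cut`, `left`, `right`, `leaf_id`,
#' stable across runs for diffing and frequency counting.
#'
#' @param tree A `bdt_tree`.
#' @param var_names Optional split-variable names.
#' @return `tree_to_json()` a JSON string; `tree_from_json()` a `bdt_tree`.
#' @export
tree_to_json <- function(tree, var_names = attr(tree, "var_names")) {
  ln <- leaf_nodes(tree)
  rec <- function(nd) {
    if (is.na(tree$var[nd])) return(list(leaf_id = match(nd, ln)))
    list(var = if (!is.null(var_names)) var_names[tree$var[nd]] else tree$var[nd],
         cut = tree$cut[nd],
         left = rec(tree$left[nd]), right = rec(tree$right[nd]))
  }
  jsonlite::toJSON(rec(1L), auto_unbox = TRUE, digits = NA)
}

#' @rdname tree_to_json
#' @param json JSON produced by [tree_to_json()].
#' @param split_vars Character vector mapping variable names to indices.
#' @export
tree_from_json <- function(json, split_vars = NULL) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  tree <- root_tree()
  build <- function(node, nd) {
    if (!is.null(node$leaf_id)) return(NULL)
    vi <- if (is.character(node$var)) {
      if (is.null(split_vars)) stop("need 'split_vars' to decode variable names")
      match(node$var, split_vars)
    } else as.integer(node$var)
    tree <<- grow_leaf(tree, nd, vi, node$cut)
    l <- tree$left[nd]; r <- tree$right[nd]
    build(node$left, l)
    build(node$right, r)
  }
  build(obj, 1L)
  if (!is.null(split_vars)) attr(tree, "var_names") <- split_vars
  tree
}

#' Sample trees from the depth prior by a prior-only birth/death chain
#'
#' Runs the birth/death Metropolis-Hastings kernel with the likelihood term
#' switched off, so the chain's stationary distribution is the tree prior
#' itself. No data enter, hence no leaf-occupancy constraints apply. Used to
#' calibrate the prior (e.g. the root-tree probability `1 - c0`).
#'
#' @param grids Cutpoint grids (see [build_cutpoint_grid()]).
#' @param n_draws Number of retained tree draws.
#' @param stride Moves between retained draws (thinning).
#' @param c0,d0 Tree-prior parameters.
#' @param X Optional covariate matrix; defaults to a token one-row matrix
#'   (the prior does not look at data).
#' @return Integer vector of leaf counts of the retained draws.
#' @export
prior_tree_chain <- function(grids, n_draws = 1000, stride = 25,
                             c0 = 0.95, d0 = 2, X = NULL) {
  m <- length(grids)
  if (is.null(X)) {
    X <- matrix(0, 2, m, dimnames = list(NULL, names(grids)))
  }
  X <- as.matrix(X)
  n <- nrow(X)
  kap0 <- matrix(0, n, 9L)
  Xa <- matrix(1, n, 1L)
  tr <- root_tree()
  attr(tr, "var_names") <- names(grids)
  out <- integer(n_draws)
  for (d in seq_len(n_draws)) {
    res <- cpp_tree_sweep(unclass(tr), X, grids, Xa, Xa, kap0,
                          numeric(n), 0, 1,
                          rep(1L, n), rep(1L, n), rep(1L, n),
                          2L, 1L, 1L, 1L,
                          1, c0, d0, 0L, FALSE, as.integer(stride), TRUE)
    tr <- structure(res$tree, class = "bdt_tree")
    attr(tr, "var_names") <- names(grids)
    out[d] <- num_leaves(tr)
  }
  out
}
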