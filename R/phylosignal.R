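# Precompute the Felsenstein pruning schedule of a tree: a sequence of
# pairwise combines with trait-independent weights. Polytomies are resolved
# on the fly into left-deep bifurcations with zero-length internal branches,
# children taken in order of their smallest subtree tip label (deterministic;
# preserves the tip covariance matrix exactly and yields n - 1 contrasts).
pic_schedule <- function(tree) {
  validate_phylo(tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  ntip <- ape::Ntip(tree)
  if (ntip < 2) abort("need at least 2 tips")
  n_all <- ntip + tree$Nnode
  el <- rep(0, n_all)
  el[tree$edge[, 2]] <- tree$edge.length
  ch <- children_list(tree)
  minlab <- subtree_min_label(tree)
  po_int <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])

  n_ops <- ntip - 1L
  op_i <- integer(n_ops); op_j <- integer(n_ops); op_t <- integer(n_ops)
  op_sd <- numeric(n_ops); op_wi <- numeric(n_ops); op_wj <- numeric(n_ops)
  op_node <- integer(n_ops)
  slot <- integer(n_all); slot[seq_len(ntip)] <- seq_len(ntip)
  badj <- numeric(n_all); badj[seq_len(ntip)] <- el[seq_len(ntip)]
  next_slot <- ntip
  k <- 0L
  for (v in po_int) {
    kids <- ch[[v]]
    kids <- kids[order(minlab[kids])]
    cur_slot <- slot[kids[1]]
    cur_b <- badj[kids[1]]
    for (c in kids[-1]) {
      sb <- cur_b + badj[c]
      if (sb <= 0) abort("zero combined branch length at an internal node")
      k <- k + 1L
      next_slot <- next_slot + 1L
      op_i[k] <- cur_slot; op_j[k] <- slot[c]; op_t[k] <- next_slot
      op_sd[k] <- sqrt(sb)
      op_wi[k] <- badj[c] / sb; op_wj[k] <- cur_b / sb
      op_node[k] <- v
      cur_slot <- next_slot
      cur_b <- cur_b * badj[c] / sb
    }
    slot[v] <- cur_slot
    badj[v] <- el[v] + cur_b
  }
  root <- root_node(tree)
  list(ntip = ntip, n_slots = next_slot,
       op_i = op_i, op_j = op_j, op_t = op_t,
       op_sd = op_sd, op_wi = op_wi, op_wj = op_wj, op_node = op_node,
       root_slot = slot[root], root_extra_var = badj[root] - el[root],
       tr_v = sum(ape::node.depth.edgelength(tree)[seq_len(ntip)]))
}

pic_eval <- function(sched, x) {
  val <- numeric(sched$n_slots)
  val[seq_len(sched$ntip)] <- x
  n_ops <- length(sched$op_i)
  contrasts <- numeric(n_ops)
  for (k in seq_len(n_ops)) {
    vi <- val[sched$op_i[k]]; vj <- val[sched$op_j[k]]
    contrasts[k] <- (vi - vj) / sched$op_sd[k]
    val[sched$op_t[k]] <- sched$op_wi[k] * vi + sched$op_wj[k] * vj
  }
  list(contrasts = contrasts, root_value = val[sched$root_slot])
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning algorithm: at each internal node the difference
#' between the two daughter values is standardized by the square root of its
#' expected variance (the sum of the daughters' adjusted branch lengths), the
#' nodal value is their weighted mean, and the node's parent branch is
#' extended by `b_i * b_j / (b_i + b_j)`. Polytomies are resolved into
#' left-deep zero-length bifurcations in deterministic (sorted smallest tip
#' label) order, so a tree with `n` tips always yields `n - 1` contrasts.
#'
#' @param tree A `phylo` with branch lengths.
#' @param trait Tip values: a named numeric vector or a two-column data frame
#'   `(tip_label, value)`.
#' @return A tibble of class `pic_contrasts` with columns `node` (internal
#'   node id), `contrast` (standardized) and `variance` (expected variance,
#'   i.e. the sum of adjusted branch lengths), plus attributes `root_value`
#'   (the GLS estimate of the root state) and `root_variance` (its variance
#'   in units of the Brownian rate).
#' @export
#' @examples
#' tr <- read_tree_newick("((A:1,B:1):1,C:2);")
#' pic_contrasts(tr, c(A = 2, B = 0, C = 1))
pic_contrasts <- function(tree, trait) {
  x <- resolve_trait(tree, trait)
  sched <- pic_schedule(tree)
  ev <- pic_eval(sched, x)
  out <- tibble(node = sched$op_node, contrast = ev$contrasts,
                variance = sched$op_sd^2)
  attr(out, "root_value") <- ev$root_value
  attr(out, "root_variance") <- sched$root_extra_var
  class(out) <- c("pic_contrasts", class(out))
  out
}

#' Correlation of two contrast sets through the origin
#'
#' Contrasts have an arbitrary sign, so their association is measured by the
#' correlation constrained through the origin,
#' `r = sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))`.
#'
#' @param cx,cy `pic_contrasts` tibbles from the same tree (or bare numeric
#'   vectors of equal length).
#' @return The correlation coefficient.
#' @export
pic_correlation <- function(cx, cy) {
  x <- if (is.data.frame(cx)) cx$contrast else cx
  y <- if (is.data.frame(cy)) cy$contrast else cy
  if (length(x) != length(y)) abort("contrast sets differ in length")
  if (is.data.frame(cx) && is.data.frame(cy) && !identical(cx$node, cy$node)) {
    abort("contrast sets come from different node orders")
  }
  ssx <- sum(x^2); ssy <- sum(y^2)
  if (ssx == 0 || ssy == 0) abort("zero sum of squares in a contrast set")
  sum(x * y) / sqrt(ssx * ssy)
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' K compares the observed ratio of the non-phylogenetic to the phylogenetic
#' mean squared error of a trait with its expectation under Brownian motion
#' on the given tree: with `a` the GLS phylogenetic mean,
#' `MSE0 = (x - a)'(x - a) / (n - 1)`,
#' `MSE = (x - a)' V^-1 (x - a) / (n - 1)` and
#' `K = (MSE0 / MSE) / ((tr(V) - n / sum(V^-1)) / (n - 1))`.
#' K = 1 under Brownian evolution; K < 1 indicates less, K > 1 more
#' resemblance among relatives than Brownian motion predicts.
#'
#' Two algebraically identical routes are provided: the explicit matrix
#' formula, and a contrast-based route that never forms `V` (the sum of
#' squared contrasts equals the GLS quadratic form).
#'
#' @inheritParams pic_contrasts
#' @param method `"contrasts"` (default, O(n)) or `"matrix"`.
#' @return The K statistic (numeric scalar).
#' @export
blomberg_k <- function(tree, trait, method = c("contrasts", "matrix")) {
  method <- match.arg(method)
  x <- resolve_trait(tree, trait)
  n <- length(x)
  if (stats::var(x) == 0) abort("constant trait: K is undefined")
  if (method == "matrix") {
    V <- phylo_covariance(tree)
    Vi <- solve(V)
    a <- sum(Vi %*% x) / sum(Vi)
    r <- x - a
    mse0 <- sum(r^2) / (n - 1)
    mse <- drop(t(r) %*% Vi %*% r) / (n - 1)
    expected <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  } else {
    sched <- pic_schedule(tree)
    ev <- pic_eval(sched, x)
    a <- ev$root_value
    mse0 <- sum((x - a)^2) / (n - 1)
    mse <- sum(ev$contrasts^2) / (n - 1)
    expected <- (sched$tr_v - n * sched$root_extra_var) / (n - 1)
  }
  (mse0 / mse) / expected
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Permutation test for phylogenetic signal
#'
#' The observed variance of the standardized contrasts (the mean of their
#' squares, `sum(c^2) / (n - 1)`) is compared with a null distribution
#' obtained by reshuffling the trait values across the tips of the phylogeny.
#' A low observed variance relative to the null indicates that close
#' relatives resemble each other, i.e. phylogenetic signal. Significance at
#' alpha = 0.05 is declared when the observed variance is lower than 95% of
#' the null values; a one-tailed permutation p-value with the plus-one
#' correction, `p = (1 + #\{null <= obs\}) / (1 + n_perm)`, is reported
#' alongside, together with Blomberg's K and its own permutation p-value
#' (fraction of reshuffles with K at least as large).
#'
#' @inheritParams pic_contrasts
#' @param n_perm Number of reshuffles (>= 99) in `"sample"` mode.
#' @param seed Integer seed for the reshuffles.
#' @param mode `"sample"` (Monte-Carlo, default) or `"exact"` (all `n!`
#'   assignments, tips <= 8; p-values are then exhaustive proportions
#'   without the plus-one rule).
#' @return An object of class `signal_test`: a list with elements `K`,
#'   `var_obs`, `null_vars`, `null_mean`, `p_value` (variance-based),
#'   `p_value_k` (K-based), `n_permutations`, `seed`, `mode`,
#'   `significant_alpha05`. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
phylo_signal_test <- function(tree, trait, n_perm = 999, seed = NULL,
                              mode = c("sample", "exact")) {
  mode <- match.arg(mode)
  x <- resolve_trait(tree, trait)
  n <- length(x)
  if (stats::var(x) == 0) abort("constant trait")
  sched <- pic_schedule(tree)
  expected <- (sched$tr_v - n * sched$root_extra_var) / (n - 1)

  stat_pair <- function(xx) {
    ev <- pic_eval(sched, xx)
    v <- sum(ev$contrasts^2) / (n - 1)
    mse0 <- sum((xx - ev$root_value)^2) / (n - 1)
    c(v, (mse0 / v) / expected)
  }
  obs <- stat_pair(x)
  var_obs <- obs[1]; k_obs <- obs[2]

  if (mode == "exact") {
    if (n > 8) abort("exact mode supports at most 8 tips")
    perms <- all_permutations(n)
    null_stats <- apply(perms, 1, function(idx) stat_pair(x[idx]))
    null_vars <- null_stats[1, ]
    null_k <- null_stats[2, ]
    p_var <- mean(null_vars <= var_obs)
    p_k <- mean(null_k >= k_obs)
    n_perm <- nrow(perms)
  } else {
    if (n_perm < 99) abort("n_perm must be at least 99")
    if (!is.null(seed)) set.seed(seed)
    null_vars <- numeric(n_perm)
    null_k <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      st <- stat_pair(x[sample.int(n)])
      null_vars[b] <- st[1]; null_k[b] <- st[2]
    }
    p_var <- (1 + sum(null_vars <= var_obs)) / (1 + n_perm)
    p_k <- (1 + sum(null_k >= k_obs)) / (1 + n_perm)
  }

  structure(list(K = k_obs, var_obs = var_obs, null_vars = null_vars,
                 null_mean = mean(null_vars), p_value = p_var,
                 p_value_k = p_k, n_permutations = n_perm,
                 seed = seed, mode = mode,
                 significant_alpha05 = mean(null_vars > var_obs) >= 0.95),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  cat("Phylogenetic signal (contrast-variance permutation test)\n")
  cat(sprintf("  K = %.4g\n", x$K))
  cat(sprintf("  observed contrast variance = %.4g (null mean %.4g)\n",
              x$var_obs, x$null_mean))
  cat(sprintf("  p (variance-based) = %.4g; p (K-based) = %.4g  [%s, %d permutations]\n",
              x$p_value, x$p_value_k, x$mode, x$n_permutations))
  cat(sprintf("  significant at alpha = 0.05: %s\n", x$significant_alpha05))
  invisible(x)
}

#' @method tidy signal_test
#' @export
tidy.signal_test <- function(x, ...) {
  tibble(K = x$K, var_obs = x$var_obs, null_mean = x$null_mean,
         p.value = x$p_value, p.value.k = x$p_value_k,
         n_permutations = x$n_permutations,
         significant = x$significant_alpha05)
}

#' @method glance signal_test
#' @export
glance.signal_test <- function(x, ...) tidy(x)
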