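# canonical key of a two-locus haplotype-count configuration, folded over
# allele relabelling at either locus and over locus exchange: the
# lexicographically smallest of the 8 symmetry images of (n00, n01, n10, n11)
fold_config_keys <- function(counts) {
  a <- counts[, 1]; b <- counts[, 2]; c <- counts[, 3]; d <- counts[, 4]
  variants <- list(
    cbind(a, b, c, d), cbind(c, d, a, b), cbind(b, a, d, c), cbind(d, c, b, a),
    cbind(a, c, b, d), cbind(b, d, a, c), cbind(c, a, d, b), cbind(d, b, c, a)
  )
  keys <- sprintf("%03d.%03d.%03d.%03d",
                  variants[[1]][, 1], variants[[1]][, 2],
                  variants[[1]][, 3], variants[[1]][, 4])
  for (v in variants[-1]) {
    kv <- sprintf("%03d.%03d.%03d.%03d", v[, 1], v[, 2], v[, 3], v[, 4])
    keys <- pmin(keys, kv)
  }
  keys
}

#' Monte-Carlo two-locus configuration probability table
#'
#' For each value of the population recombination rate rho on a grid,
#' simulates `mc_reps` two-locus coalescent genealogies for a sample of `n`
#' haplotypes and records the probability of every two-locus haplotype-count
#' configuration, conditional on both loci segregating (one infinite-sites
#' mutation per locus). Configurations are folded over allele relabelling at
#' either locus and over locus exchange. The table is the likelihood engine
#' behind [composite_rho()], in the spirit of the pairwise composite-
#' likelihood method of Hudson as implemented in LDhat.
#'
#' Unobserved configurations are later floored at `1 / (mc_reps + 1)` so that
#' composite log-likelihoods stay finite.
#'
#' @param n Number of haplotypes (4..62).
#' @param rho_grid Increasing grid of rho values; must include 0.
#' @param mc_reps Monte-Carlo replicates per grid point (>= 10000).
#' @param seed Integer seed.
#' @return An object of class `two_locus_table`: list with `n`, `rho_grid`,
#'   `mc_reps`, `floor`, and `probs` (matrix, folded configuration keys x
#'   grid points).
#' @export
two_locus_table <- function(n, rho_grid = c(0, 0.5, 1, 2, 5, 10, 20, 50, 100),
                            mc_reps = 10000, seed = NULL) {
  if (n < 4) abort("n must be at least 4")
  if (any(rho_grid < 0)) abort("rho_grid values must be >= 0")
  if (!0 %in% rho_grid) abort("rho_grid must include 0")
  if (is.unsorted(rho_grid, strictly = TRUE)) abort("rho_grid must be strictly increasing")
  if (mc_reps < 10000) abort("mc_reps must be at least 10000")
  if (!is.null(seed)) set.seed(seed)
  counts_by_rho <- lapply(rho_grid, function(r) {
    cfg <- cpp_two_locus_configs(as.integer(n), r, as.integer(mc_reps))
    table(fold_config_keys(cfg))
  })
  keys <- sort(unique(unlist(lapply(counts_by_rho, names))))
  probs <- matrix(0, length(keys), length(rho_grid),
                  dimnames = list(keys, as.character(rho_grid)))
  for (g in seq_along(rho_grid)) {
    tb <- counts_by_rho[[g]]
    probs[names(tb), g] <- as.numeric(tb) / mc_reps
  }
  structure(list(n = n, rho_grid = rho_grid, mc_reps = mc_reps,
                 floor = 1 / (mc_reps + 1), probs = probs),
            class = "two_locus_table")
}

#' @export
print.two_locus_table <- function(x, ...) {
  cat(sprintf("two_locus_table: n = %d, %d grid points (rho %g..%g), %d reps each, %d configs\n",
              x$n, length(x$rho_grid), min(x$rho_grid), max(x$rho_grid),
              x$mc_reps, nrow(x$probs)))
  invisible(x)
}

# log P(config | rho) interpolated from the table: linear in log rho between
# positive grid points, linear in rho between 0 and the first positive point,
# clamped at the grid ends; vectorized over rho
interp_logp <- function(lp, grid, rho) {
  out <- numeric(length(rho))
  rho <- pmin(rho, max(grid))
  at0 <- rho <= 0
  out[at0] <- lp[1]
  if (any(!at0)) {
    r <- rho[!at0]
    g1 <- grid[2]
    small <- r < g1
    val <- numeric(length(r))
    if (any(small)) {
      val[small] <- lp[1] + (lp[2] - lp[1]) * r[small] / g1
    }
    if (any(!small)) {
      lg <- log(grid[-1])
      idx <- findInterval(log(r[!small]), lg, all.inside = TRUE)
      x0 <- lg[idx]; x1 <- lg[idx + 1]
      y0 <- lp[idx + 1]; y1 <- lp[idx + 2]
      w <- (log(r[!small]) - x0) / (x1 - x0)
      val[!small] <- y0 + w * (y1 - y0)
    }
    out[!at0] <- val
  }
  out
}

#' Composite-likelihood estimate of the population recombination rate
#'
#' Pairwise composite likelihood over all pairs of segregating sites: each
#' pair contributes `log P(config | rho_ij)` looked up in a precomputed
#' [two_locus_table()], with the per-pair rate scaled by physical distance,
#' `rho_ij = rho * d_ij / d_total` (`d_total` = span of the gene). The
#' per-gene estimate `rho_hat` maximizes the composite log-likelihood over a
#' deterministic candidate grid (ties resolved toward the smaller value, so
#' perfect linkage disequilibrium yields the boundary estimate 0).
#' Probabilities for configurations never observed in the Monte-Carlo table
#' are floored at `1 / (mc_reps + 1)`; interpolation between grid points is
#' linear in log rho.
#'
#' @param snp A `snp_matrix` (typically parsimony-informative sites only).
#' @param table A `two_locus_table` built for the same number of haplotypes.
#' @param positions Physical positions of the columns; defaults to
#'   `snp$positions`.
#' @param candidates Candidate per-gene rho values; default 0 plus a 60-point
#'   log-spaced grid from 0.01 to twice the table maximum.
#' @param theta_w_gene Per-gene Watterson theta used for the `rho_over_theta`
#'   ratio; defaults to `S / a_n` computed from `snp` itself.
#' @return A one-row tibble `(rho_hat, rho_over_theta, loglik, n_pairs)`,
#'   with the composite log-likelihood profile in the `"profile"` attribute.
#' @export
composite_rho <- function(snp, table, positions = NULL, candidates = NULL,
                          theta_w_gene = NULL) {
  g <- snp$geno
  n <- nrow(g)
  if (n != table$n) abort("table was built for a different sample size")
  S <- ncol(g)
  if (S < 2) abort("need at least 2 segregating sites")
  pos <- positions %||% snp$positions
  d_total <- max(pos) - min(pos)
  if (d_total <= 0) abort("sites span zero distance")
  if (is.null(candidates)) {
    candidates <- c(0, exp(seq(log(0.01), log(2 * max(table$rho_grid)), length.out = 60)))
  }
  if (is.null(theta_w_gene)) theta_w_gene <- S / sum(1 / seq_len(n - 1))

  pr <- utils::combn(S, 2)
  n11 <- colSums(g[, pr[1, ], drop = FALSE] * g[, pr[2, ], drop = FALSE])
  p1 <- colSums(g[, pr[1, ], drop = FALSE])
  p2 <- colSums(g[, pr[2, ], drop = FALSE])
  counts <- cbind(n - p1 - p2 + n11, p2 - n11, p1 - n11, n11)
  keys <- fold_config_keys(counts)
  d <- (pos[pr[2, ]] - pos[pr[1, ]]) / d_total

  lp_floor <- log(table$floor)
  known <- rownames(table$probs)
  ll <- numeric(length(candidates))
  for (u in unique(keys)) {
    sel <- keys == u
    if (u %in% known) {
      lp <- log(pmax(table$probs[u, ], table$floor))
      for (ci in seq_along(candidates)) {
        ll[ci] <- ll[ci] + sum(interp_logp(lp, table$rho_grid, candidates[ci] * d[sel]))
      }
    } else {
      ll <- ll + sum(sel) * lp_floor
    }
  }
  best <- which.max(ll)  # first maximum = smallest candidate on ties
  out <- tibble(rho_hat = candidates[best],
                rho_over_theta = candidates[best] / theta_w_gene,
                loglik = ll[best], n_pairs = ncol(pr))
  attr(out, "profile") <- tibble(rho = candidates, loglik = ll)
  out
}
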