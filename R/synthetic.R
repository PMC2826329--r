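#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation with exponential waiting times: starting from the root
#' split (two lineages at time 0), with `k` lineages the next split occurs
#' after an Exp(`k * birth_rate`) wait on a uniformly chosen lineage; after
#' the `n`-th lineage appears one final Exp(`n * birth_rate`) wait is added
#' before the present, so the expected root-to-tip depth is
#' `sum(1 / (k * birth_rate), k = 2..n)`. The tree is ultrametric by
#' construction.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per Myr.
#' @param seed Integer seed.
#' @return An ultrametric `phylo` with tips labelled `t001`, `t002`, ...
#' @export
sim_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2) abort("n_tips must be at least 2")
  if (birth_rate <= 0) abort("birth_rate must be positive")
  if (!is.null(seed)) set.seed(seed)

  n_int <- n_tips - 1L
  int_parent <- integer(n_int)  # 0 for root
  int_time <- numeric(n_int)
  int_parent[1] <- 0L
  int_time[1] <- 0
  pend_parent <- c(1L, 1L)
  t <- 0
  if (n_tips > 2) {
    for (k in 2:(n_tips - 1L)) {
      t <- t + rexp(1, k * birth_rate)
      idx <- sample.int(length(pend_parent), 1)
      m <- k  # internal node id in creation order
      int_parent[m] <- pend_parent[idx]
      int_time[m] <- t
      pend_parent <- c(pend_parent[-idx], m, m)
    }
  }
  t_present <- t + rexp(1, n_tips * birth_rate)

  ntip <- n_tips
  edge <- matrix(0L, 2L * ntip - 2L, 2)
  elen <- numeric(nrow(edge))
  e <- 0L
  for (m in seq_len(n_int)[-1]) {
    e <- e + 1L
    edge[e, ] <- c(ntip + int_parent[m], ntip + m)
    elen[e] <- int_time[m] - int_time[int_parent[m]]
  }
  for (i in seq_along(pend_parent)) {
    e <- e + 1L
    edge[e, ] <- c(ntip + pend_parent[i], i)
    elen[e] <- t_present - int_time[pend_parent[i]]
  }
  tree <- list(edge = edge, edge.length = elen, Nnode = n_int,
               tip.label = sprintf("t%03d", seq_len(ntip)))
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Each child value equals its parent value plus a Gaussian increment with
#' variance `sigma2 * branch_length` (univariate), or with covariance
#' `Sigma * branch_length` for a bivariate trait.
#'
#' @param tree A `phylo` with branch lengths.
#' @param sigma2 Brownian rate (variance per Myr); ignored when `Sigma` is
#'   supplied.
#' @param root_value Trait value at the root (length 1 or 2).
#' @param seed Integer seed.
#' @param Sigma Optional 2x2 positive semi-definite per-Myr covariance for a
#'   bivariate trait.
#' @return A tibble with column `tip` and trait column `value` (univariate)
#'   or `x`, `y` (bivariate).
#' @export
sim_bm <- function(tree, sigma2 = 1, root_value = 0, seed = NULL, Sigma = NULL) {
  validate_phylo(tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  d <- if (is.null(Sigma)) 1L else 2L
  if (!is.null(Sigma)) {
    Sigma <- as.matrix(Sigma)
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1)) abort("Sigma is not positive semi-definite")
    Ch <- chol(Sigma + diag(1e-14, 2))
  }
  val <- matrix(0, n_all, d)
  val[root_node(tree), ] <- root_value
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(cw$edge))) {
    p <- cw$edge[i, 1]; ch <- cw$edge[i, 2]; bl <- cw$edge.length[i]
    inc <- if (is.null(Sigma)) rnorm(1, 0, sqrt(sigma2 * bl))
           else sqrt(bl) * drop(t(Ch) %*% rnorm(2))
    val[ch, ] <- val[p, ] + inc
  }
  out <- tibble(tip = tree$tip.label)
  if (d == 1L) out$value <- val[seq_len(ntip), 1]
  else { out$x <- val[seq_len(ntip), 1]; out$y <- val[seq_len(ntip), 2] }
  out
}

#' Assign life-forms to tips and shift a trait by group effects
#'
#' Two modes. Markov: a discrete life-form character evolves from the root
#' by a continuous-time symmetric switch process (total switch rate
#' `switch_rate` per Myr; each switch moves to a uniformly chosen other
#' level). Clade painting: `clades` names, per level, a set of tips whose
#' most recent common ancestor's whole clade is painted with that level
#' (applied after the Markov/root assignment, emulating, e.g., conifers as a
#' coherent clade).
#'
#' @param tree A `phylo` with branch lengths.
#' @param levels Life-form levels (subset of herb/shrub/tree/conifer tree).
#' @param switch_rate Total switch rate per Myr (0 = all tips inherit the
#'   root state).
#' @param root_state State at the root (default first level).
#' @param clades Optional named list: level -> character vector of tips; the
#'   MRCA clade of those tips is painted with the level.
#' @param group_effects Optional named additive shifts applied to `trait`.
#' @param trait Optional tip trait (named vector or tibble) to shift.
#' @param seed Integer seed.
#' @return A tibble `(tip, life_form)`, plus `value` (shifted trait) when
#'   `trait` is given.
#' @export
sim_life_forms <- function(tree, levels = c("tree", "herb", "shrub"),
                           switch_rate = 0, root_state = levels[1],
                           clades = NULL, group_effects = NULL, trait = NULL,
                           seed = NULL) {
  validate_phylo(tree)
  if (length(levels) == 0) abort("empty level set")
  allowed <- c("herb", "shrub", "tree", "conifer tree")
  if (!all(levels %in% allowed)) abort("levels must be herb/shrub/tree/conifer tree")
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  state <- character(n_all)
  state[root_node(tree)] <- root_state
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(cw$edge))) {
    p <- cw$edge[i, 1]; ch <- cw$edge[i, 2]; bl <- cw$edge.length[i]
    s <- state[p]
    if (switch_rate > 0 && length(levels) > 1) {
      n_sw <- rpois(1, switch_rate * bl)
      for (j in seq_len(n_sw)) s <- sample(setdiff(levels, s), 1)
    }
    state[ch] <- s
  }
  lf <- state[seq_len(ntip)]
  names(lf) <- tree$tip.label
  if (!is.null(clades)) {
    for (lv in names(clades)) {
      tips <- clades[[lv]]
      if (length(tips) == 1) {
        lf[tips] <- lv
      } else {
        node <- ape::getMRCA(tree, tips)
        lf[ape::extract.clade(tree, node)$tip.label] <- lv
      }
    }
  }
  out <- tibble(tip = tree$tip.label, life_form = unname(lf))
  if (!is.null(trait)) {
    x <- resolve_trait(tree, trait)
    eff <- if (is.null(group_effects)) setNames(numeric(length(levels)), levels)
           else group_effects
    shift <- ifelse(out$life_form %in% names(eff), eff[out$life_form], 0)
    out$value <- x + unname(shift)
  }
  out
}

#' Synthetic species table with known ground truth
#'
#' Generates, on a calibrated tree, the delimited species table the rate
#' pipeline consumes, with every latent quantity known. Heterozygosity is a
#' bounded logistic transform of a Brownian trait (scaled to the realistic
#' SSR range 0.3-0.9); the latent log genome-wide rate is
#' `intercept + slope_He * He + group_effect + Brownian deviation (+ iid
#' noise)`. Life-forms follow a Markov switch with an optional conifer clade
#' painting. Map lengths, marker counts and genome sizes are then
#' back-solved so that [build_rate_table()] reproduces the latent log rate
#' exactly (to numerical precision), and every record passes the inclusion
#' filters by construction.
#'
#' @param tree An ultrametric `phylo` (tip set = species).
#' @param intercept Baseline (tree life-form) log rate.
#' @param slope_He Effect of He on log rate.
#' @param group_effects Named additive life-form effects on log rate.
#' @param bm_sigma2 Variance per Myr of the Brownian deviation of log rate.
#' @param noise_sd SD of an additional iid (non-phylogenetic) deviation.
#' @param conifer_frac Approximate fraction of tips painted as a conifer
#'   clade (0 disables conifers).
#' @param switch_rate Life-form Markov switch rate per Myr; defaults to
#'   `2 / depth` so that all three forms appear on typical trees.
#' @param seed Integer seed.
#' @return A tibble of species records (see [build_rate_table()]) with extra
#'   ground-truth columns `true_log_rate`, `true_He`.
#' @export
sim_species_table <- function(tree, intercept = -1.5, slope_He = 0.8,
                              group_effects = c(tree = 0, herb = -0.9,
                                                shrub = -0.7,
                                                `conifer tree` = -1.1),
                              bm_sigma2 = NULL, noise_sd = 0,
                              conifer_frac = 0.1, switch_rate = NULL,
                              seed = NULL) {
  validate_phylo(tree)
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  depth <- max(ape::node.depth.edgelength(tree))
  if (depth <= 0) abort("tree has zero depth")
  if (is.null(switch_rate)) switch_rate <- 2 / depth
  if (is.null(bm_sigma2)) bm_sigma2 <- 0.25 / depth

  he_bm <- sim_bm(tree, sigma2 = 1.5 / depth)
  He <- 0.3 + 0.6 * stats::plogis(he_bm$value)

  clades <- NULL
  if (conifer_frac > 0 && ntip >= 10) {
    # deterministic clade of size closest to conifer_frac * ntip
    po <- ape::reorder.phylo(tree, "postorder")$edge
    n_desc <- c(rep(1, ntip), rep(0, tree$Nnode))
    for (i in seq_len(nrow(po))) n_desc[po[i, 1]] <- n_desc[po[i, 1]] + n_desc[po[i, 2]]
    internals <- (ntip + 1):(ntip + tree$Nnode)
    cand <- internals[n_desc[internals] < ntip / 2]
    node <- cand[which.min(abs(n_desc[cand] - conifer_frac * ntip))]
    clades <- list(`conifer tree` = ape::extract.clade(tree, node)$tip.label)
  }
  lf <- sim_life_forms(tree, levels = c("tree", "herb", "shrub"),
                       switch_rate = switch_rate, root_state = "tree",
                       clades = clades)
  eff <- ifelse(lf$life_form %in% names(group_effects),
                group_effects[lf$life_form], 0)
  dev <- sim_bm(tree, sigma2 = bm_sigma2)$value
  log_rate <- intercept + slope_He * He + unname(eff) + dev +
    rnorm(ntip, 0, noise_sd)
  rate <- exp(log_rate)

  conifer <- lf$life_form == "conifer tree"
  genome <- exp(rnorm(ntip, log(800), 0.6))
  genome[conifer] <- exp(rnorm(sum(conifer), log(15000), 0.3))
  corrected <- rate * genome
  if (any(corrected <= 0)) abort("infeasible back-solve: non-positive map length")

  n_chrom <- sample(5:12, ntip, replace = TRUE)
  chrom_lengths <- character(ntip)
  chrom_markers <- character(ntip)
  for (i in seq_len(ntip)) {
    C <- n_chrom[i]
    m <- sample(20:60, C, replace = TRUE)
    raw_total <- corrected[i] / (1 + 2 * C / sum(m - 1))
    w <- runif(C, 0.5, 1.5); w <- w / sum(w)
    chrom_lengths[i] <- paste(sprintf("%.17g", raw_total * w), collapse = ";")
    chrom_markers[i] <- paste(m, collapse = ";")
  }
  use_pg <- seq_len(ntip) %% 2 == 0
  tibble(
    species = tree$tip.label,
    life_form = ifelse(conifer, "tree", lf$life_form),
    taxon_group = ifelse(conifer, "conifer", "angiosperm"),
    chrom_lengths = chrom_lengths,
    chrom_markers = chrom_markers,
    n_chromosomes = n_chrom,
    genome_size_mb = ifelse(use_pg, NA_real_, genome),
    c_value_pg = ifelse(use_pg, genome / 978, NA_real_),
    map_coverage = runif(ntip, 0.7, 0.98),
    He = He,
    n_ssr_loci = sample(5:30, ntip, replace = TRUE),
    domesticated = FALSE,
    true_log_rate = log_rate,
    true_He = He
  )
}
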