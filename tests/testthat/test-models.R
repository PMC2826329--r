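fake_rate_table <- function(n = 30, conifers = 0, seed = 1) {
  set.seed(seed)
  lf <- sample(c("tree", "herb", "shrub"), n, replace = TRUE)
  lf[1:3] <- c("tree", "herb", "shrub")  # ensure all levels present
  tg <- rep("angiosperm", n)
  if (conifers > 0) {
    idx <- which(lf == "tree")[seq_len(conifers)]
    tg[idx] <- "conifer"
  }
  tibble::tibble(species = sprintf("sp%02d", 1:n), life_form = lf,
                 taxon_group = tg, corrected_cm = 1000, genome_mb = 500,
                 rate = 2, log_rate = rnorm(n), He = runif(n, 0.3, 0.9))
}

test_that("design matrix uses tree baseline and fixed column order", {
  tab <- fake_rate_table(12, conifers = 2, seed = 2)
  d <- build_design(tab)
  expect_equal(colnames(d$X), c("intercept", "He", "herb", "shrub"))
  tree_rows <- tab$life_form == "tree"
  expect_true(all(d$X[tree_rows, c("herb", "shrub")] == 0))
  expect_equal(d$X[, "herb"], as.numeric(tab$life_form == "herb"), ignore_attr = TRUE)

  d2 <- build_design(tab, conifer_separate = TRUE)
  expect_equal(colnames(d2$X),
               c("intercept", "He", "herb", "shrub", "conifer_tree"))
  con <- tab$life_form == "tree" & tab$taxon_group == "conifer"
  expect_equal(d2$X[, "conifer_tree"], as.numeric(con), ignore_attr = TRUE)
  expect_true(all(d2$X[con, c("herb", "shrub")] == 0))

  # absent level is dropped with a warning
  tab3 <- dplyr::filter(tab, life_form != "shrub")
  expect_warning(d3 <- build_design(tab3), "shrub")
  expect_false("shrub" %in% colnames(d3$X))
})

test_that("GLS reduces to OLS with identity correlation", {
  set.seed(7)
  n <- 40
  x <- runif(n)
  y <- 2 + 3 * x
  X <- cbind(intercept = 1, x = x)
  fit <- fit_gaussian(y, X)
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_lt(fit$sigma2, 1e-20)

  y2 <- y + rnorm(n)
  fit2 <- fit_gaussian(y2, X)
  lmfit <- lm(y2 ~ x)
  expect_equal(unname(fit2$coefficients), unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(unname(fit2$se), unname(sqrt(diag(vcov(lmfit)))), tolerance = 1e-10)
  expect_equal(unname(fit2$p.value),
               unname(summary(lmfit)$coefficients[, 4]), tolerance = 1e-10)

  # explicit identity R gives the same fit
  fit3 <- fit_gaussian(y2, X, R = diag(n))
  expect_equal(fit3$coefficients, fit2$coefficients, tolerance = 1e-12)
  expect_equal(fit3$se, fit2$se, tolerance = 1e-12)

  expect_error(fit_gaussian(y2, cbind(X, x), R = NULL), "rank deficient")
  expect_error(fit_gaussian(y2, X, R = diag(n) - 2), "positive definite")
})

test_that("GLS estimates are equivariant and minimize the Mahalanobis norm", {
  set.seed(17)
  n <- 25
  y <- sim_yule_tree(n, seed = 18)
  R <- phylo_correlation(y)
  He <- runif(n, 0.3, 0.9)
  X <- cbind(intercept = 1, He = He)
  resp <- drop(chol(R) %*% rnorm(n)) + 1 + 0.5 * He
  fit <- fit_gaussian(resp, X, R)

  # scaling the response scales the coefficients
  fit_scaled <- fit_gaussian(3 * resp, X, R)
  expect_equal(fit_scaled$coefficients, 3 * fit$coefficients, tolerance = 1e-10)
  # translating the covariate shifts only the intercept
  X2 <- cbind(intercept = 1, He = He + 10)
  fit_shift <- fit_gaussian(resp, X2, R)
  expect_equal(fit_shift$coefficients[["He"]], fit$coefficients[["He"]],
               tolerance = 1e-8)
  expect_equal(fit_shift$coefficients[["intercept"]],
               fit$coefficients[["intercept"]] - 10 * fit$coefficients[["He"]],
               tolerance = 1e-8)

  # any perturbation of beta increases the generalized residual norm
  Ri <- solve(R)
  qf <- function(b) { r <- resp - drop(X %*% b); drop(t(r) %*% Ri %*% r) }
  base <- qf(fit$coefficients)
  set.seed(99)
  for (i in 1:25) {
    expect_gt(qf(fit$coefficients + rnorm(2, 0, 0.1)), base)
  }
})

test_that("fitted group means combine intercept and level coefficients", {
  # arithmetic of the published coefficient table: -1.527 + (-0.858) = -2.385
  cf <- c(intercept = -1.527, He = 0.836, herb = -0.858, shrub = -0.726)
  gm <- fitted_group_means(cf)
  expect_equal(gm$mean[gm$life_form == "herb"], -2.385)
  expect_equal(gm$mean[gm$life_form == "tree"], -1.527)
  expect_equal(gm$mean[gm$life_form == "shrub"], -2.253)

  # all-zero coefficients collapse every level onto the intercept
  cf0 <- c(intercept = -1.5, He = 0, herb = 0, shrub = 0)
  expect_true(all(fitted_group_means(cf0)$mean == -1.5))

  expect_error(fitted_group_means(c(He = 1)), "intercept")

  # delta-method SE from a fitted model agrees with direct linear-combination
  tab <- fake_rate_table(40, conifers = 5, seed = 5)
  tr <- sim_yule_tree(40, seed = 6)
  tr$tip.label <- tab$species
  fits <- fit_rate_models(tab, tr)
  gm2 <- fitted_group_means(fits$phylo2)
  L <- c(1, 0, 1, 0, 0)  # intercept + herb
  expect_equal(gm2$se[gm2$life_form == "herb"],
               sqrt(drop(t(L) %*% fits$phylo2$vcov %*% L)), tolerance = 1e-10)
  expect_equal(gm2$life_form[1], "angiosperm tree")
})

test_that("Kruskal-Wallis H matches hand-ranked arithmetic", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 12 / 42 * 13.5, tolerance = 1e-10)  # 3.857143
  expect_equal(res$df, 1)

  expect_error(kruskal_wallis(1:6, rep("a", 6)), "2 groups")
  expect_error(kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3)), "identical")

  # chi-square approximation is close to the exact permutation p in the
  # significance tail (fully separated groups, n = 4 + 4)
  vals <- c(1.1, 2.4, 3.2, 4.8, 5.3, 6.6, 7.1, 8.9)
  grp <- rep(c("a", "b"), each = 4)
  obs <- kruskal_wallis(vals, grp)
  combos <- utils::combn(8, 4)
  perm_stats <- apply(combos, 2, function(idx) {
    g <- rep("b", 8); g[idx] <- "a"
    suppressWarnings(stats::kruskal.test(vals, factor(g))$statistic)
  })
  p_exact <- mean(perm_stats >= obs$statistic - 1e-12)
  expect_lt(abs(obs$p.value - p_exact), 0.03)
})

test_that("clade-confounded data flips the He coefficient sign once corrected", {
  # two deep clades: between-clade association negative, within-clade positive
  newick <- paste0("((", paste(sprintf("a%d:1", 1:8), collapse = ","), "):9,(",
                   paste(sprintf("b%d:1", 1:8), collapse = ","), "):9);")
  tr <- read_tree_newick(newick)
  set.seed(101)
  within <- rep(seq(-0.15, 0.15, length.out = 8), 2)
  He <- c(0.35 + within[1:8], 0.75 + within[9:16])
  lr <- 2 * within + c(rep(0.5, 8), rep(-0.5, 8)) + rnorm(16, 0, 0.02)
  tab <- tibble::tibble(species = tr$tip.label,
                        life_form = "tree", taxon_group = "angiosperm",
                        corrected_cm = 1, genome_mb = 1, rate = exp(lr),
                        log_rate = lr, He = He)
  X <- cbind(intercept = 1, He = He)
  ols <- fit_gaussian(tab$log_rate, X)
  R <- phylo_correlation(tr)[tab$species, tab$species]
  gls <- fit_gaussian(tab$log_rate, X, R)
  expect_lt(ols$coefficients[["He"]], 0)
  expect_gt(gls$coefficients[["He"]], 0)
})
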