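#' Design matrix for the recombination-rate regressions
#'
#' Builds the response (log genome-wide recombination rate) and design matrix
#' used by the three comparative models: an intercept, the SSR expected
#' heterozygosity `He` ("Diversity"), and life-form dummies with trees as the
#' baseline. With `conifer_separate = TRUE` conifer trees are treated as a
#' life-form of their own (the baseline is then angiosperm trees) and receive
#' their own dummy column. Column order is fixed: intercept, He, herb,
#' shrub, conifer_tree.
#'
#' @param table A `rate_table` from [build_rate_table()].
#' @param conifer_separate Treat conifer trees as a separate life-form?
#' @return A list with `y` (named response vector), `X` (design matrix) and
#'   `life_form` (the factor used, one level per row).
#' @export
build_design <- function(table, conifer_separate = FALSE) {
  if (nrow(table) == 0) abort("empty rate table")
  lf <- table$life_form
  if (conifer_separate) {
    lf <- ifelse(lf == "tree" & table$taxon_group == "conifer", "conifer tree", lf)
  }
  levels_all <- c("herb", "shrub", if (conifer_separate) "conifer tree")
  X <- cbind(intercept = rep(1, nrow(table)), He = table$He)
  for (lv in levels_all) {
    col <- as.numeric(lf == lv)
    nm <- gsub(" ", "_", lv)
    if (sum(col) == 0) {
      warn(sprintf("life-form level '%s' absent from data; column dropped", lv))
    } else {
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- nm
    }
  }
  list(y = setNames(table$log_rate, table$species), X = X, life_form = lf)
}

#' Gaussian regression with a fixed correlation structure (GLS / GEE)
#'
#' Fits `y = X beta + e` with `Var(e) = sigma^2 R` for a known correlation
#' matrix `R` by generalized least squares. For a Gaussian identity-link
#' model with a fixed working correlation, the generalized estimating
#' equations reduce exactly to GLS, so the fit is computed in a single step:
#' `beta = (X' R^-1 X)^-1 X' R^-1 y`. With `R = NULL` (identity) this is
#' ordinary least squares. In the comparative analysis `R` is the
#' phylogenetic correlation matrix from [phylo_correlation()], rows/columns
#' ordered like `y`.
#'
#' Standard errors come from `sigma^2 (X' R^-1 X)^-1` with
#' `sigma^2 = (y - X beta)' R^-1 (y - X beta) / (n - p)`; p-values are
#' two-sided t with `n - p` degrees of freedom. Software that fits the same
#' model through the GEE machinery may use a different degrees-of-freedom
#' convention, so p-values (not estimates) can differ between
#' implementations.
#'
#' @param y Response vector.
#' @param X Design matrix (full column rank), `nrow(X) == length(y)`.
#' @param R Correlation matrix (symmetric positive definite) or `NULL` for
#'   the identity.
#' @param method Label stored in the fit (`"uncorrected"` or `"phylo_gee"`).
#' @return An object of class `phylo_gls` with components `coefficients`,
#'   `se`, `statistic`, `p.value`, `sigma2`, `df`, `vcov`, `method`, `n`,
#'   `logLik_quad` (the residual Mahalanobis norm). Has [tidy()] and
#'   [glance()] methods.
#' @export
fit_gaussian <- function(y, X, R = NULL, method = if (is.null(R)) "uncorrected" else "phylo_gee") {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) abort("X and y dimensions disagree")
  if (qr(X)$rank < p) abort("design matrix is rank deficient")
  if (is.null(R)) {
    Ri <- diag(n)
  } else {
    if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8))) abort("R must be symmetric")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(ev)) abort("R is not positive definite")
    Ri <- chol2inv(chol(R))
  }
  XtRi <- crossprod(X, Ri)
  A <- XtRi %*% X
  beta <- drop(solve(A, XtRi %*% y))
  names(beta) <- colnames(X)
  resid <- y - drop(X %*% beta)
  quad <- drop(crossprod(resid, Ri %*% resid))
  df <- n - p
  sigma2 <- quad / df
  vc <- sigma2 * solve(A)
  se <- sqrt(diag(vc))
  stat <- beta / se
  pval <- 2 * pt(-abs(stat), df)
  structure(list(coefficients = beta, se = se, statistic = stat,
                 p.value = pval, sigma2 = sigma2, df = df, vcov = vc,
                 method = method, n = n, logLik_quad = quad,
                 r_fingerprint = if (is.null(R)) "identity" else
                   sprintf("%dx%d/sum=%.8g", nrow(R), ncol(R), sum(R))),
            class = "phylo_gls")
}

#' @export
print.phylo_gls <- function(x, ...) {
  cat(sprintf("Gaussian %s fit (n = %d, df = %d)\n", x$method, x$n, x$df))
  print(tidy(x))
  invisible(x)
}

#' @method tidy phylo_gls
#' @export
tidy.phylo_gls <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std.error = unname(x$se), statistic = unname(x$statistic),
         p.value = unname(x$p.value))
}

#' @method glance phylo_gls
#' @export
glance.phylo_gls <- function(x, ...) {
  tibble(nobs = x$n, df.residual = x$df, sigma = sqrt(x$sigma2),
         method = x$method)
}

#' Fit the three comparative recombination-rate models
#'
#' Fits, on one rate table: (1) the uncorrected Gaussian model of log rate on
#' He and life-form; (2) the phylogeny-corrected model using the tree-derived
#' correlation matrix; and (3) the phylogeny-corrected model with conifer
#' trees treated as a separate life-form. The tree must be ultrametric and
#' contain every species in the table.
#'
#' @param table A `rate_table`.
#' @param tree A calibrated (ultrametric) `phylo`; extra tips are pruned.
#' @return A list of class `rate_models` with elements `uncorrected`,
#'   `phylo1`, `phylo2` (each a `phylo_gls`). `tidy()` returns the
#'   coefficients of all three models in a long tibble.
#' @export
fit_rate_models <- function(table, tree) {
  missing <- setdiff(table$species, tree$tip.label)
  if (length(missing)) {
    abort(paste("species absent from tree:", paste(missing, collapse = ", ")))
  }
  tree <- ape::keep.tip(tree, table$species)
  R <- phylo_correlation(tree)
  R <- R[table$species, table$species]
  d1 <- build_design(table, conifer_separate = FALSE)
  d2 <- build_design(table, conifer_separate = TRUE)
  out <- list(
    uncorrected = fit_gaussian(d1$y, d1$X, NULL, method = "uncorrected"),
    phylo1 = fit_gaussian(d1$y, d1$X, R, method = "phylo_gee"),
    phylo2 = fit_gaussian(d2$y, d2$X, R, method = "phylo_gee")
  )
  class(out) <- "rate_models"
  out
}

#' @method tidy rate_models
#' @export
tidy.rate_models <- function(x, ...) {
  bind_rows(
    mutate(tidy(x$uncorrected), model = "uncorrected"),
    mutate(tidy(x$phylo1), model = "phylo1"),
    mutate(tidy(x$phylo2), model = "phylo2")
  )
}

#' @export
print.rate_models <- function(x, ...) {
  cat("Comparative models of log genome-wide recombination rate\n")
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    print(tidy(x[[nm]]))
  }
  invisible(x)
}

#' Fitted mean log recombination rate per life-form
#'
#' Combines the intercept with each life-form coefficient to give the fitted
#' mean log rate per life-form at the model's intercept scale (optionally at
#' a given He). Standard errors follow from the coefficient covariance by
#' the delta method: `SE^2 = var(b0) + var(bl) + 2 cov(b0, bl)`.
#'
#' @param fit A `phylo_gls` fit, or a named coefficient vector (names as in
#'   [build_design()]; standard errors are then `NA`).
#' @param at_He Optional He value at which to evaluate the mean (adds
#'   `at_He * beta_He`).
#' @return A tibble `(life_form, mean, se)` with the baseline (tree or
#'   angiosperm tree) first.
#' @export
fitted_group_means <- function(fit, at_He = NULL) {
  if (is.numeric(fit) && !is.null(names(fit))) {
    cf <- fit
    vc <- NULL
  } else if (inherits(fit, "phylo_gls")) {
    cf <- fit$coefficients
    vc <- fit$vcov
  } else {
    abort("fit must be a phylo_gls object or a named coefficient vector")
  }
  if (!"intercept" %in% names(cf)) abort("no intercept coefficient")
  levels <- setdiff(names(cf), c("intercept", "He"))
  base_label <- if ("conifer_tree" %in% levels) "angiosperm tree" else "tree"
  he_shift <- if (!is.null(at_He) && "He" %in% names(cf)) at_He * cf[["He"]] else 0
  rows <- lapply(c("(baseline)", levels), function(lv) {
    if (lv == "(baseline)") {
      m <- cf[["intercept"]] + he_shift
      v <- if (is.null(vc)) NA_real_ else vc["intercept", "intercept"]
      tibble(life_form = base_label, mean = m, se = sqrt(v))
    } else {
      if (!lv %in% names(cf)) abort(sprintf("unknown level '%s'", lv))
      m <- cf[["intercept"]] + cf[[lv]] + he_shift
      v <- if (is.null(vc)) NA_real_ else
        vc["intercept", "intercept"] + vc[lv, lv] + 2 * vc["intercept", lv]
      tibble(life_form = gsub("_", " ", lv), mean = m, se = sqrt(v))
    }
  })
  bind_rows(rows)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tidy wrapper around [stats::kruskal.test()] (tie-corrected H statistic,
#' chi-square approximation with k - 1 df), used to compare within-gene
#' recombination estimates across life-forms.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values` (>= 2 groups).
#' @return A one-row tibble `(statistic, df, p.value)`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) abort("need at least 2 groups")
  if (length(unique(values)) < 2) abort("all values identical")
  kt <- stats::kruskal.test(values, groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p.value = kt$p.value)
}
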