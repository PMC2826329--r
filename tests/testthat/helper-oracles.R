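# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force phylogenetic covariance: V[i, j] = sum of branch lengths on the
# path from the root to the MRCA of tips i and j, via parent pointers
brute_force_vcv <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  parent <- integer(n_all)
  elen <- numeric(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- ntip + 1L
  ancestors <- function(v) {
    path <- v
    while (v != root) { v <- parent[v]; path <- c(path, v) }
    path
  }
  depth_of <- function(v) {
    d <- 0
    while (v != root) { d <- d + elen[v]; v <- parent[v] }
    d
  }
  V <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  anc <- lapply(seq_len(ntip), ancestors)
  for (i in seq_len(ntip)) {
    for (j in i:ntip) {
      common <- intersect(anc[[i]], anc[[j]])
      mrca <- common[which.max(vapply(common, depth_of, numeric(1)))]
      V[i, j] <- V[j, i] <- depth_of(mrca)
    }
  }
  V
}

# GLS quadratic form (x - a)' V^-1 (x - a) with a the GLS mean, via solve()
gls_quadratic_form <- function(tree, x) {
  V <- ape::vcv(tree)
  x <- x[colnames(V)]
  Vi <- solve(V)
  a <- sum(Vi %*% x) / sum(Vi)
  drop(t(x - a) %*% Vi %*% (x - a))
}

# exhaustive Hudson-Kaplan oracle: minimum number of inter-site breakpoints
# hitting every four-gamete-incompatible open interval, by brute force over
# all subsets of the S - 1 inter-site gaps
rm_exhaustive_oracle <- function(geno, pos) {
  S <- ncol(geno)
  if (S < 2) return(0L)
  pairs <- list()
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      a <- geno[, i]; b <- geno[, j]
      if (any(a == 0 & b == 0) && any(a == 0 & b == 1) &&
          any(a == 1 & b == 0) && any(a == 1 & b == 1)) {
        pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
  }
  if (length(pairs) == 0) return(0L)
  gaps <- seq_len(S - 1)  # gap g sits strictly between site g and g + 1
  hits <- function(chosen) {
    all(vapply(pairs, function(p) any(chosen >= p[1] & chosen < p[2]), logical(1)))
  }
  for (k in seq_along(gaps)) {
    combos <- utils::combn(gaps, k)
    for (c in seq_len(ncol(combos))) {
      if (hits(combos[, c])) return(k)
    }
  }
  length(gaps)
}

# random binary SNP matrix wrapped as the package's snp_matrix structure
random_snp_matrix <- function(n, S, p = NULL) {
  if (is.null(p)) p <- runif(S, 0.1, 0.9)
  g <- sapply(seq_len(S), function(j) rbinom(n, 1, p[j]))
  g <- matrix(as.integer(g), n, S)
  keep <- colSums(g) > 0 & colSums(g) < n
  g <- g[, keep, drop = FALSE]
  structure(list(geno = g, positions = which(keep),
                 dropped = tibble::tibble(position = integer(), reason = character())),
            class = "snp_matrix")
}

random_trait <- function(tree) stats::setNames(stats::rnorm(ape::Ntip(tree)), tree$tip.label)

# canonical folded key of two-locus configurations (independent re-derivation
# of the 8-element symmetry group: relabel alleles at either locus, swap loci)
fold_keys_oracle <- function(parts) {
  apply(parts, 1, function(v) {
    m <- matrix(v, 2, 2, byrow = TRUE)  # rows = locus A alleles, cols = locus B
    images <- character(0)
    for (fa in 0:1) for (fb in 0:1) for (tp in 0:1) {
      mm <- m
      if (fa) mm <- mm[2:1, ]
      if (fb) mm <- mm[, 2:1]
      if (tp) mm <- t(mm)
      images <- c(images, sprintf("%03d.%03d.%03d.%03d",
                                  mm[1, 1], mm[1, 2], mm[2, 1], mm[2, 2]))
    }
    min(images)
  })
}
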