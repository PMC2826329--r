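#' Read a rooted phylogeny from a Newick string or file
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is an
#' ape `phylo` object, the container used throughout the package. Trees may
#' lack branch lengths (they can be assigned later by [bladj_calibrate()]),
#' but must be rooted, have unique tip labels and be non-empty. Polytomies are
#' accepted; algorithms that require a bifurcating tree resolve them
#' internally (see [pic_contrasts()]).
#'
#' @param x A Newick string (terminated by `;`) or the path to a file
#'   containing one.
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- read_tree_newick("((A:1,B:1):1,C:2);")
read_tree_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  if (file.exists(x) && !grepl(";", x)) {
    x <- paste(readLines(x, warn = FALSE), collapse = "")
  }
  x <- trimws(x)
  if (nchar(x) == 0 || identical(x, ";")) abort("empty Newick string")
  if (!grepl(";\\s*$", x)) abort("Newick string must be terminated by ';'")
  if (lengths(regmatches(x, gregexpr("\\(", x))) !=
      lengths(regmatches(x, gregexpr("\\)", x)))) {
    abort("unbalanced parentheses in Newick string")
  }
  tree <- tryCatch(ape::read.tree(text = x),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) abort("could not parse Newick string")
  validate_phylo(tree)
  tree
}

#' Write a phylogeny as a Newick string
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @param digits Number of significant digits for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_tree_newick <- function(tree, file = NULL, digits = 12) {
  validate_phylo(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a `phylo` object")
  if (ape::Ntip(tree) < 1) abort("empty tree")
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels")
  if (!is.null(tree$edge.length) && any(tree$edge.length < -1e-12)) {
    abort("negative branch lengths")
  }
  invisible(tree)
}

root_node <- function(tree) ape::Ntip(tree) + 1L

children_list <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2])
  }
  ch
}

# smallest tip label in the subtree of every node (used for deterministic
# tie-breaks); character vector indexed by node id
subtree_min_label <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  lab <- character(n_all)
  lab[seq_len(ntip)] <- tree$tip.label
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]; c <- po[i, 2]
    lab[p] <- if (lab[p] == "") lab[c] else min(lab[p], lab[c])
  }
  lab
}

#' Calibrate node ages by even interpolation between dated nodes
#'
#' Assigns an age (Myr before present) to every node of a rooted tree given
#' ages for a subset of nodes, in the manner of Phylocom's bladj: each maximal
#' chain of undated nodes between a dated ancestor and its nearest dated
#' descendant (fewest intervening undated nodes) receives evenly spaced ages
#' between the two. Tips default to age 0; the root age must be supplied.
#' Branch lengths of the returned tree are recomputed as parent age minus
#' child age, so the result is ultrametric whenever all constrained tips are
#' contemporaneous.
#'
#' When several dated descendants tie for nearest, the chain descends through
#' the child subtree containing the lexicographically smallest tip label, a
#' deterministic convention.
#'
#' @param tree A rooted `phylo`; internal nodes referenced by the constraints
#'   must carry labels (`tree$node.label`).
#' @param ages A two-column data frame `(label, age)` or a named numeric
#'   vector of ages in Myr; labels may name tips or internal nodes.
#' @return The tree with recomputed `edge.length` and a `node.ages` component
#'   (numeric vector over node ids).
#' @export
#' @examples
#' tr <- read_tree_newick("((A,B)ab,C)root;")
#' cal <- bladj_calibrate(tr, c(root = 10, ab = 4))
bladj_calibrate <- function(tree, ages) {
  validate_phylo(tree)
  if (is.data.frame(ages)) ages <- setNames(as.numeric(ages[[2]]), as.character(ages[[1]]))
  if (is.null(names(ages)) || any(names(ages) == "")) abort("ages must be labelled")
  if (any(ages < 0)) abort("ages must be >= 0")

  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  node_lab <- c(tree$tip.label,
                if (is.null(tree$node.label)) rep("", tree$Nnode) else tree$node.label)
  age <- rep(NA_real_, n_all)
  age[seq_len(ntip)] <- 0

  for (i in seq_along(ages)) {
    id <- which(node_lab == names(ages)[i])
    if (length(id) == 0) abort(sprintf("constrained label '%s' not in tree", names(ages)[i]))
    if (length(id) > 1) abort(sprintf("label '%s' is not unique", names(ages)[i]))
    age[id] <- ages[i]
  }

  root <- root_node(tree)
  if (is.na(age[root])) abort("root age must be constrained")

  parent <- integer(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent[root] <- root  # self-parent keeps vectorized indexing aligned

  # dated ancestors must be strictly older than dated descendants
  po <- ape::reorder.phylo(tree, "postorder")$edge
  cw <- ape::reorder.phylo(tree, "cladewise")$edge
  pre_nodes <- c(root, cw[, 2])  # parents before children
  anc_age <- rep(NA_real_, n_all)
  anc_age[root] <- Inf
  for (v in pre_nodes) {
    if (v == root) next
    p <- parent[v]
    nearest <- if (is.na(age[p])) anc_age[p] else age[p]
    anc_age[v] <- nearest
    if (!is.na(age[v]) && age[v] >= nearest) {
      abort(sprintf("age constraint inversion at node '%s' (%g >= ancestor %g)",
                    node_lab[v], age[v], nearest))
    }
  }

  internals_post <- unique(po[, 1])
  minlab <- subtree_min_label(tree)
  ch <- children_list(tree)

  repeat {
    und <- which(is.na(age))
    if (length(und) == 0) break
    # distance (intervening undated nodes) to the nearest dated descendant,
    # and the child chosen to reach it
    k <- rep(NA_real_, n_all)
    choice <- rep(NA_integer_, n_all)
    for (v in internals_post) {
      if (!is.na(age[v])) next
      cost <- vapply(ch[[v]], function(c) if (!is.na(age[c])) 0 else 1 + k[c], numeric(1))
      ord <- order(cost, vapply(ch[[v]], function(c) minlab[c], character(1)))
      k[v] <- cost[ord[1]]
      choice[v] <- ch[[v]][ord[1]]
    }
    # first undated node (preorder) whose parent is dated starts a chain
    u0 <- pre_nodes[which(is.na(age[pre_nodes]) & !is.na(age[parent[pre_nodes]]))[1]]
    chain <- u0
    w <- choice[u0]
    while (is.na(age[w])) {
      chain <- c(chain, w)
      w <- choice[w]
    }
    tA <- age[parent[u0]]
    tD <- age[w]
    m <- length(chain)
    age[chain] <- tA - seq_len(m) * (tA - tD) / (m + 1)
  }

  el <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  if (any(el < 0)) abort("calibration produced a negative branch length")
  tree$edge.length <- el
  tree$node.ages <- age
  tree
}

#' Phylogenetic covariance and correlation matrices
#'
#' `phylo_covariance()` returns the tip-by-tip covariance matrix `V` implied
#' by a tree with branch lengths: `V[i, j]` is the depth (shared path length
#' from the root) of the most recent common ancestor of tips `i` and `j`, and
#' `diag(V)` holds root-to-tip depths. `phylo_correlation()` scales `V` by the
#' (common) root-to-tip depth, which requires an ultrametric tree; it is the
#' "correlating matrix" used by the phylogeny-corrected regressions.
#'
#' @param tree A `phylo` with branch lengths.
#' @param tol Relative spread of root-to-tip depths tolerated before the tree
#'   is declared non-ultrametric (default `1e-6`).
#' @return A square numeric matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_phylo(tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  ape::vcv(tree)
}

#' @rdname phylo_covariance
#' @export
phylo_correlation <- function(tree, tol = 1e-6) {
  V <- phylo_covariance(tree)
  d <- diag(V)
  if ((max(d) - min(d)) / max(d) > tol) {
    abort("tree is not ultrametric: root-to-tip depths differ beyond tolerance")
  }
  R <- stats::cov2cor(V)
  dimnames(R) <- dimnames(V)
  R
}
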