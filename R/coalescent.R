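#' Coalescent haplotypes with recombination (ancestral recombination graph)
#'
#' Simulates a sample of `n` haplotypes under the neutral coalescent with
#' recombination, backward in time: coalescence at rate `k(k-1)/2` among the
#' `k` active lineages; recombination at rate `rho/2` per unit of ancestral
#' span (breakpoints uniform within a lineage's ancestral span, material
#' outside ancestral segments is not tracked, as in ms); infinite-sites
#' mutations at rate `theta/2` per unit branch length on segregating
#' ancestral material. Mutation positions on the unit interval are mapped to
#' distinct integer base pairs in `1..L` (collisions resampled). Segments
#' whose descendant set reaches the full sample have found their MRCA and
#' are dropped; the simulation ends when no ancestral material remains.
#'
#' With `rho = 0` the sample evolves on a single marginal genealogy, so no
#' pair of sites can show all four gametes and [rm_hudson_kaplan()] is 0 on
#' every output.
#'
#' @param n Number of haplotypes (>= 2).
#' @param theta Population-scaled mutation rate for the whole locus (4 Ne mu).
#' @param rho Population-scaled recombination rate for the whole locus (4 Ne r).
#' @param L Physical length in bp onto which mutations are mapped.
#' @param seed Integer seed.
#' @param full_alignment When `TRUE` (default) the returned alignment has all
#'   `L` columns with monomorphic reference bases between the variable sites
#'   (what the gene-wise pipeline reads); when `FALSE` only the polymorphic
#'   columns are returned, with `positions` holding their bp coordinates
#'   (lighter, for simulation studies of the summary statistics).
#' @return A [haplotype_alignment()]; the `"truth"` attribute records
#'   `(theta, rho, L, S)`.
#' @export
sim_coalescent <- function(n, theta, rho = 0, L = 10000, seed = NULL,
                           full_alignment = TRUE) {
  if (n < 2) abort("n must be at least 2")
  if (theta < 0 || rho < 0) abort("theta and rho must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  # lineage: list(a = starts, b = ends, sets = list of integer id vectors)
  lineages <- lapply(seq_len(n), function(i) list(a = 0, b = 1, sets = list(i)))
  mut_pos <- numeric(0)
  mut_sets <- list()

  total_len <- function(l) sum(l$b - l$a)
  span <- function(l) max(l$b) - min(l$a)

  merge_lineages <- function(l1, l2) {
    bp <- sort(unique(c(l1$a, l1$b, l2$a, l2$b)))
    a_out <- numeric(0); b_out <- numeric(0); sets_out <- list()
    for (i in seq_len(length(bp) - 1)) {
      lo <- bp[i]; hi <- bp[i + 1]
      mid <- (lo + hi) / 2
      s1 <- which(l1$a <= lo & l1$b >= hi)
      s2 <- which(l2$a <= lo & l2$b >= hi)
      if (length(s1) == 0 && length(s2) == 0) next
      members <- sort(unique(c(
        if (length(s1)) l1$sets[[s1[1]]] else integer(0),
        if (length(s2)) l2$sets[[s2[1]]] else integer(0)
      )))
      if (length(members) == n) next  # MRCA reached for this stretch
      m <- length(a_out)
      if (m > 0 && b_out[m] == lo && identical(sets_out[[m]], members)) {
        b_out[m] <- hi  # coalesce adjacent equal-set segments
      } else {
        a_out <- c(a_out, lo); b_out <- c(b_out, hi)
        sets_out[[m + 1]] <- members
      }
    }
    if (length(a_out) == 0) return(NULL)
    list(a = a_out, b = b_out, sets = sets_out)
  }

  while (length(lineages) >= 2) {
    k <- length(lineages)
    spans <- vapply(lineages, span, numeric(1))
    lens <- vapply(lineages, total_len, numeric(1))
    cr <- k * (k - 1) / 2
    rr <- rho / 2 * sum(spans)
    tot <- cr + rr
    dt <- rexp(1, tot)

    # mutations over this interval
    lam <- theta / 2 * dt * sum(lens)
    if (lam > 0) {
      n_mut <- rpois(1, lam)
      if (n_mut > 0) {
        who <- sample.int(k, n_mut, replace = TRUE, prob = lens)
        for (w in who) {
          l <- lineages[[w]]
          seg_len <- l$b - l$a
          s <- sample.int(length(seg_len), 1, prob = seg_len)
          mut_pos <- c(mut_pos, runif(1, l$a[s], l$b[s]))
          mut_sets[[length(mut_sets) + 1]] <- l$sets[[s]]
        }
      }
    }

    if (runif(1) * tot < cr) {
      pair <- sample.int(k, 2)
      merged <- merge_lineages(lineages[[pair[1]]], lineages[[pair[2]]])
      lineages[c(pair[1], pair[2])] <- NULL
      if (!is.null(merged)) lineages[[length(lineages) + 1]] <- merged
    } else {
      w <- sample.int(k, 1, prob = spans)
      l <- lineages[[w]]
      u <- runif(1, min(l$a), max(l$b))
      left_idx <- which(l$a < u)
      right_idx <- which(l$b > u)
      left <- list(a = l$a[left_idx], b = pmin(l$b[left_idx], u),
                   sets = l$sets[left_idx])
      right <- list(a = pmax(l$a[right_idx], u), b = l$b[right_idx],
                    sets = l$sets[right_idx])
      if (length(left$a) > 0 && length(right$a) > 0) {
        lineages[[w]] <- left
        lineages[[length(lineages) + 1]] <- right
      }
      # u outside all material on one side: event has no effect
    }
  }

  S <- length(mut_pos)
  labels <- sprintf("hap%02d", seq_len(n))
  bases <- c("A", "C", "G", "T")

  # map unit-interval positions to distinct integer bp (resample collisions)
  bp <- as.integer(ceiling(mut_pos * L))
  bp[bp < 1] <- 1L
  while (anyDuplicated(bp)) {
    dup <- duplicated(bp)
    bp[dup] <- sample.int(L, sum(dup), replace = TRUE)
  }
  ord <- order(bp)
  bp <- bp[ord]
  mut_sets <- mut_sets[ord]

  if (full_alignment) {
    ref <- sample(bases, L, replace = TRUE)
    seqs <- matrix(rep(ref, each = n), n, L, dimnames = list(labels, NULL))
    for (j in seq_len(S)) {
      alt <- sample(setdiff(bases, ref[bp[j]]), 1)
      seqs[mut_sets[[j]], bp[j]] <- alt
    }
    aln <- haplotype_alignment(seqs)
  } else {
    if (S == 0) {
      seqs <- matrix(rep(sample(bases, 1), n), n, 1, dimnames = list(labels, NULL))
      aln <- haplotype_alignment(seqs, positions = 1L)
    } else {
      ref <- sample(bases, S, replace = TRUE)
      seqs <- matrix(rep(ref, each = n), n, S, dimnames = list(labels, NULL))
      for (j in seq_len(S)) {
        alt <- sample(setdiff(bases, ref[j]), 1)
        seqs[mut_sets[[j]], j] <- alt
      }
      aln <- haplotype_alignment(seqs, positions = bp)
    }
  }
  attr(aln, "truth") <- list(theta = theta, rho = rho, L = L, S = S)
  aln
}
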