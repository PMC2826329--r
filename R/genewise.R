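#' Haplotype alignments
#'
#' A `haplotype_alignment` holds `n` phased haplotype sequences of equal
#' aligned length `L` as an upper-case character matrix (rows = haplotypes,
#' columns = alignment positions), with unique row labels and 1-based
#' physical positions (defaulting to column indices).
#'
#' @param seqs Character matrix of single characters, or a character vector
#'   of equal-length strings.
#' @param labels Row labels (unique); defaults to existing rownames.
#' @param positions Physical positions of the columns.
#' @return An object of class `haplotype_alignment`.
#' @export
haplotype_alignment <- function(seqs, labels = NULL, positions = NULL) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) abort("sequences differ in length")
    seqs <- do.call(rbind, strsplit(seqs, ""))
  }
  seqs <- toupper(seqs)
  if (!is.null(labels)) rownames(seqs) <- labels
  if (is.null(rownames(seqs))) rownames(seqs) <- paste0("hap", seq_len(nrow(seqs)))
  if (anyDuplicated(rownames(seqs))) abort("duplicate sequence labels")
  if (nrow(seqs) < 2) abort("need at least 2 sequences")
  if (is.null(positions)) positions <- seq_len(ncol(seqs))
  if (length(positions) != ncol(seqs)) abort("positions do not match alignment length")
  structure(list(seqs = seqs, positions = positions),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("haplotype_alignment: %d haplotypes x %d columns\n",
              nrow(x$seqs), ncol(x$seqs)))
  invisible(x)
}

#' Read a haplotype alignment from a FASTA file
#'
#' @param path Path to an aligned FASTA file of phased haplotypes.
#' @return A [haplotype_alignment()]. Mixed-case bases are normalized to
#'   upper case; sequences of unequal length or duplicate labels are errors.
#' @export
read_haplotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) abort("empty FASTA file")
  lens <- lengths(dna)
  if (length(unique(lens)) != 1) abort("sequences differ in length")
  mat <- toupper(do.call(rbind, as.character(dna)))
  rownames(mat) <- names(dna)
  haplotype_alignment(mat)
}

#' Write a haplotype alignment to FASTA
#'
#' @param aln A `haplotype_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(aln, path) {
  lines <- character(2 * nrow(aln$seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln$seqs))
  lines[c(FALSE, TRUE)] <- apply(aln$seqs, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Extract the biallelic SNP matrix of an alignment
#'
#' Columns are screened in order: columns containing a gap (`-`) or ambiguous
#' base (`N`, `?`) are dropped (reason `"indel"`), monomorphic columns are
#' dropped (`"monomorphic"`), columns with more than two states are dropped
#' (`">2 states"`), and, when `informative_only = TRUE`, singleton columns
#' whose minor allele occurs once are dropped (`"singleton"`), leaving only
#' parsimony-informative sites. Retained columns are encoded 0 for the major
#' allele (ties broken by first occurrence in the column) and 1 for the
#' minor allele.
#'
#' @param aln A `haplotype_alignment`.
#' @param informative_only Keep only parsimony-informative sites?
#' @return An object of class `snp_matrix`: a list with `geno` (n x S 0/1
#'   integer matrix), `positions` (physical positions of retained columns)
#'   and `dropped` (tibble of position and reason per dropped column). An
#'   empty matrix is allowed.
#' @export
filter_sites <- function(aln, informative_only = FALSE) {
  seqs <- aln$seqs
  n <- nrow(seqs)
  keep <- logical(ncol(seqs))
  reason <- character(ncol(seqs))
  geno <- matrix(0L, n, 0)
  cols <- list()
  for (j in seq_len(ncol(seqs))) {
    col <- seqs[, j]
    if (any(col %in% c("-", "N", "?"))) { reason[j] <- "indel"; next }
    alleles <- unique(col)
    if (length(alleles) == 1) { reason[j] <- "monomorphic"; next }
    if (length(alleles) > 2) { reason[j] <- ">2 states"; next }
    counts <- c(sum(col == alleles[1]), sum(col == alleles[2]))
    major <- if (counts[2] > counts[1]) alleles[2] else alleles[1]
    g <- as.integer(col != major)
    if (informative_only && sum(g) < 2) { reason[j] <- "singleton"; next }
    keep[j] <- TRUE
    cols[[length(cols) + 1]] <- g
  }
  geno <- if (length(cols)) do.call(cbind, cols) else matrix(0L, n, 0)
  rownames(geno) <- rownames(seqs)
  structure(list(geno = geno,
                 positions = aln$positions[keep],
                 dropped = tibble(position = aln$positions[!keep],
                                  reason = reason[!keep])),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d haplotypes x %d biallelic sites (%d columns dropped)\n",
              nrow(x$geno), ncol(x$geno), nrow(x$dropped)))
  invisible(x)
}

#' Eligibility of a gene for recombination estimation
#'
#' A gene enters the within-gene survey only when its alignment spans at
#' least 800 bp, shows at least 10 segregating sites, and was sampled for
#' more than 20 chromosomes (strictly; 20 does not qualify).
#'
#' @param aln A `haplotype_alignment`.
#' @param S Number of segregating (biallelic, gap-free) sites.
#' @param min_length,min_segsites,min_chromosomes Filter thresholds.
#' @return A one-row tibble `(eligible, n, L, S, reasons)` where `reasons`
#'   is a comma-joined string of violated rules (empty when eligible).
#' @export
check_eligibility <- function(aln, S, min_length = 800, min_segsites = 10,
                              min_chromosomes = 20) {
  n <- nrow(aln$seqs)
  L <- ncol(aln$seqs)
  reasons <- c(
    if (L < min_length) "length",
    if (S < min_segsites) "segregating sites",
    if (n <= min_chromosomes) "chromosomes"
  )
  tibble(eligible = length(reasons) == 0, n = n, L = L, S = S,
         reasons = paste(reasons, collapse = ","))
}

#' Per-site nucleotide diversity and Watterson's theta
#'
#' From a binary SNP matrix: `theta_pi` is the average number of pairwise
#' nucleotide differences per site, `sum(2 p (1 - p)) * n / (n - 1) / L`
#' over segregating sites with allele frequency `p`; `theta_w` is Watterson's
#' estimator `S / (a_n L)` with `a_n = sum(1/i, i = 1..n-1)`.
#'
#' @param snp A `snp_matrix`.
#' @param L Alignment length in bp over which the per-site values are scaled.
#' @return A one-row tibble `(S, theta_pi, theta_w)`.
#' @export
diversity_stats <- function(snp, L) {
  if (L <= 0) abort("L must be positive")
  g <- snp$geno
  n <- nrow(g)
  if (n < 2) abort("need at least 2 haplotypes")
  S <- ncol(g)
  if (S == 0) return(tibble(S = 0L, theta_pi = 0, theta_w = 0))
  p <- colMeans(g)
  theta_pi <- sum(2 * p * (1 - p)) * n / (n - 1) / L
  a_n <- sum(1 / seq_len(n - 1))
  tibble(S = S, theta_pi = theta_pi, theta_w = S / (a_n * L))
}

# incompatible site pairs by the four-gamete test; returns a two-column
# matrix of position indices (i < j, in column order)
four_gamete_pairs <- function(geno) {
  S <- ncol(geno)
  if (S < 2) return(matrix(0L, 0, 2))
  G <- geno
  n11 <- crossprod(G)
  n10 <- crossprod(G, 1 - G)
  n01 <- t(n10)
  n00 <- crossprod(1 - G)
  bad <- n11 > 0 & n10 > 0 & n01 > 0 & n00 > 0
  bad[lower.tri(bad, diag = TRUE)] <- FALSE
  which(bad, arr.ind = TRUE)
}

#' Hudson-Kaplan minimum number of recombination events (Rm)
#'
#' Every pair of biallelic sites exhibiting all four gametes (00, 01, 10, 11)
#' requires at least one recombination event strictly between them under the
#' infinite-sites model. Incompatible pairs define open intervals; intervals
#' that contain another incompatible interval are redundant and removed; the
#' remaining intervals are scanned left to right, greedily selecting disjoint
#' ones (intervals sharing an endpoint count as disjoint, since events fall
#' strictly between sites). Rm is the number selected -- the minimum number
#' of recombination events compatible with the sample.
#'
#' @param snp A `snp_matrix` with columns ordered by position.
#' @return The Rm count (0 for fewer than 2 segregating sites).
#' @export
rm_hudson_kaplan <- function(snp) {
  pos <- snp$positions
  pr <- four_gamete_pairs(snp$geno)
  if (nrow(pr) == 0) return(0L)
  iv <- cbind(pos[pr[, 1]], pos[pr[, 2]])
  # remove intervals containing another incompatible interval
  minimal <- rep(TRUE, nrow(iv))
  for (k in seq_len(nrow(iv))) {
    contains <- iv[, 1] >= iv[k, 1] & iv[, 2] <= iv[k, 2] &
      (iv[, 1] > iv[k, 1] | iv[, 2] < iv[k, 2])
    if (any(contains)) minimal[k] <- FALSE
  }
  iv <- iv[minimal, , drop = FALSE]
  iv <- iv[order(iv[, 2], iv[, 1]), , drop = FALSE]
  rm_count <- 0L
  last_right <- -Inf
  for (k in seq_len(nrow(iv))) {
    if (iv[k, 1] >= last_right) {
      rm_count <- rm_count + 1L
      last_right <- iv[k, 2]
    }
  }
  rm_count
}
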