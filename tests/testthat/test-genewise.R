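aln_from_strings <- function(x, labels = NULL) {
  haplotype_alignment(x, labels = labels %||% paste0("h", seq_along(x)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("FASTA round trip preserves the alignment and normalizes case", {
  aln <- aln_from_strings(c("ACGTACGTAC", "acgtacgtat"))
  expect_equal(nrow(aln$seqs), 2)
  expect_equal(ncol(aln$seqs), 10)
  expect_true(all(aln$seqs %in% c("A", "C", "G", "T")))

  path <- withr::local_tempfile(fileext = ".fa")
  write_haplotypes(aln, path)
  back <- read_haplotypes(path)
  expect_equal(back$seqs, aln$seqs)

  expect_error(aln_from_strings(c("ACGTACGTAC", "ACGTACGTA")), "length")
  expect_error(haplotype_alignment(c("ACGT", "ACGA"), labels = c("a", "a")),
               "duplicate")
  expect_error(read_haplotypes(withr::local_tempfile(fileext = ".fa")),
               "not found")
})

test_that("site filtering drops indels, multistate and singleton columns", {
  #            12345
  aln <- aln_from_strings(c("AA-CA",
                            "AACCA",
                            "TACGT",
                            "TACAT"))
  snp <- filter_sites(aln)
  # col1 A/A/T/T kept; col2 monomorphic; col3 gap; col4 >2 states; col5 kept
  expect_equal(snp$positions, c(1L, 5L))
  expect_equal(snp$geno[, 1], c(0L, 0L, 1L, 1L), ignore_attr = TRUE)
  expect_setequal(snp$dropped$reason, c("monomorphic", "indel", ">2 states"))
  expect_equal(snp$dropped$reason[snp$dropped$position == 3], "indel")
  expect_equal(snp$dropped$reason[snp$dropped$position == 4], ">2 states")

  # tie on allele counts: first-occurring allele is the 0-coded major
  tie <- filter_sites(aln_from_strings(c("T", "T", "A", "A")))
  expect_equal(tie$geno[, 1], c(0L, 0L, 1L, 1L), ignore_attr = TRUE)

  # singleton columns survive the default filter but not informative_only
  aln2 <- aln_from_strings(c("AT", "AT", "AT", "CA"))
  expect_equal(ncol(filter_sites(aln2)$geno), 2)
  inf <- filter_sites(aln2, informative_only = TRUE)
  expect_equal(ncol(inf$geno), 0)
  expect_true(all(inf$dropped$reason == "singleton"))
})

test_that("gene eligibility applies the length, S and chromosome rules strictly", {
  fake_aln <- function(n, L) {
    structure(list(seqs = matrix("A", n, L), positions = seq_len(L)),
              class = "haplotype_alignment")
  }
  e1 <- check_eligibility(fake_aln(30, 799), S = 15)
  expect_false(e1$eligible)
  expect_match(e1$reasons, "length")
  e2 <- check_eligibility(fake_aln(30, 1000), S = 9)
  expect_false(e2$eligible)
  expect_match(e2$reasons, "segregating")
  e3 <- check_eligibility(fake_aln(20, 1000), S = 12)
  expect_false(e3$eligible)
  expect_match(e3$reasons, "chromosomes")
  expect_true(check_eligibility(fake_aln(21, 800), S = 10)$eligible)
})

test_that("diversity estimators match closed-form arithmetic", {
  aln <- aln_from_strings(c(strrep("A", 100),
                            paste0(strrep("A", 99), "T")))
  d <- diversity_stats(filter_sites(aln), L = 100)
  expect_equal(d$theta_pi, 0.01)
  expect_equal(d$theta_w, 0.01)
  expect_equal(d$S, 1L)

  same <- aln_from_strings(rep(strrep("ACGT", 25), 3))
  d0 <- diversity_stats(filter_sites(same), L = 100)
  expect_equal(unlist(d0), c(S = 0, theta_pi = 0, theta_w = 0))

  # Watterson: S = 10, n = 11, L = 1000 -> 10 / (sum(1/1..1/10) * 1000)
  set.seed(2)
  g <- matrix(0L, 11, 10)
  for (j in 1:10) g[sample(11, sample(2:9, 1)), j] <- 1L
  snp <- structure(list(geno = g, positions = 1:10,
                        dropped = tibble::tibble()), class = "snp_matrix")
  d2 <- diversity_stats(snp, L = 1000)
  harmonic <- sum(1 / 1:10)
  expect_equal(d2$theta_w, 10 / (harmonic * 1000), tolerance = 1e-7)
  expect_equal(round(harmonic, 6), 2.928968)

  # theta_pi never exceeds S/L; invariant to row order and allele relabelling
  for (rep in 1:10) {
    snp_r <- random_snp_matrix(8, 12)
    d3 <- diversity_stats(snp_r, L = 50)
    expect_lte(d3$theta_pi, d3$S / 50 + 1e-12)
    perm <- snp_r; perm$geno <- perm$geno[sample(nrow(perm$geno)), , drop = FALSE]
    expect_equal(diversity_stats(perm, 50), d3)
    flip <- snp_r; flip$geno <- 1L - flip$geno
    expect_equal(diversity_stats(flip, 50), d3)
  }
})

test_that("Rm detects four-gamete incompatibilities", {
  # perfect tree-like data: no incompatible pair
  aln <- aln_from_strings(c("AAAA", "AATT", "TTAA", "TTAA"))
  expect_equal(rm_hudson_kaplan(filter_sites(aln)), 0L)

  # the canonical all-four-gametes pair
  aln2 <- aln_from_strings(c("AA", "AT", "TA", "TT"))
  expect_equal(rm_hudson_kaplan(filter_sites(aln2)), 1L)
})

test_that("greedy Rm equals the exhaustive minimum-breakpoint oracle", {
  set.seed(61)
  checked <- 0
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    S <- sample(2:10, 1)
    snp <- random_snp_matrix(n, S)
    if (ncol(snp$geno) < 2) next
    checked <- checked + 1
    expect_identical(as.integer(rm_hudson_kaplan(snp)),
                     as.integer(rm_exhaustive_oracle(snp$geno, snp$positions)))
  }
  expect_gt(checked, 150)
})

test_that("two-locus table respects its structural contracts", {
  tab <- two_locus_table(8, rho_grid = c(0, 1, 10), mc_reps = 10000, seed = 5)
  parts <- do.call(rbind, lapply(strsplit(rownames(tab$probs), ".", fixed = TRUE),
                                 as.integer))
  expect_true(all(rowSums(parts) == 8))
  # every probability column sums to one
  expect_equal(unname(colSums(tab$probs)), rep(1, 3))
  # no recombination: configurations with all four gametes are impossible
  fourg <- rowSums(parts > 0) == 4
  expect_equal(sum(tab$probs[fourg, "0"]), 0)
  expect_gt(sum(tab$probs[fourg, "10"]), 0)
  # keys are canonical under the 8-fold symmetry group
  keys <- rownames(tab$probs)
  sym <- fold_keys_oracle(parts)
  expect_identical(keys, sym)

  expect_error(two_locus_table(8, rho_grid = c(1, 10)), "include 0")
  expect_error(two_locus_table(8, mc_reps = 100), "10000")
})

test_that("two independent table builds agree within Monte-Carlo error", {
  tab1 <- two_locus_table(10, rho_grid = c(0, 10), mc_reps = 10000, seed = 1)
  tab2 <- two_locus_table(10, rho_grid = c(0, 10), mc_reps = 10000, seed = 2)
  keys <- union(rownames(tab1$probs), rownames(tab2$probs))
  get <- function(tab, k, col) ifelse(k %in% rownames(tab$probs), tab$probs[k, col], 0)
  for (col in c("0", "10")) {
    p1 <- vapply(keys, get, numeric(1), tab = tab1, col = col)
    p2 <- vapply(keys, get, numeric(1), tab = tab2, col = col)
    se <- sqrt((p1 + p2) / 2 * (1 - (p1 + p2) / 2) * 2 / 10000)
    big <- (p1 + p2) / 2 > 0.005  # cells with enough mass to compare
    expect_true(all(abs(p1 - p2)[big] <= 3 * se[big] + 1e-9))
  }
})

test_that("composite rho is zero under perfect LD and scales as a ratio", {
  tab <- two_locus_table(10, rho_grid = c(0, 1, 10, 50), mc_reps = 10000, seed = 9)
  # two identical columns: complete linkage disequilibrium
  g <- matrix(0L, 10, 2)
  g[1:4, ] <- 1L
  snp <- structure(list(geno = g, positions = c(100L, 700L),
                        dropped = tibble::tibble()), class = "snp_matrix")
  res <- composite_rho(snp, tab)
  expect_equal(res$rho_hat, 0)
  expect_equal(res$n_pairs, 1)

  res2 <- composite_rho(snp, tab, theta_w_gene = 4)
  expect_equal(res2$rho_over_theta, res2$rho_hat / 4)

  expect_error(composite_rho(snp, two_locus_table(8, mc_reps = 10000, seed = 1)),
               "sample size")
  one <- snp; one$geno <- g[, 1, drop = FALSE]; one$positions <- 100L
  expect_error(composite_rho(one, tab), "at least 2")
})
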