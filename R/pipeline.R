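#' Diversity and recombination statistics for one gene
#'
#' Computes, from a haplotype alignment: the segregating-site count and
#' per-site diversity (theta-pi and Watterson's theta-W) on all biallelic
#' gap-free sites; the Hudson-Kaplan minimum number of recombination events
#' and (when a two-locus table is supplied) the composite-likelihood rho on
#' parsimony-informative sites only, with indels and more-than-two-state
#' polymorphisms disregarded; and the eligibility of the gene for the
#' within-gene survey. The `rho_over_theta` ratio uses the per-gene
#' Watterson theta from all segregating sites.
#'
#' @param aln A `haplotype_alignment`.
#' @param table Optional [two_locus_table()] matching the sample size.
#' @param gene Optional gene label carried into the output.
#' @return A one-row tibble: `gene`, `n`, `L`, `S`, `theta_pi`, `theta_w`,
#'   `Rm`, `rho_hat`, `rho_over_theta`, `eligible`, `reasons`.
#' @export
gene_stats <- function(aln, table = NULL, gene = NA_character_) {
  n <- nrow(aln$seqs)
  L <- ncol(aln$seqs)
  snp_all <- filter_sites(aln, informative_only = FALSE)
  div <- diversity_stats(snp_all, L = L)
  elig <- check_eligibility(aln, S = div$S)
  snp_inf <- filter_sites(aln, informative_only = TRUE)
  rm_count <- rm_hudson_kaplan(snp_inf)
  rho_hat <- NA_real_; rho_ratio <- NA_real_
  if (!is.null(table) && ncol(snp_inf$geno) >= 2) {
    a_n <- sum(1 / seq_len(n - 1))
    cr <- composite_rho(snp_inf, table, theta_w_gene = div$S / a_n)
    rho_hat <- cr$rho_hat; rho_ratio <- cr$rho_over_theta
  }
  tibble(gene = gene, n = n, L = L, S = div$S,
         theta_pi = div$theta_pi, theta_w = div$theta_w,
         Rm = rm_count, rho_hat = rho_hat, rho_over_theta = rho_ratio,
         eligible = elig$eligible, reasons = elig$reasons)
}

#' Within-gene recombination survey over a set of genes
#'
#' Applies the gene eligibility filters (>= 800 bp, >= 10 segregating sites,
#' > 20 chromosomes), computes diversity and recombination statistics for
#' every eligible gene, and, when life-form labels are provided, compares
#' each recombination estimate across life-forms with a Kruskal-Wallis test.
#' Two-locus lookup tables are built once per distinct sample size.
#'
#' @param genes A named list of `haplotype_alignment` objects, or a character
#'   vector of FASTA paths (or a directory of `.fa`/`.fasta` files).
#' @param life_forms Optional data frame `(gene, life_form)`.
#' @param rho_grid,mc_reps Passed to [two_locus_table()].
#' @param estimate_rho Compute the composite-likelihood rho? (Disable for a
#'   quick diversity-only pass.)
#' @param seed Integer seed for the Monte-Carlo tables.
#' @return A list of class `genewise_report`: `stats` (eligible genes),
#'   `excluded` (gene, reasons), `kruskal` (one row per statistic tested
#'   across life-forms, or `NULL`).
#' @export
run_genewise <- function(genes, life_forms = NULL,
                         rho_grid = c(0, 0.5, 1, 2, 5, 10, 20, 50, 100),
                         mc_reps = 10000, estimate_rho = TRUE, seed = NULL) {
  if (is.character(genes)) {
    if (length(genes) == 1 && dir.exists(genes)) {
      genes <- list.files(genes, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    }
    if (length(genes) == 0) abort("no FASTA files found")
    paths <- genes
    genes <- lapply(paths, read_haplotypes)
    names(genes) <- sub("\\.(fa|fasta)$", "", basename(paths))
  }
  if (is.null(names(genes))) names(genes) <- paste0("gene", seq_along(genes))

  pre <- bind_rows(lapply(names(genes), function(g) {
    aln <- genes[[g]]
    snp_all <- filter_sites(aln)
    el <- check_eligibility(aln, S = ncol(snp_all$geno))
    mutate(el, gene = g)
  }))
  eligible_genes <- pre$gene[pre$eligible]
  excluded <- select(filter(pre, !.data$eligible), "gene", "reasons")

  tables <- list()
  if (estimate_rho && length(eligible_genes) > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (nn in unique(pre$n[pre$eligible])) {
      tables[[as.character(nn)]] <-
        two_locus_table(nn, rho_grid = rho_grid, mc_reps = mc_reps)
    }
  }

  stats <- bind_rows(lapply(eligible_genes, function(g) {
    aln <- genes[[g]]
    tb <- if (estimate_rho) tables[[as.character(nrow(aln$seqs))]] else NULL
    gene_stats(aln, table = tb, gene = g)
  }))

  kruskal <- NULL
  if (!is.null(life_forms) && nrow(stats) > 0) {
    stats <- left_join(stats, as_tibble(life_forms), by = "gene")
    test_cols <- c("Rm", "rho_hat", "rho_over_theta", "theta_pi")
    kruskal <- bind_rows(lapply(test_cols, function(cl) {
      v <- stats[[cl]]
      ok <- !is.na(v)
      if (sum(ok) < 3 || length(unique(stats$life_form[ok])) < 2 ||
          length(unique(v[ok])) < 2) return(NULL)
      mutate(kruskal_wallis(v[ok], stats$life_form[ok]), statistic_name = cl)
    }))
  }
  structure(list(stats = stats, excluded = excluded, kruskal = kruskal),
            class = "genewise_report")
}

#' @export
print.genewise_report <- function(x, ...) {
  cat(sprintf("Within-gene recombination survey: %d eligible, %d excluded\n",
              nrow(x$stats), nrow(x$excluded)))
  if (nrow(x$stats)) print(x$stats)
  if (!is.null(x$kruskal) && nrow(x$kruskal)) {
    cat("Kruskal-Wallis across life-forms:\n")
    print(x$kruskal)
  }
  invisible(x)
}

#' Run the full comparative analysis of genome-wide recombination rates
#'
#' End-to-end pipeline: assemble the rate table with its inclusion filters;
#' prune the phylogeny to the retained species (species present in the table
#' but absent from the tree abort the run); optionally calibrate node ages;
#' test for phylogenetic signal in log rate; correlate the independent
#' contrasts of log rate and He; and fit the three comparative models
#' (uncorrected, phylogeny-corrected, phylogeny-corrected with conifer trees
#' separate). Identical inputs and seed reproduce the report exactly.
#'
#' @param species_table Species records (see [build_rate_table()]).
#' @param tree A rooted `phylo` containing all table species; extra tips are
#'   pruned (and logged in the report).
#' @param ages Optional age constraints for [bladj_calibrate()] (applied
#'   after pruning; the tree must then carry node labels).
#' @param n_perm Permutations for the signal test.
#' @param seed Integer seed (signal-test reshuffles).
#' @return A list of class `analysis_report`: `rate_table`, `exclusions`,
#'   `pruned_tips`, `signal` (log rate), `signal_he`, `pic_cor` (contrast
#'   correlation of log rate vs He), `models` (a `rate_models`),
#'   `group_means` (fitted per-life-form means from the conifer-separate
#'   model), and `meta`.
#' @export
run_comparative_analysis <- function(species_table, tree, ages = NULL,
                                     n_perm = 999, seed = 1) {
  rt <- build_rate_table(species_table)
  missing <- setdiff(rt$species, tree$tip.label)
  if (length(missing)) {
    abort(paste("species absent from tree:", paste(missing, collapse = ", ")))
  }
  pruned <- setdiff(tree$tip.label, rt$species)
  if (nrow(rt) < 4) abort("fewer than 4 species after filtering")
  tree <- ape::keep.tip(tree, rt$species)
  if (!is.null(ages)) tree <- bladj_calibrate(tree, ages)

  log_rate <- setNames(rt$log_rate, rt$species)
  he <- setNames(rt$He, rt$species)
  signal <- phylo_signal_test(tree, log_rate, n_perm = n_perm, seed = seed)
  signal_he <- phylo_signal_test(tree, he, n_perm = n_perm, seed = seed + 1)
  pic_cor <- pic_correlation(pic_contrasts(tree, log_rate),
                             pic_contrasts(tree, he))
  models <- fit_rate_models(rt, tree)
  group_means <- fitted_group_means(models$phylo2)

  structure(list(rate_table = rt, exclusions = exclusions(rt),
                 pruned_tips = pruned, signal = signal,
                 signal_he = signal_he, pic_cor = pic_cor, models = models,
                 group_means = group_means,
                 meta = list(n_species = nrow(rt), n_perm = n_perm,
                             seed = seed)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Comparative analysis of %d species (%d excluded, %d tree tips pruned)\n",
              x$meta$n_species, nrow(x$exclusions), length(x$pruned_tips)))
  cat("\n-- Phylogenetic signal of log recombination rate --\n")
  print(x$signal)
  cat(sprintf("\nPIC correlation (log rate vs He, through origin): %.3f\n", x$pic_cor))
  cat("\n")
  print(x$models)
  cat("\n-- Fitted mean log rate per life-form (conifer-separate model) --\n")
  print(x$group_means)
  invisible(x)
}
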