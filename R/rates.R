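#' Correct a genetic map length for marker density and terminal crossovers
#'
#' Published linkage maps underestimate total map length because the terminal
#' markers of each chromosome rarely coincide with the telomeres, and because
#' marker densities vary across studies. Two corrections are available:
#'
#' * `"add2s"` (default, after Hall & Willis): the mean inter-marker spacing
#'   `s = sum(lengths) / sum(markers - 1)` is added twice per chromosome,
#'   `corrected = sum(lengths) + 2 * s * C` with `C` chromosomes.
#' * `"chakravarti"`: each chromosome is inflated by `(m + 1) / (m - 1)`,
#'   `corrected = sum(length_c * (m_c + 1) / (m_c - 1))`.
#'
#' @param chrom_lengths Numeric vector of per-chromosome map lengths (cM).
#' @param chrom_markers Integer vector of per-chromosome marker counts
#'   (each >= 2), aligned with `chrom_lengths`.
#' @param method `"add2s"` or `"chakravarti"`.
#' @return The corrected total map length in cM, with the method recorded in
#'   the `"method"` attribute.
#' @export
#' @examples
#' correct_map_length(c(100, 100), c(11, 11))  # 240
correct_map_length <- function(chrom_lengths, chrom_markers,
                               method = c("add2s", "chakravarti")) {
  method <- match.arg(method)
  if (length(chrom_lengths) != length(chrom_markers)) {
    abort("chrom_lengths and chrom_markers must be aligned")
  }
  if (any(chrom_lengths <= 0)) abort("map lengths must be positive")
  if (any(chrom_markers < 2)) abort("every chromosome needs at least 2 markers")
  corrected <- switch(method,
    add2s = {
      s <- sum(chrom_lengths) / sum(chrom_markers - 1)
      sum(chrom_lengths) + 2 * s * length(chrom_lengths)
    },
    chakravarti = sum(chrom_lengths * (chrom_markers + 1) / (chrom_markers - 1))
  )
  structure(corrected, method = method)
}

#' Physical genome size in megabases
#'
#' Records carry either a genome size in Mb directly or a haploid C-value in
#' picograms; the latter is converted with the standard 1 pg = 978 Mb.
#'
#' @param genome_size_mb Genome size in Mb, or `NA`.
#' @param c_value_pg Haploid (1C) DNA content in pg, or `NA`.
#' @return Genome size in Mb. Exactly one of the two arguments must be
#'   non-missing.
#' @export
genome_size_mb <- function(genome_size_mb = NA_real_, c_value_pg = NA_real_) {
  has_mb <- !is.na(genome_size_mb)
  has_pg <- !is.na(c_value_pg)
  if (has_mb == has_pg) {
    abort("exactly one of genome_size_mb / c_value_pg must be present")
  }
  if (has_pg) 978 * c_value_pg else genome_size_mb
}

parse_num_list <- function(x) {
  if (is.numeric(x)) return(x)
  as.numeric(strsplit(as.character(x), ";", fixed = TRUE)[[1]])
}

#' Assemble a genome-wide recombination rate table
#'
#' Takes one row per species (columns as produced by [sim_species_table()] or
#' read from a delimited file: `species`, `life_form`, `taxon_group`,
#' `chrom_lengths` and `chrom_markers` as semicolon-joined lists,
#' `genome_size_mb` or `c_value_pg`, `map_coverage`, `He`, `n_ssr_loci`,
#' `domesticated`) and computes the corrected map length, genome size, the
#' genome-wide recombination rate `rate = corrected_cM / genome_Mb` and its
#' natural logarithm. Records are excluded when the map covers less than 60%
#' of the genome or the heterozygosity estimate rests on fewer than five SSR
#' loci; the exclusion log (species, violated rule) is attached as the
#' `"exclusions"` attribute and retrievable with [exclusions()].
#'
#' @param records A data frame of species records.
#' @param method Map-length correction method, see [correct_map_length()].
#' @param min_coverage Minimum map coverage retained (default 0.60).
#' @param min_ssr_loci Minimum number of SSR loci behind He (default 5).
#' @return A tibble of class `rate_table`, sorted by species, with columns
#'   `species`, `life_form`, `taxon_group`, `corrected_cm`, `genome_mb`,
#'   `rate`, `log_rate`, `He`.
#' @export
build_rate_table <- function(records, method = c("add2s", "chakravarti"),
                             min_coverage = 0.60, min_ssr_loci = 5) {
  method <- match.arg(method)
  records <- as_tibble(records)
  need <- c("species", "life_form", "taxon_group", "map_coverage", "He", "n_ssr_loci")
  missing <- setdiff(need, names(records))
  if (length(missing)) abort(paste("missing columns:", paste(missing, collapse = ", ")))
  if (!"genome_size_mb" %in% names(records)) records$genome_size_mb <- NA_real_
  if (!"c_value_pg" %in% names(records)) records$c_value_pg <- NA_real_

  keep_cov <- records$map_coverage >= min_coverage
  keep_ssr <- records$n_ssr_loci >= min_ssr_loci
  excl <- bind_rows(
    tibble(species = records$species[!keep_cov],
           reason = sprintf("coverage<%.2f", min_coverage)),
    tibble(species = records$species[keep_cov & !keep_ssr],
           reason = sprintf("ssr_loci<%d", min_ssr_loci))
  )
  kept <- records[keep_cov & keep_ssr, , drop = FALSE]
  if (nrow(kept) == 0) abort("no records pass the inclusion filters")

  nk <- nrow(kept)
  corrected <- numeric(nk)
  genome <- numeric(nk)
  for (i in seq_len(nk)) {
    corrected[i] <- as.numeric(correct_map_length(
      parse_num_list(kept$chrom_lengths[[i]]),
      parse_num_list(kept$chrom_markers[[i]]), method = method))
    genome[i] <- genome_size_mb(genome_size_mb = kept$genome_size_mb[i],
                                c_value_pg = kept$c_value_pg[i])
  }
  out <- tibble(species = kept$species, life_form = kept$life_form,
                taxon_group = kept$taxon_group,
                corrected_cm = corrected, genome_mb = genome,
                rate = corrected / genome, log_rate = log(corrected / genome),
                He = kept$He)
  out <- arrange(out, .data$species)
  attr(out, "exclusions") <- excl
  attr(out, "method") <- method
  class(out) <- c("rate_table", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exclusion log of a rate table
#'
#' @param table A `rate_table` from [build_rate_table()].
#' @return A tibble `(species, reason)` of dropped records.
#' @export
exclusions <- function(table) {
  attr(table, "exclusions") %||% tibble(species = character(), reason = character())
}

#' Compare recombination rates of domesticated species and wild relatives
#'
#' Paired nonparametric comparison (Wilcoxon signed-rank on log rates) of
#' domesticated species against their matched wild relatives, used to decide
#' whether the two groups can be pooled into a single analysis. Pooling is
#' recommended when the paired difference is not significant (p > 0.05).
#'
#' @param table A `rate_table`.
#' @param pairs A two-column data frame `(domesticated, wild)` of species
#'   names, both present in `table`.
#' @return A one-row tibble: `statistic` (signed-rank V), `df` (`NA`, the
#'   statistic has no chi-square df), `n_pairs`, `p.value`, `pool`.
#' @export
domestication_check <- function(table, pairs) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) < 2) abort("need at least 2 domesticated/wild pairs")
  lr <- setNames(table$log_rate, table$species)
  missing <- setdiff(c(pairs[[1]], pairs[[2]]), names(lr))
  if (length(missing)) {
    abort(paste("pair members absent from table:", paste(missing, collapse = ", ")))
  }
  d <- lr[pairs[[1]]] - lr[pairs[[2]]]
  if (all(d == 0)) {
    res <- tibble(statistic = 0, df = NA_real_, n_pairs = nrow(pairs),
                  p.value = 1, pool = TRUE)
    return(res)
  }
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = FALSE))
  tibble(statistic = unname(wt$statistic), df = NA_real_,
         n_pairs = nrow(pairs), p.value = wt$p.value,
         pool = wt$p.value > 0.05)
}
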