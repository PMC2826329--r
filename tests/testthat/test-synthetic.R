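test_that("Yule trees are ultrametric, seeded, and have the analytic depth", {
  cherry <- sim_yule_tree(2, seed = 1)
  expect_equal(ape::Ntip(cherry), 2)
  expect_equal(cherry$edge.length[1], cherry$edge.length[2])

  a <- sim_yule_tree(20, birth_rate = 2, seed = 7)
  b <- sim_yule_tree(20, birth_rate = 2, seed = 7)
  expect_identical(write_tree_newick(a), write_tree_newick(b))
  expect_true(ape::is.ultrametric(a))
  expect_error(sim_yule_tree(1), "at least 2")

  # E[depth] = sum 1/(k * lambda), k = 2..n  (independent summation)
  n <- 20; lambda <- 1
  depths <- vapply(1:500, function(i)
    max(ape::node.depth.edgelength(sim_yule_tree(n, lambda, seed = 10000 + i))),
    numeric(1))
  expected <- sum(1 / ((2:n) * lambda))
  expect_lt(abs(mean(depths) - expected) / expected, 0.10)
})

test_that("Brownian simulation matches the tree covariance", {
  flat <- sim_yule_tree(6, seed = 2)
  flat$edge.length <- flat$edge.length * 0
  z <- sim_bm(flat, sigma2 = 1, root_value = 3.3, seed = 4)
  expect_equal(z$value, rep(3.3, 6))

  tr <- sim_yule_tree(10, seed = 5)
  V <- phylo_covariance(tr)
  B <- 2000
  sims <- matrix(0, B, 10)
  set.seed(6)
  for (b in seq_len(B)) sims[b, ] <- sim_bm(tr, sigma2 = 1)$value
  Chat <- crossprod(sims) / B  # mean zero at the root
  se <- sqrt((outer(diag(V), diag(V)) + V^2) / B)
  expect_true(all(abs(Chat - V) <= 3.5 * se + 0.02))

  expect_error(sim_bm(tr, Sigma = matrix(c(1, 2, 2, 1), 2)), "positive semi-definite")
})

test_that("life-form assignment honours root state, clades and stationarity", {
  tr <- sim_yule_tree(15, seed = 8)
  lf0 <- sim_life_forms(tr, switch_rate = 0, root_state = "shrub")
  expect_true(all(lf0$life_form == "shrub"))
  expect_error(sim_life_forms(tr, levels = character(0)), "empty")
  expect_error(sim_life_forms(tr, levels = "cactus"), "levels")

  # clade painting overrides the Markov states inside the painted clade
  tips <- tr$tip.label[1:2]
  node <- ape::getMRCA(tr, tips)
  clade_tips <- ape::extract.clade(tr, node)$tip.label
  lf <- sim_life_forms(tr, switch_rate = 0, root_state = "herb",
                       clades = list(`conifer tree` = tips))
  expect_true(all(lf$life_form[lf$tip %in% clade_tips] == "conifer tree"))
  expect_true(all(lf$life_form[!lf$tip %in% clade_tips] == "herb"))

  # group effects shift the trait additively
  x <- setNames(rep(1, 15), tr$tip.label)
  lf2 <- sim_life_forms(tr, switch_rate = 0, root_state = "herb", trait = x,
                        group_effects = c(herb = -0.9))
  expect_equal(lf2$value, rep(0.1, 15))

  # high switch rate on a star tree reaches the uniform stationary mix
  star <- ape::compute.brlen(ape::stree(600, "star"), 10)
  lfs <- sim_life_forms(star, levels = c("tree", "herb", "shrub"),
                        switch_rate = 5, seed = 11)
  freq <- table(lfs$life_form) / 600
  se <- sqrt(1 / 3 * 2 / 3 / 600)
  expect_true(all(abs(freq - 1 / 3) < 3.5 * se))
})

test_that("coalescent simulator matches neutral expectations", {
  # rho = 0: one marginal genealogy, Rm = 0 always
  for (i in 1:25) {
    aln <- sim_coalescent(12, theta = 8, rho = 0, L = 2000, seed = 600 + i,
                          full_alignment = FALSE)
    expect_equal(rm_hudson_kaplan(filter_sites(aln, informative_only = TRUE)), 0L)
  }

  # E[S] = theta * sum(1/i): n = 30, theta = 10 -> 39.55
  set.seed(71)
  S <- replicate(400, attr(sim_coalescent(30, theta = 10, rho = 0,
                                          full_alignment = FALSE), "truth")$S)
  expected <- 10 * sum(1 / 1:29)  # = 39.62
  expect_lt(abs(mean(S) - expected), 3 * sd(S) / sqrt(length(S)))

  # E[pairwise differences] = theta for n = 2
  set.seed(72)
  pi2 <- replicate(600, attr(sim_coalescent(2, theta = 5,
                                            full_alignment = FALSE), "truth")$S)
  expect_lt(abs(mean(pi2) - 5), 3 * sd(pi2) / sqrt(length(pi2)))

  # seeded reproducibility and full-alignment consistency
  a <- sim_coalescent(6, theta = 4, rho = 3, L = 900, seed = 99)
  b <- sim_coalescent(6, theta = 4, rho = 3, L = 900, seed = 99)
  expect_identical(a$seqs, b$seqs)
  expect_equal(ncol(a$seqs), 900)
  snp <- filter_sites(a)
  expect_equal(ncol(snp$geno) + sum(snp$dropped$reason != "monomorphic"),
               attr(a, "truth")$S)
})

test_that("coalescent output matches msprime on the distribution of S", {
  reps <- 400
  set.seed(81)
  ours <- replicate(reps, attr(sim_coalescent(10, theta = 5, rho = 5,
                                              full_alignment = FALSE), "truth")$S)
  script <- '
import msprime, sys
n, theta, rho, reps = 10, 5.0, 5.0, 400
out = []
anc = msprime.sim_ancestry(samples=[msprime.SampleSet(n, ploidy=1)], ploidy=1,
                           population_size=1.0, sequence_length=1.0,
                           recombination_rate=rho/2, num_replicates=reps,
                           random_seed=4242)
for i, ts in enumerate(anc):
    m = msprime.sim_mutations(ts, rate=theta/2, random_seed=90000+i,
                              discrete_genome=False)
    out.append(str(m.num_sites))
sys.stdout.write("\\n".join(out))
'
  f <- withr::local_tempfile(fileext = ".py")
  writeLines(script, f)
  theirs <- as.integer(system2("python", f, stdout = TRUE))
  expect_length(theirs, reps)
  ks <- suppressWarnings(stats::ks.test(ours, theirs))
  expect_gt(ks$p.value, 0.01)
})

test_that("species-table fixture reproduces its latent rates through the pipeline", {
  tr <- sim_yule_tree(40, seed = 21)
  tab <- sim_species_table(tr, seed = 22)
  rt <- build_rate_table(tab)
  expect_equal(nrow(rt), 40)  # all records pass the filters by construction
  truth <- tab$true_log_rate[match(rt$species, tab$species)]
  expect_equal(rt$log_rate, truth, tolerance = 1e-9)
  expect_true(all(rt$He >= 0.3 & rt$He <= 0.9))

  # degenerate generator: no slope, no effects, no deviation
  flat <- sim_species_table(tr, intercept = -1.5, slope_He = 0,
                            group_effects = c(tree = 0, herb = 0, shrub = 0,
                                              `conifer tree` = 0),
                            bm_sigma2 = 0, seed = 23)
  rt_flat <- build_rate_table(flat)
  expect_equal(rt_flat$log_rate, rep(-1.5, 40), tolerance = 1e-9)

  # pure function of (parameters, seed)
  expect_identical(sim_species_table(tr, seed = 30),
                   sim_species_table(tr, seed = 30))
})
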