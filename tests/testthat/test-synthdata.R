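# Seeded generator: determinism, drift calibration, environment model.

test_that("identical configs give identical datasets", {
  cfg <- synth_config(lineages = "a", n_pops = 6, n_ind = 8, n_loci = 40,
                      clinal_fraction = 0.1, n_shared_clinal = 0, seed = 5)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$genotypes, s2$dataset$genotypes)
  expect_identical(s1$environment, s2$environment)
  expect_identical(s1$truth$loci, s2$truth$loci)
  s3 <- simulate_dataset(synth_config(lineages = "a", n_pops = 6, n_ind = 8,
                                      n_loci = 40, clinal_fraction = 0.1,
                                      n_shared_clinal = 0, seed = 6))
  expect_false(identical(s1$dataset$genotypes, s3$dataset$genotypes))
})

test_that("missing_rate zero yields a complete matrix; infeasible configs fail", {
  cfg <- synth_config(lineages = "a", n_pops = 4, n_ind = 6, n_loci = 20,
                      missing_rate = 0, n_shared_clinal = 0, seed = 1)
  expect_false(anyNA(simulate_dataset(cfg)$dataset$genotypes))
  expect_error(synth_config(lo = 0.9, hi = 0.1), "hi < lo")
  expect_error(synth_config(theta = 1.2), "theta")
  expect_error(synth_config(missing_rate = 1), "missing_rate")
  expect_error(synth_config(n_shared_clinal = 500), "n_shared_clinal")
})

test_that("pure-drift panels recover the generating theta and ancestral mean", {
  # multilocus Weir-Cockerham F_ST near theta = 0.1, averaged over seeds
  fst <- vapply(1:10, function(s) {
    cfg <- synth_config(lineages = "a", n_pops = 40, n_ind = 30,
                        n_loci = 1000, clinal_fraction = 0,
                        n_shared_clinal = 0, theta = 0.1,
                        missing_rate = 0, seed = s)
    wc_fst(simulate_dataset(cfg)$dataset)$multilocus
  }, numeric(1))
  expect_lt(abs(mean(fst) - 0.1), 0.02)

  # moment check: mean population frequency tracks the ancestral pi
  cfg <- synth_config(lineages = "a", n_pops = 60, n_ind = 20, n_loci = 300,
                      clinal_fraction = 0, n_shared_clinal = 0, theta = 0.1,
                      missing_rate = 0, seed = 11)
  sim <- simulate_dataset(cfg)
  fr <- allele_frequencies(sim$dataset)
  pbar <- colMeans(fr$p)
  pi <- sim$truth$loci$pi
  # Monte-Carlo error of a mean over 60 Beta(F=0.1) pops is about
  # sqrt(0.1 * p(1-p) / 60) <= 0.021; allow 4 sigma
  expect_lt(max(abs(pbar - pi)), 4 * sqrt(0.1 * 0.25 / 60) + 0.02)
  expect_lt(mean(abs(pbar - pi)), 0.03)
})

test_that("shared clinal loci are planted consistently across lineages", {
  cfg <- synth_config(lineages = c("w", "e"), n_pops = c(6, 6), n_ind = 5,
                      n_loci = 60, clinal_fraction = 0.2,
                      n_shared_clinal = 5, seed = 3)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth
  expect_length(tr$shared_clinal, 5)
  expect_true(all(tr$shared_clinal %in% tr$clinal$w))
  expect_true(all(tr$shared_clinal %in% tr$clinal$e))
  expect_length(tr$clinal$w, 12)
  # truth covers every locus in both lineages
  expect_equal(nrow(tr$loci), 2 * 60)
  expect_setequal(unique(tr$loci$locus), colnames(sim$dataset$genotypes))
})

test_that("environment covariates follow the affine-in-latitude model", {
  pops <- data.frame(population = paste0("p", 1:60),
                     latitude = seq(44, 60, length.out = 60))
  exact <- simulate_environment(
    pops, data.frame(covariate = "t", intercept = 10, slope = -0.5, sd = 0),
    seed = 1)
  expect_equal(exact$t, 10 - 0.5 * pops$latitude)
  expect_equal(cor(exact$t, pops$latitude), -1)

  # two identical noise-free models give an exactly collinear pair
  pair <- simulate_environment(
    pops, data.frame(covariate = c("t1", "t2"), intercept = 10,
                     slope = -0.5, sd = 0), seed = 1)
  expect_equal(pair$t1, pair$t2)

  # noisy covariate: sample correlation near the closed-form value
  slope <- -0.5; sd_noise <- 2
  noisy <- simulate_environment(
    pops, data.frame(covariate = "t", intercept = 10, slope = slope,
                     sd = sd_noise), seed = 42)
  analytic <- slope * sd(pops$latitude) /
    sqrt(slope^2 * var(pops$latitude) + sd_noise^2)
  expect_lt(abs(cor(noisy$t, pops$latitude) - analytic), 0.1)

  expect_error(simulate_environment(
    pops, data.frame(covariate = c("t", "t"), intercept = 1, slope = 1,
                     sd = 1)), "duplicate")
})

test_that("neutral loci rarely exceed the clinal threshold at theta 0.1", {
  fpr <- vapply(1:5, function(s) {
    cfg <- synth_config(lineages = "a", n_pops = 40, n_ind = 25,
                        n_loci = 400, clinal_fraction = 0,
                        n_shared_clinal = 0, theta = 0.1, seed = s + 100)
    sim <- simulate_dataset(cfg)
    fits <- fit_clines(allele_frequencies(sim$dataset))
    length(classify_clinal(fits, 0.40)$loci) / nrow(fits)
  }, numeric(1))
  expect_lte(mean(fpr), 0.01)
})
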