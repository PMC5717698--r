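# Heterozygosity, Weir-Cockerham F_ST (with independent ANOVA oracle),
# AMOVA and isolation-by-distance.

test_that("observed heterozygosity counts heterozygotes", {
  ds <- toy_dataset(list(p1 = cbind(c(1L, 1L, 1L, 1L),
                                    c(2L, 2L, 0L, 0L),
                                    c(1L, 1L, 2L, 0L))))
  ho <- observed_heterozygosity(ds)
  expect_equal(unname(ho$ho[1, ]), c(1, 0, 0.5))
  all_na <- toy_dataset(list(p1 = matrix(c(NA_integer_, NA_integer_,
                                           1L, 1L), 2, 2)))
  expect_true(is.na(observed_heterozygosity(all_na)$ho[1, 1]))
})

test_that("Weir-Cockerham theta hits the fixed and null limits", {
  # complete differentiation: alternatively fixed populations
  fixed <- toy_dataset(list(p1 = matrix(2L, 20, 1), p2 = matrix(0L, 20, 1)))
  expect_equal(wc_fst(fixed)$per_locus$theta, 1)

  # identical genotype count vectors: estimator's finite-sample theta <= 0
  block <- matrix(rep(c(2L, 1L, 1L, 0L), c(10, 15, 15, 10)), ncol = 1)
  same <- toy_dataset(list(p1 = block, p2 = block))
  th <- wc_fst(same)$per_locus$theta
  expect_lte(th, 0)
  expect_lt(abs(th), 0.05)

  # monomorphic locus is undefined and excluded from multilocus sums
  ds <- toy_dataset(list(p1 = cbind(c(2L, 0L, 1L), 2L),
                         p2 = cbind(c(0L, 0L, 1L), 2L)))
  r <- wc_fst(ds)
  expect_true(is.na(r$per_locus$theta[2]))
  expect_equal(r$multilocus,
               r$per_locus$a[1] / (r$per_locus$a[1] + r$per_locus$b[1] +
                                   r$per_locus$c[1]))
})

test_that("per-locus components match the independent ANOVA oracle", {
  # toy counts: pop1 10 AA, 5 Aa, 5 aa; pop2 2 AA, 6 Aa, 12 aa
  g1 <- rep(c(2L, 1L, 0L), c(10, 5, 5))
  g2 <- rep(c(2L, 1L, 0L), c(2, 6, 12))
  ds <- toy_dataset(list(p1 = matrix(g1, ncol = 1),
                         p2 = matrix(g2, ncol = 1)))
  got <- wc_fst(ds)$per_locus
  ora <- wc_oracle(c(g1, g2), rep(c("p1", "p2"), c(20, 20)))
  expect_equal(got$a, ora$a, tolerance = 1e-10)
  expect_equal(got$b, ora$b, tolerance = 1e-10)
  expect_equal(got$c, ora$c, tolerance = 1e-10)
  expect_equal(got$theta, ora$theta, tolerance = 1e-10)

  # randomized cases, unequal sizes and missing data
  set.seed(8)
  for (rep_i in 1:5) {
    sizes <- sample(5:25, 3)
    gl <- lapply(sizes, function(n) {
      v <- rbinom(n, 2, runif(1, 0.2, 0.8))
      v[runif(n) < 0.1] <- NA
      matrix(as.integer(v), ncol = 1)
    })
    names(gl) <- paste0("p", 1:3)
    ds <- toy_dataset(gl)
    got <- wc_fst(ds)$per_locus
    ora <- wc_oracle(ds$genotypes[, 1], ds$individuals$population)
    expect_equal(got$theta, ora$theta, tolerance = 1e-10)
  }
})

test_that("AMOVA saturates, sums exactly, and orders components sensibly", {
  # two groups fixed for alternative alleles, identical pops within groups
  mk <- function(code) matrix(rep(code, 10 * 5), 10, 5)
  ds <- toy_dataset(list(a1 = mk(2L), a2 = mk(2L), b1 = mk(0L), b2 = mk(0L)))
  grp <- c(a1 = "g1", a2 = "g1", b1 = "g2", b2 = "g2")
  am <- amova_two_level(ds, grp, n_perm = 29, seed = 1)
  expect_gt(am$f_ct, 0.95)
  expect_lt(abs(am$f_sc), 1e-10)
  # exact sum-of-squares identity
  expect_lt(abs(sum(am$ss[1:3]) - am$ss[["total"]]), 1e-10)

  # synthetic two-lineage panel: between-lineage >> within -> F_CT > F_SC
  cfg <- synth_config(lineages = c("w", "e"), n_pops = c(5, 5), n_ind = 10,
                      n_loci = 80, clinal_fraction = 0, n_shared_clinal = 0,
                      theta = 0.03, missing_rate = 0, seed = 4)
  sim <- simulate_dataset(cfg)
  am2 <- amova_two_level(sim$dataset, n_perm = 29, seed = 2)
  expect_lt(abs(sum(am2$ss[1:3]) - am2$ss[["total"]]), 1e-8)
  expect_gt(am2$f_ct, am2$f_sc)
})

test_that("isolation-by-distance recovers an exact linear construction", {
  set.seed(3)
  n <- 8
  d <- as.matrix(dist(cbind(runif(n, 0, 1000), runif(n, 0, 1000))))
  lin <- 0.001 * d                       # F/(1-F) = 0.001 * distance exactly
  fst <- lin / (1 + lin)
  r <- ibd_regression(fst, d, n_perm = 99, seed = 1)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
  expect_equal(r$slope, 0.001, tolerance = 1e-10)
  expect_equal(r$mantel_p, 1 / 100)

  # 3-population closed-form OLS check
  d3 <- matrix(c(0, 10, 20, 10, 0, 15, 20, 15, 0), 3)
  f3 <- matrix(c(0, .1, .3, .1, 0, .2, .3, .2, 0), 3)
  r3 <- ibd_regression(f3, d3, n_perm = 9, seed = 1)
  y <- c(.1 / .9, .3 / .7, .2 / .8); x <- c(10, 20, 15)
  slope_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(r3$slope, slope_cf, tolerance = 1e-12)

  # F_ST = 1 pairs are excluded with a warning
  f1 <- f3; f1[1, 2] <- f1[2, 1] <- 1
  expect_warning(ibd_regression(f1, d3, n_perm = 9, seed = 1), "excluded")
})
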