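# The binomial logistic cline fitter and the steep-change classifier.

test_that("a flat frequency profile fits a zero slope and zero range", {
  lat <- seq(44, 60, length.out = 10)
  fit <- fit_locus_cline(rep(0.5, 10), rep(40, 10), lat)
  expect_equal(fit$b, 0, tolerance = 1e-8)
  expect_equal(fit$dp, 0, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("noiseless logistic frequencies recover the generating curve", {
  a <- -50; b <- 1
  lat <- seq(44, 60, length.out = 12)
  p <- plogis(a + b * lat)
  fit <- fit_locus_cline(p, rep(1e6, 12), lat)
  expect_lt(abs(fit$a - a) / abs(a), 0.01)
  expect_lt(abs(fit$b - b) / abs(b), 0.01)
  dp_true <- abs(plogis(a + b * 60) - plogis(a + b * 44))
  expect_lt(abs(fit$dp - dp_true), 0.005)
})

test_that("the IRLS fit agrees with glm's binomial logistic fit", {
  set.seed(7)
  for (i in 1:5) {
    lat <- sort(runif(12, 44, 60))
    m <- sample(c(30, 60, 90), 12, replace = TRUE)
    p_true <- plogis(-20 + 0.4 * lat)
    k <- rbinom(12, m, p_true)
    fit <- fit_locus_cline(k / m, m, lat)
    ref <- suppressWarnings(
      glm(cbind(k, m - k) ~ lat, family = binomial()))
    expect_equal(fit$a, unname(coef(ref)[1]), tolerance = 1e-5)
    expect_equal(fit$b, unname(coef(ref)[2]), tolerance = 1e-5)
  }
})

test_that("complete separation is capped and flagged", {
  lat <- c(44, 46, 48, 56, 58, 60)
  p <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_locus_cline(p, rep(20, 6), lat)
  expect_false(fit$converged)
  expect_true(fit$capped)
  expect_equal(abs(fit$b), 50)
  expect_gt(fit$dp, 0.99)
})

test_that("a within-lineage monomorphic locus is degenerate with dp 0", {
  fit <- fit_locus_cline(rep(1, 5), rep(20, 5), seq(45, 55, length.out = 5))
  expect_true(fit$degenerate)
  expect_equal(fit$dp, 0, tolerance = 1e-6)
})

test_that("classification is strict at the threshold", {
  fits <- data.frame(locus = c("a", "b", "c", "d"),
                     dp = c(0.45, 0.40, 0, 0.62),
                     converged = TRUE, capped = FALSE)
  cs <- classify_clinal(fits, threshold = 0.40)
  expect_setequal(cs$loci, c("a", "d"))           # 0.40 exactly is NOT clinal
  # capped (separation) fits are eligible; unconverged-uncapped are not
  fits2 <- data.frame(locus = c("x", "y"), dp = c(0.9, 0.9),
                      converged = FALSE, capped = c(TRUE, FALSE))
  expect_equal(classify_clinal(fits2)$loci, "x")
})

test_that("polarity and latitude-shift invariances hold", {
  set.seed(21)
  lat <- seq(44, 60, length.out = 10)
  m <- rep(60, 10)
  p <- plogis(-26 + 0.5 * lat) * 0.9 + 0.05
  f1 <- fit_locus_cline(p, m, lat)
  f2 <- fit_locus_cline(1 - p, m, lat)              # recoded counted allele
  expect_equal(f1$dp, f2$dp, tolerance = 1e-6)
  f3 <- fit_locus_cline(p, m, lat + 100)            # shifted latitudes
  expect_equal(f3$b, f1$b, tolerance = 1e-6)
  expect_equal(f3$dp, f1$dp, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(f3$a, f1$a)))
})

test_that("threshold scan counts are monotone and locate a planted knee", {
  set.seed(9)
  fits <- data.frame(locus = paste0("L", 1:200),
                     dp = c(abs(rnorm(180, 0, 0.06)), runif(20, 0.55, 0.65)),
                     converged = TRUE, capped = FALSE)
  sc <- threshold_scan(fits, thresholds = seq(0, 0.9, by = 0.05))
  expect_true(all(diff(sc$table$count) <= 0))
  expect_equal(sc$table$count[1], sum(fits$dp > 0))
  # the maximal-curvature knee sits where the neutral bulk collapses,
  # strictly below the planted 0.6 clines
  expect_gt(sc$knee, 0)
  expect_lt(sc$knee, 0.55)
  expect_lte(sc$table$count[sc$table$threshold == sc$knee], 180)
  # on drift panels with planted clines the knee separates bulk from signal
  hits <- vapply(1:5, function(s) {
    cfg <- synth_config(lineages = "a", n_pops = 30, n_ind = 20,
                        n_loci = 200, clinal_fraction = 0.1,
                        n_shared_clinal = 0, theta = 0.1, seed = 300 + s)
    sim <- simulate_dataset(cfg)
    f <- fit_clines(allele_frequencies(sim$dataset))
    k <- threshold_scan(f, seq(0, 0.95, 0.05))$knee
    k > 0 && k < 0.7
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # short grids: counts returned, knee undefined
  sc2 <- threshold_scan(fits, thresholds = c(0, 1))
  expect_true(is.na(sc2$knee))
  expect_equal(sc2$table$count[2], 0)
  expect_error(threshold_scan(fits, thresholds = c(0.5, 0.2)), "increasing")
})

test_that("fit_clines requires enough populations and defined frequencies", {
  ds <- toy_dataset(list(p1 = matrix(1L, 3, 1), p2 = matrix(1L, 3, 1)))
  expect_error(fit_clines(allele_frequencies(ds)), ">= 3 populations")
  expect_error(fit_locus_cline(c(NA, NA, NA, 0.5), rep(10, 4),
                               c(44, 45, 46, 47)), "defined frequency")
  expect_error(fit_locus_cline(rep(0.4, 4), rep(10, 4), rep(50, 4)),
               "latitudes")
})
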