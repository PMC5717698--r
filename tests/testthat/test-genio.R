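# Genepop parsing, counted-allele recoding, locus filters, frequencies.

write_genepop_fixture <- function(lines, path = tempfile(fileext = ".gen")) {
  writeLines(lines, path)
  path
}

test_that("genepop genotypes are recoded to counts of the smaller allele", {
  path <- write_genepop_fixture(c(
    "toy panel", "L1",
    "POP", "aaa_01 ,  0101", "aaa_02 ,  0101",
    "POP", "bbb_01 ,  0101"))
  meta <- write_toy_metadata(c("aaa", "bbb"), tempfile(fileext = ".csv"))
  ds <- read_genepop(path, meta)
  expect_equal(unname(ds$genotypes[, 1]), c(2L, 2L, 2L))
  fr <- allele_frequencies(ds)
  expect_equal(unname(fr$p[, 1]), c(1, 1))

  path2 <- write_genepop_fixture(c(
    "toy", "L1",
    "POP", "aaa_01 , 0102", "aaa_02 , 0202"))
  ds2 <- read_genepop(path2, write_toy_metadata("aaa", tempfile()))
  expect_equal(unname(ds2$genotypes[, 1]), c(1L, 0L))
})

test_that("genepop round-trips and 3-digit / missing codes parse", {
  path <- write_genepop_fixture(c(
    "toy", "L1", "L2",
    "POP", "aaa_01 , 001002 000000", "aaa_02 , 002002 001001",
    "POP", "bbb_01 , 001001 001002"))
  meta <- write_toy_metadata(c("aaa", "bbb"), tempfile(fileext = ".csv"))
  ds <- read_genepop(path, meta)
  expect_equal(unname(ds$genotypes[, 1]), c(1L, 0L, 2L))
  expect_true(is.na(ds$genotypes[1, 2]))

  out <- tempfile(fileext = ".gen")
  write_genepop(ds, out)
  ds2 <- read_genepop(out, meta)
  expect_equal(ds2$genotypes, ds$genotypes)
  expect_equal(ds2$individuals, ds$individuals)
  expect_equal(ds2$populations, ds$populations)
  # frequencies from written-then-read file equal the in-memory ones exactly
  expect_identical(allele_frequencies(ds2)$p, allele_frequencies(ds)$p)
})

test_that("genepop parse and metadata errors are informative", {
  bad <- write_genepop_fixture(c("t", "L1", "POP", "aaa_01  0101"))
  expect_error(read_genepop(bad, write_toy_metadata("aaa", tempfile())),
               "comma")
  tri <- write_genepop_fixture(c("t", "L1", "POP", "aaa_01 , 0102",
                                 "aaa_02 , 0303"))
  expect_error(read_genepop(tri, write_toy_metadata("aaa", tempfile())),
               "biallelic")
  ok <- write_genepop_fixture(c("t", "L1", "POP", "zzz_01 , 0101"))
  expect_error(read_genepop(ok, write_toy_metadata("aaa", tempfile())),
               "missing metadata.*zzz")
})

test_that("genotype CSV round-trips through the dataset", {
  ds <- toy_dataset(list(p1 = rbind(c(2, 1), c(0, NA)),
                         p2 = rbind(c(1, 1), c(2, 0))))
  path <- tempfile(fileext = ".csv")
  write_genotype_csv(ds, path)
  ds2 <- read_genotype_csv(path, ds$populations)
  expect_equal(ds2$genotypes, ds$genotypes)
})

test_that("locus filters remove by first matching rule with exact boundaries", {
  # 100 individuals in one pop: engineered pooled MAF and missingness
  n <- 100
  mk <- function(n2, n1, n_na = 0) {
    v <- c(rep(2L, n - n2 - n1 - n_na), rep(1L, n1), rep(0L, n2),
           rep(NA_integer_, n_na))
    v
  }
  g <- cbind(
    maf_low   = mk(0, 1),          # MAF = 1/200 = 0.005 < 0.01
    maf_edge  = mk(0, 2),          # MAF = 2/200 = 0.01 exactly -> retained
    mono      = rep(2L, n),        # monomorphic
    miss_over = mk(10, 20, 16),    # 16% missing -> removed
    miss_edge = mk(10, 20, 15),    # 15% exactly -> retained
    keep      = mk(30, 40))
  ds <- toy_dataset(list(p1 = g))
  flt <- filter_loci(ds)
  expect_setequal(flt$removed$locus, c("maf_low", "mono", "miss_over"))
  expect_equal(flt$removed$rule[flt$removed$locus == "maf_low"], "maf")
  expect_equal(flt$removed$rule[flt$removed$locus == "mono"], "monomorphic")
  expect_equal(flt$removed$rule[flt$removed$locus == "miss_over"], "missing")
  expect_setequal(colnames(flt$dataset$genotypes),
                  c("maf_edge", "miss_edge", "keep"))
  # a monomorphic locus missing in 20% gets the first rule, not "missing"
  g2 <- cbind(both = c(rep(2L, 80), rep(NA_integer_, 20)), keep = mk(30, 40))
  flt2 <- filter_loci(toy_dataset(list(p1 = g2)))
  expect_equal(flt2$removed$rule[flt2$removed$locus == "both"], "monomorphic")
})

test_that("filtering is idempotent and errors on an empty panel", {
  set.seed(42)
  g <- matrix(rbinom(600, 2, 0.3), 60, 10)
  g[sample(length(g), 80)] <- NA
  ds <- toy_dataset(list(p1 = g[1:30, ], p2 = g[31:60, ]))
  f1 <- filter_loci(ds)
  f2 <- filter_loci(f1$dataset)
  expect_equal(f2$dataset$genotypes, f1$dataset$genotypes)
  expect_equal(nrow(f2$removed), 0)
  mono <- toy_dataset(list(p1 = matrix(2L, 10, 2)))
  expect_error(filter_loci(mono), "empty panel")
})

test_that("allele frequencies count alleles and flag undefined cells", {
  ds <- toy_dataset(list(p1 = matrix(c(2L, 1L, 1L, 0L), ncol = 1)))
  fr <- allele_frequencies(ds)
  expect_equal(unname(fr$p[1, 1]), 0.5)
  expect_equal(unname(fr$m[1, 1]), 8)

  ds2 <- toy_dataset(list(p1 = matrix(c(2L, NA, 0L), ncol = 1),
                          p2 = matrix(NA_integer_, 2, 1)))
  fr2 <- allele_frequencies(ds2)
  expect_equal(unname(fr2$p[1, 1]), 0.5)
  expect_equal(unname(fr2$m[1, 1]), 4)
  expect_true(is.na(fr2$p[2, 1]))   # undefined, not 0
  expect_equal(unname(fr2$m[2, 1]), 0)
})

test_that("dataset invariants are enforced", {
  expect_error(toy_dataset(list(p1 = matrix(3L, 2, 1))), "codes")
  g <- matrix(1L, 2, 2); colnames(g) <- c("a", "a")
  expect_error(genotype_dataset(
    g, data.frame(individual = c("i1", "i2"), population = "p1"),
    data.frame(population = "p1", latitude = 50, longitude = 0,
               lineage = "x")), "unique")
  expect_error(genotype_dataset(
    matrix(1L, 1, 1), data.frame(individual = "i1", population = "p9"),
    data.frame(population = "p1", latitude = 50, longitude = 0,
               lineage = "x")), "absent")
})
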