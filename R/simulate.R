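#' Configuration for the two-lineage cline simulator
#'
#' Defaults emulate a range-wide diadromous-fish SNP survey: two diverged
#' lineages (western and eastern Atlantic) of 74 and 60 river populations
#' genotyped at 1773 biallelic loci, latitude spans of about 15 and 27
#' degrees, lineage-level drift F_ST of 0.110 and 0.089, a minority of loci
#' carrying steep logistic latitudinal clines (fractions 84/1773 and
#' 195/1773, 12 of them clinal in both lineages), latitude-driven climate
#' covariates, and 5% missing genotypes.
#'
#' @param lineages Character vector of lineage labels.
#' @param n_pops Populations per lineage (recycled to `length(lineages)`).
#' @param n_ind Individuals per population.
#' @param n_loci Number of biallelic loci (shared panel).
#' @param clinal_fraction Fraction of loci clinal, per lineage.
#' @param n_shared_clinal Loci clinal in *both* lineages (ignored for a
#'   single lineage).
#' @param lat_range List of `c(min, max)` latitude per lineage.
#' @param theta Drift F_ST parameter per lineage (Balding-Nichols), in (0,1).
#' @param theta_clinal Drift jitter applied around the cline expectation;
#'   default `theta / 4` so planted clines stay visible above drift.
#' @param x0,s Cline inflection latitude (per lineage) and steepness scale
#'   (degrees latitude per logistic unit).
#' @param lo,hi Cline asymptote frequencies (generating range `hi - lo`).
#' @param missing_rate I.i.d. genotype missingness in `[0, 1)`.
#' @param env_model Data frame `covariate,intercept,slope,sd` describing
#'   each climate covariate as affine in latitude plus Gaussian noise.
#' @param seed Integer seed governing all randomness.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(lineages = c("north_america", "europe"),
                         n_pops = c(74, 60),
                         n_ind = 30,
                         n_loci = 1773,
                         clinal_fraction = c(84 / 1773, 195 / 1773),
                         n_shared_clinal = 12,
                         lat_range = list(c(45, 60), c(43, 70)),
                         theta = c(0.110, 0.089),
                         theta_clinal = NULL,
                         x0 = c(53.3, 59.9),
                         s = 1.5,
                         lo = 0.1, hi = 0.9,
                         missing_rate = 0.05,
                         env_model = default_env_model(),
                         seed = 1) {
  L <- length(lineages)
  rec <- function(x) rep_len(x, L)
  n_pops <- rec(n_pops); clinal_fraction <- rec(clinal_fraction)
  theta <- rec(theta); x0 <- rec(x0); s <- rec(s)
  if (!is.list(lat_range)) lat_range <- list(lat_range)
  lat_range <- rep_len(lat_range, L)
  if (is.null(theta_clinal)) theta_clinal <- theta / 4
  theta_clinal <- rec(theta_clinal)

  if (any(clinal_fraction < 0 | clinal_fraction > 1))
    stop("clinal_fraction must be in [0, 1]")
  n_clinal <- round(clinal_fraction * n_loci)
  if (L > 1 && n_shared_clinal > min(n_clinal))
    stop("n_shared_clinal exceeds a lineage's clinal locus count")
  if (any(theta <= 0 | theta >= 1) || any(theta_clinal <= 0 | theta_clinal >= 1))
    stop("theta parameters must lie in (0, 1)")
  if (hi < lo) stop("infeasible cline asymptotes: hi < lo")
  if (lo < 0 || hi > 1) stop("cline asymptotes must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (any(vapply(lat_range, function(r) diff(r) <= 0, logical(1))))
    stop("each lat_range must be increasing")
  if (anyDuplicated(env_model$covariate))
    stop("duplicate covariate names in env_model")

  structure(list(lineages = lineages, n_pops = n_pops, n_ind = n_ind,
                 n_loci = n_loci, clinal_fraction = clinal_fraction,
                 n_clinal = n_clinal, n_shared_clinal = n_shared_clinal,
                 lat_range = lat_range, theta = theta,
                 theta_clinal = theta_clinal, x0 = x0, s = s,
                 lo = lo, hi = hi, missing_rate = missing_rate,
                 env_model = env_model, seed = as.integer(seed)),
            class = "synth_config")
}

#' Default climate covariate model (affine in latitude + noise)
#' @return Data frame `covariate,intercept,slope,sd`.
#' @export
default_env_model <- function() {
  data.frame(
    covariate = c("temp_spring", "temp_winter", "temp_annual",
                  "precip_annual", "days_above_10"),
    intercept = c(26, 22, 24, 1800, 400),
    slope     = c(-0.40, -0.55, -0.45, -14, -5.5),
    sd        = c(0.8, 1.0, 0.9, 60, 12),
    stringsAsFactors = FALSE)
}

balding_nichols <- function(n, pi, theta) {
  stats::rbeta(n, pi * (1 - theta) / theta, (1 - pi) * (1 - theta) / theta)
}

logistic_cline <- function(x, x0, s, lo, hi, direction = 1) {
  lo + (hi - lo) / (1 + exp(-direction * (x - x0) / s))
}

#' Simulate a two-lineage SNP panel with planted latitudinal clines
#'
#' Neutral loci draw an ancestral frequency per lineage from Uniform(0.05,
#' 0.95) and per-population frequencies from the Balding-Nichols beta
#' distribution at the lineage's drift parameter `theta`. Clinal loci follow
#' a logistic expectation in latitude (random north-high or south-high
#' orientation) with the same beta jitter at the milder `theta_clinal`.
#' Genotypes are Binomial(2, p) per individual (Hardy-Weinberg within
#' population) and missingness is i.i.d. All randomness derives from
#' `config$seed`; identical configs give identical output.
#'
#' @param config A [synth_config()].
#' @return A list: `dataset` (a [genotype_dataset()]), `environment`
#'   (per-population covariate table), and `truth` (a `synth_truth` list:
#'   per-locus-per-lineage class and cline parameters, the shared clinal
#'   locus names, and the covariate generating coefficients).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  L <- length(config$lineages)
  loci <- sprintf("locus_%04d", seq_len(config$n_loci))

  # shared clinal loci first, then lineage-specific complements
  shared <- character(0)
  if (L > 1 && config$n_shared_clinal > 0)
    shared <- sample(loci, config$n_shared_clinal)
  clinal_sets <- vector("list", L)
  for (l in seq_len(L)) {
    extra_n <- config$n_clinal[l] - length(shared)
    pool <- setdiff(loci, shared)
    clinal_sets[[l]] <- c(shared, if (extra_n > 0) sample(pool, extra_n))
  }

  geno_blocks <- list(); ind_blocks <- list(); pop_blocks <- list()
  truth_rows <- list()

  for (l in seq_len(L)) {
    lin <- config$lineages[l]
    n_pops <- config$n_pops[l]
    pops <- sprintf("%s_pop%03d", lin, seq_len(n_pops))
    lat <- seq(config$lat_range[[l]][1], config$lat_range[[l]][2],
               length.out = n_pops)
    # coastline-like longitudes: a drifting base with a meander so that
    # longitude is not an exact linear function of latitude
    lon_base <- if (l == 1) c(-70, -55) else c(-10, 30)
    lon <- seq(lon_base[1], lon_base[2], length.out = n_pops) +
      2 * sin(seq(0, 4 * pi, length.out = n_pops))

    is_clinal <- loci %in% clinal_sets[[l]]
    pi_anc <- stats::runif(config$n_loci, 0.05, 0.95)
    direction <- ifelse(stats::runif(config$n_loci) < 0.5, -1, 1)

    # population frequency matrix (pops x loci)
    pmat <- matrix(NA_real_, n_pops, config$n_loci)
    for (j in seq_len(config$n_loci)) {
      if (is_clinal[j]) {
        mu <- logistic_cline(lat, config$x0[l], config$s[l],
                             config$lo, config$hi, direction[j])
        # beta jitter around each population's own cline expectation
        pmat[, j] <- stats::rbeta(
          n_pops,
          mu * (1 - config$theta_clinal[l]) / config$theta_clinal[l],
          (1 - mu) * (1 - config$theta_clinal[l]) / config$theta_clinal[l])
      } else {
        pmat[, j] <- balding_nichols(n_pops, pi_anc[j], config$theta[l])
      }
    }

    n_ind_tot <- n_pops * config$n_ind
    g <- matrix(stats::rbinom(n_ind_tot * config$n_loci, 2L,
                              prob = pmat[rep(seq_len(n_pops),
                                              each = config$n_ind), ]),
                n_ind_tot, config$n_loci)
    if (config$missing_rate > 0)
      g[stats::runif(length(g)) < config$missing_rate] <- NA_integer_
    colnames(g) <- loci

    ids <- sprintf("%s_i%02d", rep(pops, each = config$n_ind),
                   rep(seq_len(config$n_ind), n_pops))
    geno_blocks[[l]] <- g
    ind_blocks[[l]] <- data.frame(individual = ids,
                                  population = rep(pops, each = config$n_ind),
                                  stringsAsFactors = FALSE)
    pop_blocks[[l]] <- data.frame(population = pops, latitude = lat,
                                  longitude = lon, lineage = lin,
                                  stringsAsFactors = FALSE)
    truth_rows[[l]] <- data.frame(
      locus = loci, lineage = lin,
      class = ifelse(is_clinal, "clinal", "neutral"),
      pi = ifelse(is_clinal, NA_real_, pi_anc),
      x0 = ifelse(is_clinal, config$x0[l], NA_real_),
      s = ifelse(is_clinal, config$s[l], NA_real_),
      lo = ifelse(is_clinal, config$lo, NA_real_),
      hi = ifelse(is_clinal, config$hi, NA_real_),
      direction = ifelse(is_clinal, direction, NA_real_),
      stringsAsFactors = FALSE)
  }

  populations <- do.call(rbind, pop_blocks)
  ds <- genotype_dataset(do.call(rbind, geno_blocks),
                         do.call(rbind, ind_blocks), populations)
  env <- simulate_environment(populations, config$env_model,
                              seed = config$seed + 104729L)
  truth <- structure(list(loci = do.call(rbind, truth_rows),
                          shared_clinal = shared,
                          clinal = stats::setNames(clinal_sets, config$lineages),
                          env_model = config$env_model,
                          config = config),
                     class = "synth_truth")
  list(dataset = ds, environment = env, truth = truth)
}

#' Simulate per-population climate covariates
#'
#' Each covariate is affine in latitude plus independent Gaussian noise:
#' `value = intercept + slope * latitude + Normal(0, sd)`.
#'
#' @param populations Data frame with columns `population` and `latitude`.
#' @param env_model Data frame `covariate,intercept,slope,sd`.
#' @param seed Integer seed.
#' @return Data frame: `population`, then one column per covariate.
#' @export
simulate_environment <- function(populations, env_model, seed = 1) {
  if (!all(c("population", "latitude") %in% names(populations)))
    stop("populations needs `population` and `latitude` columns")
  if (anyDuplicated(env_model$covariate))
    stop("duplicate covariate names in env_model")
  set.seed(as.integer(seed))
  out <- data.frame(population = populations$population,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(env_model))) {
    out[[env_model$covariate[k]]] <-
      env_model$intercept[k] + env_model$slope[k] * populations$latitude +
      stats::rnorm(nrow(populations), 0, env_model$sd[k])
  }
  out
}
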