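# Binomial logistic regression of allele frequency on latitude, fitted by
# iteratively reweighted least squares with an explicit separation cap, and
# the steep-change ("fitted range") clinal classifier built on it.

#' Fit a binomial logistic cline for one locus
#'
#' Maximizes the binomial log-likelihood of counted-allele counts
#' `k_j = p_j * m_j` out of `m_j` alleles in population j, with success
#' probability `1 / (1 + exp(-(a + b * latitude)))`, by IRLS. The fitted
#' range `dp` is the absolute difference of fitted frequencies at the
#' observed latitude extremes — the clinal classifier statistic. Complete
#' separation is handled by capping `|b|` at `cap` (flagged, intercept
#' re-profiled at the capped slope); a locus monomorphic within the lineage
#' gets a degenerate intercept-only fit with `dp = 0`.
#'
#' @param freq Counted-allele frequencies per population (NA = undefined).
#' @param m Allele sample sizes per population (2 x genotyped individuals).
#' @param latitudes Population latitudes (degrees N).
#' @param locus Locus name carried into the result.
#' @param cap Separation cap on `|b|` (per degree latitude).
#' @param tol,max_iter IRLS convergence tolerance and iteration cap.
#' @return A one-row data frame of class `cline_fit`: `locus, a, b, p_min,
#'   p_max, dp, converged, capped, degenerate, p_wald`.
#' @export
fit_locus_cline <- function(freq, m, latitudes, locus = "locus",
                            cap = 50, tol = 1e-8, max_iter = 100L) {
  ok <- is.finite(freq) & is.finite(m) & m > 0 & is.finite(latitudes)
  if (sum(ok) < 3) stop("need >= 3 populations with defined frequency")
  x <- latitudes[ok]; m_j <- m[ok]; k_j <- freq[ok] * m_j
  if (length(unique(x)) < 2) stop("latitudes must not all be equal")
  xr <- range(x)

  res <- irls_binomial(k_j, m_j, x, cap = cap, tol = tol, max_iter = max_iter)
  p_ends <- stats::plogis(res$a + res$b * xr)
  out <- data.frame(locus = locus, a = res$a, b = res$b,
                    p_min = p_ends[1], p_max = p_ends[2],
                    dp = abs(p_ends[2] - p_ends[1]),
                    converged = res$converged, capped = res$capped,
                    degenerate = res$degenerate, p_wald = res$p_wald,
                    stringsAsFactors = FALSE)
  class(out) <- c("cline_fit", class(out))
  out
}

# IRLS core shared with the generalized logistic coefficient models: k may
# be fractional (quasi-binomial), m are prior weights.
irls_binomial <- function(k, m, x, cap = 50, tol = 1e-8, max_iter = 100L) {
  if (all(k <= 0) || all(k >= m)) {
    # monomorphic within lineage: perfect intercept-only fit
    pbar <- sum(k) / sum(m)
    a <- stats::qlogis(min(max(pbar, 1e-12), 1 - 1e-12))
    return(list(a = a, b = 0, converged = TRUE, capped = FALSE,
                degenerate = TRUE, p_wald = NA_real_, logL = 0))
  }
  # exact complete separation (all fixed 0 or m, perfectly ordered in x):
  # the MLE slope diverges, so jump straight to the capped fit
  fixed0 <- k == 0; fixed1 <- k == m
  if (all(fixed0 | fixed1) && any(fixed0) && any(fixed1) &&
      (max(x[fixed0]) < min(x[fixed1]) || max(x[fixed1]) < min(x[fixed0]))) {
    b <- if (max(x[fixed0]) < min(x[fixed1])) cap else -cap
    mid <- if (b > 0) (max(x[fixed0]) + min(x[fixed1])) / 2
           else (max(x[fixed1]) + min(x[fixed0])) / 2
    a <- profile_intercept(k, m, x, b, -b * mid)
    mu <- pmin(pmax(stats::plogis(a + b * x), 1e-12), 1 - 1e-12)
    return(list(a = a, b = b, converged = FALSE, capped = TRUE,
                degenerate = FALSE, p_wald = NA_real_,
                logL = sum(k * log(mu) + (m - k) * log(1 - mu))))
  }

  X <- cbind(1, x)
  pbar <- min(max(sum(k) / sum(m), 1e-6), 1 - 1e-6)
  beta <- c(stats::qlogis(pbar), 0)
  converged <- FALSE; capped <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- pmax(m * mu * (1 - mu), 1e-12)
    z <- eta + (k - m * mu) / w
    new_beta <- tryCatch(
      drop(solve(crossprod(X, w * X), crossprod(X, w * z))),
      error = function(e) beta)
    if (abs(new_beta[2]) > cap) {
      capped <- TRUE
      new_beta[2] <- sign(new_beta[2]) * cap
      # re-profile the intercept at the capped slope
      new_beta[1] <- profile_intercept(k, m, x, new_beta[2], new_beta[1])
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  w <- m * mu * (1 - mu)
  info <- crossprod(X, w * X)
  se_b <- tryCatch(sqrt(solve(info)[2, 2]), error = function(e) NA_real_)
  p_wald <- if (is.finite(se_b) && se_b > 0 && !capped)
    2 * stats::pnorm(-abs(beta[2]) / se_b) else NA_real_
  logL <- sum(k * log(mu) + (m - k) * log(1 - mu))
  beta <- unname(beta)
  list(a = beta[1], b = beta[2], converged = converged && !capped,
       capped = capped, degenerate = FALSE, p_wald = p_wald, logL = logL)
}

profile_intercept <- function(k, m, x, b_fixed, a_start,
                              tol = 1e-8, max_iter = 100L) {
  a <- a_start
  for (it in seq_len(max_iter)) {
    mu <- pmin(pmax(stats::plogis(a + b_fixed * x), 1e-12), 1 - 1e-12)
    w <- pmax(m * mu * (1 - mu), 1e-12)
    step <- sum(k - m * mu) / sum(w)
    a <- a + step
    if (abs(step) < tol) break
  }
  a
}

#' Fit clines for every locus of a frequency table
#'
#' Runs [fit_locus_cline()] per locus for one lineage (each lineage is
#' analysed separately).
#'
#' @param freqs A `freq_table` from [allele_frequencies()].
#' @param lineage Optional lineage label; restricts to that lineage's
#'   populations.
#' @inheritParams fit_locus_cline
#' @return Data frame of per-locus cline fits (class `cline_fits`).
#' @export
fit_clines <- function(freqs, lineage = NULL, cap = 50, tol = 1e-8,
                       max_iter = 100L) {
  stopifnot(inherits(freqs, "freq_table"))
  keep <- if (is.null(lineage)) seq_len(nrow(freqs$p))
          else which(freqs$populations$lineage %in% lineage)
  if (length(keep) < 3) stop("need >= 3 populations in the lineage")
  lat <- freqs$populations$latitude[keep]
  fits <- lapply(seq_along(freqs$loci), function(j)
    fit_locus_cline(freqs$p[keep, j], freqs$m[keep, j], lat,
                    locus = freqs$loci[j], cap = cap, tol = tol,
                    max_iter = max_iter))
  out <- do.call(rbind, fits)
  class(out) <- c("cline_fits", "data.frame")
  out
}

#' Classify clinal loci by fitted frequency range
#'
#' A locus is clinal when its fitted allele-frequency change across the
#' lineage's latitudinal range *strictly* exceeds `threshold` and the fit
#' either converged or was separation-capped (a capped fit is a maximally
#' steep cline, not a failure). The logistic functional form already
#' guarantees a monotone sigmoid with exponentially decaying tails, so no
#' further shape vetting is applied.
#'
#' @param fits Per-locus fits from [fit_clines()].
#' @param threshold Fitted-range threshold (default 0.40).
#' @return A list of class `clinal_set`: `threshold`, `loci` (ordered
#'   clinal locus names), and `fits` (their rows).
#' @export
classify_clinal <- function(fits, threshold = 0.40) {
  stopifnot(is.data.frame(fits))
  member <- fits$dp > threshold & (fits$converged | fits$capped)
  member[is.na(member)] <- FALSE
  structure(list(threshold = threshold,
                 loci = fits$locus[member],
                 fits = fits[member, , drop = FALSE]),
            class = "clinal_set")
}

#' @export
print.clinal_set <- function(x, ...) {
  cat("clinal_set:", length(x$loci), "loci with fitted range >",
      x$threshold, "\n")
  invisible(x)
}

#' Scan classification thresholds and locate the count elbow
#'
#' Counts loci whose fitted range exceeds each threshold of a grid and
#' estimates the elbow — the grid point maximizing the discrete second
#' difference of the count curve — as a diagnostic for where the steep
#' decline in selected loci occurs. The default classification threshold
#' remains whatever [classify_clinal()] is given; the scan is descriptive.
#'
#' @param fits Per-locus fits from [fit_clines()].
#' @param thresholds Strictly increasing grid in `[0, 1]`.
#' @return A list of class `threshold_scan`: `table` (data frame
#'   `threshold,count`) and `knee` (NA when the grid has < 3 points).
#' @export
threshold_scan <- function(fits, thresholds = seq(0, 0.95, by = 0.05)) {
  stopifnot(is.data.frame(fits))
  if (is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds < 0 | thresholds > 1))
    stop("thresholds must be strictly increasing within [0, 1]")
  counts <- vapply(thresholds, function(t) sum(fits$dp > t, na.rm = TRUE),
                   numeric(1))
  knee <- NA_real_
  if (length(thresholds) >= 3) {
    d2 <- counts[-c(1, 2)] - 2 * counts[-c(1, length(counts))] +
      counts[-c(length(counts) - 1, length(counts))]
    knee <- thresholds[which.max(d2) + 1L]
  }
  structure(list(table = data.frame(threshold = thresholds, count = counts),
                 knee = knee),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("threshold_scan over", nrow(x$table), "thresholds; knee at",
      format(x$knee), "\n")
  invisible(x)
}
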