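# Matrix-correlation permutation machinery shared by the isolation-by-
# distance regression and the (partial) Mantel tests. Statistics use the
# lower-triangle off-diagonal entries; non-finite pairs are dropped.

lower_vec <- function(m) m[lower.tri(m)]

check_square <- function(..., names = NULL) {
  mats <- list(...)
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1) stop("matrices must share dimensions")
  for (m in mats) {
    if (nrow(m) != ncol(m)) stop("matrices must be square")
    if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8) stop("matrices must be symmetric")
  }
  invisible(n)
}

mantel_r <- function(av, bv) {
  ok <- is.finite(av) & is.finite(bv)
  if (stats::sd(av[ok]) == 0 || stats::sd(bv[ok]) == 0)
    stop("constant off-diagonal entries: Mantel correlation undefined")
  stats::cor(av[ok], bv[ok])
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of off-diagonal entries with significance from
#' jointly permuting the rows and columns of `a`. `p = (exceedances + 1) /
#' (n_perm + 1)`.
#'
#' @param a,b Symmetric matrices with common population order.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param alternative `"greater"` (one-sided, the isolation-by-distance
#'   convention) or `"two.sided"` (on `|r|`).
#' @return A list of class `mantel_result`: `r`, `p`, `n_perm`,
#'   `alternative`.
#' @export
mantel_test <- function(a, b, n_perm = 999, seed = 1,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- check_square(a, b)
  r_obs <- mantel_r(lower_vec(a), lower_vec(b))
  set.seed(as.integer(seed))
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample(n)
    r_p <- mantel_r(lower_vec(a[idx, idx]), lower_vec(b))
    hit <- if (alternative == "greater") r_p >= r_obs else abs(r_p) >= abs(r_obs)
    if (hit) exceed <- exceed + 1L
  }
  structure(list(r = r_obs, p = (exceed + 1) / (n_perm + 1),
                 n_perm = n_perm, alternative = alternative,
                 control = NULL),
            class = "mantel_result")
}

#' Partial Mantel test controlling for a third matrix
#'
#' Correlates the residuals of `a` and `b` after matrix regression of each
#' on the control `c_mat` (off-diagonal ordinary least squares), with
#' significance from jointly permuting rows/columns of `a` and
#' re-residualizing. Two-sided by default (on `|r|`).
#'
#' @param a,b Symmetric distance matrices.
#' @param c_mat Symmetric control matrix (e.g. geographic distance).
#' @inheritParams mantel_test
#' @return A `mantel_result` with `control = "c_mat"`.
#' @export
partial_mantel <- function(a, b, c_mat, n_perm = 999, seed = 1,
                           alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n <- check_square(a, b, c_mat)
  cv <- lower_vec(c_mat)
  resid_on <- function(v) {
    ok <- is.finite(v) & is.finite(cv)
    r <- rep(NA_real_, length(v))
    r[ok] <- stats::lm.fit(cbind(1, cv[ok]), v[ok])$residuals
    r
  }
  ra <- resid_on(lower_vec(a)); rb <- resid_on(lower_vec(b))
  r_obs <- mantel_r(ra, rb)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample(n)
    r_p <- mantel_r(resid_on(lower_vec(a[idx, idx])), rb)
    hit <- if (alternative == "greater") r_p >= r_obs else abs(r_p) >= abs(r_obs)
    if (hit) exceed <- exceed + 1L
  }
  structure(list(r = r_obs, p = (exceed + 1) / (n_perm + 1),
                 n_perm = n_perm, alternative = alternative,
                 control = deparse(substitute(c_mat))),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(if (is.null(x$control)) "Mantel test" else
      paste0("Partial Mantel test (control: ", x$control, ")"),
      sprintf(": r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$alternative, x$n_perm))
  invisible(x)
}

#' Isolation-by-distance regression
#'
#' Regresses linearized F_ST, `F_ST / (1 - F_ST)`, on pairwise geographic
#' distance over unordered population pairs. The slope and r-squared come
#' from ordinary least squares; significance from a one-sided Mantel
#' permutation of population labels. Pairs with `F_ST = 1` linearize to
#' infinity and are excluded with a warning.
#'
#' @param fst_matrix Symmetric pairwise F_ST matrix.
#' @param dist_matrix Symmetric pairwise distance matrix (same order).
#' @inheritParams mantel_test
#' @return A list of class `ibd_result`: `slope`, `intercept`, `r_squared`,
#'   `mantel_p`, `n_pairs`.
#' @export
ibd_regression <- function(fst_matrix, dist_matrix, n_perm = 999, seed = 1) {
  check_square(fst_matrix, dist_matrix)
  if (any(lower_vec(dist_matrix) <= 0))
    stop("off-diagonal distances must be positive")
  lin <- fst_matrix / (1 - fst_matrix)
  if (any(is.infinite(lin[lower.tri(lin)]))) {
    warning("pairs with F_ST = 1 excluded (infinite linearization)")
    lin[is.infinite(lin)] <- NA_real_
  }
  y <- lower_vec(lin); x <- lower_vec(dist_matrix)
  ok <- is.finite(y) & is.finite(x)
  fit <- stats::lm(y[ok] ~ x[ok])
  mt <- mantel_test(lin, dist_matrix, n_perm = n_perm, seed = seed,
                    alternative = "greater")
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 mantel_r = mt$r, mantel_p = mt$p,
                 n_pairs = sum(ok), n_perm = n_perm),
            class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat(sprintf(
    "Isolation by distance: slope = %.3g, r^2 = %.3f, Mantel p = %.4g (%d pairs)\n",
    x$slope, x$r_squared, x$mantel_p, x$n_pairs))
  invisible(x)
}
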