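#' Spearman rank correlation tolerating infinite values
#'
#' Rank-based association implemented directly so that +Inf covariates
#' (sea:land residence ratios of trajectories that never crossed land) enter
#' through their ranks instead of being dropped or capped: ties receive
#' average ranks, +Inf ranks above every finite value, rho is the Pearson
#' correlation of the rank vectors, and the two-sided p-value uses the
#' t-approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of
#' freedom. An optional permutation mode replaces the t-approximation for
#' small samples.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, no missing values
#'   (+/-Inf allowed).
#' @param n_perm If positive, compute the p-value by randomly permuting `y`
#'   this many times instead of the t-approximation.
#' @return An object of class `olf_assoc`: a list with `n`, `rho`, `p_value`
#'   and `method`.
#' @export
#' @examples
#' spearman_rho(1:10, (1:10)^3)   # rho = 1
spearman_rho <- function(x, y, n_perm = 0) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed")
  n <- length(x)
  if (n < 3L) abort("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) abort("zero variance in ranks")
  rho <- cor(rx, ry)
  p <- if (n_perm > 0) {
    obs <- abs(rho)
    hits <- sum(vapply(seq_len(n_perm), function(i) {
      abs(cor(rx, sample(ry))) >= obs - 1e-12
    }, logical(1)))
    (hits + 1) / (n_perm + 1)
  } else if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  structure(
    list(n = n, rho = rho, p_value = p,
         method = if (n_perm > 0) "permutation" else "t-approximation"),
    class = "olf_assoc"
  )
}

#' Association between homing indices and air-mass covariates
#'
#' Joins the per-bird index table with the per-bird residence-count table,
#' drops birds without a consistent initial orientation (mean vector length
#' r < 0.1) and birds missing either variable, and returns the Spearman
#' association between the chosen index and covariate. This is the analysis
#' that relates deviation from west of the initial orientation to the
#' sea:land residence ratio of the air masses at the release site.
#'
#' @param indices Per-bird index tibble from [compute_indices()] (needs
#'   `bird_id`, `consistent` and the chosen `index_col`).
#' @param covariates Per-bird covariate tibble (needs `bird_id` and the
#'   chosen `covariate_col`), e.g. residence counts keyed by bird.
#' @param index_col Index column name (default `"dev_west_abs"`).
#' @param covariate_col Covariate column name (default `"ratio_sea_land"`).
#' @param n_perm Passed to [spearman_rho()].
#' @return An `olf_assoc` object; `n` is the number of birds after
#'   exclusions.
#' @export
orientation_association <- function(indices, covariates,
                                    index_col = "dev_west_abs",
                                    covariate_col = "ratio_sea_land",
                                    n_perm = 0) {
  stopifnot(index_col %in% names(indices), covariate_col %in% names(covariates))
  joined <- dplyr::inner_join(
    dplyr::filter(indices, .data$consistent),
    covariates, by = "bird_id"
  )
  x <- joined[[index_col]]
  y <- joined[[covariate_col]]
  keep <- !is.na(x) & !is.na(y) & !is.nan(y)
  if (sum(keep) == 0L) abort("empty join: no consistent birds with complete covariates")
  spearman_rho(x[keep], y[keep], n_perm = n_perm)
}

#' @export
print.olf_assoc <- function(x, ...) {
  cat(sprintf("Spearman association (%s): n = %d, rho = %.3f, p = %.3g\n",
              x$method, x$n, x$rho, x$p_value))
  invisible(x)
}

#' Tidy an association result
#'
#' @param x An `olf_assoc` object.
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `statistic`, `p.value`,
#'   `method` (tidy) or `n`, `rho`, `p.value`, `method` (glance).
#' @importFrom generics tidy glance
#' @method tidy olf_assoc
#' @export
tidy.olf_assoc <- function(x, ...) {
  tibble::tibble(
    estimate = x$rho,
    statistic = if (abs(x$rho) < 1) x$rho * sqrt((x$n - 2) / (1 - x$rho^2)) else Inf * sign(x$rho),
    p.value = x$p_value,
    method = paste("Spearman", x$method)
  )
}

#' @rdname tidy.olf_assoc
#' @method glance olf_assoc
#' @export
glance.olf_assoc <- function(x, ...) {
  tibble::tibble(n = x$n, rho = x$rho, p.value = x$p_value, method = x$method)
}

#' @export
generics::tidy

#' @export
generics::glance
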