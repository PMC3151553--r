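#' Haplotype sampling completeness (equal-frequency urn estimator)
#'
#' Given `n` sampled individuals showing `h` distinct haplotypes, treats
#' the population as an urn of `k` equally frequent haplotypes and
#' evaluates the likelihood `L(k) = k (k-1) ... (k-h+1) / k^n` (the
#' Stirling-number factor counting set partitions is constant in `k` and
#' cancels) over `k = h, ..., k_max` in log space. With a uniform prior on
#' `k`:
#' * `p_complete` -- posterior probability that all haplotypes were
#'   sampled, `L(h) / sum_k L(k)`;
#' * `h_hat` -- maximum-likelihood (= posterior mode) true haplotype
#'   count, ties broken to the smaller `k`.
#'
#' @param n Sample size (individuals), `n >= h`.
#' @param h Observed number of distinct haplotypes, `h >= 1`.
#' @param k_max Upper bound of the uniform prior on the true haplotype
#'   number (default 1000).
#' @return List with `p_complete`, `h_hat` and `posterior` (data.frame
#'   `k`, `prob` summing to 1).
#' @examples
#' completeness(2, 1)$p_complete   # ~0.134
#' completeness(65, 23)$h_hat      # 24
#' @export
completeness <- function(n, h, k_max = 1000) {
  stopifnot(length(n) == 1L, length(h) == 1L)
  if (h < 1) stop("h must be >= 1")
  if (h > n) stop("h must not exceed n")
  if (k_max < h) stop("k_max must be >= h")
  ks <- h:k_max
  # log L(k) = sum_{i=0}^{h-1} log(k - i) - n log k
  ll <- lgamma(ks + 1) - lgamma(ks - h + 1) - n * log(ks)
  m <- max(ll)
  w <- exp(ll - m)
  post <- w / sum(w)
  list(p_complete = post[1],
       h_hat = ks[which.max(ll)],
       posterior = data.frame(k = ks, prob = post))
}

#' Completeness estimates for an island table
#'
#' Adds `h_hat` and `p_complete` columns to a distributional-island table.
#' Rows with `n == h` are marked not applicable (`NA`): with every
#' individual showing a distinct haplotype the sample carries no
#' information about how many haplotypes remain unseen, so completeness is
#' only evaluated when `n > h`.
#'
#' @param islands Island data.frame (see [read_island_table()]).
#' @param k_max Prior upper bound, see [completeness()].
#' @return The input data.frame with `h_hat` and `p_complete` appended.
#' @export
island_completeness <- function(islands, k_max = 1000) {
  stopifnot(all(c("n", "h") %in% names(islands)))
  islands$h_hat <- NA_integer_
  islands$p_complete <- NA_real_
  for (i in seq_len(nrow(islands))) {
    if (islands$n[i] > islands$h[i]) {
      cp <- completeness(islands$n[i], islands$h[i], k_max = k_max)
      islands$h_hat[i] <- cp$h_hat
      islands$p_complete[i] <- cp$p_complete
    }
  }
  islands
}

ols_result <- function(fit) {
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n = length(stats::fitted(fit)))
}

#' Haplotype-area regression
#'
#' Ordinary least squares of the observed number of unique composite
#' haplotypes `h` on `log10` distributional-island area -- the
#' haplotype-area curve, formally analogous to a species-area curve but
#' explained by population-genetic equilibrium between mutation and drift.
#'
#' @param islands Island data.frame with columns `log10_area_km2` and `h`.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`
#'   (two-sided t test on the slope, n - 2 df) and `n`.
#' @export
haplotype_area_regression <- function(islands) {
  stopifnot(all(c("log10_area_km2", "h") %in% names(islands)))
  if (nrow(islands) < 3L) stop("need at least 3 islands")
  if (stats::var(islands$log10_area_km2) == 0)
    stop("zero variance in log10 area")
  ols_result(stats::lm(h ~ log10_area_km2, data = islands))
}

#' Haplotype count versus sample size, with leverage diagnostics
#'
#' OLS of per-locality haplotype count on the number of individuals
#' sampled, plus hat values and a leave-one-out table of slope and slope-P
#' with each locality removed. A locality is flagged influential when its
#' removal flips the significance of the slope at `alpha`.
#'
#' @param df Data.frame with columns `n` (individuals) and `h`
#'   (haplotypes), optionally `locality_id`.
#' @param alpha Significance level for the influence flag (default 0.05).
#' @return List with the elements of [haplotype_area_regression()]'s
#'   return plus `leverage` (hat values) and `loo` (data.frame:
#'   `dropped`, `slope`, `p_value`, `flips_significance`).
#' @export
haplotype_samplesize_regression <- function(df, alpha = 0.05) {
  stopifnot(all(c("n", "h") %in% names(df)))
  if (nrow(df) < 3L) stop("need at least 3 localities")
  if (stats::var(df$n) == 0) stop("zero variance in sample size")
  fit <- stats::lm(h ~ n, data = df)
  res <- ols_result(fit)
  res$leverage <- unname(stats::hatvalues(fit))
  ids <- if ("locality_id" %in% names(df)) df$locality_id
  else as.character(seq_len(nrow(df)))
  sig_full <- res$p_value < alpha
  loo <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    f <- stats::lm(h ~ n, data = df[-i, ])
    r <- ols_result(f)
    data.frame(dropped = ids[i], slope = r$slope, p_value = r$p_value,
               flips_significance = (r$p_value < alpha) != sig_full,
               stringsAsFactors = FALSE)
  }))
  res$loo <- loo
  res
}
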