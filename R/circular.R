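#' Axial bearing between two coordinates
#'
#' Initial great-circle (spherical) forward azimuth from point A to point B,
#' folded modulo 180 degrees so that the A/B ordering is irrelevant up to
#' the small spherical azimuth asymmetry (documented to stay below 0.5
#' degrees for pairs less than ~500 km apart at mid latitudes). A planar
#' (plate carree) option is provided for comparison with map-measured
#' bearings.
#'
#' @param lat_a,lon_a,lat_b,lon_b Decimal-degree WGS84 coordinates.
#' @param method `"sphere"` (initial great-circle azimuth, default) or
#'   `"planar"` (equirectangular local approximation).
#' @return Axial angle in degrees in `[0, 180)`.
#' @examples
#' axial_bearing(39, -117, 41, -117) # due north -> 0
#' @export
axial_bearing <- function(lat_a, lon_a, lat_b, lon_b,
                          method = c("sphere", "planar")) {
  method <- match.arg(method)
  if (isTRUE(all(lat_a == lat_b & lon_a == lon_b)))
    stop("coincident coordinates: bearing undefined")
  p1 <- c(lat_a, lon_a) * pi / 180
  p2 <- c(lat_b, lon_b) * pi / 180
  if (method == "sphere") {
    dlon <- p2[2] - p1[2]
    theta <- atan2(sin(dlon) * cos(p2[1]),
                   cos(p1[1]) * sin(p2[1]) -
                     sin(p1[1]) * cos(p2[1]) * cos(dlon))
  } else {
    theta <- atan2((p2[2] - p1[2]) * cos((p1[1] + p2[1]) / 2),
                   p2[1] - p1[1])
  }
  (theta * 180 / pi) %% 180
}

#' Bearing between two localities of a locality table
#'
#' Applies [axial_bearing()] from the lexicographically smaller
#' `locality_id` to the larger, making results independent of argument
#' order.
#'
#' @param localities Locality data.frame (see [read_locality_table()]).
#' @param id_a,id_b Locality ids.
#' @inheritParams axial_bearing
#' @return Axial angle in degrees in `[0, 180)`.
#' @export
locality_bearing <- function(localities, id_a, id_b,
                             method = c("sphere", "planar")) {
  method <- match.arg(method)
  if (id_a == id_b) stop("bearing of a locality with itself is undefined")
  ids <- sort(c(id_a, id_b))
  rows <- match(ids, localities$locality_id)
  if (anyNA(rows))
    stop("unresolvable locality reference: ",
         paste(ids[is.na(rows)], collapse = ", "))
  axial_bearing(localities$lat[rows[1]], localities$lon[rows[1]],
                localities$lat[rows[2]], localities$lon[rows[2]],
                method = method)
}

check_axial <- function(angles) {
  if (length(angles) == 0L) stop("empty angle sample")
  if (any(angles < 0 | angles >= 180))
    stop("axial angles must lie in [0, 180)")
  angles
}

#' Axial mean direction and mean resultant length
#'
#' Standard axial summary: angles are doubled onto the full circle, the
#' mean resultant is computed there, and the mean direction is halved back.
#' Because the data are axial, the mean axis mu is reported together with
#' its reciprocal mu + 180.
#'
#' @param angles Axial angles in degrees in `[0, 180)`.
#' @return List with `mu` (degrees in `[0,180)`, NA when `rbar` is 0),
#'   `mu_reciprocal`, `rbar` (mean resultant length on doubled angles) and
#'   `n`.
#' @export
axial_summary <- function(angles) {
  angles <- check_axial(angles)
  a2 <- 2 * angles * pi / 180
  C <- sum(cos(a2)); S <- sum(sin(a2))
  n <- length(angles)
  rbar <- sqrt(C^2 + S^2) / n
  mu <- if (rbar < 1e-12) NA_real_ else
    ((atan2(S, C) * 180 / pi) %% 360) / 2
  list(mu = mu, mu_reciprocal = if (is.na(mu)) NA_real_ else mu + 180,
       rbar = rbar, n = n)
}

circ_result <- function(method, statistic, p_value = NA_real_,
                        p_band = NA_character_, n, ...) {
  structure(c(list(method = method, statistic = statistic,
                   p_value = p_value, p_band = p_band, n = n), list(...)),
            class = "circ_test")
}

#' @export
print.circ_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4f, n = %s\n", x$statistic,
              paste(x$n, collapse = "/")))
  if (!is.na(x$p_value)) cat(sprintf("  P = %.4g\n", x$p_value))
  if (!is.na(x$p_band)) cat(sprintf("  P %s (tabulated bands)\n", x$p_band))
  if (!is.null(x$p_mc) && !is.na(x$p_mc))
    cat(sprintf("  Monte-Carlo P = %.4g (%d reps)\n", x$p_mc, x$mc_reps))
  invisible(x)
}

# Monte-Carlo P for a uniformity statistic on axial data
mc_uniformity_p <- function(stat_fun, stat_obs, n, reps, seed) {
  if (!is.null(seed)) set.seed(seed)
  sims <- vapply(seq_len(reps), function(i) stat_fun(runif(n, 0, 180)), 0)
  (1 + sum(sims >= stat_obs)) / (reps + 1)
}

rayleigh_stat <- function(angles) {
  a2 <- 2 * angles * pi / 180
  n <- length(angles)
  (sum(cos(a2))^2 + sum(sin(a2))^2) / n
}

# series approximation to the Rayleigh P, clamped to [0, 1]
rayleigh_series_p <- function(Z, n) {
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  min(1, max(0, p))
}

#' Rayleigh test of uniformity for axial data
#'
#' Angles are doubled and the Rayleigh statistic Z = n * Rbar^2 computed on
#' the doubled circle. P uses the standard series approximation
#' `exp(-Z) * (1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2))`,
#' clamped to `[0, 1]`. The Rayleigh test is powerful against unimodal
#' (here: single-axis) alternatives.
#'
#' @param angles Axial angles in degrees in `[0, 180)`.
#' @param mc_reps Optional Monte-Carlo replicate count for an exact
#'   simulated P (uniform null).
#' @param seed Seed for the Monte-Carlo P.
#' @return A `circ_test` with statistic Z.
#' @export
rayleigh_test <- function(angles, mc_reps = NULL, seed = NULL) {
  angles <- check_axial(angles)
  n <- length(angles)
  if (n < 4) warning("Rayleigh test with n < 4 has little power")
  Z <- rayleigh_stat(angles)
  res <- circ_result("Rayleigh uniformity test (axial)", Z,
                     p_value = rayleigh_series_p(Z, n), n = n)
  if (!is.null(mc_reps)) {
    res$p_mc <- mc_uniformity_p(rayleigh_stat, Z, n, mc_reps, seed)
    res$mc_reps <- mc_reps
  }
  res
}

rao_stat <- function(angles) {
  a2 <- sort((2 * angles) %% 360)
  n <- length(a2)
  sp <- diff(c(a2, a2[1] + 360))
  0.5 * sum(abs(sp - 360 / n))
}

# regenerates one row of the packaged Rao critical-value table: upper
# quantiles of U under the exact uniform null at sample size n (this is
# how .rao_crit in R/rao_table.R was produced, at reps = 2e5 for n <= 50)
rao_crit_simulate <- function(n, reps = 2e5, seed = 20110601) {
  set.seed(seed)
  u <- vapply(seq_len(reps), function(i) rao_stat(stats::runif(n, 0, 180)), 0)
  stats::quantile(u, c(0.90, 0.95, 0.99, 0.999), names = FALSE)
}

# interpolate packaged critical values at sample size n
rao_critical <- function(n) {
  tab <- .rao_crit
  if (n <= tab$n[1]) return(tab[1, -1])
  if (n >= tab$n[nrow(tab)]) return(tab[nrow(tab), -1])
  i <- findInterval(n, tab$n)
  w <- (n - tab$n[i]) / (tab$n[i + 1] - tab$n[i])
  (1 - w) * tab[i, -1] + w * tab[i + 1, -1]
}

#' Rao spacing test of uniformity for axial data
#'
#' On the doubled angles sorted ascending, with circular spacings `T_i`
#' (including the wrap-around spacing), the statistic is
#' `U = 0.5 * sum(|T_i - 360/n|)` in degrees. Large U means spacings far
#' from equal, i.e. clustering. P is reported as a band against the
#' packaged critical-value table (levels 0.10 / 0.05 / 0.01 / 0.001,
#' linear interpolation in n); the table was computed by large-scale
#' Monte-Carlo simulation of the exact null.
#'
#' @inheritParams rayleigh_test
#' @return A `circ_test` with statistic U and a `p_band` string.
#' @export
rao_spacing_test <- function(angles, mc_reps = NULL, seed = NULL) {
  angles <- check_axial(angles)
  n <- length(angles)
  if (n < 4) stop("Rao spacing test requires n >= 4")
  U <- rao_stat(angles)
  cv <- rao_critical(n)
  band <- if (U >= cv$c0001) "<0.001"
  else if (U >= cv$c001) "<0.01"
  else if (U >= cv$c005) "<0.05"
  else if (U >= cv$c010) "<0.10"
  else ">=0.10"
  res <- circ_result("Rao spacing test (axial)", U, p_band = band, n = n,
                     critical_values = cv)
  if (!is.null(mc_reps)) {
    res$p_mc <- mc_uniformity_p(rao_stat, U, n, mc_reps, seed)
    res$mc_reps <- mc_reps
  }
  res
}

kuiper_vstar <- function(angles) {
  u <- sort(((2 * angles) %% 360) / 360)
  n <- length(u)
  i <- seq_len(n)
  dp <- max(i / n - u)
  dm <- max(u - (i - 1) / n)
  (dp + dm) * (sqrt(n) + 0.155 + 0.24 / sqrt(n))
}

kuiper_series_p <- function(vstar) {
  if (vstar < 0.05) return(1)  # series terms decay too slowly; P is 1 here
  p <- 0
  for (j in 1:1000) {
    term <- (4 * j^2 * vstar^2 - 1) * exp(-2 * j^2 * vstar^2)
    p <- p + term
    if (abs(term) < 1e-12) break
  }
  min(1, max(0, 2 * p))
}

#' Kuiper test of uniformity for axial data
#'
#' Rotation-invariant Kolmogorov-type test on the doubled angles. The raw
#' statistic `V = D+ + D-` is standardised to
#' `V* = V * (sqrt(n) + 0.155 + 0.24/sqrt(n))` and P evaluated by the
#' asymptotic series `2 * sum_j (4 j^2 V*^2 - 1) exp(-2 j^2 V*^2)`.
#'
#' @inheritParams rayleigh_test
#' @return A `circ_test` with statistic V* (raw V in `$v_raw`).
#' @export
kuiper_test <- function(angles, mc_reps = NULL, seed = NULL) {
  angles <- check_axial(angles)
  n <- length(angles)
  if (n < 5) warning("Kuiper test with n < 5 has little power")
  vstar <- kuiper_vstar(angles)
  res <- circ_result("Kuiper uniformity test (axial)", vstar,
                     p_value = kuiper_series_p(vstar), n = n,
                     v_raw = vstar / (sqrt(n) + 0.155 + 0.24 / sqrt(n)))
  if (!is.null(mc_reps)) {
    res$p_mc <- mc_uniformity_p(kuiper_vstar, vstar, n, mc_reps, seed)
    res$mc_reps <- mc_reps
  }
  res
}

# uniform-scores statistic for two samples of doubled angles; ties get
# midranks
mww_stat <- function(a2_pooled, n1) {
  N <- length(a2_pooled)
  r <- rank(a2_pooled, ties.method = "average")
  beta <- 2 * pi * r / N
  i1 <- seq_len(n1)
  C1 <- sum(cos(beta[i1])); S1 <- sum(sin(beta[i1]))
  C2 <- sum(cos(beta[-i1])); S2 <- sum(sin(beta[-i1]))
  2 * ((C1^2 + S1^2) / n1 + (C2^2 + S2^2) / (N - n1))
}

mc_twosample_p <- function(stat_fun, stat_obs, pooled, n1, reps, seed) {
  if (!is.null(seed)) set.seed(seed)
  N <- length(pooled)
  sims <- vapply(seq_len(reps), function(i) {
    stat_fun(pooled[sample.int(N)], n1)
  }, 0)
  (1 + sum(sims >= stat_obs)) / (reps + 1)
}

# number of label arrangements below which the two-sample tests switch
# from the asymptotic approximation to exact permutation enumeration
EXACT_ENUM_LIMIT <- 250000

# exact permutation P for a two-sample statistic: enumerate every
# assignment of n1 of the N pooled values to sample A. Both statistics
# used here depend on the pooled values only through the sorted order, so
# the enumeration works on sorted positions in vectorised chunks.
exact_two_sample_p <- function(pooled, n1, stat_obs,
                               kind = c("mww", "watson")) {
  kind <- match.arg(kind)
  N <- length(pooled)
  n2 <- N - n1
  o <- order(pooled)
  vals <- pooled[o]
  idx <- utils::combn(N, n1)
  K <- ncol(idx)
  if (kind == "mww") {
    r <- rank(vals, ties.method = "average")
    beta <- 2 * pi * r / N
    cb <- cos(beta); sb <- sin(beta)
    Ctot <- sum(cb); Stot <- sum(sb)
    C1 <- colSums(matrix(cb[idx], nrow = n1))
    S1 <- colSums(matrix(sb[idx], nrow = n1))
    stats <- 2 * ((C1^2 + S1^2) / n1 +
                    ((Ctot - C1)^2 + (Stot - S1)^2) / n2)
  } else {
    grp_end <- which(c(vals[-1] != vals[-N], TRUE))
    t_w <- diff(c(0L, grp_end))
    L <- matrix(0, length(grp_end), N)
    for (g in seq_along(grp_end)) L[g, seq_len(grp_end[g])] <- 1
    stats <- numeric(K)
    chunk <- 50000L
    done <- 0L
    while (done < K) {
      kk <- min(chunk, K - done)
      cols <- done + seq_len(kk)
      Z <- matrix(0, N, kk)
      Z[cbind(as.vector(idx[, cols]), rep(seq_len(kk), each = n1))] <- 1
      cumA <- L %*% Z                      # cumulative A-counts at group ends
      d <- cumA / n1 - (grp_end - cumA) / n2
      stats[cols] <- (n1 * n2 / N^2) *
        (colSums(t_w * d^2) - colSums(t_w * d)^2 / N)
      done <- done + kk
    }
  }
  mean(stats >= stat_obs - 1e-12)
}

#' Mardia-Watson-Wheeler two-sample test for axial data
#'
#' Uniform-scores test of equality of two angular distributions: pooled
#' doubled angles are ranked, mapped to equally spaced scores on the
#' circle, and the statistic `W = 2 * sum_j (C_j^2 + S_j^2) / n_j`
#' referred to chi-square with 2 df. For small samples (at most 250,000
#' label arrangements, e.g. two samples of 10) the P value is instead
#' computed by exact enumeration of the permutation null, where the
#' chi-square approximation is visibly biased in the body of the
#' distribution. Ties are broken by midranks; when
#' more than 10% of pooled values tie, a warning suggests the permutation
#' P (`mc_reps`).
#'
#' @param angles_a,angles_b Axial angle samples in degrees in `[0, 180)`.
#' @param mc_reps Optional permutation replicate count.
#' @param seed Seed for the permutation P.
#' @return A `circ_test` with statistic W; `n` holds `c(n1, n2)`.
#' @export
mww_test <- function(angles_a, angles_b, mc_reps = NULL, seed = NULL) {
  angles_a <- check_axial(angles_a); angles_b <- check_axial(angles_b)
  n1 <- length(angles_a); n2 <- length(angles_b)
  if (n1 < 5 || n2 < 5)
    warning("Mardia-Watson-Wheeler test recommended for n1, n2 >= 5")
  pooled <- c((2 * angles_a) %% 360, (2 * angles_b) %% 360)
  if (length(unique(pooled)) == 1L)
    stop("all pooled angles identical; test undefined")
  tie_frac <- 1 - length(unique(pooled)) / length(pooled)
  if (tie_frac > 0.10)
    warning(sprintf("%.0f%% of pooled angles tie; midranks used - consider ",
                    100 * tie_frac), "the Monte-Carlo P (mc_reps)")
  W <- mww_stat(pooled, n1)
  exact <- choose(n1 + n2, n1) <= EXACT_ENUM_LIMIT
  p <- if (exact) exact_two_sample_p(pooled, n1, W, "mww")
  else stats::pchisq(W, df = 2, lower.tail = FALSE)
  res <- circ_result("Mardia-Watson-Wheeler two-sample test (axial)", W,
                     p_value = p, n = c(n1, n2),
                     p_method = if (exact) "exact enumeration"
                     else "chi-square(2) approximation")
  if (!is.null(mc_reps)) {
    res$p_mc <- mc_twosample_p(mww_stat, W, pooled, n1, mc_reps, seed)
    res$mc_reps <- mc_reps
  }
  res
}

watson_u2_stat <- function(a2_pooled, n1) {
  N <- length(a2_pooled)
  o <- order(a2_pooled)
  vals <- a2_pooled[o]
  is_a <- c(rep(TRUE, n1), rep(FALSE, N - n1))[o]
  n2 <- N - n1
  # evaluate the ECDF difference once per distinct pooled value, weighting
  # tied groups by their multiplicity (reduces to the plain sum when all
  # values are distinct)
  grp_end <- which(c(vals[-1] != vals[-N], TRUE))
  d <- (cumsum(is_a) / n1 - cumsum(!is_a) / n2)[grp_end]
  t_w <- diff(c(0L, grp_end))
  (n1 * n2 / N^2) * (sum(t_w * d^2) - sum(t_w * d)^2 / N)
}

watson_series_p <- function(u2) {
  if (u2 < 0.002) return(1)  # series terms decay too slowly; P is 1 here
  p <- 0
  for (m in 1:1000) {
    term <- (-1)^(m - 1) * exp(-2 * m^2 * pi^2 * u2)
    p <- p + term
    if (abs(term) < 1e-12) break
  }
  min(1, max(0, 2 * p))
}

#' Watson U2 two-sample test for axial data
#'
#' Cramer-von-Mises-type comparison of two angular distributions on the
#' doubled circle: at each ordered pooled value the difference of the two
#' empirical CDFs is taken, and
#' `U2 = (n1 n2 / N^2) * (sum(d^2) - sum(d)^2 / N)` (tied pooled values
#' are handled as weighted groups). P by the asymptotic series
#' `2 * sum_m (-1)^(m-1) exp(-2 m^2 pi^2 U2)`; for small samples (at most
#' 250,000 label arrangements) the exact permutation null is enumerated
#' instead, since the asymptotic body is shifted at such sizes.
#'
#' @inheritParams mww_test
#' @return A `circ_test` with statistic U2; `n` holds `c(n1, n2)`.
#' @export
watson_u2_test <- function(angles_a, angles_b, mc_reps = NULL, seed = NULL) {
  angles_a <- check_axial(angles_a); angles_b <- check_axial(angles_b)
  n1 <- length(angles_a); n2 <- length(angles_b)
  if (n1 < 5 || n2 < 5)
    warning("Watson U2 test recommended for n1, n2 >= 5")
  pooled <- c((2 * angles_a) %% 360, (2 * angles_b) %% 360)
  if (length(unique(pooled)) == 1L)
    stop("all pooled angles identical; test undefined")
  U2 <- watson_u2_stat(pooled, n1)
  exact <- choose(n1 + n2, n1) <= EXACT_ENUM_LIMIT
  p <- if (exact) exact_two_sample_p(pooled, n1, U2, "watson")
  else watson_series_p(U2)
  res <- circ_result("Watson U2 two-sample test (axial)", U2,
                     p_value = p, n = c(n1, n2),
                     p_method = if (exact) "exact enumeration"
                     else "asymptotic series")
  if (!is.null(mc_reps)) {
    res$p_mc <- mc_twosample_p(watson_u2_stat, U2, pooled, n1, mc_reps, seed)
    res$mc_reps <- mc_reps
  }
  res
}

#' Directional analysis of phylogeographical patterns (DAPP)
#'
#' Full pipeline from haplotype-sharing patterns to circular statistics:
#' computes the axial bearing of every pairwise locality combination of
#' every shared haplotype, groups the bearings into named orientation
#' patterns, summarises each pattern (mean axis, resultant length), runs
#' the three uniformity tests per pattern, and compares every pair of
#' patterns with the Mardia-Watson-Wheeler and Watson U2 tests. Patterns
#' with fewer than 4 bearings are flagged under-powered and skipped by the
#' uniformity tests.
#'
#' @param sharing Data.frame of sharing patterns (`haplotype_id`,
#'   list-column `localities`), e.g. `classify_private()$shared`.
#' @param localities Locality data.frame with coordinates.
#' @param pattern_assignment Named character vector haplotype_id -> pattern
#'   label; `NULL` puts every haplotype in one `"all"` pattern.
#' @param method Bearing method, see [axial_bearing()].
#' @param mc_reps,seed Optional Monte-Carlo settings passed to the tests.
#' @return List with `bearings` (provenance data.frame: haplotype, locality
#'   pair, angle, pattern), `patterns` (per-pattern list: `angles`,
#'   `summary`, `rayleigh`, `rao`, `kuiper`, `underpowered`),
#'   `comparisons` (per pattern pair: `mww`, `watson_u2`) and `pooled`
#'   (axial summary over all bearings).
#' @export
dapp_pipeline <- function(sharing, localities, pattern_assignment = NULL,
                          method = c("sphere", "planar"),
                          mc_reps = NULL, seed = NULL) {
  method <- match.arg(method)
  sp <- sharing_pairs(sharing)
  pairs <- sp$pairs
  if (is.null(pattern_assignment)) {
    pattern_assignment <- stats::setNames(
      rep("all", nrow(sharing)), sharing$haplotype_id)
  }
  unassigned <- setdiff(unique(pairs$haplotype_id), names(pattern_assignment))
  if (length(unassigned) > 0L)
    stop("shared haplotype(s) without a pattern label: ",
         paste(unassigned, collapse = ", "))
  pairs$angle <- vapply(seq_len(nrow(pairs)), function(i) {
    locality_bearing(localities, pairs$locality_a[i], pairs$locality_b[i],
                     method = method)
  }, 0)
  pairs$pattern <- unname(pattern_assignment[pairs$haplotype_id])

  patterns <- lapply(split(pairs, pairs$pattern), function(df) {
    ang <- df$angle
    underpowered <- length(ang) < 4L
    out <- list(angles = ang, summary = axial_summary(ang),
                underpowered = underpowered)
    if (!underpowered) {
      out$rayleigh <- rayleigh_test(ang, mc_reps = mc_reps, seed = seed)
      out$rao <- rao_spacing_test(ang, mc_reps = mc_reps, seed = seed)
      out$kuiper <- kuiper_test(ang, mc_reps = mc_reps, seed = seed)
    }
    out
  })

  labels <- names(patterns)
  comparisons <- list()
  if (length(labels) >= 2L) {
    for (ij in utils::combn(labels, 2, simplify = FALSE)) {
      key <- paste(ij, collapse = " vs ")
      a <- patterns[[ij[1]]]$angles
      b <- patterns[[ij[2]]]$angles
      comparisons[[key]] <- list(
        mww = mww_test(a, b, mc_reps = mc_reps, seed = seed),
        watson_u2 = watson_u2_test(a, b, mc_reps = mc_reps, seed = seed))
    }
  }
  list(bearings = pairs, patterns = patterns, comparisons = comparisons,
       pooled = axial_summary(pairs$angle))
}
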