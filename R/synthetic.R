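#' Configuration for the synthetic phylogeography generator
#'
#' Bundles every tunable of the generator with defaults that emulate the
#' shape of a Great Basin mtDNA phylogeography survey: a handful of
#' distributional islands spanning 2.5-5 log10 km2, a haplotype-area curve
#' with slope ~13 haplotypes per log10 km2, ~9 general localities per
#' island with a mean of ~4 individuals each, a 990-column three-partition
#' alignment, an instantaneous transition/transversion bias kappa of 4,
#' and two designed orientation patterns (a concentrated north-northeast
#' axis and an isotropic web).
#'
#' @param seed Integer seed; every generator op derives its own sub-stream
#'   deterministically from it, so ops can be re-run independently.
#' @param n_islands Number of distributional islands (= clades).
#' @param log10_area_range Range of island log10 areas (km2).
#' @param area_curve List `a`, `b`, `sigma`: true haplotype counts per
#'   island are `max(1, round(a + b * log10A + N(0, sigma)))`.
#' @param localities_per_island General localities per island.
#' @param samples_lambda Per-locality sample sizes are `1 + Poisson(lambda)`.
#' @param partitions Named integer vector of partition lengths (columns).
#' @param coding_partition Name of the protein-coding partition (frame 0).
#' @param clade_subs Expected substitutions from root to each island
#'   (clade) ancestor (Poisson).
#' @param island_subs Expected substitutions from island ancestor to each
#'   derived haplotype (Poisson, star phylogeny).
#' @param kappa Instantaneous transition/transversion bias: a substitution
#'   is a transition with probability `kappa / (kappa + 2)`.
#' @param dirichlet_alpha Concentration of per-locality haplotype
#'   frequency vectors.
#' @param window Geographic window `c(lat_min, lat_max, lon_min, lon_max)`
#'   confining locality coordinates (default a Great-Basin-like box where
#'   spherical and planar bearings agree closely).
#' @param sharing Named list of orientation-pattern designs; each element
#'   is a list with `n_hap` (number of shared haplotypes), `m` (locality
#'   multiplicities, recycled to `n_hap`), `axis` (target axial direction
#'   in degrees, or `NA` for an isotropic pattern), `kappa_axial`
#'   (von Mises concentration on doubled angles) and `span_km` (extent of
#'   a haplotype's locality chain).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_islands = 5,
                       log10_area_range = c(2.5, 5.0),
                       area_curve = list(a = -35, b = 13, sigma = 2),
                       localities_per_island = 9,
                       samples_lambda = 3,
                       partitions = c(gene16S = 542, cytb = 403, tRNAGlu = 45),
                       coding_partition = "cytb",
                       clade_subs = 25,
                       island_subs = 3,
                       kappa = 4,
                       dirichlet_alpha = 1,
                       window = c(38, 42, -120, -114),
                       sharing = list(
                         northsouth = list(n_hap = 10, m = c(5, 4, 3, 3, 3, 2, 2, 2, 2, 2),
                                           axis = 20, kappa_axial = 8, span_km = 200),
                         web = list(n_hap = 2, m = c(6, 7), axis = NA,
                                    kappa_axial = 0, span_km = 250))) {
  stopifnot(seed == round(seed), n_islands >= 1,
            length(log10_area_range) == 2,
            log10_area_range[1] <= log10_area_range[2],
            area_curve$sigma >= 0, localities_per_island >= 1,
            samples_lambda >= 0, all(partitions >= 1),
            clade_subs >= 0, island_subs >= 0, kappa > 0,
            dirichlet_alpha > 0, length(window) == 4)
  if (!is.null(names(partitions)) && !is.na(coding_partition))
    stopifnot(coding_partition %in% names(partitions))
  for (p in sharing)
    stopifnot(p$n_hap >= 0, all(p$m >= 2), p$kappa_axial >= 0, p$span_km > 0)
  structure(as.list(environment()), class = "sim_config")
}

# deterministic sub-stream: each generator op gets its own offset so ops
# can be rerun independently of call order
sim_seed <- function(cfg, offset) set.seed((cfg$seed %% 100000000L) * 10L + offset)

# von Mises sampler (Best & Fisher 1979 rejection scheme), radians
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f))) + mu) %% (2 * pi)
    }
  }
  out
}

# apply n_subs substitutions at distinct columns; transitions with
# probability kappa/(kappa+2); returns list(seq, columns)
mutate_seq <- function(chars, n_subs, kappa) {
  n_subs <- min(n_subs, length(chars))
  if (n_subs == 0L) return(list(chars = chars, columns = integer()))
  cols <- sample.int(length(chars), n_subs)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  for (j in cols) {
    base <- chars[j]
    if (stats::runif(1) < kappa / (kappa + 2)) {
      chars[j] <- transition[[base]]
    } else {
      chars[j] <- sample(transversions[[base]], 1)
    }
  }
  list(chars = chars, columns = cols)
}

# island true haplotype counts off the area curve
true_k_from_areas <- function(cfg, areas) {
  noise <- if (cfg$area_curve$sigma > 0)
    stats::rnorm(length(areas), 0, cfg$area_curve$sigma) else 0
  pmax(1, round(cfg$area_curve$a + cfg$area_curve$b * areas + noise))
}

#' Simulate a distributional-island table
#'
#' Draws island areas uniformly in the configured log10 range, true
#' haplotype counts `k` off the configured area curve, per-island sample
#' sizes from the locality design, and the observed haplotype count `h` as
#' the number of distinct draws when `n` individuals are sampled from `k`
#' equally frequent haplotypes.
#'
#' @param cfg A [sim_config()].
#' @return List with `islands` (data.frame `island_id`, `log10_area_km2`,
#'   `n`, `h`) and `truth` (list `a`, `b`, `k`).
#' @export
simulate_island_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sim_seed(cfg, 3L)
  areas <- stats::runif(cfg$n_islands, cfg$log10_area_range[1],
                        cfg$log10_area_range[2])
  k <- true_k_from_areas(cfg, areas)
  n <- vapply(seq_len(cfg$n_islands), function(i) {
    sum(1L + stats::rpois(cfg$localities_per_island, cfg$samples_lambda))
  }, 0L)
  h <- vapply(seq_len(cfg$n_islands), function(i) {
    length(unique(sample.int(k[i], n[i], replace = TRUE)))
  }, 0L)
  list(islands = data.frame(
    island_id = sprintf("I%02d", seq_len(cfg$n_islands)),
    log10_area_km2 = areas, n = n, h = h, stringsAsFactors = FALSE),
    truth = list(a = cfg$area_curve$a, b = cfg$area_curve$b, k = k))
}

#' Simulate clade-structured aligned sequences
#'
#' Root sequence drawn uniformly over A/C/G/T; island (clade) ancestors
#' derived from the root by Poisson-many substitutions; each island's `k`
#' haplotypes derived star-wise from the island ancestor; specimens
#' assigned haplotypes by sampling per-locality frequency vectors drawn
#' from a symmetric Dirichlet. Substitutions are transitions with
#' probability `kappa / (kappa + 2)`.
#'
#' @param cfg A [sim_config()].
#' @param k Optional integer vector of true haplotype counts per island;
#'   by default drawn from the configured area curve.
#' @return List with `alignment` (a [hap_alignment()]), `specimens`
#'   (data.frame `specimen_id`, `locality_id`, `group_label`) and `truth`
#'   (`k`, `mutated_columns` of the within-island star branches,
#'   `haplotype_of_specimen`, `expected_between` = expected per-site
#'   between-clade substitution load).
#' @export
simulate_sequences <- function(cfg, k = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  sim_seed(cfg, 1L)
  total_len <- sum(cfg$partitions)
  if (is.null(k)) {
    areas <- stats::runif(cfg$n_islands, cfg$log10_area_range[1],
                          cfg$log10_area_range[2])
    k <- true_k_from_areas(cfg, areas)
  }
  stopifnot(length(k) == cfg$n_islands, all(k >= 1))
  root <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)

  hap_seqs <- list()       # island -> matrix-ish list of haplotype strings
  mutated_columns <- integer()
  for (i in seq_len(cfg$n_islands)) {
    anc <- mutate_seq(root, stats::rpois(1, cfg$clade_subs), cfg$kappa)$chars
    haps <- character(k[i])
    for (j in seq_len(k[i])) {
      mt <- mutate_seq(anc, stats::rpois(1, cfg$island_subs), cfg$kappa)
      haps[j] <- paste(mt$chars, collapse = "")
      mutated_columns <- union(mutated_columns, mt$columns)
    }
    hap_seqs[[i]] <- haps
  }

  specimens <- list(); seqs <- character(); hap_of <- character()
  sid <- 0L
  for (i in seq_len(cfg$n_islands)) {
    for (l in seq_len(cfg$localities_per_island)) {
      loc_id <- sprintf("I%02d_L%02d", i, l)
      freq <- stats::rgamma(k[i], cfg$dirichlet_alpha)
      freq <- freq / sum(freq)
      n_s <- 1L + stats::rpois(1, cfg$samples_lambda)
      picks <- sample.int(k[i], n_s, replace = TRUE, prob = freq)
      for (p in picks) {
        sid <- sid + 1L
        id <- sprintf("S%04d", sid)
        seqs[id] <- hap_seqs[[i]][p]
        hap_of[id] <- sprintf("I%02d_h%03d", i, p)
        specimens[[sid]] <- data.frame(
          specimen_id = id, locality_id = loc_id,
          group_label = sprintf("I%02d", i), stringsAsFactors = FALSE)
      }
    }
  }
  ends <- cumsum(cfg$partitions)
  parts <- Map(function(s, e) c(s, e), ends - cfg$partitions, ends)
  names(parts) <- names(cfg$partitions)
  frames <- if (!is.na(cfg$coding_partition))
    stats::setNames(0L, cfg$coding_partition) else NULL
  list(alignment = hap_alignment(seqs, partitions = parts, frames = frames),
       specimens = do.call(rbind, specimens),
       truth = list(k = k, mutated_columns = sort(mutated_columns),
                    haplotype_of_specimen = hap_of,
                    island_haplotypes = hap_seqs))
}

km_offset <- function(lat, lon, bearing_deg, dist_km) {
  th <- bearing_deg * pi / 180
  c(lat = lat + dist_km * cos(th) / 110.574,
    lon = lon + dist_km * sin(th) / (111.320 * cos(lat * pi / 180)))
}

axial_dev <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Simulate localities and haplotype-sharing patterns with controlled
#' orientation
#'
#' For each designed shared haplotype an axis is drawn from the pattern's
#' axial von Mises distribution (isotropic when `kappa_axial = 0`), its
#' localities are placed along that axis inside the geographic window, and
#' the placement is accepted only when every realized pairwise axial
#' bearing deviates from the drawn axis by less than a tolerance derived
#' from the concentration (no rejection for isotropic patterns). Realized
#' bearings are returned as ground truth.
#'
#' @param cfg A [sim_config()].
#' @param max_attempts Rejection-sampling bound per haplotype.
#' @return List with `localities` (data.frame), `sharing` (data.frame with
#'   list-column `localities`, ready for [sharing_pairs()] /
#'   [dapp_pipeline()]), `pattern_assignment` (haplotype -> pattern label)
#'   and `truth` (per-haplotype drawn axis and realized bearings).
#' @export
simulate_localities_and_sharing <- function(cfg, max_attempts = 200) {
  stopifnot(inherits(cfg, "sim_config"))
  sim_seed(cfg, 2L)
  w <- cfg$window
  loc_rows <- list(); share_rows <- list(); assign <- character()
  truth <- list()
  hap_no <- 0L
  for (label in names(cfg$sharing)) {
    des <- cfg$sharing[[label]]
    if (des$n_hap == 0L) next
    m_vec <- rep_len(des$m, des$n_hap)
    isotropic <- is.na(des$axis) || des$kappa_axial <= 0
    tol <- if (isotropic) Inf else max(2, 180 / (pi * sqrt(des$kappa_axial)) / 2)
    for (hh in seq_len(des$n_hap)) {
      hap_no <- hap_no + 1L
      hap_id <- sprintf("SH%03d", hap_no)
      m <- m_vec[hh]
      axis <- if (isotropic) stats::runif(1, 0, 180) else
        ((rvonmises(1, 2 * des$axis * pi / 180, des$kappa_axial) * 180 / pi) / 2) %% 180
      placed <- NULL
      for (attempt in seq_len(max_attempts)) {
        margin_lat <- 0.55 * des$span_km / 110
        margin_lon <- 0.55 * des$span_km / 85
        clat <- stats::runif(1, w[1] + margin_lat, w[2] - margin_lat)
        clon <- stats::runif(1, w[3] + margin_lon, w[4] - margin_lon)
        if (isotropic) {
          # scatter in a disc: by rotational symmetry the pairwise bearings
          # of uniform points in a disc are uniformly distributed
          rr <- (des$span_km / 2) * sqrt(stats::runif(m))
          th <- stats::runif(m, 0, 360)
          pts <- t(vapply(seq_len(m), function(ii)
            km_offset(clat, clon, th[ii], rr[ii]), numeric(2)))
          dmat <- as.matrix(stats::dist(pts * c(110.6, 85)))
          if (min(dmat[upper.tri(dmat)]) < des$span_km / (10 * m)) next
        } else {
          # chain along the drawn axis with small perpendicular jitter
          t_pos <- sort(stats::runif(m, -des$span_km / 2, des$span_km / 2))
          if (min(diff(t_pos)) < des$span_km / (6 * m)) next
          jitter_km <- min(des$span_km / 20, des$span_km * tol / 360)
          pts <- t(vapply(seq_len(m), function(ii) {
            p <- km_offset(clat, clon, axis, t_pos[ii])
            p + c(stats::rnorm(1, 0, jitter_km / 110.574),
                  stats::rnorm(1, 0, jitter_km / 85))
          }, numeric(2)))
        }
        if (any(pts[, 1] < w[1] | pts[, 1] > w[2] |
                  pts[, 2] < w[3] | pts[, 2] > w[4])) next
        prs <- all_pairs(m)
        bearings <- vapply(seq_len(nrow(prs)), function(r) {
          axial_bearing(pts[prs[r, 1], 1], pts[prs[r, 1], 2],
                        pts[prs[r, 2], 1], pts[prs[r, 2], 2])
        }, 0)
        if (all(axial_dev(bearings, axis) <= tol)) {
          placed <- list(pts = pts, bearings = bearings)
          break
        }
      }
      if (is.null(placed))
        stop("rejection sampling failed for haplotype ", hap_id,
             " (pattern '", label, "'): axial tolerance too tight for the ",
             "window geometry")
      ids <- sprintf("%s_%s_%02d", label, hap_id, seq_len(m))
      loc_rows[[length(loc_rows) + 1L]] <- data.frame(
        locality_id = ids, name = ids,
        lat = placed$pts[, 1], lon = placed$pts[, 2],
        island_id = label, stringsAsFactors = FALSE)
      sr <- data.frame(haplotype_id = hap_id, n_localities = m,
                       stringsAsFactors = FALSE)
      sr$localities <- list(ids)
      share_rows[[length(share_rows) + 1L]] <- sr
      assign[hap_id] <- label
      truth[[hap_id]] <- list(pattern = label, axis = axis,
                              bearings = placed$bearings)
    }
  }
  localities <- validate_localities(do.call(rbind, loc_rows))
  sharing <- do.call(rbind, share_rows)
  list(localities = localities, sharing = sharing,
       pattern_assignment = assign, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Runs the three generator stages off one configuration: the island table
#' (areas, true and observed haplotype counts), the clade-structured
#' alignment with specimens (reusing the island table's true `k` so the
#' two stages agree), and the locality/sharing geometry with designed
#' orientation patterns.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `islands`, `sequences`, `geography` (the
#'   returns of the three stage functions).
#' @export
simulate_dataset <- function(cfg) {
  isl <- simulate_island_table(cfg)
  list(islands = isl,
       sequences = simulate_sequences(cfg, k = isl$truth$k),
       geography = simulate_localities_and_sharing(cfg))
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `aln.fasta`, `specimens.tsv`, `localities.tsv`, `sharing.tsv` and
#' `islands.tsv` into a directory. Output is byte-identical for a given
#' configuration seed.
#'
#' @param sim Return value of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(sim$sequences$alignment, file.path(dir, "aln.fasta"))
  write_tsv(sim$sequences$specimens, file.path(dir, "specimens.tsv"))
  write_tsv(sim$geography$localities, file.path(dir, "localities.tsv"))
  sh <- sim$geography$sharing
  write_tsv(data.frame(haplotype_id = sh$haplotype_id,
                       localities = vapply(sh$localities, paste, "",
                                           collapse = ","),
                       group = unname(sim$geography$pattern_assignment[sh$haplotype_id]),
                       stringsAsFactors = FALSE),
            file.path(dir, "sharing.tsv"))
  write_tsv(sim$islands$islands, file.path(dir, "islands.tsv"))
  invisible(dir)
}
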