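#' Base composition and chi-square homogeneity test
#'
#' Per-sequence A/C/G/T frequencies (unambiguous bases only), their mean,
#' and the standard R x 4 contingency chi-square test for heterogeneity of
#' base frequencies across sequences (df = 3(R - 1)).
#'
#' @param aln A [hap_alignment()] or `haplotype_table`.
#' @param scope Partition name or `"composite"` (ignored for a
#'   `haplotype_table`, which is already scoped).
#' @return List with `freq` (R x 4 matrix of per-sequence frequencies),
#'   `mean_freq`, `counts`, `chi_sq`, `df` and `p_value`.
#' @export
base_composition <- function(aln, scope = "composite") {
  seqs <- scoped_sequences(aln, scope)
  if (length(seqs) < 2L) stop("base composition test needs >= 2 sequences")
  counts <- t(vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    c(A = sum(ch == "A"), C = sum(ch == "C"),
      G = sum(ch == "G"), T = sum(ch == "T"))
  }, numeric(4)))
  if (any(rowSums(counts) == 0))
    stop("sequence with zero unambiguous bases: ",
         paste(names(seqs)[rowSums(counts) == 0], collapse = ", "))
  freq <- counts / rowSums(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi <- sum((counts - expected)^2 / expected)
  df <- 3 * (nrow(counts) - 1)
  list(freq = freq, mean_freq = colMeans(freq), counts = counts,
       chi_sq = chi, df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE))
}

scoped_sequences <- function(x, scope = "composite") {
  if (inherits(x, "hap_alignment")) return(alignment_scope(x, scope))
  if (inherits(x, "haplotype_table"))
    return(stats::setNames(x$sequence, x$haplotype_id))
  if (is.character(x) && !is.null(names(x))) return(toupper(x))
  stop("expected a hap_alignment, haplotype_table or named character vector")
}

#' Pairwise p-distance, transition/transversion counts and K2P distance
#'
#' Compares two equal-length aligned sequences under pairwise deletion:
#' only columns where both sequences carry an unambiguous base (A/C/G/T)
#' enter the comparison. Transitions are A<->G and C<->T; everything else
#' is a transversion. The Kimura two-parameter distance is
#' \deqn{d = -\tfrac12 \ln[(1 - 2P - Q)\sqrt{1 - 2Q}]}
#' with P and Q the transition and transversion proportions; when the
#' argument of a logarithm is non-positive the distance is flagged
#' undefined (saturation) rather than raising an error.
#'
#' @param seq_a,seq_b Sequences (character scalars) of equal length.
#' @return List with `p_distance`, `ts_count`, `tv_count`, `compared_sites`,
#'   `k2p` (NA when undefined) and `k2p_defined`.
#' @export
pairwise_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b))
    stop("sequences have unequal lengths (", length(a), " vs ", length(b), ")")
  acgt <- c("A", "C", "G", "T")
  use <- a %in% acgt & b %in% acgt
  n <- sum(use)
  if (n == 0L) stop("no comparable sites under pairwise deletion")
  ai <- a[use]; bi <- b[use]
  diff <- ai != bi
  ts <- sum(diff & ((ai == "A" & bi == "G") | (ai == "G" & bi == "A") |
                      (ai == "C" & bi == "T") | (ai == "T" & bi == "C")))
  tv <- sum(diff) - ts
  P <- ts / n; Q <- tv / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  defined <- arg1 > 0 && arg2 > 0
  k2p <- if (defined) -0.5 * log(arg1 * sqrt(arg2)) else NA_real_
  list(p_distance = (ts + tv) / n, ts_count = ts, tv_count = tv,
       compared_sites = n, k2p = k2p, k2p_defined = defined)
}

all_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(), nrow = 0, ncol = 2))
  t(utils::combn(n, 2))
}

#' Mean within- or between-group sequence divergence
#'
#' Arithmetic mean of pairwise p and K2P distances over all pairs within a
#' group, or over all cross-group pairs, reported as percentages. Pairs
#' with undefined (saturated) K2P are excluded from the K2P mean and
#' counted.
#'
#' @param table A `haplotype_table` (or named character vector of sequences).
#' @param groups Named character vector: haplotype/sequence id -> group.
#' @param mode `"within"` or `"between"`.
#' @param group_a,group_b Group labels; `group_b` only for `"between"`.
#' @return List with `mean_p_pct`, `mean_k2p_pct`, `n_pairs`,
#'   `n_undefined_k2p`.
#' @export
group_divergence <- function(table, groups, mode = c("within", "between"),
                             group_a, group_b = NULL) {
  mode <- match.arg(mode)
  seqs <- scoped_sequences(table)
  missing <- setdiff(names(seqs), names(groups))
  seqs <- seqs[names(seqs) %in% names(groups)]
  g <- unname(groups[names(seqs)])
  if (mode == "within") {
    idx <- which(g == group_a)
    if (length(idx) < 2L)
      stop("group '", group_a, "' has fewer than 2 members")
    prs <- all_pairs(length(idx))
    prs <- cbind(idx[prs[, 1]], idx[prs[, 2]])
  } else {
    if (is.null(group_b)) stop("between-mode needs group_b")
    ia <- which(g == group_a); ib <- which(g == group_b)
    if (length(ia) == 0L || length(ib) == 0L)
      stop("empty group in between-mode comparison")
    prs <- as.matrix(expand.grid(ia, ib))
  }
  p <- k <- numeric(nrow(prs))
  undef <- 0L
  for (r in seq_len(nrow(prs))) {
    d <- pairwise_distance(seqs[[prs[r, 1]]], seqs[[prs[r, 2]]])
    p[r] <- d$p_distance
    if (d$k2p_defined) k[r] <- d$k2p else { k[r] <- NA_real_; undef <- undef + 1L }
  }
  list(mean_p_pct = 100 * mean(p),
       mean_k2p_pct = 100 * mean(k, na.rm = TRUE),
       n_pairs = nrow(prs), n_undefined_k2p = undef)
}

#' Overall transition/transversion ratio
#'
#' Ratio of summed transition to summed transversion counts over all
#' unordered sequence pairs (pairwise deletion). Flagged undefined when no
#' transversions are observed.
#'
#' @param table A `haplotype_table` or named character vector.
#' @param scope Partition name when `table` is an alignment.
#' @return List with `ratio` (NA when undefined), `ts_total`, `tv_total`,
#'   `defined`.
#' @export
ts_tv_ratio <- function(table, scope = "composite") {
  seqs <- scoped_sequences(table, scope)
  if (length(seqs) < 2L) stop("need >= 2 sequences")
  prs <- all_pairs(length(seqs))
  ts <- tv <- 0L
  for (r in seq_len(nrow(prs))) {
    d <- pairwise_distance(seqs[[prs[r, 1]]], seqs[[prs[r, 2]]])
    ts <- ts + d$ts_count; tv <- tv + d$tv_count
  }
  list(ratio = if (tv > 0) ts / tv else NA_real_,
       ts_total = ts, tv_total = tv, defined = tv > 0)
}

#' Saturation series: transitions versus uncorrected p distance
#'
#' One record per unordered pair of sequences, for plotting the number of
#' transitions (and transversions) against uncorrected p distance to judge
#' substitutional saturation. Restriction to a codon position uses only the
#' columns at that offset of the declared reading frame.
#'
#' @param table A `haplotype_table` or named character vector of sequences
#'   over a protein-coding scope.
#' @param codon_position 1, 2, 3 or `"all"`.
#' @param frame Reading-frame offset (0, 1 or 2) of the first column;
#'   required when `codon_position != "all"`.
#' @return Data.frame with `id_a`, `id_b`, `p_distance`, `ts_count`,
#'   `tv_count`, `compared_sites`.
#' @export
saturation_series <- function(table, codon_position = "all", frame = NULL) {
  seqs <- scoped_sequences(table)
  if (!identical(codon_position, "all")) {
    if (is.null(frame))
      stop("codon-position restriction requires a declared reading frame")
    stopifnot(codon_position %in% 1:3, frame %in% 0:2)
    len <- nchar(seqs[[1]])
    first <- frame + as.integer(codon_position)   # 1-based column of position
    keep <- seq(from = first, to = len, by = 3)
    seqs <- vapply(seqs, function(s)
      paste(strsplit(s, "")[[1]][keep], collapse = ""), "")
  }
  prs <- all_pairs(length(seqs))
  out <- vector("list", nrow(prs))
  for (r in seq_len(nrow(prs))) {
    i <- prs[r, 1]; j <- prs[r, 2]
    d <- pairwise_distance(seqs[[i]], seqs[[j]])
    out[[r]] <- data.frame(id_a = names(seqs)[i], id_b = names(seqs)[j],
                           p_distance = d$p_distance, ts_count = d$ts_count,
                           tv_count = d$tv_count,
                           compared_sites = d$compared_sites,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
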