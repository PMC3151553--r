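#' @importFrom Biostrings getGeneticCode
NULL

# translation table; id "2" is the vertebrate mitochondrial code
genetic_code_table <- function(code = "vertebrate-mito") {
  id <- switch(code,
               "vertebrate-mito" = "2",
               "standard" = "1",
               code)
  Biostrings::getGeneticCode(id)
}

# classify the single-nucleotide steps connecting two codons as
# synonymous / non-synonymous, averaging over all minimal-step orderings;
# orderings passing through a stop codon are dropped unless all do.
# Returns c(syn, nonsyn), possibly fractional.
codon_path_classify <- function(codon_a, codon_b, code_tab) {
  ca <- strsplit(codon_a, "")[[1]]
  cb <- strsplit(codon_b, "")[[1]]
  diff <- which(ca != cb)
  d <- length(diff)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  orders <- if (d == 1L) list(diff) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
      out
    }
    perms(diff)
  }
  tally <- matrix(NA_real_, nrow = length(orders), ncol = 2)
  through_stop <- logical(length(orders))
  for (k in seq_along(orders)) {
    cur <- ca
    syn <- non <- 0
    stopped <- FALSE
    for (pos in orders[[k]]) {
      nxt <- cur
      nxt[pos] <- cb[pos]
      aa1 <- code_tab[[paste(cur, collapse = "")]]
      aa2 <- code_tab[[paste(nxt, collapse = "")]]
      if (identical(aa2, "*") && !identical(paste(nxt, collapse = ""), codon_b))
        stopped <- TRUE
      if (identical(aa1, aa2)) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    tally[k, ] <- c(syn, non)
    through_stop[k] <- stopped
  }
  keep <- if (all(through_stop)) seq_along(orders) else which(!through_stop)
  cm <- colMeans(tally[keep, , drop = FALSE])
  c(syn = cm[1], nonsyn = cm[2])
}

# codon states per triplet: list of character vectors (unambiguous codons
# observed among the sequences), with their frequencies
codon_states <- function(seqs, frame) {
  len <- nchar(seqs[[1]])
  start <- frame + 1L
  n_codons <- (len - frame) %/% 3L
  mats <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  lapply(seq_len(n_codons), function(j) {
    cols <- start + 3L * (j - 1L) + 0:2
    cods <- vapply(mats, function(ch) paste(ch[cols], collapse = ""), "")
    cods <- cods[grepl("^[ACGT]{3}$", cods)]
    if (length(cods) == 0L) return(character())
    sort(table(cods), decreasing = TRUE)
  })
}

# majority codon, lexicographic tie-break
consensus_codon <- function(tab) {
  top <- names(tab)[tab == max(tab)]
  sort(top)[1]
}

#' McDonald-Kreitman test of selective neutrality
#'
#' Contrasts the ratio of non-synonymous to synonymous fixed differences
#' between a focal group and an outgroup with the same ratio among
#' polymorphisms segregating within the groups, using a protein-coding
#' alignment scope. At each codon, a difference is *fixed* when the codon
#' state sets of the two groups are disjoint (classified between the two
#' group-consensus codons), and *polymorphic* when two or more states
#' segregate within either group (each minor state classified against the
#' group's majority codon). Codons connected by more than one nucleotide
#' change are decomposed into single steps averaged over all minimal-step
#' orderings, so counts can be fractional; both raw and rounded counts are
#' reported, and Fisher's exact test runs on the rounded 2 x 2 table.
#'
#' Three Fisher P conventions are reported: the one-tailed hypergeometric
#' tail of the observed cell, the doubled one-tailed value, and the
#' two-tailed minimum-likelihood (point-probability) value.
#'
#' @param focal,outgroup `haplotype_table`s or named character vectors of
#'   aligned coding sequences (equal lengths across both groups).
#' @param frame Reading-frame offset (0, 1 or 2) of the first column.
#' @param code Genetic code: `"vertebrate-mito"` (default), `"standard"`,
#'   or an NCBI translation-table id.
#' @return Object of class `mk_result`: counts (`fixed_nonsyn`,
#'   `fixed_syn`, `poly_nonsyn`, `poly_syn`, raw and rounded), the 2 x 2
#'   `table`, `p_one_tailed`, `p_doubled`, `p_two_tailed_minlik`, and
#'   `applicable` (FALSE when a margin of the table is empty).
#' @export
mk_test <- function(focal, outgroup, frame = 0, code = "vertebrate-mito") {
  fs <- scoped_sequences(focal)
  os <- scoped_sequences(outgroup)
  if (length(fs) == 0L || length(os) == 0L) stop("both groups must be non-empty")
  lens <- unique(nchar(c(fs, os)))
  if (length(lens) != 1L) stop("focal and outgroup sequences must align to equal length")
  stopifnot(frame %in% 0:2)
  if ((lens - frame) < 3L) stop("scope shorter than one codon at this frame")
  tab <- genetic_code_table(code)

  # warn on internal stops in representatives
  for (nm in names(c(fs[1], os[1]))) {
    s <- c(fs[1], os[1])[[nm]]
    cods <- substring(s, seq(frame + 1, nchar(s) - 2, 3),
                      seq(frame + 3, nchar(s), 3))
    cods <- cods[grepl("^[ACGT]{3}$", cods)]
    aas <- unname(tab[cods])
    if (any(aas[-length(aas)] == "*"))
      warning("internal stop codon in representative sequence '", nm, "'")
  }

  fstates <- codon_states(fs, frame)
  ostates <- codon_states(os, frame)
  counts <- c(fixed_syn = 0, fixed_nonsyn = 0, poly_syn = 0, poly_nonsyn = 0)
  for (j in seq_along(fstates)) {
    ft <- fstates[[j]]; ot <- ostates[[j]]
    if (length(ft) == 0L || length(ot) == 0L) next
    # within-group polymorphism
    for (tabg in list(ft, ot)) {
      if (length(tabg) >= 2L) {
        center <- consensus_codon(tabg)
        for (s in setdiff(names(tabg), center)) {
          cl <- codon_path_classify(center, s, tab)
          counts["poly_syn"] <- counts["poly_syn"] + cl[["syn"]]
          counts["poly_nonsyn"] <- counts["poly_nonsyn"] + cl[["nonsyn"]]
        }
      }
    }
    # fixed difference: state sets disjoint
    if (length(intersect(names(ft), names(ot))) == 0L) {
      cl <- codon_path_classify(consensus_codon(ft), consensus_codon(ot), tab)
      counts["fixed_syn"] <- counts["fixed_syn"] + cl[["syn"]]
      counts["fixed_nonsyn"] <- counts["fixed_nonsyn"] + cl[["nonsyn"]]
    }
  }
  rc <- round(counts)
  fis <- fisher_2x2(rc[["fixed_nonsyn"]], rc[["fixed_syn"]],
                    rc[["poly_nonsyn"]], rc[["poly_syn"]])
  structure(list(
    counts_raw = counts,
    fixed_nonsyn = rc[["fixed_nonsyn"]], fixed_syn = rc[["fixed_syn"]],
    poly_nonsyn = rc[["poly_nonsyn"]], poly_syn = rc[["poly_syn"]],
    table = matrix(rc[c("fixed_nonsyn", "fixed_syn",
                        "poly_nonsyn", "poly_syn")],
                   2, 2, byrow = TRUE,
                   dimnames = list(c("fixed", "polymorphic"),
                                   c("nonsyn", "syn"))),
    p_one_tailed = fis$p_one_tailed,
    p_doubled = fis$p_doubled,
    p_two_tailed_minlik = fis$p_two_tailed_minlik,
    applicable = fis$applicable), class = "mk_result")
}

#' @export
print.mk_result <- function(x, ...) {
  cat("McDonald-Kreitman test\n")
  print(x$table)
  if (!x$applicable) {
    cat("test not applicable (empty table margin)\n")
  } else {
    cat(sprintf("Fisher exact: one-tailed P = %.4g, doubled = %.4g, ",
                x$p_one_tailed, x$p_doubled))
    cat(sprintf("two-tailed (min-likelihood) P = %.4g\n", x$p_two_tailed_minlik))
  }
  invisible(x)
}

#' Fisher's exact test for a 2 x 2 table, three tail conventions
#'
#' Exact hypergeometric P values for the table `[[a, b], [c, d]]`
#' (rows: fixed / polymorphic, columns: non-synonymous / synonymous in the
#' MK application, but the function is generic). Reports the one-tailed
#' value (the smaller hypergeometric tail containing the observed cell
#' `a`), its doubling (capped at 1), and the two-tailed minimum-likelihood
#' rule (sum of all tables with point probability not exceeding the
#' observed table's).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List with `p_one_tailed`, `p_doubled`, `p_two_tailed_minlik`,
#'   `applicable` (FALSE when a margin is zero, in which case all P are NA).
#' @export
fisher_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m1 <- a + b   # row 1 total
  k <- a + c    # column 1 total
  N <- a + b + c + d
  if (m1 == 0 || k == 0 || m1 == N || k == N)
    return(list(p_one_tailed = NA_real_, p_doubled = NA_real_,
                p_two_tailed_minlik = NA_real_, applicable = FALSE))
  lo <- max(0L, m1 + k - N)
  hi <- min(m1, k)
  xs <- lo:hi
  dens <- stats::dhyper(xs, k, N - k, m1)
  p_low <- sum(dens[xs <= a])
  p_high <- sum(dens[xs >= a])
  p_one <- min(p_low, p_high)
  obs <- stats::dhyper(a, k, N - k, m1)
  p_two <- sum(dens[dens <= obs * (1 + 1e-7)])
  list(p_one_tailed = p_one,
       p_doubled = min(1, 2 * p_one),
       p_two_tailed_minlik = min(1, p_two),
       applicable = TRUE)
}
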