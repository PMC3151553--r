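#' Collapse aligned sequences into unique haplotypes
#'
#' Partitions the specimens of an alignment into equivalence classes of
#' identical sequences over the chosen scope, the standard first step before
#' haplotype-based phylogeographic analyses. Under `matching = "strict"` two
#' sequences belong to the same haplotype iff their scope columns are
#' identical strings (gap, `N` and IUPAC codes are literal states that match
#' only themselves). Under `"ambiguity"` a sequence joins an existing class
#' only if it is compatible at every column (ambiguity codes match any
#' compatible base); specimens are processed in sorted id order so the
#' result is deterministic.
#'
#' For `scope = "composite"` (concatenation of all partitions) a specimen
#' whose characters are entirely missing (`N`, `-` or `?`) in any partition
#' is excluded from collapsing and reported via `message()`.
#'
#' @param aln A [hap_alignment()].
#' @param scope Partition name or `"composite"`.
#' @param matching `"strict"` (default) or `"ambiguity"`.
#' @param specimens Optional data.frame with `specimen_id` and `locality_id`
#'   columns; when supplied each haplotype carries its locality set.
#' @return An object of class `haplotype_table`: a data.frame with one row
#'   per unique haplotype and columns `haplotype_id`, `representative`,
#'   `sequence`, `n_members`, plus list-columns `members` and (if specimens
#'   are mapped) `localities`. Haplotypes are numbered in lexicographic
#'   order of their representative (first member by sorted specimen id).
#' @export
collapse_haplotypes <- function(aln, scope = "composite",
                                matching = c("strict", "ambiguity"),
                                specimens = NULL) {
  matching <- match.arg(matching)
  seqs <- alignment_scope(aln, scope)

  if (identical(scope, "composite") && length(aln$partitions) > 1L) {
    missing_part <- rep(FALSE, length(aln$seq))
    for (nm in names(aln$partitions)) {
      part <- alignment_scope(aln, nm)
      allmiss <- !grepl("[ACGTRYSWKMBDHV]", part)
      missing_part <- missing_part | allmiss
    }
    if (any(missing_part)) {
      message("excluding ", sum(missing_part),
              " specimen(s) missing an entire partition from composite ",
              "collapsing: ", paste(names(seqs)[missing_part], collapse = ", "))
      seqs <- seqs[!missing_part]
    }
  }
  if (length(seqs) == 0L) stop("no specimens available for collapsing")
  seqs <- seqs[order(names(seqs))]

  if (matching == "strict") {
    classes <- split(names(seqs), factor(seqs, levels = unique(seqs)))
  } else {
    classes <- list()
    reps <- character()
    for (id in names(seqs)) {
      s <- seqs[[id]]
      hit <- 0L
      if (length(reps) > 0L) {
        for (j in seq_along(reps)) {
          if (iupac_compatible(reps[j], s)) { hit <- j; break }
        }
      }
      if (hit == 0L) {
        classes[[length(classes) + 1L]] <- id
        reps <- c(reps, s)
      } else {
        classes[[hit]] <- c(classes[[hit]], id)
        # refine the class representative so it stays compatible with all
        # members: replace ambiguous columns by the joining sequence's
        # unambiguous state where possible
        reps[hit] <- iupac_refine(reps[hit], s)
      }
    }
    names(classes) <- reps
  }

  representative <- vapply(classes, function(m) sort(m)[1], "")
  o <- order(representative)
  classes <- classes[o]
  representative <- representative[o]
  ht <- data.frame(
    haplotype_id = sprintf("H%03d", seq_along(classes)),
    representative = representative,
    sequence = vapply(seq_along(classes),
                      function(i) unname(seqs[[representative[i]]]), ""),
    n_members = vapply(classes, length, 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  ht$members <- unname(lapply(classes, sort))

  if (!is.null(specimens)) {
    map <- stats::setNames(specimens$locality_id, specimens$specimen_id)
    unmapped <- setdiff(names(seqs), names(map))
    if (length(unmapped) > 0L)
      stop("specimen(s) without a locality mapping: ",
           paste(unmapped, collapse = ", "))
    ht$localities <- lapply(ht$members, function(m) sort(unique(unname(map[m]))))
  }
  structure(ht, class = c("haplotype_table", "data.frame"),
            scope = scope, matching = matching)
}

# TRUE if sequences a and b are compatible at every column under IUPAC
# semantics (gap and ? only match themselves)
iupac_compatible <- function(a, b) {
  if (a == b) return(TRUE)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  diff <- which(ca != cb)
  for (i in diff) {
    if (length(intersect(IUPAC_SETS[[ca[i]]], IUPAC_SETS[[cb[i]]])) == 0L)
      return(FALSE)
  }
  TRUE
}

# narrow the representative toward unambiguous states shared with a new member
iupac_refine <- function(rep_seq, new_seq) {
  ca <- strsplit(rep_seq, "")[[1]]
  cb <- strsplit(new_seq, "")[[1]]
  amb <- ca %in% c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  use <- amb & cb %in% c("A", "C", "G", "T")
  ca[use] <- cb[use]
  paste(ca, collapse = "")
}

#' Count polymorphic sites among haplotypes
#'
#' A column is polymorphic when at least two distinct unambiguous bases
#' (`A`, `C`, `G`, `T`) occur among the haplotype sequences; sites whose
#' only differences involve gaps or ambiguity codes are not counted.
#'
#' @param table A `haplotype_table`.
#' @return Integer count of polymorphic columns.
#' @export
polymorphic_sites <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  if (nrow(table) == 0L) stop("empty haplotype table")
  if (nrow(table) == 1L) return(0L)
  m <- do.call(rbind, strsplit(table$sequence, ""))
  sum(apply(m, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2L
  }))
}

#' Classify private versus shared haplotypes
#'
#' A haplotype is private when it occurs at exactly one general locality,
#' and shared when it occurs at two or more.
#'
#' @param table A `haplotype_table` with resolved localities (built with
#'   `specimens =` in [collapse_haplotypes()]).
#' @return List with `n_total`, `n_private`, `n_shared`,
#'   `private_fraction` (percentage), `private_by_locality` (named integer
#'   vector of private-haplotype counts per locality) and `shared`
#'   (data.frame of sharing patterns: `haplotype_id`, `n_localities`,
#'   list-column `localities`).
#' @export
classify_private <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  if (is.null(table$localities))
    stop("haplotype table has no locality mapping; ",
         "collapse with a specimen table")
  m <- vapply(table$localities, length, 0L)
  private <- m == 1L
  counts <- table(unlist(table$localities[private]))
  shared <- data.frame(haplotype_id = table$haplotype_id[!private],
                       n_localities = m[!private],
                       stringsAsFactors = FALSE, row.names = NULL)
  shared$localities <- table$localities[!private]
  list(
    n_total = nrow(table),
    n_private = sum(private),
    n_shared = sum(!private),
    private_fraction = 100 * sum(private) / nrow(table),
    private_ids = table$haplotype_id[private],
    private_by_locality = stats::setNames(as.integer(counts), names(counts)),
    shared = shared)
}

#' Enumerate pairwise locality combinations of shared haplotypes
#'
#' Each haplotype shared among `m` localities contributes all
#' `choose(m, 2)` unordered locality pairs; these pairs are the raw
#' material of the directional (DAPP) analysis. A pair whose two localities
#' belong to the same group (clade) is assigned to that group; pairs
#' bridging two groups are tallied separately under `"cross-group"` (for
#' clade-structured data this category is expected to be empty).
#'
#' @param shared Data.frame of sharing patterns with columns `haplotype_id`
#'   and list-column `localities` (as returned in `classify_private()$shared`
#'   or by [read_sharing_table()]).
#' @param grouping Named character vector mapping locality id to group
#'   label, or `NULL` for no grouping.
#' @return List with `pairs` (data.frame: `haplotype_id`, `locality_a`,
#'   `locality_b`, `group`), `totals` (named integer vector per group) and
#'   `n_pairs` (overall total).
#' @export
sharing_pairs <- function(shared, grouping = NULL) {
  if (nrow(shared) == 0L)
    return(list(pairs = data.frame(), totals = integer(), n_pairs = 0L))
  m <- vapply(shared$localities, length, 0L)
  if (any(m < 2L))
    stop("sharing pattern with fewer than 2 localities: ",
         paste(shared$haplotype_id[m < 2L], collapse = ", "))
  out <- vector("list", nrow(shared))
  for (i in seq_len(nrow(shared))) {
    locs <- sort(unique(shared$localities[[i]]))
    cmb <- utils::combn(locs, 2)
    out[[i]] <- data.frame(haplotype_id = shared$haplotype_id[i],
                           locality_a = cmb[1, ], locality_b = cmb[2, ],
                           stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out)
  if (!is.null(grouping)) {
    unresolved <- setdiff(unique(c(pairs$locality_a, pairs$locality_b)),
                          names(grouping))
    if (length(unresolved) > 0L)
      stop("locality without group assignment: ",
           paste(unresolved, collapse = ", "))
    ga <- unname(grouping[pairs$locality_a])
    gb <- unname(grouping[pairs$locality_b])
    pairs$group <- ifelse(ga == gb, ga, "cross-group")
  } else {
    pairs$group <- "all"
  }
  totals <- vapply(split(pairs, pairs$group), nrow, 0L)
  list(pairs = pairs, totals = totals, n_pairs = nrow(pairs))
}

#' Read a haplotype-sharing table
#'
#' TSV with columns `haplotype_id` and `localities` (comma-separated list of
#' locality ids at which the haplotype occurs); `#` comment lines skipped.
#'
#' @param path Path to a TSV file.
#' @return Data.frame with `haplotype_id`, `n_localities` and list-column
#'   `localities`, suitable for [sharing_pairs()].
#' @export
read_sharing_table <- function(path) {
  df <- read_tsv_checked(path, c("haplotype_id", "localities"))
  locs <- lapply(strsplit(df$localities, ","), trimws)
  out <- data.frame(haplotype_id = df$haplotype_id,
                    n_localities = vapply(locs, length, 0L),
                    stringsAsFactors = FALSE)
  out$localities <- locs
  if ("group" %in% names(df)) out$group <- df$group
  out
}
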