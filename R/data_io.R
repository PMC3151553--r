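#' Multi-partition sequence alignment
#'
#' Light container for an aligned set of sequences keyed by specimen id,
#' optionally carved into named gene partitions. Partitions are 0-based,
#' half-open column intervals `[start, end)`; protein-coding partitions may
#' declare a reading-frame offset (0, 1 or 2 columns into the partition).
#'
#' @param seqs Named character vector of aligned sequences (equal length,
#'   characters from `A C G T N -` and IUPAC ambiguity codes; case is
#'   normalised to upper).
#' @param partitions Named list of length-2 integer vectors `c(start, end)`,
#'   0-based half-open. `NULL` means a single partition spanning all columns.
#' @param frames Optional named integer vector giving the reading-frame
#'   offset of coding partitions (names must be partition names).
#' @return An object of class `hap_alignment` with elements `seq`,
#'   `partitions` and `frames`.
#' @export
hap_alignment <- function(seqs, partitions = NULL, frames = NULL) {
  if (length(seqs) == 0L) stop("alignment must contain at least one sequence")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named by specimen id")
  if (anyDuplicated(names(seqs)))
    stop("duplicate specimen ids in alignment: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("aligned sequences must all have equal length; observed lengths: ",
         paste(sort(len), collapse = ", "))
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), seqs)
  if (any(bad))
    stop("sequence(s) contain characters outside the DNA/IUPAC alphabet: ",
         paste(names(seqs)[bad], collapse = ", "))
  if (is.null(partitions)) partitions <- list(all = c(0L, len))
  if (is.null(names(partitions)) || any(names(partitions) == ""))
    stop("partitions must be named")
  for (nm in names(partitions)) {
    iv <- partitions[[nm]]
    if (length(iv) != 2L || iv[1] < 0 || iv[2] > len || iv[1] >= iv[2])
      stop("partition '", nm, "' is not a valid 0-based half-open interval ",
           "within [0, ", len, ")")
  }
  ivs <- do.call(rbind, partitions)
  o <- order(ivs[, 1])
  if (any(ivs[o, 2][-nrow(ivs)] > ivs[o, 1][-1]))
    stop("partitions overlap")
  if (!is.null(frames)) {
    if (is.null(names(frames)) || !all(names(frames) %in% names(partitions)))
      stop("frames must be named by partition")
    if (!all(frames %in% 0:2)) stop("frame offsets must be 0, 1 or 2")
  }
  structure(list(seq = seqs, partitions = partitions, frames = frames),
            class = "hap_alignment")
}

# alphabet: unambiguous bases, gap, and IUPAC ambiguity codes ('-' kept
# last so the set can be pasted into a regex character class)
IUPAC_CHARS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "?", "-")

# IUPAC code -> compatible base set (gap and ? only match themselves)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  `-` = "-", `?` = "?")

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("hap_alignment: %d sequences x %d columns\n",
              length(x$seq), nchar(x$seq[[1]])))
  for (nm in names(x$partitions)) {
    iv <- x$partitions[[nm]]
    fr <- if (!is.null(x$frames) && nm %in% names(x$frames))
      sprintf(" (frame %d)", x$frames[[nm]]) else ""
    cat(sprintf("  partition %-12s [%d, %d)%s\n", nm, iv[1], iv[2], fr))
  }
  invisible(x)
}

#' Extract the columns of one partition (or the composite) as strings
#'
#' @param aln A [hap_alignment()].
#' @param scope A partition name, or `"composite"` for the concatenation of
#'   all partitions in declared order.
#' @return Named character vector of per-specimen sequences over the scope.
#' @export
alignment_scope <- function(aln, scope = "composite") {
  stopifnot(inherits(aln, "hap_alignment"))
  if (identical(scope, "composite")) {
    parts <- lapply(names(aln$partitions), function(nm) {
      iv <- aln$partitions[[nm]]
      substr(aln$seq, iv[1] + 1L, iv[2])
    })
    out <- do.call(paste0, parts)
    names(out) <- names(aln$seq)
    return(out)
  }
  if (!scope %in% names(aln$partitions))
    stop("unknown partition: '", scope, "'")
  iv <- aln$partitions[[scope]]
  out <- substr(aln$seq, iv[1] + 1L, iv[2])
  names(out) <- names(aln$seq)
  out
}

#' Read an aligned FASTA file
#'
#' @param path Path to a FASTA file of aligned sequences.
#' @inheritParams hap_alignment
#' @return A [hap_alignment()].
#' @export
read_alignment <- function(path, partitions = NULL, frames = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- vapply(as.character(dna), function(s) paste(s, collapse = ""), "")
  names(seqs) <- names(dna)
  hap_alignment(seqs, partitions = partitions, frames = frames)
}

#' Write an alignment to FASTA
#'
#' @param aln A [hap_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "hap_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(aln$seq)) {
    writeLines(paste0(">", nm), con)
    writeLines(aln$seq[[nm]], con)
  }
  invisible(path)
}

read_tsv_checked <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (cc in intersect(numeric_cols, names(df))) {
    suppressWarnings(v <- as.numeric(df[[cc]]))
    if (any(is.na(v) & !(df[[cc]] %in% c("", "NA"))))
      stop("non-numeric value in column '", cc, "' of ", path)
    df[[cc]] <- v
  }
  df
}

#' Read a locality table
#'
#' Tab-separated, UTF-8, `#` comment lines skipped. Required columns:
#' `locality_id`, `name`, `lat`, `lon`; optional `island_id`, `captures`,
#' `trapnights`. Coordinates are WGS84 decimal degrees.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of validated localities.
#' @export
read_locality_table <- function(path) {
  df <- read_tsv_checked(path, c("locality_id", "name", "lat", "lon"),
                         numeric_cols = c("lat", "lon", "captures", "trapnights"))
  validate_localities(df)
}

#' Validate a locality data.frame
#'
#' @param df Data.frame with at least `locality_id`, `lat`, `lon`.
#' @return The validated data.frame (invisibly usable in pipelines).
#' @export
validate_localities <- function(df) {
  if (anyDuplicated(df$locality_id))
    stop("duplicate locality_id: ",
         paste(unique(df$locality_id[duplicated(df$locality_id)]), collapse = ", "))
  if (any(df$lat < -90 | df$lat > 90, na.rm = TRUE))
    stop("latitude out of range [-90, 90]")
  if (any(df$lon < -180 | df$lon > 180, na.rm = TRUE))
    stop("longitude out of range [-180, 180]")
  if (all(c("captures", "trapnights") %in% names(df))) {
    bad <- !is.na(df$captures) & !is.na(df$trapnights) &
      (df$captures < 0 | df$trapnights < 0 | df$captures > df$trapnights)
    if (any(bad))
      stop("captures must satisfy 0 <= captures <= trapnights (locality ",
           paste(df$locality_id[bad], collapse = ", "), ")")
  }
  df
}

#' Read a specimen table
#'
#' Required columns: `specimen_id`, `locality_id`; optional `group_label`
#' (clade or island assignment).
#'
#' @param path Path to a TSV file.
#' @param localities Optional locality data.frame; when given, every
#'   `locality_id` must resolve against it.
#' @return Data.frame of specimens.
#' @export
read_specimen_table <- function(path, localities = NULL) {
  df <- read_tsv_checked(path, c("specimen_id", "locality_id"))
  if (anyDuplicated(df$specimen_id))
    stop("duplicate specimen_id: ",
         paste(unique(df$specimen_id[duplicated(df$specimen_id)]), collapse = ", "))
  if (!is.null(localities)) {
    unresolved <- setdiff(df$locality_id, localities$locality_id)
    if (length(unresolved) > 0L)
      stop("specimen locality_id not in locality table: ",
           paste(unresolved, collapse = ", "))
  }
  df
}

#' Read a distributional-island table
#'
#' Required columns: `island_id`, `log10_area_km2`, `n`, `h` (sample size and
#' observed number of unique composite haplotypes per island).
#'
#' @param path Path to a TSV file.
#' @return Data.frame of island records.
#' @export
read_island_table <- function(path) {
  df <- read_tsv_checked(path, c("island_id", "log10_area_km2", "n", "h"),
                         numeric_cols = c("log10_area_km2", "n", "h"))
  if (anyDuplicated(df$island_id)) stop("duplicate island_id")
  if (any(df$n < 1 | df$h < 1 | df$h > df$n))
    stop("island rows must satisfy 1 <= h <= n")
  df
}

#' Write a data.frame as a TSV table
#'
#' @param df Data.frame.
#' @param path Output path.
#' @param comment Optional comment line(s) written with a leading `#`.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Percentage trapping success
#'
#' Field effort summary: `100 * captures / trapnights`.
#'
#' @param captures Number of individuals captured (0 <= captures <= trapnights).
#' @param trapnights Number of trapnights (> 0).
#' @return Percentage trap success (full precision; round at presentation).
#' @examples
#' trap_success(199, 27014) # ~0.74 %
#' @export
trap_success <- function(captures, trapnights) {
  if (any(trapnights <= 0)) stop("trapnights must be > 0")
  if (any(captures < 0 | captures > trapnights))
    stop("captures must satisfy 0 <= captures <= trapnights")
  100 * captures / trapnights
}
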