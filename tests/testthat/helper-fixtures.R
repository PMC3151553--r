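# in-code fixtures shared across test files

# small three-partition alignment builder; rows supplied as named strings
make_aln <- function(seqs, partitions = NULL, frames = NULL) {
  hap_alignment(seqs, partitions = partitions, frames = frames)
}

# random ACGT sequence
rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

extdata <- function(f) {
  p <- system.file("extdata", f, package = "phylodapp")
  if (p == "") p <- file.path("..", "..", "inst", "extdata", f)
  p
}

table4_islands <- function() read_island_table(extdata("islands_table4.tsv"))

table3_sharing <- function() read_sharing_table(extdata("sharing_table3.tsv"))

# locality -> clade map derived from the sharing fixture's group column
table3_grouping <- function() {
  sh <- table3_sharing()
  g <- rep(sh$group, vapply(sh$localities, length, 0L))
  stats::setNames(g, unlist(sh$localities))
}

# write a small TSV and return its path
tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
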