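# Fixture builders shared across test files. Everything is generated in
# code; files are written to tempdirs at test time.

# 3 genes x 2 samples with counts {{10,0},{5,2},{0,0}} and lengths in bp.
tiny_counts <- function() {
  m <- matrix(c(10, 0,
                5, 2,
                0, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  count_matrix(m, c(gA = 1000, gB = 2000, gC = 500))
}

# Write arbitrary TSV content (vector of lines) to a temp file.
write_lines_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

write_tiny_count_files <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  counts <- file.path(dir, "counts.tsv")
  lengths <- file.path(dir, "lengths.tsv")
  writeLines(c("gene\ts1\ts2",
               "gA\t10\t0",
               "gB\t5\t2",
               "gC\t0\t0"), counts)
  writeLines(c("gene\tlength_bp",
               "gA\t1000",
               "gB\t2000",
               "gC\t500"), lengths)
  list(counts = counts, lengths = lengths)
}

# Long-format profile table from a named list tissue -> named gene vector
# of means (sd defaults to 0, n to 1).
toy_profiles <- function(means, sds = NULL, n = NULL) {
  rows <- lapply(names(means), function(t) {
    mu <- means[[t]]
    s <- if (is.null(sds)) rep(0, length(mu)) else sds[[t]]
    nn <- if (is.null(n)) ifelse(s == 0, 1, 2) else n
    data.frame(gene = names(mu), tissue = t, mean = as.numeric(mu),
               sd = as.numeric(s), n = nn, imputed = FALSE,
               stringsAsFactors = FALSE)
  })
  tissue_profiles(do.call(rbind, rows))
}

# Metadata data frame for given sample ids and tissue labels.
toy_metadata <- function(sample_id, tissue, dataset = "test") {
  data.frame(sample_id = sample_id, tissue = tissue, dataset = dataset,
             stringsAsFactors = FALSE)
}

# Adjusted Rand index between two label vectors; thin wrapper so tests read
# clearly and the oracle package is referenced in one place.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
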