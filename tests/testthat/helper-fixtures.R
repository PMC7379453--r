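# Shared helpers: fixture builders and independent brute-force oracles.

make_records <- function(seqs, accession = sprintf("R%02d", seq_along(seqs)),
                         source = "other", description = "", species = "",
                         signal_len = 0L) {
  sequence_records(accession, seqs, source = source,
                   description = description, species = species,
                   signal_len = signal_len)
}

random_protein <- function(len, letters = c("A", "C", "D", "E", "F", "G",
                                            "H", "I", "K", "L", "M", "N",
                                            "P", "Q", "R", "S", "T", "V",
                                            "W", "Y")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Q/P-biased random sequence, the composition regime the pipeline targets
random_prolamin <- function(len) {
  letters <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y")
  w <- rep(0.5 / 18, 20)
  w[letters == "Q"] <- 0.35
  w[letters == "P"] <- 0.15
  paste(sample(letters, len, replace = TRUE, prob = w), collapse = "")
}

# Brute-force chymotryptic enumerator: independent of the implementation,
# lists every substring running from just-after one cleavage boundary to
# another, counting internal retained sites.
brute_digest <- function(sequence, max_missed) {
  L <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  is_site <- function(i) i >= 1 && i < L &&
    chars[i] %in% c("Y", "W", "F", "L") && chars[i + 1] != "P"
  bounds <- c(0, Filter(is_site, seq_len(L)), L)
  out <- list()
  for (a in seq_along(bounds)) {
    for (b in seq_along(bounds)) {
      if (b <= a) next
      inner <- bounds[bounds > bounds[a] & bounds < bounds[b]]
      if (length(inner) > max_missed) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(sequence, bounds[a] + 1, bounds[b]),
        start = bounds[a] + 1L, end = bounds[b],
        missed = length(inner))
    }
  }
  do.call(rbind, out)
}

# Naive regex-free repeat scanner used as the oracle for find_repeats
naive_find_repeats <- function(sequence, pattern) {
  L <- nchar(sequence)
  p <- nchar(pattern$prefix)
  hits <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(max(L - p + 1, 0))) {
    if (substr(sequence, i, i + p - 1) != pattern$prefix) next
    if (pattern$q_run_max == 0) {
      hits <- rbind(hits, data.frame(start = i, end = i + p - 1L))
      next
    }
    run <- 0L
    while (i + p + run <= L &&
           substr(sequence, i + p + run, i + p + run) == "Q") run <- run + 1L
    if (run >= pattern$q_run_min)
      hits <- rbind(hits, data.frame(
        start = i, end = i + p - 1L + min(run, pattern$q_run_max)))
  }
  hits
}

toy_fasta <- function(dir = tempdir()) {
  path <- file.path(dir, paste0("toy-", as.integer(runif(1, 1, 1e8)),
                                ".fasta"))
  writeLines(c(
    ">sp|P06470|HOR1_HORVU B1 hordein OS=Hordeum vulgare",
    "MKTFLVFALL AMAMSIATTQ",
    ">tr|L0L8A4|L0L8A4_AVESA Avenin OS=Avena sativa",
    "MASKVVLSQL QCPFQQPQLP",
    ">x1 synthetic record",
    "MQQPFPQQPQ QPFPQ"), path)
  path
}
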