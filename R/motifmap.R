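#' Read a coeliac-toxic-motif panel
#'
#' Plain text, one peptide per line; `#` starts a comment. Peptides must be
#' over the 20 standard residues. Duplicate entries are collapsed with a
#' warning so that the unique-motif count is well defined; motifs that are
#' substrings (fragments) of other motifs are expected and kept.
#'
#' @param path path to the panel file.
#' @return character vector of unique upper-case motifs, input order.
#' @export
read_motif_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  motifs <- toupper(lines[nzchar(lines)])
  bad <- motifs[grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"),
                      motifs)]
  if (length(bad) > 0)
    stop("panel motif(s) with non-standard residues: ",
         paste(utils::head(bad, 3), collapse = ", "))
  if (anyDuplicated(motifs)) {
    warning("collapsing ", sum(duplicated(motifs)),
            " duplicate motif(s) in panel")
    motifs <- motifs[!duplicated(motifs)]
  }
  motifs
}

check_panel <- function(panel) {
  stopifnot(is.character(panel))
  if (anyDuplicated(panel)) stop("panel contains duplicate motifs")
  if (length(panel) > 0 && any(!nzchar(panel)))
    stop("panel contains empty motif(s)")
  invisible(panel)
}

#' Exact motif hits in one sequence
#'
#' Every occurrence of every panel motif as an exact, case-sensitive
#' substring — including overlapping occurrences and occurrences of motifs
#' that are fragments of longer panel motifs.
#'
#' @param sequence one amino-acid string.
#' @param panel character vector of unique motifs.
#' @return `data.frame` with columns `motif`, `start`, `end` (1-based
#'   inclusive), sorted by start then end.
#' @examples
#' find_hits("QQPFPQQPQQPFPQ", c("PFPQ", "QQPFPQ", "QQQQ"))
#' @export
find_hits <- function(sequence, panel) {
  check_panel(panel)
  stopifnot(length(sequence) == 1, nzchar(sequence))
  if (length(panel) == 0)
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  subj <- Biostrings::AAString(sequence)
  L <- nchar(sequence)
  rows <- lapply(panel, function(m) {
    if (nchar(m) > L) return(NULL)
    hit <- Biostrings::matchPattern(m, subj)
    if (length(hit) == 0) return(NULL)
    data.frame(motif = m, start = Biostrings::start(hit),
               end = Biostrings::end(hit), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  out <- out[order(out$start, out$end, match(out$motif, panel)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif statistics for one sequence
#'
#' The three per-sequence statistics: `m`, the number of distinct panel
#' motifs present at least once (repeat occurrences not re-counted, nested
#' fragment motifs counted separately); `density = m / L` motifs per
#' residue (also reported per 100 residues); and `coverage_pct`, the
#' percentage of residues covered by the union of all hit intervals,
#' reported to two decimals.
#'
#' @inheritParams find_hits
#' @return one-row `data.frame`: `L`, `m`, `density`, `density_per100`,
#'   `coverage_pct`.
#' @examples
#' motif_metrics("QQPFPQQPQQPFPQ", c("PFPQ", "QQPFPQ", "QQQQ"))
#' @export
motif_metrics <- function(sequence, panel) {
  hits <- find_hits(sequence, panel)
  L <- nchar(sequence)
  m <- length(unique(hits$motif))
  cov <- if (nrow(hits) == 0) 0 else {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = hits$start, end = hits$end))))
  }
  data.frame(L = L, m = m, density = m / L, density_per100 = 100 * m / L,
             coverage_pct = round(100 * cov / L, 2))
}

#' Motif statistics for every record
#'
#' @param records a record set (typically curated).
#' @param panel character vector of unique motifs.
#' @return `data.frame` with one row per record, input order: `accession`
#'   plus the [motif_metrics()] columns.
#' @export
map_database <- function(records, panel) {
  validate_records(records)
  check_panel(panel)
  rows <- lapply(seq_len(nrow(records)), function(i)
    cbind(data.frame(accession = records$accession[i],
                     stringsAsFactors = FALSE),
          motif_metrics(records$sequence[i], panel)))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(accession = character(0), L = integer(0),
                      m = integer(0), density = numeric(0),
                      density_per100 = numeric(0), coverage_pct = numeric(0))
  rownames(out) <- NULL
  out
}

#' All motif hits for every record
#'
#' @inheritParams map_database
#' @return `data.frame`: `accession`, `motif`, `start`, `end`.
#' @export
map_hits <- function(records, panel) {
  validate_records(records)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    h <- find_hits(records$sequence[i], panel)
    if (nrow(h) == 0) return(NULL)
    cbind(data.frame(accession = records$accession[i],
                     stringsAsFactors = FALSE), h)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(accession = character(0), motif = character(0),
                      start = integer(0), end = integer(0))
  rownames(out) <- NULL
  out
}

#' Per-group five-number summaries of motif statistics
#'
#' For each group and each of the three statistics (`m`, `density`,
#' `coverage_pct`): min, lower quartile, median, upper quartile, max and
#' mean. Quartiles use linear interpolation (R's default type-7 quantile).
#'
#' @param metrics output of [map_database()].
#' @param groups named character vector mapping accession to group label;
#'   every accession in `metrics` must be present.
#' @return long `data.frame`: `group`, `statistic`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`, `mean`.
#' @export
summarize_by_group <- function(metrics, groups) {
  stopifnot(is.data.frame(metrics))
  g <- groups[metrics$accession]
  if (any(is.na(g)))
    stop("summarize_by_group: accession(s) without a group: ",
         paste(utils::head(metrics$accession[is.na(g)], 3), collapse = ", "))
  stats <- c("m", "density", "coverage_pct")
  rows <- list()
  for (gr in unique(g)) {
    for (s in stats) {
      v <- metrics[[s]][g == gr]
      q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
      rows[[length(rows) + 1L]] <- data.frame(
        group = gr, statistic = s, n = length(v), min = min(v),
        q1 = q[1], median = q[2], q3 = q[3], max = max(v), mean = mean(v),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
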