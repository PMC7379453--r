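#' Repeat-motif pattern
#'
#' Prolamin repetitive domains are described by a short literal prefix
#' optionally followed by a bounded glutamine run, e.g. `PFM` + Q(1-5) for
#' Group A avenins, `MLL` + Q(3-6) and `PFV` + Q(2-4) for Group B and C,
#' or pure literals such as `VFQPQLQQ`. `q_run_min = q_run_max = 0` denotes
#' a literal-only pattern.
#'
#' @param prefix non-empty residue string.
#' @param q_run_min,q_run_max bounds on the glutamine run following the
#'   prefix (both 0 for literal patterns).
#' @return a list of class `repeat_pattern`.
#' @export
repeat_pattern <- function(prefix, q_run_min = 0, q_run_max = 0) {
  stopifnot(nzchar(prefix), q_run_min >= 0, q_run_min <= q_run_max)
  structure(list(prefix = toupper(prefix),
                 q_run_min = as.integer(q_run_min),
                 q_run_max = as.integer(q_run_max)),
            class = "repeat_pattern")
}

#' Prolamin group template
#'
#' A classification anchor for one protein group: its repeat grammar, the
#' expected cysteine-skeleton size, and the accessions of its master
#' sequences (representative, ideally protein-level-evidenced records).
#'
#' @param group_name unique group label (e.g. `"avenin_A"`, `"omega"`).
#' @param repeat_patterns list of [repeat_pattern()]s.
#' @param expected_cys expected number of cysteines (may be `NA`).
#' @param master_accessions character vector of master accessions.
#' @return a list of class `group_template`.
#' @export
group_template <- function(group_name, repeat_patterns = list(),
                           expected_cys = NA_integer_,
                           master_accessions = character(0)) {
  stopifnot(nzchar(group_name))
  structure(list(group_name = group_name,
                 repeat_patterns = repeat_patterns,
                 expected_cys = expected_cys,
                 master_accessions = master_accessions),
            class = "group_template")
}

#' Count cysteine residues
#'
#' The conserved cysteine skeleton separates prolamin classes: sulphur-poor
#' omega-type prolamins have none, B- and C-avenins have eight, A-avenins
#' nine. Vectorised.
#'
#' @param sequence character vector of amino-acid strings.
#' @return integer vector of `C` counts.
#' @export
count_cysteines <- function(sequence) {
  nchar(gsub("[^C]", "", sequence))
}

#' Find repeat-motif occurrences
#'
#' Reports every (possibly overlapping) occurrence of the pattern prefix
#' followed by a glutamine run of length within the pattern bounds. Runs
#' are matched greedily and capped at `q_run_max`; literal patterns match
#' the prefix exactly.
#'
#' @param sequence one amino-acid string.
#' @param pattern a [repeat_pattern()].
#' @return `data.frame` with 1-based inclusive `start`, `end` columns.
#' @examples
#' find_repeats("PFMQQQ", repeat_pattern("PFM", 1, 5)) # one hit (1, 6)
#' @export
find_repeats <- function(sequence, pattern) {
  stopifnot(inherits(pattern, "repeat_pattern"), length(sequence) == 1)
  L <- nchar(sequence)
  p <- nchar(pattern$prefix)
  if (L < p)
    return(data.frame(start = integer(0), end = integer(0)))
  m <- Biostrings::matchPattern(pattern$prefix,
                                Biostrings::AAString(sequence))
  starts <- Biostrings::start(m)
  hits_s <- integer(0); hits_e <- integer(0)
  for (s in starts) {
    if (pattern$q_run_max == 0) {
      hits_s <- c(hits_s, s); hits_e <- c(hits_e, s + p - 1L)
      next
    }
    i <- s + p
    run <- 0L
    while (i + run <= L && substr(sequence, i + run, i + run) == "Q")
      run <- run + 1L
    if (run >= pattern$q_run_min) {
      hits_s <- c(hits_s, s)
      hits_e <- c(hits_e, s + p - 1L + min(run, pattern$q_run_max))
    }
  }
  data.frame(start = hits_s, end = hits_e)
}

#' Alignment parameters for percent identity
#'
#' @param substitution_matrix name of the scoring matrix (default
#'   `"BLOSUM62"`, the matrix used for the average-distance tree).
#' @param gap_open,gap_extend positive gap penalties for global alignment.
#' @return a list of class `align_params`.
#' @export
align_params <- function(substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Global-alignment percent identity of two sequences
#'
#' End-to-end (Needleman-Wunsch) alignment under the given substitution
#' matrix and affine gap penalties; identity is 100 x identical aligned
#' residue pairs / total alignment columns, gap columns counting in the
#' denominator. Symmetric by construction.
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @param params an [align_params()].
#' @return identity percentage in `[0, 100]`.
#' @examples
#' pairwise_identity("PQPQ", "PQPQ") # 100
#' pairwise_identity("PQPQ", "PQPA") # 75
#' @export
pairwise_identity <- function(seq_a, seq_b, params = align_params()) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("pairwise_identity: empty sequence")
  mat <- get_submat(params$substitution_matrix)
  ok <- rownames(mat)
  for (s in c(seq_a, seq_b)) {
    ch <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    bad <- setdiff(ch, ok)
    if (length(bad) > 0)
      stop("residue(s) not scored by ", params$substitution_matrix, ": ",
           paste(bad, collapse = ", "))
  }
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  a <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  100 * sum(a == b & a != "-") / length(a)
}

#' All-against-all identity matrix
#'
#' @param records a record set.
#' @param params an [align_params()].
#' @return symmetric numeric matrix with 100 on the diagonal, labelled by
#'   accession.
#' @export
identity_matrix <- function(records, params = align_params()) {
  validate_records(records)
  n <- nrow(records)
  m <- diag(100, n)
  dimnames(m) <- list(records$accession, records$accession)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      m[i, j] <- m[j, i] <-
        pairwise_identity(records$sequence[i], records$sequence[j], params)
    }
  }
  m
}

#' Mean within-group pairwise identity
#'
#' The within-group sequence-similarity summary: the mean of pairwise
#' global-alignment identities over all unordered pairs in each group.
#'
#' @param records a record set.
#' @param groups named character vector mapping accession to group label;
#'   every group must contain at least two records.
#' @param params an [align_params()].
#' @return named numeric vector of per-group mean identities, rounded to
#'   two decimals.
#' @export
group_homology <- function(records, groups, params = align_params()) {
  validate_records(records)
  g <- groups[records$accession]
  if (any(is.na(g))) stop("group_homology: record(s) without a group")
  sizes <- table(g)
  if (any(sizes < 2))
    stop("group_homology: group(s) of size < 2: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  out <- vapply(names(sizes), function(gr) {
    idx <- which(g == gr)
    vals <- numeric(0)
    for (i in seq_along(idx)[-length(idx)])
      for (j in seq.int(i + 1, length(idx)))
        vals <- c(vals, pairwise_identity(records$sequence[idx[i]],
                                          records$sequence[idx[j]], params))
    round(mean(vals), 2)
  }, numeric(1))
  out
}

#' Classify one record against group templates and master sequences
#'
#' Computes the evidence triplet (P+Q content, cysteine count, repeat-motif
#' hits per template) plus identity to every master sequence, and assigns
#' the group of the best-identity master when that identity reaches
#' `identity_floor`. Ties are broken by more repeat-pattern hits for the
#' tied group, then template order. Below the floor the record is
#' `"unclassified"`.
#'
#' @param record a one-row record set.
#' @param templates list of [group_template()]s (non-empty).
#' @param masters record set containing every master accession named in
#'   `templates`.
#' @param identity_floor minimum identity (default 30, mirroring the
#'   homology floor used when recovering related sequences).
#' @param params an [align_params()].
#' @return a list of class `classification_result` with fields `accession`,
#'   `assigned_group`, `pq_percent`, `cys_count`, `repeat_hits`,
#'   `best_master`, `best_identity`.
#' @export
classify_record <- function(record, templates, masters,
                            identity_floor = 30, params = align_params()) {
  stopifnot(length(templates) > 0, nrow(record) == 1)
  validate_records(record)
  validate_records(masters)

  tnames <- vapply(templates, `[[`, character(1), "group_name")
  m_group <- rep(NA_character_, nrow(masters))
  for (t in templates)
    m_group[masters$accession %in% t$master_accessions] <- t$group_name
  if (any(is.na(m_group)))
    masters <- masters[!is.na(m_group), , drop = FALSE]
  m_group <- m_group[!is.na(m_group)]
  if (nrow(masters) == 0) stop("no master sequences match the templates")

  hits <- lapply(templates, function(t) {
    do.call(rbind, c(lapply(t$repeat_patterns, function(p)
      find_repeats(record$sequence, p)),
      list(data.frame(start = integer(0), end = integer(0)))))
  })
  names(hits) <- tnames
  n_hits <- vapply(hits, nrow, integer(1))

  ids <- vapply(seq_len(nrow(masters)), function(i)
    pairwise_identity(record$sequence, masters$sequence[i], params),
    numeric(1))
  best <- max(ids)
  cand <- unique(m_group[ids == best])
  if (length(cand) > 1) {
    hh <- n_hits[cand]
    cand <- cand[hh == max(hh)]
    cand <- cand[order(match(cand, tnames))]
  }
  group <- if (best >= identity_floor) cand[1] else "unclassified"
  best_master <- masters$accession[which(ids == best &
                                           m_group == cand[1])[1]]
  if (is.na(best_master)) best_master <- masters$accession[which.max(ids)]

  structure(list(accession = record$accession,
                 assigned_group = group,
                 pq_percent = pq_content(record$sequence),
                 cys_count = count_cysteines(record$sequence),
                 repeat_hits = hits,
                 best_master = best_master,
                 best_identity = best),
            class = "classification_result")
}

#' Classify every record in a set
#'
#' @param records a record set.
#' @inheritParams classify_record
#' @return `data.frame` with one row per record: `accession`, `group`,
#'   `pq_percent`, `cys_count`, `n_repeat_hits` (hits of the assigned
#'   group's patterns, 0 when unclassified), `best_master`, `identity`.
#' @export
classify_database <- function(records, templates, masters,
                              identity_floor = 30,
                              params = align_params()) {
  validate_records(records)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- classify_record(records[i, , drop = FALSE], templates, masters,
                         identity_floor, params)
    nh <- if (r$assigned_group %in% names(r$repeat_hits))
      nrow(r$repeat_hits[[r$assigned_group]]) else 0L
    data.frame(accession = r$accession, group = r$assigned_group,
               pq_percent = r$pq_percent, cys_count = r$cys_count,
               n_repeat_hits = nh, best_master = r$best_master,
               identity = round(r$best_identity, 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(accession = character(0), group = character(0),
                      pq_percent = numeric(0), cys_count = integer(0),
                      n_repeat_hits = integer(0),
                      best_master = character(0), identity = numeric(0))
  out
}
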