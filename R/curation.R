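#' Curation settings
#'
#' Bundles the deterministic rules used to reduce a raw sequence download to
#' a curated database: which letters count as ambiguous, how "partial"
#' records are recognised, the proline+glutamine composition threshold used
#' to flag doubtful prolamins, and the source-preference order applied when
#' collapsing duplicate sequences.
#'
#' @param ambiguous_letters letters whose presence marks a record as
#'   ambiguous (default `X`, `B`, `Z`, `J`).
#' @param min_length records shorter than this are treated as fragments
#'   (default 50; mature prolamins are all well above it).
#' @param require_initiator_met flag records that do not start with `M` and
#'   have no recorded signal peptide (default `TRUE`).
#' @param pq_threshold_percent proline+glutamine percentage below which a
#'   kept record is flagged (not removed) as a doubtful prolamin
#'   (default 30).
#' @param partial_keywords case-insensitive header substrings marking
#'   partial records.
#' @param source_preference total order over sources used to pick the
#'   representative of a duplicated sequence, most-preferred first.
#' @return a list of class `curation_config`.
#' @export
curation_config <- function(ambiguous_letters = c("X", "B", "Z", "J"),
                            min_length = 50,
                            require_initiator_met = TRUE,
                            pq_threshold_percent = 30,
                            partial_keywords = c("partial", "fragment"),
                            source_preference = SOURCE_LEVELS) {
  stopifnot(min_length >= 1,
            pq_threshold_percent >= 0, pq_threshold_percent <= 100,
            setequal(source_preference, SOURCE_LEVELS))
  structure(list(ambiguous_letters = ambiguous_letters,
                 min_length = min_length,
                 require_initiator_met = isTRUE(require_initiator_met),
                 pq_threshold_percent = pq_threshold_percent,
                 partial_keywords = partial_keywords,
                 source_preference = source_preference),
            class = "curation_config")
}

empty_removals <- function() {
  data.frame(accession = character(0), reason = character(0),
             detail = character(0), stringsAsFactors = FALSE)
}

#' Collapse duplicate sequences and accessions
#'
#' Exact duplicate sequences are collapsed to one representative chosen by
#' the configured source preference (UniProt Swiss-Prot first), ties broken
#' by input order; records sharing an accession are then collapsed to the
#' first occurrence. Survivors keep input order.
#'
#' @param records a record set.
#' @param config a [curation_config()].
#' @return a list with `records` (the survivors) and `removals` (a
#'   `data.frame` of accession / reason / detail rows).
#' @export
deduplicate <- function(records, config = curation_config()) {
  validate_records(records)
  if (nrow(records) == 0)
    return(list(records = records, removals = empty_removals()))
  pref <- match(records$source, config$source_preference)
  drop <- logical(nrow(records))
  removals <- list()

  for (grp in split(seq_len(nrow(records)), records$sequence)) {
    if (length(grp) < 2) next
    keep <- grp[order(pref[grp], grp)][1]
    for (i in setdiff(grp, keep)) {
      drop[i] <- TRUE
      removals[[length(removals) + 1L]] <- data.frame(
        accession = records$accession[i], reason = "duplicate_sequence",
        detail = paste0("same sequence as ", records$accession[keep]),
        stringsAsFactors = FALSE)
    }
  }
  surv <- which(!drop)
  dup_acc <- surv[duplicated(records$accession[surv])]
  for (i in dup_acc) {
    drop[i] <- TRUE
    removals[[length(removals) + 1L]] <- data.frame(
      accession = records$accession[i], reason = "duplicate_accession",
      detail = "accession seen earlier in input", stringsAsFactors = FALSE)
  }
  rem <- if (length(removals)) do.call(rbind, removals) else empty_removals()
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, removals = rem)
}

#' Flag records containing ambiguous residues
#'
#' @param records a record set.
#' @param config a [curation_config()].
#' @return logical vector, `TRUE` where the sequence contains any of the
#'   configured ambiguity letters.
#' @export
flag_ambiguous <- function(records, config = curation_config()) {
  validate_records(records)
  if (nrow(records) == 0) return(logical(0))
  pat <- paste0("[", paste(config$ambiguous_letters, collapse = ""), "]")
  grepl(pat, records$sequence)
}

#' Flag likely partial (fragment) records
#'
#' A record is flagged when it is shorter than the configured floor, when it
#' lacks an initiator methionine with no recorded signal peptide, or when
#' its description carries a partial/fragment keyword (case-insensitive).
#'
#' @inheritParams flag_ambiguous
#' @return logical vector.
#' @export
flag_partial <- function(records, config = curation_config()) {
  validate_records(records)
  if (nrow(records) == 0) return(logical(0))
  short <- nchar(records$sequence) < config$min_length
  no_met <- if (config$require_initiator_met)
    substr(records$sequence, 1, 1) != "M" & records$signal_len == 0
  else rep(FALSE, nrow(records))
  kw <- Reduce(`|`, lapply(config$partial_keywords, function(k)
    grepl(k, records$description, ignore.case = TRUE, fixed = FALSE)),
    rep(FALSE, nrow(records)))
  short | no_met | kw
}

#' Proline + glutamine content of a sequence
#'
#' The composition statistic used to confirm candidate prolamins: the
#' percentage of residues that are proline or glutamine, reported to two
#' decimal places. Vectorised over sequences.
#'
#' @param sequence character vector of non-empty amino-acid strings.
#' @return numeric vector of percentages in `[0, 100]`.
#' @examples
#' pq_content("PQPQ") # 100
#' pq_content("AAAA") # 0
#' @export
pq_content <- function(sequence) {
  if (any(is.na(sequence) | !nzchar(sequence)))
    stop("pq_content: empty sequence")
  n_pq <- nchar(gsub("[^PQ]", "", sequence))
  round(100 * n_pq / nchar(sequence), 2)
}

#' Curate a record set
#'
#' Applies, in order: duplicate collapsing ([deduplicate()]), removal of
#' ambiguous-residue records, removal of likely partial records. Records
#' whose proline+glutamine content falls below the configured threshold are
#' reported as warnings but kept, since genuine prolamins can fall below
#' the 30% confirmation criterion.
#'
#' @inheritParams flag_ambiguous
#' @return a list with `records` (curated set, input order) and `report`
#'   (class `curation_report`: `n_input`, `n_kept`, `removals`, per-reason
#'   `tallies`, and `low_pq` flags).
#' @export
curate <- function(records, config = curation_config()) {
  validate_records(records)
  n_input <- nrow(records)
  dd <- deduplicate(records, config)
  kept <- dd$records
  removals <- dd$removals

  amb <- flag_ambiguous(kept, config)
  if (any(amb)) {
    removals <- rbind(removals, data.frame(
      accession = kept$accession[amb], reason = "ambiguous_residue",
      detail = "sequence contains ambiguity letter(s)",
      stringsAsFactors = FALSE))
    kept <- kept[!amb, , drop = FALSE]
  }
  part <- flag_partial(kept, config)
  if (any(part)) {
    removals <- rbind(removals, data.frame(
      accession = kept$accession[part], reason = "partial_sequence",
      detail = "length / initiator-Met / header keyword rule",
      stringsAsFactors = FALSE))
    kept <- kept[!part, , drop = FALSE]
  }
  rownames(kept) <- NULL

  pq <- if (nrow(kept)) pq_content(kept$sequence) else numeric(0)
  low <- pq < config$pq_threshold_percent
  reasons <- c("duplicate_sequence", "duplicate_accession",
               "ambiguous_residue", "partial_sequence")
  tallies <- vapply(reasons, function(r) sum(removals$reason == r),
                    integer(1))
  report <- structure(list(
    n_input = n_input, n_kept = nrow(kept), removals = removals,
    tallies = tallies,
    low_pq = data.frame(accession = kept$accession[low],
                        pq_percent = pq[low], stringsAsFactors = FALSE)),
    class = "curation_report")
  stopifnot(report$n_input == report$n_kept + nrow(report$removals))
  list(records = kept, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report:", x$n_input, "record(s) in,", x$n_kept, "kept,",
      nrow(x$removals), "removed\n")
  for (r in names(x$tallies))
    if (x$tallies[[r]] > 0) cat("  ", r, ": ", x$tallies[[r]], "\n", sep = "")
  if (nrow(x$low_pq) > 0)
    cat("  low P+Q warning for:",
        paste(x$low_pq$accession, collapse = ", "), "\n")
  invisible(x)
}

#' Write a curation report as TSV
#'
#' @param report a `curation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(report, path) {
  stopifnot(inherits(report, "curation_report"))
  write.table(report$removals, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
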