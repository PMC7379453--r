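#' Construct a set of sequence records
#'
#' A record set is a plain `data.frame` with one row per protein sequence and
#' columns `accession`, `source`, `description`, `species`, `sequence` and
#' `signal_len`. All prolamap stages consume and return this shape.
#'
#' @param accession character vector of non-empty identifiers.
#' @param sequence character vector of upper-case amino-acid strings. The 20
#'   standard residues plus the ambiguity codes `X`, `B`, `Z`, `J` are
#'   accepted; anything else (including `U`, `O`, `*`) is an error.
#' @param source sequence origin dialect, one of `"uniprot_sp"`,
#'   `"uniprot_tr"`, `"ncbi"`, `"other"`. Recycled.
#' @param description free-text description (may be empty). Recycled.
#' @param species organism name, possibly empty. Recycled.
#' @param signal_len known signal-peptide length in residues; 0 means
#'   unknown or none. Must be smaller than the sequence length. Recycled.
#' @return a `data.frame` of validated records.
#' @examples
#' sequence_records("A1", "MQQPFPQQC")
#' @export
sequence_records <- function(accession, sequence, source = "other",
                             description = "", species = "",
                             signal_len = 0L) {
  n <- length(accession)
  rec <- data.frame(
    accession = as.character(accession),
    source = rep_len(as.character(source), n),
    description = rep_len(as.character(description), n),
    species = rep_len(as.character(species), n),
    sequence = rep_len(as.character(sequence), n),
    signal_len = rep_len(as.integer(signal_len), n),
    stringsAsFactors = FALSE
  )
  validate_records(rec)
  rec
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("accession", "source", "description", "species", "sequence",
            "signal_len")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("record set lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0) return(invisible(records))
  if (any(!nzchar(records$accession)))
    stop("accessions must be non-empty")
  bad_src <- setdiff(unique(records$source), SOURCE_LEVELS)
  if (length(bad_src) > 0)
    stop("unknown source value(s): ", paste(bad_src, collapse = ", "))
  for (i in seq_len(nrow(records))) {
    check_sequence(records$sequence[i], records$accession[i])
    if (records$signal_len[i] < 0 ||
        records$signal_len[i] >= nchar(records$sequence[i]))
      stop("record ", records$accession[i],
           ": signal_len must be in [0, L)")
  }
  invisible(records)
}

# Error (naming the record and the offending position) unless `sequence`
# is a non-empty upper-case string over the allowed alphabet.
check_sequence <- function(sequence, accession) {
  if (is.na(sequence) || !nzchar(sequence))
    stop("record ", accession, ": empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALLOWED))
  if (length(bad) > 0)
    stop("record ", accession, ": disallowed residue '", chars[bad[1]],
         "' at position ", bad[1])
  invisible(TRUE)
}

#' Parse one FASTA definition line
#'
#' Understands the UniProt `sp|ACC|NAME` and `tr|ACC|NAME` pipe dialects,
#' NCBI identifiers (`gi|...|db|ACC.V|` or a bare accession.version token),
#' and falls back to treating the first whitespace-delimited token as the
#' accession with source `"other"`. A trailing UniProt `OS=` field, when
#' present, is extracted as the species.
#'
#' @param header the text after `>` on a FASTA definition line.
#' @return a list with elements `accession`, `source`, `description`,
#'   `species`.
#' @examples
#' parse_header("sp|Q402I5|OMG5_WHEAT Omega-5 gliadin OS=Triticum aestivum")
#' parse_header("myseq1 synthetic")
#' @export
parse_header <- function(header) {
  header <- trimws(header)
  if (!nzchar(header)) stop("empty FASTA header")
  first <- sub("\\s.*$", "", header)
  description <- trimws(sub("^\\S+", "", header))
  species <- ""
  os <- regmatches(header,
                   regexpr("OS=.*?(?=\\s[A-Z]{2}=|$)", header, perl = TRUE))
  if (length(os) == 1) {
    species <- trimws(sub("^OS=", "", os))
    # the species lives in its own field, not in the description
    description <- trimws(sub(os, "", description, fixed = TRUE))
  }

  if (grepl("^(sp|tr)\\|", first)) {
    fields <- strsplit(first, "|", fixed = TRUE)[[1]]
    if (length(fields) < 2 || !nzchar(fields[2]))
      stop("header with no accession token: '", header, "'")
    acc <- fields[2]
    src <- if (fields[1] == "sp") "uniprot_sp" else "uniprot_tr"
  } else if (grepl("^gi\\|", first)) {
    fields <- strsplit(first, "|", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    # prefer the trailing db accession over the bare gi number
    acc <- fields[length(fields)]
    if (length(fields) >= 2 && acc %in% c("gb", "ref", "emb", "dbj", "sp"))
      acc <- fields[2]
    src <- "ncbi"
  } else if (grepl("^[A-Za-z]+_?[0-9]+\\.[0-9]+$", first)) {
    acc <- first
    src <- "ncbi"
  } else {
    acc <- first
    src <- "other"
  }
  if (!nzchar(acc)) stop("header with no accession token: '", header, "'")
  list(accession = acc, source = src, description = description,
       species = species)
}

#' Read a protein FASTA file into a record set
#'
#' One record per entry, input order preserved. Whitespace and digits are
#' stripped from sequence lines and letters upper-cased before validation;
#' residues outside the allowed alphabet (including `U`, `O`, `*`) abort
#' with an error naming the record and position.
#'
#' @param path path to an existing FASTA file.
#' @return a record set `data.frame` (see [sequence_records()]);
#'   `signal_len` is 0 for all records.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty FASTA file: ", path)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("malformed FASTA (data before first header): ", path)
  idx <- which(is_hdr)
  ends <- c(idx[-1] - 1L, length(lines))
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    hdr <- parse_header(substring(lines[idx[k]], 2))
    body <- lines[seq.int(idx[k] + 1L, ends[k])[seq_len(ends[k] - idx[k])]]
    seq <- toupper(gsub("[[:space:][:digit:]]", "", paste(body, collapse = "")))
    check_sequence(seq, hdr$accession)
    out[[k]] <- data.frame(accession = hdr$accession, source = hdr$source,
                           description = hdr$description,
                           species = hdr$species, sequence = seq,
                           signal_len = 0L, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Rebuild a definition line that re-parses to the same record fields:
# UniProt records keep their pipe dialect, others use the plain-token form.
build_header <- function(record) {
  desc <- record$description
  if (nzchar(record$species) && !grepl("OS=", desc, fixed = TRUE))
    desc <- trimws(paste(desc, paste0("OS=", record$species)))
  tok <- switch(record$source,
                uniprot_sp = sprintf("sp|%s|%s", record$accession,
                                     record$accession),
                uniprot_tr = sprintf("tr|%s|%s", record$accession,
                                     record$accession),
                record$accession)
  trimws(paste(tok, desc))
}

#' Write a record set to FASTA
#'
#' Deterministic output: records in input order, sequence lines wrapped at
#' `wrap` residues, headers rebuilt so that [read_fasta()] recovers the same
#' accession, source, description and species (`signal_len` is in-memory
#' metadata and is not representable in FASTA).
#'
#' @param records a record set.
#' @param path output file path.
#' @param wrap positive line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60) {
  validate_records(records)
  stopifnot(wrap >= 1)
  if (nrow(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- vapply(seq_len(nrow(records)),
                       function(i) build_header(records[i, ]), character(1))
  Biostrings::writeXStringSet(set, filepath = path, width = wrap)
  invisible(path)
}
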