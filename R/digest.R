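# Monoisotopic residue masses (Da) for the 20 standard amino acids.
RESIDUE_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
MASS_WATER <- 18.010565
MASS_CAM <- 57.021464  # carbamidomethylation of cysteine

#' In-silico chymotryptic digestion
#'
#' Cleavage occurs after every `Y`, `W`, `F` or `L` whose following residue
#' exists and is not `P`. Zero-missed-cleavage peptides are the fragments
#' between consecutive cleavage sites (plus the termini); peptides with
#' `j` missed cleavages (`1 <= j <= max_missed`) are concatenations of
#' `j + 1` consecutive fragments.
#'
#' @param sequence one amino-acid string.
#' @param max_missed maximum missed cleavages (default 2, matching the
#'   search settings the marker filters mirror).
#' @param accession optional parent accession recorded on each peptide.
#' @return `data.frame`: `accession`, `peptide`, `start`, `end` (1-based
#'   inclusive), `missed`; ordered by missed cleavages then start.
#' @examples
#' chymotryptic_digest("ALPFGW")$peptide # ALPF, GW, ALPFGW
#' @export
chymotryptic_digest <- function(sequence, max_missed = 2,
                                accession = NA_character_) {
  if (max_missed < 0) stop("max_missed must be >= 0")
  stopifnot(length(sequence) == 1, nzchar(sequence))
  L <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sites <- which(chars[-L] %in% c("Y", "W", "F", "L") & chars[-1] != "P")
  bounds <- c(0L, sites, L)  # fragment f spans bounds[f]+1 .. bounds[f+1]
  nf <- length(bounds) - 1L
  rows <- list()
  for (j in 0:min(max_missed, nf - 1L)) {
    for (f in seq_len(nf - j)) {
      s <- bounds[f] + 1L
      e <- bounds[f + j + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        accession = accession, peptide = substr(sequence, s, e),
        start = s, end = e, missed = j, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water; with `fixed_cam`,
#' carbamidomethylation adds 57.021464 Da per cysteine (the one fixed
#' modification the marker workflow supports). Vectorised over peptides.
#'
#' @param peptide character vector of peptides over the 20 standard
#'   residues (ambiguity letters are an error).
#' @param fixed_cam apply fixed carbamidomethyl-C (default `FALSE`).
#' @return numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("GW") # 261.11134
#' @export
monoisotopic_mass <- function(peptide, fixed_cam = FALSE) {
  if (any(is.na(peptide) | !nzchar(peptide)))
    stop("monoisotopic_mass: empty peptide")
  vapply(peptide, function(p) {
    chars <- strsplit(p, "", fixed = TRUE)[[1]]
    m <- RESIDUE_MONO_MASS[chars]
    if (anyNA(m))
      stop("monoisotopic_mass: non-standard residue '",
           chars[which(is.na(m))[1]], "' in ", p)
    sum(m) + MASS_WATER + if (fixed_cam) MASS_CAM * sum(chars == "C") else 0
  }, numeric(1), USE.NAMES = FALSE)
}

# Uniqueness key: merge I and L when MS cannot distinguish them.
peptide_key <- function(peptide, ileq) {
  if (ileq) chartr("L", "I", peptide) else peptide
}

#' Database-wide peptide uniqueness
#'
#' Digests every record and maps each peptide string to the set of distinct
#' parent accessions; a peptide is proteotypic (unique) when it maps to
#' exactly one. Uniqueness is database-relative: adding homologues can
#' demote peptides that looked unique in a smaller set.
#'
#' @param records a record set.
#' @param max_missed maximum missed cleavages (default 2).
#' @param ileq treat isoleucine and leucine as equivalent (isobaric) when
#'   keying peptides (default `FALSE`).
#' @return named list mapping peptide key to a character vector of parent
#'   accessions.
#' @export
peptide_uniqueness <- function(records, max_missed = 2, ileq = FALSE) {
  validate_records(records)
  stopifnot(nrow(records) >= 1)
  pairs <- lapply(seq_len(nrow(records)), function(i) {
    d <- chymotryptic_digest(records$sequence[i], max_missed,
                             records$accession[i])
    data.frame(key = peptide_key(d$peptide, ileq), accession = d$accession,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs)
  lapply(split(pairs$accession, pairs$key), unique)
}

#' Select marker-peptide candidates
#'
#' Nominates proteotypic peptides suitable as quantitation markers:
#' database-unique digestion peptides of at least `min_len` residues whose
#' neutral monoisotopic mass reaches `min_mass` (mirroring a 750 Da
#' precursor-ion floor). Each candidate records whether its parent-sequence
#' interval overlaps any coeliac-toxic-motif hit, so markers diagnostic of
#' toxic regions can be separated from merely protein-specific ones.
#'
#' @param records a record set.
#' @param panel optional motif panel used for the overlap annotation;
#'   required when `require_motif_overlap` is `TRUE`.
#' @param max_missed maximum missed cleavages (default 2).
#' @param min_len minimum peptide length (default 5).
#' @param min_mass minimum neutral monoisotopic mass in Da (default 750).
#' @param require_motif_overlap keep only candidates overlapping a motif
#'   hit (default `FALSE`).
#' @param ileq isobaric I/L merging for uniqueness (default `FALSE`).
#' @param fixed_cam carbamidomethyl-C fixed modification for masses
#'   (default `FALSE`).
#' @return `data.frame` sorted by accession then start: `accession`,
#'   `peptide`, `start`, `end`, `missed`, `mass`, `unique`, `n_parents`,
#'   `overlaps_motif` (`NA` when no panel given).
#' @export
select_markers <- function(records, panel = NULL, max_missed = 2,
                           min_len = 5, min_mass = 750,
                           require_motif_overlap = FALSE, ileq = FALSE,
                           fixed_cam = FALSE) {
  validate_records(records)
  if (require_motif_overlap && (is.null(panel) || length(panel) == 0))
    stop("require_motif_overlap needs a non-empty motif panel")
  parents <- peptide_uniqueness(records, max_missed, ileq)

  rows <- lapply(seq_len(nrow(records)), function(i) {
    d <- chymotryptic_digest(records$sequence[i], max_missed,
                             records$accession[i])
    d$n_parents <- vapply(peptide_key(d$peptide, ileq),
                          function(k) length(parents[[k]]), integer(1))
    d <- d[d$n_parents == 1 & nchar(d$peptide) >= min_len, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    d$mass <- monoisotopic_mass(d$peptide, fixed_cam)
    d <- d[d$mass >= min_mass, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    d$unique <- TRUE
    if (!is.null(panel) && length(panel) > 0) {
      hits <- find_hits(records$sequence[i], panel)
      d$overlaps_motif <- vapply(seq_len(nrow(d)), function(r)
        any(hits$start <= d$end[r] & hits$end >= d$start[r]), logical(1))
    } else d$overlaps_motif <- NA
    d
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(accession = character(0), peptide = character(0),
                      start = integer(0), end = integer(0),
                      missed = integer(0), n_parents = integer(0),
                      mass = numeric(0), unique = logical(0),
                      overlaps_motif = logical(0))
  if (require_motif_overlap)
    out <- out[!is.na(out$overlaps_motif) & out$overlaps_motif, ,
               drop = FALSE]
  out <- out[order(out$accession, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("accession", "peptide", "start", "end", "missed", "mass",
          "unique", "n_parents", "overlaps_motif")]
}
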