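# Background residue sampler: prolamin-like composition, glutamine- and
# proline-rich by default. `exclude` removes letters (e.g. C, so that
# cysteine skeletons stay under the generator's control).
sample_background <- function(n, q_frac = 0.35, p_frac = 0.15,
                              exclude = character(0)) {
  letters <- setdiff(AA_STANDARD, exclude)
  w <- rep((1 - q_frac - p_frac) / (length(letters) - 2), length(letters))
  w[letters == "Q"] <- q_frac
  w[letters == "P"] <- p_frac
  paste(sample(letters, n, replace = TRUE, prob = w), collapse = "")
}

#' Specification for a synthetic prolamin family
#'
#' Describes the families the generator emits: multi-group prolamin-like
#' proteins assembled as signal peptide + N-terminal domain + repetitive
#' domain (built from the group's repeat grammar) + C-terminal domain
#' carrying a fixed cysteine skeleton, with a coeliac-toxic-motif panel
#' embedded at recorded coordinates, optional point mutations, and
#' injected duplicate / ambiguous / partial records for curation testing.
#'
#' @param seed integer RNG seed; generation is a pure function of the spec.
#' @param n_per_group clean sequences per group (first one per group is
#'   that group's master).
#' @param groups list of group descriptors; `default_synthetic_groups()`
#'   provides six prolamin-like families, including a cysteine-free
#'   omega-type group and 9- vs 8-cysteine avenin-type groups.
#' @param n_motifs panel size.
#' @param motif_len_range length range of base panel motifs (min >= 4).
#' @param frac_nested fraction of panel motifs that are substrings
#'   (fragments) of other panel motifs.
#' @param embeds_per_seq range of embedded motifs per clean sequence.
#' @param mutation_rate per-residue point-mutation probability in `[0, 1]`;
#'   mutations never touch the initiator Met, embedded motif spans or
#'   cysteines, and never introduce a cysteine.
#' @param n_duplicates,n_ambiguous,n_partial corrupted extra records.
#' @param q_frac,p_frac background glutamine / proline fractions.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, n_per_group = 5,
                           groups = default_synthetic_groups(),
                           n_motifs = 25, motif_len_range = c(6, 12),
                           frac_nested = 0.2, embeds_per_seq = c(1, 4),
                           mutation_rate = 0, n_duplicates = 2,
                           n_ambiguous = 2, n_partial = 2,
                           q_frac = 0.35, p_frac = 0.15) {
  stopifnot(n_per_group >= 1, length(groups) >= 1, n_motifs >= 1,
            motif_len_range[1] >= 4,
            motif_len_range[1] <= motif_len_range[2],
            frac_nested >= 0, frac_nested <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            n_duplicates >= 0, n_ambiguous >= 0, n_partial >= 0)
  structure(list(seed = seed, n_per_group = n_per_group, groups = groups,
                 n_motifs = n_motifs, motif_len_range = motif_len_range,
                 frac_nested = frac_nested, embeds_per_seq = embeds_per_seq,
                 mutation_rate = mutation_rate, n_duplicates = n_duplicates,
                 n_ambiguous = n_ambiguous, n_partial = n_partial,
                 q_frac = q_frac, p_frac = p_frac),
            class = "synthetic_spec")
}

#' Default synthetic prolamin groups
#'
#' Six families spanning the classification signals the pipeline uses:
#' distinct repeat grammars (literal units and prefix+Q-run units), a
#' cysteine-free sulphur-poor group, and 9- versus 8-cysteine avenin-type
#' skeletons.
#'
#' @return list of group descriptors (`name`, `patterns`, `n_cys`,
#'   `repeat_count_range`).
#' @export
default_synthetic_groups <- function() {
  list(
    list(name = "alpha", n_cys = 6, repeat_count_range = c(8, 14),
         patterns = list(repeat_pattern("PQPQPFP"))),
    list(name = "gamma", n_cys = 8, repeat_count_range = c(8, 14),
         patterns = list(repeat_pattern("QPQQPFP"))),
    list(name = "omega", n_cys = 0, repeat_count_range = c(10, 16),
         patterns = list(repeat_pattern("PQQPFPQQ"))),
    list(name = "avenin_A", n_cys = 9, repeat_count_range = c(8, 14),
         patterns = list(repeat_pattern("PFM", 1, 5))),
    list(name = "avenin_B", n_cys = 8, repeat_count_range = c(8, 14),
         patterns = list(repeat_pattern("MLL", 3, 6),
                         repeat_pattern("VFQPQLQQ"))),
    list(name = "avenin_C", n_cys = 8, repeat_count_range = c(8, 14),
         patterns = list(repeat_pattern("PFV", 2, 4),
                         repeat_pattern("FFQPQMQQ"),
                         repeat_pattern("VTQG")))
  )
}

realize_pattern <- function(pattern) {
  if (pattern$q_run_max == 0) return(pattern$prefix)
  paste0(pattern$prefix,
         strrep("Q", sample(pattern$q_run_min:pattern$q_run_max, 1)))
}

generate_panel <- function(spec) {
  n_nested <- round(spec$frac_nested * spec$n_motifs)
  n_base <- spec$n_motifs - n_nested
  motifs <- character(0)
  while (length(motifs) < n_base) {
    len <- sample(spec$motif_len_range[1]:spec$motif_len_range[2], 1)
    # cysteine-free, like the P/Q-rich T-cell epitope cores they emulate;
    # keeps embeddings from disturbing the template cysteine skeletons
    m <- sample_background(len, spec$q_frac, spec$p_frac, exclude = "C")
    if (!(m %in% motifs)) motifs <- c(motifs, m)
  }
  base <- motifs
  guard <- 0
  while (length(motifs) < spec$n_motifs && guard < 10000) {
    guard <- guard + 1
    parent <- sample(base[nchar(base) >= 5], 1)
    len <- sample(4:(nchar(parent) - 1), 1)
    s <- sample(seq_len(nchar(parent) - len + 1), 1)
    frag <- substr(parent, s, s + len - 1)
    if (!(frag %in% motifs)) motifs <- c(motifs, frag)
  }
  motifs
}

mutate_sequence <- function(sequence, rate, protected) {
  if (rate <= 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  protected <- unique(c(1L, protected, which(chars == "C")))
  eligible <- setdiff(seq_along(chars), protected)
  hit <- eligible[runif(length(eligible)) < rate]
  pool <- setdiff(AA_STANDARD, "C")
  for (i in hit) chars[i] <- sample(setdiff(pool, chars[i]), 1)
  paste(chars, collapse = "")
}

#' Generate a synthetic prolamin database with ground truth
#'
#' Deterministic given the spec (including its seed). Sequences assemble
#' as signal + N-terminal domain + repeats + C-terminal domain; panel
#' motifs are spliced into the repetitive domain at recorded coordinates;
#' point mutations are then applied outside embedded spans and away from
#' cysteines. Expected motif statistics are computed after assembly by the
#' independent per-residue oracle ([oracle_metrics()]), so incidental
#' matches created by the repetitive background are part of the truth.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `records` (record set: clean records first,
#'   then injected duplicate / ambiguous / partial records), `truth`
#'   (per-record group, corruption label and oracle motif metrics),
#'   `embedded` (embedded motif coordinates for clean records), `panel`
#'   (motif strings) and `templates` (list of [group_template()] with the
#'   per-group master accessions filled in).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_synthetic_impl(spec))
}

generate_synthetic_impl <- function(spec) {
  panel <- generate_panel(spec)
  max_motif <- max(nchar(panel))

  # per-group fixed domains (shared by all members of the group)
  domains <- lapply(spec$groups, function(g) {
    signal <- paste0("M", sample_background(
      19, q_frac = 0.1, p_frac = 0.1,
      exclude = c("C", "Y", "W", "F", "L")))
    nterm <- sample_background(30, spec$q_frac, spec$p_frac, exclude = "C")
    cterm <- sample_background(60, spec$q_frac, spec$p_frac, exclude = "C")
    if (g$n_cys > 0) {
      pos <- sort(sample(seq_len(nchar(cterm)), g$n_cys))
      cc <- strsplit(cterm, "", fixed = TRUE)[[1]]
      cc[pos] <- "C"
      cterm <- paste(cc, collapse = "")
    }
    list(signal = signal, nterm = nterm, cterm = cterm)
  })

  min_repeat_len <- min(vapply(seq_along(spec$groups), function(gi) {
    g <- spec$groups[[gi]]
    g$repeat_count_range[1] *
      min(vapply(g$patterns, function(p) nchar(p$prefix), integer(1)))
  }, numeric(1)))
  if (max_motif > min_repeat_len)
    stop("impossible spec: longest motif (", max_motif,
         ") exceeds the smallest repetitive domain (", min_repeat_len, ")")

  records <- list(); truth <- list(); embedded <- list()
  acc_id <- 0L
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[[gi]]
    dom <- domains[[gi]]
    for (s in seq_len(spec$n_per_group)) {
      acc_id <- acc_id + 1L
      acc <- sprintf("SYN%03d", acc_id)
      k <- sample(g$repeat_count_range[1]:g$repeat_count_range[2], 1)
      units <- vapply(seq_len(k), function(u)
        realize_pattern(g$patterns[[(u - 1L) %% length(g$patterns) + 1L]]),
        character(1))
      rep_region <- paste(units, collapse = "")
      seq0 <- paste0(dom$signal, dom$nterm, rep_region, dom$cterm)
      rep_off <- nchar(dom$signal) + nchar(dom$nterm)  # repeats start after

      # embed motifs at non-overlapping positions inside the repeat region
      n_emb <- sample(spec$embeds_per_seq[1]:spec$embeds_per_seq[2], 1)
      motifs <- sample(panel, min(n_emb, length(panel)))
      spans <- matrix(integer(0), ncol = 2)
      chars <- strsplit(seq0, "", fixed = TRUE)[[1]]
      for (m in motifs) {
        len <- nchar(m)
        placed <- FALSE
        for (try in seq_len(50)) {
          st <- rep_off + sample(seq_len(nchar(rep_region) - len + 1), 1)
          en <- st + len - 1L
          if (nrow(spans) == 0 ||
              all(spans[, 2] < st | spans[, 1] > en)) {
            chars[st:en] <- strsplit(m, "", fixed = TRUE)[[1]]
            spans <- rbind(spans, c(st, en))
            embedded[[length(embedded) + 1L]] <- data.frame(
              accession = acc, motif = m, start = st, end = en,
              stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed) next
      }
      seq1 <- paste(chars, collapse = "")
      prot <- if (nrow(spans)) unlist(apply(spans, 1, function(r)
        seq.int(r[1], r[2]), simplify = FALSE)) else integer(0)
      seq1 <- mutate_sequence(seq1, spec$mutation_rate, prot)

      records[[length(records) + 1L]] <- data.frame(
        accession = acc, source = "uniprot_sp",
        description = paste(g$name, "synthetic prolamin OS=Synthetica",
                            "cerealis"),
        species = "Synthetica cerealis", sequence = seq1,
        signal_len = nchar(dom$signal), stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        accession = acc, group = g$name, corruption = "clean",
        stringsAsFactors = FALSE)
    }
  }
  clean <- do.call(rbind, records)

  # corrupted extras, appended after the clean records
  corrupt <- list(); ctruth <- list()
  pick <- function(i) ((i - 1L) %% nrow(clean)) + 1L
  for (i in seq_len(spec$n_duplicates)) {
    src <- clean[pick(i), ]
    corrupt[[length(corrupt) + 1L]] <- data.frame(
      accession = sprintf("DUP%02d", i), source = "other",
      description = paste("redeposited copy of", src$accession),
      species = src$species, sequence = src$sequence,
      signal_len = 0L, stringsAsFactors = FALSE)
    ctruth[[length(ctruth) + 1L]] <- data.frame(
      accession = sprintf("DUP%02d", i), group = NA_character_,
      corruption = "duplicate", stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n_ambiguous)) {
    src <- clean[pick(spec$n_duplicates + i), ]
    chars <- strsplit(src$sequence, "", fixed = TRUE)[[1]]
    chars[sample(2:length(chars), 1)] <- "X"
    corrupt[[length(corrupt) + 1L]] <- data.frame(
      accession = sprintf("AMB%02d", i), source = "other",
      description = "low-quality translation", species = src$species,
      sequence = paste(chars, collapse = ""), signal_len = 0L,
      stringsAsFactors = FALSE)
    ctruth[[length(ctruth) + 1L]] <- data.frame(
      accession = sprintf("AMB%02d", i), group = NA_character_,
      corruption = "ambiguous", stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n_partial)) {
    src <- clean[pick(spec$n_duplicates + spec$n_ambiguous + i), ]
    corrupt[[length(corrupt) + 1L]] <- data.frame(
      accession = sprintf("PART%02d", i), source = "other",
      description = "storage prolamin (Fragment)", species = src$species,
      sequence = substr(src$sequence, 1, nchar(src$sequence) %/% 2),
      signal_len = 0L, stringsAsFactors = FALSE)
    ctruth[[length(ctruth) + 1L]] <- data.frame(
      accession = sprintf("PART%02d", i), group = NA_character_,
      corruption = "partial", stringsAsFactors = FALSE)
  }
  all_records <- rbind(clean, do.call(rbind, corrupt))
  rownames(all_records) <- NULL
  truth <- rbind(do.call(rbind, truth), do.call(rbind, ctruth))

  # expected metrics by the independent per-residue oracle, post-assembly
  om <- do.call(rbind, lapply(all_records$sequence, oracle_metrics,
                              panel = panel))
  truth <- cbind(truth, om)
  rownames(truth) <- NULL

  templates <- lapply(seq_along(spec$groups), function(gi) {
    g <- spec$groups[[gi]]
    group_template(g$name, g$patterns, g$n_cys,
                   master_accessions =
                     truth$accession[truth$group %in% g$name][1])
  })
  emb <- if (length(embedded)) do.call(rbind, embedded) else
    data.frame(accession = character(0), motif = character(0),
               start = integer(0), end = integer(0))
  list(records = all_records, truth = truth, embedded = emb,
       panel = panel, templates = templates)
}

#' Independent brute-force motif metric oracle
#'
#' Same contract as [motif_metrics()], implemented naively (substring scan
#' with per-residue boolean marking) and independently of the matching
#' machinery used by the pipeline. Used in tests and in ground-truth
#' generation.
#'
#' @inheritParams motif_metrics
#' @return one-row `data.frame`: `L`, `m`, `density`, `density_per100`,
#'   `coverage_pct`.
#' @export
oracle_metrics <- function(sequence, panel) {
  L <- nchar(sequence)
  covered <- logical(L)
  m <- 0L
  for (mot in panel) {
    k <- nchar(mot)
    if (k > L) next
    found <- FALSE
    for (i in seq_len(L - k + 1)) {
      if (substr(sequence, i, i + k - 1) == mot) {
        covered[i:(i + k - 1)] <- TRUE
        found <- TRUE
      }
    }
    if (found) m <- m + 1L
  }
  data.frame(L = L, m = m, density = m / L, density_per100 = 100 * m / L,
             coverage_pct = round(100 * sum(covered) / L, 2))
}

#' Write a generated synthetic database to disk
#'
#' Emits `sequences.fasta`, `panel.txt`, `truth.tsv`, `embedded.tsv` and
#' `templates.json` under `out_dir`.
#'
#' @param gen output of [generate_synthetic()].
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic <- function(gen, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(gen$records, file.path(out_dir, "sequences.fasta"))
  writeLines(gen$panel, file.path(out_dir, "panel.txt"))
  write.table(gen$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gen$embedded, file.path(out_dir, "embedded.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_templates(gen$templates, file.path(out_dir, "templates.json"))
  invisible(out_dir)
}

#' Write / read group templates as JSON
#'
#' @param templates list of [group_template()]s.
#' @param path JSON file path.
#' @return `path` (write) or the template list (read).
#' @export
write_templates <- function(templates, path) {
  enc <- lapply(templates, function(t) list(
    group_name = t$group_name,
    repeat_patterns = lapply(t$repeat_patterns, function(p)
      list(prefix = p$prefix, q_run_min = p$q_run_min,
           q_run_max = p$q_run_max)),
    expected_cys = t$expected_cys,
    master_accessions = as.list(t$master_accessions)))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(t) group_template(
    t$group_name,
    lapply(t$repeat_patterns, function(p)
      repeat_pattern(p$prefix, p$q_run_min, p$q_run_max)),
    if (is.null(t$expected_cys)) NA_integer_ else t$expected_cys,
    unlist(t$master_accessions)))
}
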