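#' Run configuration for the full pipeline
#'
#' @param input path to the input FASTA.
#' @param out_dir output directory (created if needed).
#' @param panel optional path to a motif panel; when `NULL` the motif
#'   mapping and marker-overlap stages are skipped and noted in the report.
#' @param templates path to a templates JSON ([write_templates()]) or a
#'   list of [group_template()]s.
#' @param masters optional path to a master-sequence FASTA; by default
#'   masters are looked up by accession among the curated input records.
#' @param curation a [curation_config()].
#' @param align an [align_params()].
#' @param identity_floor classification identity floor (default 30).
#' @param digest list of marker-stage settings: `max_missed`, `min_len`,
#'   `min_mass`, `ileq`, `fixed_cam`, `require_motif_overlap`.
#' @param cut_height optional tree cut height; when given, flat clusters
#'   are written alongside the tree.
#' @return a list of class `run_config`.
#' @export
run_config <- function(input, out_dir, panel = NULL, templates = NULL,
                       masters = NULL, curation = curation_config(),
                       align = align_params(), identity_floor = 30,
                       digest = list(), cut_height = NULL) {
  dg <- utils::modifyList(
    list(max_missed = 2, min_len = 5, min_mass = 750, ileq = FALSE,
         fixed_cam = FALSE, require_motif_overlap = FALSE), digest)
  structure(list(input = input, out_dir = out_dir, panel = panel,
                 templates = templates, masters = masters,
                 curation = curation, align = align,
                 identity_floor = identity_floor, digest = dg,
                 cut_height = cut_height),
            class = "run_config")
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full prolamin analysis pipeline
#'
#' Executes curate -> classify -> tree -> map-motifs -> markers in fixed
#' order, writing every stage output under `config$out_dir` and returning
#' a machine-readable run report whose counts chain across stages
#' (classification rows equal curated records; motif metric rows equal
#' classification rows). Outputs are deterministic given inputs and
#' configuration.
#'
#' @param config a [run_config()].
#' @return a list of class `run_report`: per-stage input/output counts, the
#'   curation report, skipped stages, and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$input))
    stop("input FASTA not found: ", config$input)
  if (!is.null(config$panel) && is.character(config$panel) &&
      !file.exists(config$panel))
    stop("motif panel not found: ", config$panel)
  templates <- config$templates
  if (is.character(templates)) {
    if (!file.exists(templates))
      stop("templates file not found: ", templates)
    templates <- read_templates(templates)
  }
  if (is.null(templates)) stop("run_pipeline needs group templates")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  skipped <- character(0)

  records <- read_fasta(config$input)
  cur <- curate(records, config$curation)
  outputs["curated_fasta"] <-
    write_fasta(cur$records, file.path(config$out_dir, "curated.fasta"))
  outputs["curation_report"] <- write_curation_report(
    cur$report, file.path(config$out_dir, "curation_report.tsv"))

  masters <- if (is.null(config$masters)) cur$records else
    read_fasta(config$masters)
  classes <- classify_database(cur$records, templates, masters,
                               config$identity_floor, config$align)
  outputs["classes"] <- write_tsv(classes,
                                  file.path(config$out_dir, "classes.tsv"))

  if (nrow(cur$records) >= 2) {
    im <- identity_matrix(cur$records, config$align)
    tree <- upgma(distances_from_identity(im))
    outputs["tree"] <- file.path(config$out_dir, "tree.nwk")
    writeLines(to_newick(tree), outputs["tree"])
    if (!is.null(config$cut_height)) {
      cl <- cut_clusters(tree, config$cut_height)
      df <- data.frame(
        accession = unlist(cl),
        cluster = rep(seq_along(cl), lengths(cl)), stringsAsFactors = FALSE)
      outputs["clusters"] <-
        write_tsv(df, file.path(config$out_dir, "clusters.tsv"))
    }
  } else skipped <- c(skipped, "tree (fewer than 2 curated records)")

  panel <- NULL
  metrics <- NULL
  if (!is.null(config$panel)) {
    panel <- if (is.character(config$panel) && length(config$panel) == 1 &&
                 file.exists(config$panel))
      read_motif_panel(config$panel) else config$panel
    metrics <- map_database(cur$records, panel)
    metrics$group <- classes$group[match(metrics$accession,
                                         classes$accession)]
    outputs["metrics"] <-
      write_tsv(metrics, file.path(config$out_dir, "metrics.tsv"))
    outputs["hits"] <- write_tsv(map_hits(cur$records, panel),
                                 file.path(config$out_dir, "hits.tsv"))
    grp <- stats::setNames(classes$group, classes$accession)
    outputs["summary"] <- write_tsv(
      summarize_by_group(metrics, grp),
      file.path(config$out_dir, "summary.tsv"))
  } else skipped <- c(skipped, "map-motifs (no panel configured)")

  markers <- select_markers(
    cur$records, panel = panel,
    max_missed = config$digest$max_missed,
    min_len = config$digest$min_len, min_mass = config$digest$min_mass,
    require_motif_overlap = config$digest$require_motif_overlap,
    ileq = config$digest$ileq, fixed_cam = config$digest$fixed_cam)
  outputs["markers"] <- write_tsv(markers,
                                  file.path(config$out_dir, "markers.tsv"))

  report <- structure(list(
    n_input = cur$report$n_input,
    n_curated = cur$report$n_kept,
    n_classified = nrow(classes),
    n_motif_rows = if (is.null(metrics)) NA_integer_ else nrow(metrics),
    n_markers = nrow(markers),
    curation = cur$report,
    skipped = skipped,
    outputs = outputs,
    config = config),
    class = "run_report")
  stopifnot(report$n_classified == report$n_curated,
            is.na(report$n_motif_rows) ||
              report$n_motif_rows == report$n_classified)
  jsonlite::write_json(
    list(n_input = report$n_input, n_curated = report$n_curated,
         n_classified = report$n_classified,
         n_motif_rows = report$n_motif_rows, n_markers = report$n_markers,
         removals = cur$report$tallies, skipped = skipped),
    file.path(config$out_dir, "report.json"), auto_unbox = TRUE,
    pretty = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", x$n_input, "records in ->", x$n_curated,
      "curated ->", x$n_classified, "classified;", x$n_markers,
      "marker candidate(s)\n")
  if (length(x$skipped))
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}
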