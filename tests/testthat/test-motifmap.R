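worked_seq <- "QQPFPQQPQQPFPQ"
worked_panel <- c("PFPQ", "QQPFPQ", "QQQQ")

test_that("find_hits reports every exact overlapping occurrence", {
  hits <- find_hits(worked_seq, worked_panel)
  expect_equal(hits[hits$motif == "PFPQ", c("start", "end")],
               data.frame(start = c(3L, 11L), end = c(6L, 14L),
                          row.names = c(2L, 4L)))
  expect_equal(hits[hits$motif == "QQPFPQ", "start"], c(1L, 9L))
  expect_false("QQQQ" %in% hits$motif)
  expect_true(!is.unsorted(hits$start))

  expect_equal(nrow(find_hits(worked_seq, character(0))), 0)
  whole <- find_hits("MPQF", "MPQF")
  expect_equal(whole, data.frame(motif = "MPQF", start = 1L, end = 4L,
                                 stringsAsFactors = FALSE))
})

test_that("motif metrics match the worked example", {
  mm <- motif_metrics(worked_seq, worked_panel)
  expect_equal(mm$m, 2)                        # PFPQ and QQPFPQ
  expect_equal(mm$density, 2 / 14)
  expect_equal(mm$coverage_pct, 85.71)         # union [1,6] u [9,14]
  # residues 7-8 are the only uncovered positions
  expect_equal(mm$L, 14)

  none <- motif_metrics("MAAA", c("PQPQ"))
  expect_equal(c(none$m, none$density, none$coverage_pct), c(0, 0, 0))
  self <- motif_metrics(worked_seq, worked_seq)
  expect_equal(c(self$m, self$coverage_pct), c(1, 100))
  expect_equal(self$density, 1 / 14)
})

test_that("metrics equal the independent per-residue oracle", {
  expect_equal(motif_metrics(worked_seq, worked_panel),
               oracle_metrics(worked_seq, worked_panel))
  set.seed(31)
  for (i in 1:100) {
    s <- random_prolamin(sample(20:120, 1))
    panel <- unique(vapply(1:6, function(j) {
      if (j <= 4) return(random_prolamin(sample(3:6, 1)))
      # fragments of the sequence itself, so hits (incl. nesting) are likely
      st <- sample(nchar(s) - 8, 1)
      substr(s, st, st + sample(3:7, 1))
    }, character(1)))
    expect_equal(motif_metrics(s, panel), oracle_metrics(s, panel))
  }
})

test_that("adding a motif never decreases any statistic", {
  set.seed(37)
  for (i in 1:20) {
    s <- random_prolamin(80)
    panel <- unique(c(substr(s, 11, 16), random_prolamin(4),
                      random_prolamin(5)))
    base <- motif_metrics(s, panel)
    extra <- substr(s, 41, 46)
    if (extra %in% panel) next
    more <- motif_metrics(s, c(panel, extra))
    expect_gte(more$m, base$m)
    expect_gte(more$density, base$density)
    expect_gte(more$coverage_pct, base$coverage_pct)
    expect_lte(more$m, length(panel) + 1)
    expect_lte(more$coverage_pct, 100)
  }
})

test_that("sequence duplication keeps coverage and halves density", {
  # repeat-free construction: single motif hit tiles identically in S and SS
  s <- "MARNDEGHIKWSTV"
  panel <- "RNDE"
  one <- motif_metrics(s, panel)
  two <- motif_metrics(paste0(s, s), panel)
  expect_equal(two$coverage_pct, one$coverage_pct)
  expect_equal(two$m, one$m)             # unique count unchanged
  expect_equal(two$density, one$density / 2)
})

test_that("map_database is deterministic and row-per-record", {
  gen <- generate_synthetic(synthetic_spec(seed = 2, n_per_group = 2,
                                           n_duplicates = 0,
                                           n_ambiguous = 0, n_partial = 0))
  tab1 <- map_database(gen$records, gen$panel)
  tab2 <- map_database(gen$records, gen$panel)
  expect_identical(tab1, tab2)
  expect_equal(tab1$accession, gen$records$accession)
  expect_equal(nrow(map_database(gen$records[0, ], gen$panel)), 0)
  # ground-truth agreement (truth computed by the oracle at generation)
  expect_equal(tab1$m, gen$truth$m)
  expect_equal(tab1$coverage_pct, gen$truth$coverage_pct)
})

test_that("group summaries use linear-interpolation quartiles", {
  metrics <- data.frame(accession = paste0("r", 1:5), L = 10, m = 0:4,
                        density = (0:4) / 10, density_per100 = 10 * (0:4),
                        coverage_pct = 10 * (0:4))
  g <- stats::setNames(rep("g1", 5), metrics$accession)
  s <- summarize_by_group(metrics, g)
  row <- s[s$statistic == "m", ]
  expect_equal(c(row$min, row$q1, row$median, row$q3, row$max, row$mean),
               c(0, 1, 2, 3, 4, 2))
  # group of one: all summary positions equal the value
  one <- summarize_by_group(metrics[3, ], g[3])
  r1 <- one[one$statistic == "coverage_pct", ]
  expect_equal(unique(unlist(r1[c("min", "q1", "median", "q3", "max",
                                  "mean")])), 20)
  expect_error(summarize_by_group(metrics, g[-1]), "without a group")
  expect_equal(sum(s$n) / 3, nrow(metrics))   # groups partition the rows
})

test_that("panel reading collapses duplicates and validates residues", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# coeliac toxic panel", "PFPQPQ", "QQPFPQ  # nested",
               "PFPQPQ", ""), path)
  expect_warning(panel <- read_motif_panel(path), "duplicate")
  expect_equal(panel, c("PFPQPQ", "QQPFPQ"))
  writeLines(c("PQXQ"), path)
  expect_error(read_motif_panel(path), "non-standard")
})
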