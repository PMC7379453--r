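test_that("deduplicate keeps the preferred source and first accession", {
  seq <- strrep("MPQ", 30)
  rec <- sequence_records(c("N1", "P1"), c(seq, seq),
                          source = c("ncbi", "uniprot_sp"))
  dd <- deduplicate(rec)
  expect_equal(dd$records$accession, "P1")   # UniProt preferentially kept
  expect_equal(dd$removals$accession, "N1")
  expect_equal(dd$removals$reason, "duplicate_sequence")

  # shared accession collapses to first occurrence
  rec2 <- sequence_records(c("A1", "A1"), c(strrep("MPQA", 20),
                                            strrep("MPQC", 20)))
  dd2 <- deduplicate(rec2)
  expect_equal(nrow(dd2$records), 1)
  expect_equal(dd2$records$sequence, strrep("MPQA", 20))
  expect_equal(dd2$removals$reason, "duplicate_accession")

  # all-distinct input passes through untouched
  rec3 <- make_records(c("MAAA", "MCCC", "MDDD"))
  expect_equal(deduplicate(rec3)$records, rec3)
  expect_equal(nrow(deduplicate(rec3)$removals), 0)
})

test_that("ambiguity and partial flags follow the configured rules", {
  cfg <- curation_config()
  rec <- make_records(c("PQXPQ", "PQPQ", strrep("MQ", 30)),
                      description = c("", "", "alpha gliadin (Fragment)"))
  expect_equal(flag_ambiguous(rec, cfg), c(TRUE, FALSE, FALSE))
  # short, no initiator Met, keyword
  expect_equal(flag_partial(rec, cfg), c(TRUE, TRUE, TRUE))

  full <- make_records(strrep("MQPF", 75))  # L=300, starts with M
  expect_false(flag_partial(full, cfg))
  short <- make_records(strrep("MQPFA", 4)) # L=20 < 50
  expect_true(flag_partial(short, cfg))
  # known signal peptide excuses a missing initiator Met
  mature <- make_records(strrep("QPQF", 25), signal_len = 19L)
  expect_false(flag_partial(mature, cfg))
  expect_true(flag_partial(make_records(strrep("QPQF", 25))))
})

test_that("pq_content is the exact P+Q percentage", {
  expect_equal(pq_content("PQPQ"), 100)
  expect_equal(pq_content("AAAA"), 0)
  expect_error(pq_content(""), "empty")
  # exactness property on constructed compositions
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:400, 1); k <- sample(0:n, 1)
    s <- paste0(strrep("P", k), strrep("A", n - k))
    expect_equal(pq_content(s), round(100 * k / n, 2))
  }
})

test_that("curate applies dedup, ambiguity and partial rules in order", {
  seqA <- strrep("MQPF", 30)
  rec <- sequence_records(
    accession = c("A", "B", "C", "D", "E"),
    sequence = c(seqA, seqA, paste0(strrep("MQPF", 20), "X"),
                 strrep("MQPA", 30), strrep("MQPC", 30)),
    source = c("uniprot_sp", "ncbi", "other", "other", "other"),
    description = c("", "", "", "partial cds", ""))
  out <- curate(rec)
  expect_equal(out$records$accession, c("A", "E"))
  expect_equal(unname(out$report$tallies[c("duplicate_sequence",
                                           "ambiguous_residue",
                                           "partial_sequence")]),
               c(1L, 1L, 1L))
  expect_equal(out$report$n_input, 5)
  expect_equal(out$report$n_kept, 2)
  # conservation
  expect_equal(out$report$n_input,
               out$report$n_kept + nrow(out$report$removals))
  # each removed accession appears exactly once
  expect_false(anyDuplicated(out$report$removals$accession) > 0)
  # idempotence
  again <- curate(out$records)
  expect_equal(again$records, out$records)
  expect_equal(nrow(again$report$removals), 0)
})

test_that("low P+Q warns but does not remove", {
  rec <- make_records(c(strrep("MA", 40), strrep("MQPQ", 20)))
  out <- curate(rec)
  expect_equal(nrow(out$records), 2)       # both kept
  expect_equal(out$report$low_pq$accession, "R01")
  expect_lt(out$report$low_pq$pq_percent, 30)
})

test_that("curation is conservative and idempotent on random corrupted sets", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(3:15, 1)
    seqs <- vapply(seq_len(n), function(j)
      paste0("M", random_prolamin(sample(40:120, 1))), character(1))
    # random corruption: duplicates, X injections, fragment keywords
    dup <- sample(n, sample(0:2, 1))
    seqs <- c(seqs, seqs[dup])
    desc <- rep("", length(seqs))
    amb <- sample(seq_along(seqs), sample(0:2, 1))
    for (a in amb) seqs[a] <- paste0(seqs[a], "X")
    frag <- sample(seq_along(seqs), sample(0:2, 1))
    desc[frag] <- "(Fragment)"
    rec <- make_records(seqs, accession = sprintf("S%03d", seq_along(seqs)),
                        description = desc)
    out <- curate(rec)
    expect_equal(out$report$n_input,
                 out$report$n_kept + nrow(out$report$removals))
    again <- curate(out$records)
    expect_equal(again$records, out$records)
    expect_equal(nrow(again$report$removals), 0)
  }
})

test_that("kept-set membership is invariant under input permutation", {
  set.seed(11)
  seqs <- c(strrep("MQPF", 30), strrep("MQPA", 30), strrep("MQPC", 30))
  rec <- sequence_records(c("A", "B", "C", "D"),
                          c(seqs, seqs[1]),
                          source = c("uniprot_sp", "other", "other", "ncbi"))
  base <- sort(curate(rec)$records$accession)
  for (i in 1:10) {
    perm <- rec[sample(nrow(rec)), ]
    expect_equal(sort(curate(perm)$records$accession), base)
  }
})
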