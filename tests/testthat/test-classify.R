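test_that("count_cysteines counts C residues", {
  expect_equal(count_cysteines("ACCA"), 2)
  expect_equal(count_cysteines(strrep("PQQPFPQQ", 10)), 0)  # omega-like
  expect_equal(count_cysteines(c("C", "PQ")), c(1L, 0L))
})

test_that("find_repeats matches prefix + greedy capped Q-runs", {
  p15 <- repeat_pattern("PFM", 1, 5)
  expect_equal(find_repeats("PFMQQQ", p15),
               data.frame(start = 1L, end = 6L))
  expect_equal(nrow(find_repeats("PFMA", p15)), 0)  # needs >= 1 Q
  expect_equal(nrow(find_repeats("AAAA", p15)), 0)
  # greedy run capped at q_run_max
  expect_equal(find_repeats(strrep("Q", 9), repeat_pattern("Q", 1, 3))$end[1],
               4L)  # prefix Q + 3-run cap
  # literal pattern
  expect_equal(find_repeats("AVTQGA", repeat_pattern("VTQG")),
               data.frame(start = 2L, end = 5L))
  # overlapping occurrences are all reported
  expect_equal(find_repeats("QQQ", repeat_pattern("QQ"))$start, c(1L, 2L))
})

test_that("find_repeats agrees with a naive scanner on random sequences", {
  set.seed(3)
  pats <- list(repeat_pattern("PFM", 1, 5), repeat_pattern("MLL", 3, 6),
               repeat_pattern("PFV", 2, 4), repeat_pattern("VFQPQLQQ"),
               repeat_pattern("VTQG"), repeat_pattern("QQ", 1, 2))
  for (i in 1:50) {
    s <- random_prolamin(sample(30:150, 1))
    for (p in pats) {
      got <- find_repeats(s, p)
      want <- naive_find_repeats(s, p)
      expect_equal(got, want, info = paste(p$prefix, s))
      if (nrow(got) > 0) {
        expect_true(all(got$start >= 1 & got$end <= nchar(s)))
      }
    }
  }
})

test_that("pairwise identity matches the stated convention", {
  expect_equal(pairwise_identity("PQPQ", "PQPQ"), 100)
  expect_equal(pairwise_identity("PQPQ", "PQPA"), 75)
  expect_error(pairwise_identity("", "PQ"), "empty")
  set.seed(5)
  for (i in 1:10) {
    a <- random_prolamin(sample(20:60, 1))
    b <- random_prolamin(sample(20:60, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("identity matrix is symmetric with 100 diagonal and is stable
           under adding unrelated records", {
  set.seed(9)
  rec <- make_records(vapply(1:4, function(i) random_prolamin(50),
                             character(1)))
  m <- identity_matrix(rec)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 4))
  rec5 <- rbind(rec, make_records(random_protein(80), accession = "EXTRA"))
  m5 <- identity_matrix(rec5)
  expect_equal(m5[1:4, 1:4], m)
})

test_that("group homology averages all unordered within-group pairs", {
  rec <- make_records(c("PQPQ", "PQPA", "PQPQ"), accession = c("a", "b", "c"))
  g <- c(a = "g1", b = "g1", c = "g1")
  expect_equal(unname(group_homology(rec, g)), 83.33)  # mean(75, 100, 75)
  two <- make_records(c("MPQF", "MPQF"), accession = c("x", "y"))
  expect_equal(unname(group_homology(two, c(x = "g", y = "g"))), 100)
  expect_error(group_homology(two[1, ], c(x = "g")), "size < 2")
})

test_that("a master classifies to its own group with identity 100", {
  gen <- generate_synthetic(synthetic_spec(seed = 4, n_per_group = 2,
                                           n_duplicates = 0,
                                           n_ambiguous = 0, n_partial = 0))
  masters_acc <- unlist(lapply(gen$templates, `[[`, "master_accessions"))
  masters <- gen$records[gen$records$accession %in% masters_acc, ]
  r <- classify_record(masters[1, ], gen$templates, masters)
  expect_equal(r$assigned_group, gen$templates[[1]]$group_name)
  expect_equal(r$best_identity, 100)
  expect_equal(r$best_master, masters$accession[1])
})

test_that("random non-prolamin strings fall below the identity floor", {
  gen <- generate_synthetic(synthetic_spec(seed = 4, n_per_group = 2,
                                           n_duplicates = 0,
                                           n_ambiguous = 0, n_partial = 0))
  masters_acc <- unlist(lapply(gen$templates, `[[`, "master_accessions"))
  masters <- gen$records[gen$records$accession %in% masters_acc, ]
  set.seed(21)
  n_unclassified <- 0
  for (i in 1:5) {
    r <- classify_record(make_records(random_protein(200)),
                         gen$templates, masters)
    n_unclassified <- n_unclassified + (r$assigned_group == "unclassified")
  }
  expect_gte(n_unclassified, 4)  # high probability, not certainty
})

test_that("classification accuracy is 100% at mutation rate 0 and does not
           improve as the rate rises", {
  rates <- c(0, 0.05, 0.2)
  acc <- vapply(rates, function(mu) {
    gen <- generate_synthetic(synthetic_spec(
      seed = 10, n_per_group = 3, mutation_rate = mu,
      n_duplicates = 0, n_ambiguous = 0, n_partial = 0))
    masters_acc <- unlist(lapply(gen$templates, `[[`, "master_accessions"))
    masters <- gen$records[gen$records$accession %in% masters_acc, ]
    cls <- classify_database(gen$records, gen$templates, masters)
    mean(cls$group == gen$truth$group)
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_true(all(diff(acc) <= 0))  # non-strict monotone degradation
})
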