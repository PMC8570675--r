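test_that("generate_reference is seeded, validated, and within design bounds", {
  expect_error(generate_reference(0))

  r1 <- generate_reference(5, 3, seed = 1)
  r2 <- generate_reference(5, 3, seed = 1)
  expect_identical(r1, r2)
  expect_false(identical(generate_reference(5, 3, seed = 2), r1))

  r <- generate_reference(3, 2, seed = 2)
  # brute-force scan of every record
  for (i in seq_len(nrow(r$arms))) {
    a <- r$arms[i, ]
    L <- a$end - a$start + 1L
    expect_gte(L, 20L); expect_lte(L, 24L)
    p <- r$precursors$sequence[r$precursors$id == a$precursor_id]
    expect_gte(a$start, 1L)
    expect_lte(a$end, nchar(p))
  }
  expect_true(all(nchar(r$precursors$sequence) >= 50))
  expect_identical(nrow(r$contaminants), 2L)
  expect_true(all(r$contaminants$family %in% c("rRNA", "tRNA", "snRNA",
                                               "snoRNA")))
  # exactly one annotated mature per precursor
  expect_identical(as.integer(table(r$matures$precursor_id)), rep(1L, 3))
})

test_that("generated precursors pass criteria 2, 4, 5 by construction", {
  r <- generate_reference(12, 0, seed = 19)
  for (i in seq_len(nrow(r$precursors))) {
    m <- r$matures[i, ]
    res <- assess_candidate(r$precursors$sequence[i],
                            mature = c(m$start, m$end))
    expect_true(res$criteria[["c2"]], info = r$precursors$id[i])
    expect_true(res$criteria[["c4"]], info = r$precursors$id[i])
    expect_true(res$criteria[["c5"]], info = r$precursors$id[i])
  }
})

test_that("simulate_sample_reads: degenerate config gives exact reads", {
  ref <- generate_reference(2, 0, seed = 4)
  m1 <- ref$matures$mature_id[1]
  cfg <- read_sim_config(n_reads = 1000, fraction_junk = 0,
                         fraction_contaminant = 0, fraction_novel_arm = 0,
                         end_variation_max = 0, mismatch_rate = 0,
                         dispersion = 0, seed = 5)
  reads <- simulate_sample_reads(ref, setNames(100, m1), cfg)
  m <- ref$matures[ref$matures$mature_id == m1, ]
  p <- ref$precursors$sequence[ref$precursors$id == m$precursor_id]
  expected <- paste0(substr(p, m$start, m$end), cfg$adapter)
  # Poisson at rate 100: some reads, all byte-identical mature+adapter
  expect_gt(nrow(reads), 0)
  expect_true(all(reads$seq == expected))
  expect_true(all(reads$qual == strrep("I", nchar(expected))))
  # expression keys must be annotated mature ids
  expect_error(simulate_sample_reads(ref, c(nonexistent = 10), cfg))
})

test_that("read simulation is deterministic and closed over the reference", {
  ref <- generate_reference(3, 2, seed = 8)
  expr <- setNames(rep(40, nrow(ref$matures)), ref$matures$mature_id)
  cfg <- read_sim_config(n_reads = 500, seed = 9)
  r1 <- simulate_sample_reads(ref, expr, cfg)
  r2 <- simulate_sample_reads(ref, expr, cfg)
  expect_identical(r1, r2)

  # FASTQ round trip is bit-exact
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(r1, f1)
  write_fastq(read_fastq(f1), f2)
  expect_identical(readLines(f1), readLines(f2))

  # closure: with junk and contaminants off, nothing ends up unmapped
  cfg2 <- read_sim_config(n_reads = 500, fraction_junk = 0,
                          fraction_contaminant = 0, seed = 10)
  reads <- simulate_sample_reads(ref, expr, cfg2)
  cleaned <- clean_reads(reads, clean_params(cfg2$adapter))
  tab <- collapse_unique(list(s = cleaned$inserts))
  ann <- annotate_table(tab, precursor_reference(ref$precursors, ref$matures))
  expect_identical(sum(ann$class == "unmapped"), 0L)

  # empty expression map emits only junk/contaminant reads
  cfg3 <- read_sim_config(n_reads = 200, fraction_novel_arm = 0, seed = 11)
  jc <- simulate_sample_reads(ref, setNames(numeric(0), character(0)), cfg3)
  expect_gt(nrow(jc), 0)
  cleaned <- clean_reads(jc, clean_params(cfg3$adapter))
  tab <- collapse_unique(list(s = cleaned$inserts))
  ann <- annotate_table(tab, precursor_reference(ref$precursors, ref$matures),
                        setNames(ref$contaminants$sequence,
                                 ref$contaminants$id))
  expect_identical(sum(ann$class %in% c("known_mature",
                                        "novel_arm_candidate")), 0L)
})

test_that("expected counts are recovered through preprocess + annotate", {
  ref <- generate_reference(2, 0, seed = 30)
  ids <- ref$matures$mature_id[1:2]
  expr <- setNames(c(50, 200), ids)
  cfg0 <- read_sim_config(n_reads = 300, fraction_junk = 0,
                          fraction_contaminant = 0, fraction_novel_arm = 0,
                          dispersion = 0.05)
  recovered <- matrix(NA_real_, nrow = 10, ncol = 2,
                      dimnames = list(NULL, ids))
  for (s in 1:10) {
    cfg <- read_sim_config(n_reads = 300, fraction_junk = 0,
                           fraction_contaminant = 0, fraction_novel_arm = 0,
                           dispersion = 0.05, seed = 100 + s)
    reads <- simulate_sample_reads(ref, expr, cfg)
    cleaned <- clean_reads(reads, clean_params(cfg$adapter))
    tab <- collapse_unique(list(x = cleaned$inserts))
    ann <- annotate_table(tab, precursor_reference(ref$precursors,
                                                   ref$matures))
    cm <- build_count_matrix(ann)
    recovered[s, ] <- cm[ids, "x"]
  }
  for (m in ids) {
    se <- sd(recovered[, m]) / sqrt(nrow(recovered))
    expect_lt(abs(mean(recovered[, m]) - expr[[m]]), 3 * se + 1e-9)
  }
})

test_that("simulate_cohort plants effects deterministically", {
  cfg <- cohort_sim_config(n_per_group = c(a = 5L, b = 5L),
                           pain_prevalence = c(a = 0, b = 1),
                           interference_slope = 0, opioid_beta = 0,
                           noise_sd = 1e-9, seed = 3)
  co <- simulate_cohort(cfg)
  # slope 0, vanishing noise: interference collapses to the intercept
  expect_equal(co$interference_mood, rep(2, 10), tolerance = 1e-6)
  # forced prevalence: pain matches group labels exactly
  expect_identical(co$pain, rep(c(0L, 1L), each = 5))

  expect_identical(simulate_cohort(cfg), co)
  expect_error(cohort_sim_config(n_per_group = c(a = 5L, b = 5L),
                                 pain_prevalence = c(a = 0, b = 1),
                                 noise_sd = -1))
})
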