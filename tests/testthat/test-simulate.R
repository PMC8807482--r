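test_that("rearrangements assemble exactly from trimmed segments and inserts", {
  ref <- default_ref()
  # force all trims and insertions to zero: full_nt must be V + D + J
  p0 <- sim_params(trim_p = 1, insert_p = 1, max_v_trim = 0, max_d_trim = 0,
                   max_j_trim = 0, max_insert = 0)
  set.seed(11)
  cl <- simulate_rearrangement(ref, params = p0)
  v <- ref$v_segments[[cl$v_name]]$sequence
  d <- ref$d_segments[[cl$d_name]]$sequence
  j <- ref$j_segments[[cl$j_name]]$sequence
  expect_identical(cl$full_nt, paste0(v, d, j))
  expect_identical(cl$cdr3_nt,
                   substr(cl$full_nt, cl$cdr3_start + 1, cl$cdr3_end))
})

test_that("every simulated clone carries a productive junction", {
  ref <- default_ref()
  set.seed(12)
  for (i in 1:50) {
    cl <- simulate_rearrangement(ref)
    expect_true(cl$productive)
    expect_identical(substr(cl$cdr3_aa, 1, 1), "C")
    expect_true(substr(cl$cdr3_aa, nchar(cl$cdr3_aa),
                       nchar(cl$cdr3_aa)) %in% c("W", "F"))
    expect_false(grepl("\\*", cl$cdr3_aa))
    expect_identical(translate_nt(cl$cdr3_nt), cl$cdr3_aa)
  }
})

test_that("rearrangement simulation is deterministic under a fixed seed", {
  ref <- default_ref()
  set.seed(77); a <- simulate_rearrangement(ref)
  set.seed(77); b <- simulate_rearrangement(ref)
  expect_identical(a, b)
})

test_that("hypermutation respects rate limits and positions", {
  s <- strrep("ACGT", 25)
  set.seed(5)
  r0 <- apply_shm(s, 0)
  expect_identical(r0$sequence, s)
  expect_length(r0$positions, 0)

  r1 <- apply_shm(s, 1)
  expect_identical(r1$positions, 0:99)
  expect_true(all(strsplit(r1$sequence, "")[[1]] != strsplit(s, "")[[1]]))

  # protected positions are never touched
  rp <- apply_shm(s, 1, protect = 0:9)
  expect_identical(substr(rp$sequence, 1, 10), substr(s, 1, 10))
  expect_identical(rp$positions, 10:99)

  # reported positions are exactly where sequence and input differ
  set.seed(6)
  rm <- apply_shm(s, 0.1)
  diff <- which(strsplit(rm$sequence, "")[[1]] != strsplit(s, "")[[1]]) - 1L
  expect_identical(rm$positions, diff)

  expect_error(apply_shm(s, -0.1), "probability")
  expect_error(apply_shm(s, 1.5), "probability")
})

test_that("hypermutation count matches the binomial expectation", {
  s <- random_nt(300)
  set.seed(42)
  counts <- replicate(10000, length(apply_shm(s, 0.02)$positions))
  expected <- 300 * 0.02
  se <- sqrt(300 * 0.02 * 0.98) / sqrt(10000)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("cohort simulation conserves the read budget and spikes publics", {
  ref <- default_ref()
  out <- tempfile()
  cfg <- cohort_config(
    groups = list(
      rna_loaded = list(n_clones = 60L, zipf_exponent = 1.1,
                        isotype_proportions = c(IgG1 = .25, IgG2b = .4, IgG2c = .35),
                        n_public = 5L),
      rna_free = list(n_clones = 30L, zipf_exponent = 1.9,
                      isotype_proportions = c(IgG1 = .6, IgG2b = .3, IgG2c = .1),
                      n_public = 3L)),
    n_samples = 2L, reads_per_sample = 100L, seed = 21L)
  sim <- simulate_cohort(cfg, ref, out)
  truth <- read_airr(sim$truth_file)

  # read-budget conservation: each sample emits exactly reads_per_sample rows
  per_sample <- table(truth$sample_id)
  expect_true(all(per_sample == 100L))
  expect_length(per_sample, 2 * 2 * 2)  # groups x time points x mice

  # every sample of a group carries all of the group's public junctions
  for (g in names(cfg$groups)) {
    pubs <- sim$public_cdr3[[g]]
    expect_length(pubs, cfg$groups[[g]]$n_public)
    gt <- truth[truth$group == g, ]
    for (sid in unique(gt$sample_id)) {
      expect_true(all(pubs %in% gt$cdr3_aa[gt$sample_id == sid]))
    }
  }

  # public junctions are never hit by hypermutation
  pub_rows <- truth[truth$is_public, ]
  expect_identical(pub_rows$read_cdr3_nt, pub_rows$cdr3_nt)

  # AIRR files: one row per read, duplicate_count fixed at 1
  a1 <- read_airr(sim$airr_files[1])
  expect_true(all(a1$duplicate_count == 1L))
})

test_that("cohort simulation is byte-identical under a fixed seed", {
  ref <- default_ref()
  cfg <- cohort_config(
    groups = list(rna_loaded = list(
      n_clones = 40L, zipf_exponent = 1.2,
      isotype_proportions = c(IgG1 = .3, IgG2b = .4, IgG2c = .3),
      n_public = 2L)),
    time_points = "d10", n_samples = 1L, reads_per_sample = 80L, seed = 33L)
  o1 <- tempfile(); o2 <- tempfile()
  s1 <- simulate_cohort(cfg, ref, o1)
  s2 <- simulate_cohort(cfg, ref, o2)
  for (i in seq_along(s1$airr_files)) {
    expect_identical(readLines(s1$airr_files[i]), readLines(s2$airr_files[i]))
  }
  expect_identical(readLines(s1$truth_file), readLines(s2$truth_file))
})

test_that("V usage and isotype proportions are recovered within 3 sigma", {
  ref <- default_ref()
  w <- bcrpipe:::default_v_bias(ref, NULL)
  set.seed(8)
  n <- 10000
  picks <- vapply(seq_len(n), function(i)
    simulate_rearrangement(ref, v_weights = w)$v_name, "")
  f <- mean(picks == "IGHV1-7*01")
  se <- sqrt(0.6 * 0.4 / n)
  expect_lt(abs(f - 0.6), 3 * se)

  # isotype proportions over emitted reads
  cfg <- cohort_config(
    groups = list(rna_loaded = list(
      n_clones = 2000L, zipf_exponent = 0.5,
      isotype_proportions = c(IgG1 = .25, IgG2b = .4, IgG2c = .35),
      n_public = 0L)),
    time_points = "d10", n_samples = 1L, reads_per_sample = 4000L,
    shm_rate = c(d10 = 0), seed = 9L)
  sim <- simulate_cohort(cfg, ref, tempfile())
  truth <- read_airr(sim$truth_file)
  # proportions apply per clone; compare at the clone level
  cl <- truth[!duplicated(truth$clone_id), ]
  for (iso in c("IgG1", "IgG2b", "IgG2c")) {
    p <- cfg$groups$rna_loaded$isotype_proportions[[iso]]
    se <- sqrt(p * (1 - p) / nrow(cl))
    expect_lt(abs(mean(cl$isotype == iso) - p), 3 * se)
  }
})

test_that("steeper clone-size law yields higher inequality (Gini)", {
  ref <- default_ref()
  gini_at <- function(zipf, seed) {
    cfg <- cohort_config(
      groups = list(g = list(
        n_clones = 100L, zipf_exponent = zipf,
        isotype_proportions = c(IgG1 = .3, IgG2b = .4, IgG2c = .3),
        n_public = 0L)),
      time_points = "d10", n_samples = 1L, reads_per_sample = 1000L,
      shm_rate = c(d10 = 0), seed = seed)
    truth <- read_airr(simulate_cohort(cfg, ref, tempfile())$truth_file)
    gini_coefficient(as.integer(table(truth$clone_id)))
  }
  g_steep <- vapply(1:15, function(i) gini_at(2.0, i), 0)
  g_flat <- vapply(1:15, function(i) gini_at(1.1, i + 100L), 0)
  expect_gt(mean(g_steep), mean(g_flat))
})
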