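test_that("perfect-match alignment scores 2x length with no substitutions", {
  ref <- default_ref()
  v <- ref$v_segments[["IGHV1-7*01"]]
  a <- align_segment(v$sequence, v)
  expect_equal(a$score, 2 * nchar(v$sequence))
  expect_length(a$substitution_read_pos, 0)
  expect_equal(a$read_interval, c(0, nchar(v$sequence)))
  expect_false(a$has_indel)
})

test_that("planted substitutions are reported at exactly their positions", {
  ref <- default_ref()
  v <- ref$v_segments[["IGHV5-6*01"]]
  s <- strsplit(v$sequence, "")[[1]]
  flip <- function(x) c(A = "C", C = "G", G = "T", T = "A")[[x]]
  s[51] <- flip(s[51]); s[200] <- flip(s[200])
  a <- align_segment(paste0(s, collapse = ""), v)
  expect_identical(a$substitution_read_pos, c(50L, 199L))
  expect_identical(a$substitution_germline_pos, c(50L, 199L))
  expect_equal(a$score, 2 * (nchar(v$sequence) - 2) - 2 * 2)
})

test_that("banded aligner reproduces the full-DP oracle on random pairs", {
  set.seed(314)
  for (i in 1:200) {
    n1 <- sample(20:60, 1); n2 <- sample(20:60, 1)
    a <- random_nt(n1); b <- random_nt(n2)
    got <- align_segment(a, b)$score
    expect_equal(got, sw_oracle_score(a, b), info = paste("pair", i))
  }
})

test_that("alignments with gaps are flagged and scored like the oracle", {
  # deletion of 3 nt from the middle of a segment copy
  ref <- default_ref()
  v <- ref$v_segments[["IGHV3-6*01"]]$sequence
  read <- paste0(substr(v, 1, 150), substr(v, 154, nchar(v)))
  a <- align_segment(read, v)
  expect_true(a$has_indel)
  expect_true(grepl("D", a$cigar))
  expect_equal(a$score, sw_oracle_score(read, v))
})

test_that("unmutated simulated reads recover truth calls and junctions", {
  ref <- default_ref()
  cfg <- cohort_config(
    groups = list(rna_loaded = list(
      n_clones = 80L, zipf_exponent = 1.1,
      isotype_proportions = c(IgG1 = .3, IgG2b = .4, IgG2c = .3),
      n_public = 3L)),
    time_points = "d10", n_samples = 1L, reads_per_sample = 400L,
    shm_rate = c(d10 = 0), seed = 55L)
  sim <- simulate_cohort(cfg, ref, tempfile())
  truth <- read_airr(sim$truth_file)
  reads <- do.call(rbind, lapply(sim$airr_files, read_airr))
  m <- match(reads$sequence_id, truth$sequence_id)
  ann <- annotate_sequences(reads$sequence, ref)

  expect_true(all(ann$pass_filter))
  expect_identical(ann$v_call, truth$v_name[m])
  expect_identical(ann$j_call, truth$j_name[m])
  expect_identical(ann$junction_aa, truth$cdr3_aa[m])
  expect_true(all(ann$v_mutation_count == 0))
})

test_that("a read whose J anchor is mutated away fails as unproductive", {
  ref <- tiny_reference()
  v <- ref$v_segments[[1]]; j <- ref$j_segments[[1]]
  # V (to anchor+3) + junction middle + J from its anchor: a clean junction
  read <- paste0(substr(v$sequence, 1, v$anchor + 3), "GATTACGAT",
                 substr(j$sequence, j$anchor + 1, nchar(j$sequence)))
  ok <- annotate_read(read, ref)
  expect_true(ok$pass_filter)
  expect_identical(ok$junction_aa, "CDYDW")

  # mutate the J anchor TGG -> TGC (Cys): junction no longer ends in W/F
  jpos <- nchar(read) - (nchar(j$sequence) - j$anchor) + 3
  broken <- read
  substr(broken, jpos, jpos) <- "C"
  bad <- annotate_read(broken, ref)
  expect_false(bad$pass_filter)
  expect_identical(bad$fail_reason, "unproductive_cdr3")
})

test_that("short reads are flagged, not errors", {
  ref <- default_ref()
  r <- annotate_read("ACGTACGTACGTACG", ref)
  expect_false(r$pass_filter)
  expect_identical(r$fail_reason, "short_read")
})

test_that("annotate_file preserves rows, is idempotent, and extends headers", {
  ref <- default_ref()
  cfg <- cohort_config(
    groups = list(rna_loaded = list(
      n_clones = 30L, zipf_exponent = 1.1,
      isotype_proportions = c(IgG1 = .3, IgG2b = .4, IgG2c = .3),
      n_public = 2L)),
    time_points = "d10", n_samples = 1L, reads_per_sample = 120L,
    shm_rate = c(d10 = 0.01), seed = 66L)
  sim <- simulate_cohort(cfg, ref, tempfile())
  f_in <- sim$airr_files[1]
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  out1 <- annotate_file(f_in, f1, ref)
  expect_identical(out1$sequence_id, read_airr(f_in)$sequence_id)

  # idempotence: annotating the annotated file reproduces it byte-identically
  annotate_file(f1, f2, ref)
  expect_identical(readLines(f1), readLines(f2))

  # header-only input: annotated header, zero rows
  f_empty <- tempfile(fileext = ".tsv")
  writeLines(paste(c("sequence_id", "sequence"), collapse = "\t"), f_empty)
  f_eo <- tempfile(fileext = ".tsv")
  out <- annotate_file(f_empty, f_eo, ref)
  expect_equal(nrow(out), 0)
  expect_true(all(c("v_call", "junction_aa", "pass_filter") %in%
                    strsplit(readLines(f_eo, n = 1), "\t")[[1]]))

  # missing mandatory column
  f_bad <- tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tfoo", "r1\tx"), f_bad)
  expect_error(annotate_file(f_bad, tempfile(), ref), "sequence")
})

test_that("V-call accuracy and mutation recovery on hypermutated reads", {
  ref <- default_ref()
  cfg <- cohort_config(
    groups = list(rna_loaded = list(
      n_clones = 400L, zipf_exponent = 1.1,
      isotype_proportions = c(IgG1 = .3, IgG2b = .4, IgG2c = .3),
      n_public = 0L)),
    time_points = "d17", n_samples = 1L, reads_per_sample = 2000L,
    shm_rate = c(d17 = 0.02), seed = 77L)
  sim <- simulate_cohort(cfg, ref, tempfile())
  truth <- read_airr(sim$truth_file)
  reads <- do.call(rbind, lapply(sim$airr_files, read_airr))
  m <- match(reads$sequence_id, truth$sequence_id)
  ann <- annotate_sequences(reads$sequence, ref)

  expect_gte(mean(ann$v_call == truth$v_name[m], na.rm = TRUE), 0.95)

  # mean substitution count within the counted V window: binomial
  # expectation over the window, excluding the two match-forced columns at
  # the alignment start (the window's right edge is the anchor cut, not an
  # alignment end, so only the left end is match-conditioned). Mutations are
  # drawn per clonal lineage, so collapse to one read per clone first.
  ok <- ann$pass_filter & !duplicated(reads$sequence)
  mu <- ann$v_mutation_count[ok]
  L <- ann$v_aligned_length[ok]
  expected <- 0.02 * mean(L - 2)
  se <- stats::sd(mu) / sqrt(length(mu))
  expect_lt(abs(mean(mu) - expected), 3 * se)

  # v_mutations is zero iff the aligned span is substitution-free
  zero <- ann$v_mutation_count[ok] == 0
  truth_zero <- truth$n_mutations[m][ok] == 0
  expect_true(all(zero[truth_zero]))
})

test_that("annotation is independent of row order", {
  ref <- default_ref()
  cfg <- cohort_config(
    groups = list(rna_loaded = list(
      n_clones = 40L, zipf_exponent = 1.1,
      isotype_proportions = c(IgG1 = .3, IgG2b = .4, IgG2c = .3),
      n_public = 0L)),
    time_points = "d10", n_samples = 1L, reads_per_sample = 150L,
    shm_rate = c(d10 = 0.01), seed = 88L)
  sim <- simulate_cohort(cfg, ref, tempfile())
  reads <- read_airr(sim$airr_files[1])
  ann <- annotate_sequences(reads$sequence, ref)
  perm <- sample(nrow(reads))
  ann_perm <- annotate_sequences(reads$sequence[perm], ref)
  expect_equal(ann_perm, ann[perm, ], ignore_attr = TRUE)
})
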