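# Independent oracles used by the test suite. These deliberately use naive,
# transparent algorithms so they share no code with the implementation.

# Full-matrix local alignment (Gotoh affine gaps), score only.
sw_oracle_score <- function(a, b, match = 2, mismatch = -2,
                            gap_open = -6, gap_extend = -1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(0)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consumes b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consumes a)
  go <- gap_open + gap_extend
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + go, E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + go, F[i - 1, j] + gap_extend)
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Venn regions by explicit set algebra (the implementation classifies
# membership patterns instead).
venn3_oracle <- function(s1, s2, s3) {
  s1 <- unique(s1); s2 <- unique(s2); s3 <- unique(s3)
  c("100" = length(setdiff(setdiff(s1, s2), s3)),
    "010" = length(setdiff(setdiff(s2, s1), s3)),
    "001" = length(setdiff(setdiff(s3, s1), s2)),
    "110" = length(setdiff(intersect(s1, s2), s3)),
    "101" = length(setdiff(intersect(s1, s3), s2)),
    "011" = length(setdiff(intersect(s2, s3), s1)),
    "111" = length(intersect(intersect(s1, s2), s3)))
}

# Naive UPGMA returning the cophenetic (merge-height) matrix.
upgma_oracle_cophenetic <- function(d) {
  n <- nrow(d)
  labs <- rownames(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  dm <- d
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  active <- seq_len(n)
  while (length(active) > 1) {
    sub <- dm[active, active, drop = FALSE]
    sub[!upper.tri(sub)] <- Inf
    w <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[w[1]]; j <- active[w[2]]
    h <- dm[i, j]
    for (x in clusters[[i]]) for (y in clusters[[j]]) {
      coph[x, y] <- coph[y, x] <- h
    }
    # average linkage update onto i
    for (k in setdiff(active, c(i, j))) {
      dm[i, k] <- dm[k, i] <-
        (sizes[i] * dm[i, k] + sizes[j] * dm[j, k]) / (sizes[i] + sizes[j])
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  coph
}

gini_coefficient <- function(x) {
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# minimal annotated-record frame for clonotype-level tests
fake_records <- function(junction_aa, vdj_nt = NULL, v_call = "IGHV1-7*01",
                         v_mut = 0L, pass = TRUE) {
  n <- length(junction_aa)
  data.frame(
    sequence_id = sprintf("r%03d", seq_len(n)),
    junction_aa = junction_aa,
    vdj_nt = if (is.null(vdj_nt)) rep_len(strrep("ACGT", 8), n) else vdj_nt,
    v_call = rep_len(v_call, n),
    v_mutation_count = rep_len(v_mut, n),
    pass_filter = rep_len(pass, n),
    stringsAsFactors = FALSE)
}

# small in-code germline for negative-path tests
tiny_reference <- function() {
  v <- germline_segment("IGHV9-1*01", "IGHV9", "V",
                        paste0(strrep("ACG", 20), "TGTGCAAGA"), anchor = 60L)
  d <- germline_segment("IGHD9-1*01", "IGHD9", "D", "GGTATAGCAGC")
  j <- germline_segment("IGHJ9*01", "IGHJ9", "J",
                        paste0("ACTACTTTGACTAC", "TGG", strrep("GTCGAA", 4)),
                        anchor = 14L)
  structure(list(v_segments = list("IGHV9-1*01" = v),
                 d_segments = list("IGHD9-1*01" = d),
                 j_segments = list("IGHJ9*01" = j),
                 version_tag = "tiny-test"),
            class = "germline_reference")
}

default_ref <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- load_default_germline()
    ref
  }
})
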