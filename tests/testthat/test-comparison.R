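test_that("jaccard handles identity, disjointness and partial overlap", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(character(0), character(0)), 0)
  # duplicates are ignored
  expect_equal(jaccard(c("a", "a", "b"), c("b", "b")), 0.5)
})

test_that("jaccard distance behaves like a metric on random triples", {
  set.seed(20)
  pool <- paste0("c", 1:40)
  for (i in 1:50) {
    A <- sample(pool, sample(5:20, 1))
    B <- sample(pool, sample(5:20, 1))
    C <- sample(pool, sample(5:20, 1))
    dAB <- 1 - jaccard(A, B); dBC <- 1 - jaccard(B, C)
    dAC <- 1 - jaccard(A, C)
    expect_lte(dAC, dAB + dBC + 1e-12)
    expect_equal(dAB, 1 - jaccard(B, A))
    expect_gte(dAB, 0); expect_lte(dAB, 1)
  }
})

test_that("sharing spectrum counts occupancy over the union", {
  # all repertoires identical: everything shared by all
  s <- sharing_spectrum(list(a = c("x", "y"), b = c("x", "y"),
                             c = c("x", "y")))
  expect_equal(s$pct_shared, 100)
  expect_equal(unname(s$shared_fraction_at_k["3"]), 100)

  # pairwise disjoint: nothing shared
  s0 <- sharing_spectrum(list(a = "x", b = "y", c = "z"))
  expect_equal(s0$pct_shared, 0)
  expect_equal(s0$universe_size, 3)

  # fractions at k are non-increasing and start at 100%
  set.seed(30)
  sets <- lapply(1:6, function(i) sample(paste0("c", 1:50), 25))
  sp <- sharing_spectrum(sets)
  expect_equal(unname(sp$shared_fraction_at_k["1"]), 100)
  expect_true(all(diff(sp$shared_fraction_at_k) <= 1e-12))
  expect_true(all(sp$occupancy >= 1 & sp$occupancy <= 6))

  expect_error(sharing_spectrum(list(a = "x")), "at least 2")
})

test_that("spiked public junctions are exactly the top-shared set", {
  # 5 publics in all 8 repertoires plus disjoint privates
  pubs <- paste0("CARPUB", 1:5, "W")
  sets <- lapply(1:8, function(i) c(pubs, paste0("CPRIV", i, "_", 1:30, "W")))
  sp <- sharing_spectrum(sets, top_threshold = 8L)
  expect_setequal(sp$top_shared, pubs)
  expect_true(all(sp$top_shared_occupancy == 8))
})

test_that("venn3 equals the set-algebra oracle", {
  # identical sets
  v <- venn3(letters[1:5], letters[1:5], letters[1:5])
  expect_equal(unname(v$regions["111"]), 5L)
  expect_equal(sum(v$regions), v$union_size)

  # fully disjoint singletons
  v2 <- venn3("a", "b", "c")
  expect_equal(unname(v2$regions[c("100", "010", "001")]), c(1L, 1L, 1L))
  expect_equal(sum(v2$regions[c("110", "101", "011", "111")]), 0L)

  set.seed(40)
  pool <- paste0("m", 1:100)
  for (i in 1:20) {
    s1 <- sample(pool, 50); s2 <- sample(pool, 50); s3 <- sample(pool, 50)
    v <- venn3(s1, s2, s3)
    o <- venn3_oracle(s1, s2, s3)
    expect_equal(v$regions[names(o)], o)
    expect_equal(sum(v$regions), length(unique(c(s1, s2, s3))))
    # pairwise counts regardless of the third set
    expect_equal(unname(v$pairwise[1]), length(intersect(s1, s2)))
  }
})

test_that("consensus takes the plurality residue with lexicographic ties", {
  u <- consensus_profile(rep("CARDYYGSWF", 10))
  expect_equal(u$consensus, "CARDYYGSWF")
  expect_equal(u$conservation, rep(1, 10))

  tie <- consensus_profile(c("CARDY", "CARDF"))
  expect_equal(tie$consensus, "CARDF")  # F < Y at the tied position
  expect_equal(tie$conservation, c(1, 1, 1, 1, 0.5))

  one <- consensus_profile("CW")
  expect_equal(one$consensus, "CW")
  expect_equal(one$conservation, c(1, 1))

  expect_error(consensus_profile(character(0)), "empty")
  expect_error(consensus_profile(c("CAW", "CAAW")), "stratify")
})

test_that("modal length stratum picks the dominant CDR3 length", {
  x <- c("CAAAAAAAAW", "CBBBBBBBBW", "CCCW")
  expect_setequal(modal_length_stratum(x), x[1:2])
  expect_identical(modal_length_stratum(character(0)), character(0))
})

test_that("repertoire distances are symmetric, bounded and exact", {
  sets <- list(r1 = c("a", "b", "c"), r2 = c("b", "c", "d"), r3 = c("x", "y"))
  d <- repertoire_distance(sets)
  expect_equal(d["r1", "r2"], 0.5)
  expect_equal(d["r1", "r3"], 1)
  expect_equal(d["r2", "r3"], 1)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))

  # duplicate repertoires at distance zero
  d0 <- repertoire_distance(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(d0["a", "b"], 0)

  expect_error(repertoire_distance(sets[1]), "at least 2")
})

test_that("bray-curtis uses clonotype frequencies", {
  t1 <- build_clonotypes(fake_records(rep(c("CAW", "CBW"), c(3, 1))), "cdr3_aa")
  t2 <- build_clonotypes(fake_records(rep(c("CAW", "CBW"), c(1, 3))), "cdr3_aa")
  d <- repertoire_distance(list(a = t1, b = t2), metric = "bray_curtis")
  # frequencies (.75,.25) vs (.25,.75): BC = 0.5
  expect_equal(unname(d["a", "b"]), 0.5)
})

test_that("UPGMA tree matches the hand-derived merge heights", {
  m <- matrix(c(0, 0.2, 0.8,
                0.2, 0, 0.8,
                0.8, 0.8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_tree(m)
  phy <- tr$phylo
  coph <- stats::cophenetic(phy)
  expect_equal(coph["A", "B"], 0.2)   # merge height 0.1 per side
  expect_equal(coph["A", "C"], 0.8)
  expect_equal(coph["B", "C"], 0.8)
  # ((A,B),C) topology: A and B form a cherry
  expect_true(ape::is.monophyletic(phy, c("A", "B")))
  expect_match(tr$newick, "A:0.1")
})

test_that("two leaves give a cherry with half the distance per branch", {
  m <- matrix(c(0, 0.6, 0.6, 0), 2, 2, dimnames = list(c("x", "y"),
                                                       c("x", "y")))
  tr <- build_tree(m)
  expect_equal(sort(tr$phylo$edge.length), c(0.3, 0.3))
})

test_that("UPGMA equals the naive agglomeration oracle on random matrices", {
  set.seed(50)
  for (i in 1:10) {
    d <- matrix(stats::runif(36, 0.1, 1), 6, 6)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    dimnames(d) <- list(paste0("L", 1:6), paste0("L", 1:6))
    tr <- build_tree(d)
    coph_got <- stats::cophenetic(tr$phylo)[paste0("L", 1:6), paste0("L", 1:6)]
    coph_exp <- upgma_oracle_cophenetic(d)
    expect_equal(coph_got, coph_exp, tolerance = 1e-9)
    # ultrametric: all leaf depths equal
    depths <- ape::node.depth.edgelength(tr$phylo)[1:6]
    expect_lt(diff(range(depths)), 1e-9)
  }
})

test_that("tree building is invariant to label order", {
  set.seed(60)
  d <- matrix(stats::runif(25, 0.1, 1), 5, 5)
  d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("r", 1:5), paste0("r", 1:5))
  t1 <- build_tree(d)
  perm <- c(3, 1, 5, 2, 4)
  t2 <- build_tree(d[perm, perm])
  c1 <- stats::cophenetic(t1$phylo)[paste0("r", 1:5), paste0("r", 1:5)]
  c2 <- stats::cophenetic(t2$phylo)[paste0("r", 1:5), paste0("r", 1:5)]
  expect_equal(c1, c2, tolerance = 1e-12)
  # newick parses back to the same leaf set
  expect_setequal(ape::read.tree(text = t1$newick)$tip.label, rownames(d))

  expect_error(build_tree(matrix(c(0, 1, 0.5, 0), 2, 2)), "symmetric")
})
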