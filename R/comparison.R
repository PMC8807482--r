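#' Jaccard index of two clonotype sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty.
#'
#' @param set_a,set_b character vectors (duplicates ignored).
#' @return A number in `[0, 1]`.
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Cross-repertoire CDR3 sharing spectrum
#'
#' Counts, for every CDR3 in the union over the compared repertoires, the
#' number of repertoires containing it (its occupancy), and reports the
#' percentage of the union shared by at least k repertoires for every k.
#' The sharing universe is the union of unique CDR3s; percentages are always
#' of this union. A per-repertoire variant (mean percentage of each
#' repertoire's own clonotypes that are shared) is reported alongside.
#'
#' @param sets named list (>= 2) of character vectors of CDR3 amino-acid
#'   sequences, one per repertoire.
#' @param share_threshold occupancy threshold for the headline
#'   `pct_shared` (default: present in at least 2 repertoires).
#' @param top_threshold minimum occupancy for `top_shared` (default > 6,
#'   i.e. >= 7 repertoires).
#' @return A `sharing_report`: list with `n_repertoires`, `universe_size`,
#'   `occupancy` (named integer), `shared_fraction_at_k` (percentages, k =
#'   1..n), `pct_shared`, `pct_shared_per_repertoire`, `top_shared`
#'   (character, ordered by decreasing occupancy then name) and the two
#'   thresholds.
#' @export
sharing_spectrum <- function(sets, share_threshold = 2L, top_threshold = 7L) {
  if (length(sets) < 2L) stop("sharing requires at least 2 repertoires")
  sets <- lapply(sets, unique)
  occ <- table(unlist(sets, use.names = FALSE))
  occ <- setNames(as.integer(occ), names(occ))
  universe <- length(occ)
  n <- length(sets)
  frac <- vapply(seq_len(n), function(k) 100 * mean(occ >= k), 0)
  names(frac) <- seq_len(n)
  shared_keys <- names(occ)[occ >= share_threshold]
  per_rep <- vapply(sets, function(s)
    if (length(s)) 100 * mean(s %in% shared_keys) else 0, 0)
  top <- occ[occ >= top_threshold]
  top <- top[order(-top, names(top))]
  structure(list(
    n_repertoires = n, universe_size = universe, occupancy = occ,
    shared_fraction_at_k = frac,
    pct_shared = 100 * mean(occ >= share_threshold),
    pct_shared_per_repertoire = per_rep,
    top_shared = names(top), top_shared_occupancy = top,
    share_threshold = share_threshold, top_threshold = top_threshold),
    class = "sharing_report")
}

#' @export
print.sharing_report <- function(x, ...) {
  cat("<sharing_report> ", x$n_repertoires, " repertoires, universe ",
      x$universe_size, "\n  shared by >= ", x$share_threshold, ": ",
      sprintf("%.1f%%", x$pct_shared), "; top shared (occupancy >= ",
      x$top_threshold, "): ", length(x$top_shared), "\n", sep = "")
  invisible(x)
}

#' Three-set Venn partition
#'
#' Counts of the 7 exclusive regions of three clonotype sets, plus the
#' pairwise-shared counts irrespective of the third set.
#'
#' @param set1,set2,set3 character vectors.
#' @param labels names used in the output.
#' @return List with `regions` (named counts: `"100"`, `"010"`, `"001"`,
#'   `"110"`, `"101"`, `"011"`, `"111"`, digit order following `labels`),
#'   `pairwise` (named counts of each intersection regardless of the third
#'   set) and `union_size`.
#' @export
venn3 <- function(set1, set2, set3, labels = c("set1", "set2", "set3")) {
  s <- list(unique(set1), unique(set2), unique(set3))
  u <- unique(unlist(s, use.names = FALSE))
  m1 <- u %in% s[[1]]; m2 <- u %in% s[[2]]; m3 <- u %in% s[[3]]
  pat <- paste0(m1 + 0L, m2 + 0L, m3 + 0L)
  keys <- c("100", "010", "001", "110", "101", "011", "111")
  regions <- setNames(vapply(keys, function(k) sum(pat == k), 0L), keys)
  pairwise <- setNames(
    c(sum(m1 & m2), sum(m1 & m3), sum(m2 & m3)),
    c(paste(labels[1], labels[2], sep = "&"),
      paste(labels[1], labels[3], sep = "&"),
      paste(labels[2], labels[3], sep = "&")))
  list(labels = labels, regions = regions, pairwise = pairwise,
       union_size = length(u))
}

#' Plurality consensus of equal-length CDR3 sequences
#'
#' Per position, the consensus residue is the most frequent one (ties broken
#' by the lexicographically smallest residue) and conservation is the
#' plurality count divided by the number of sequences. Mixed-length input is
#' an error: stratify by length first (see [modal_length_stratum()]); the
#' dominant length stratum is the one analyzed in practice.
#'
#' @param cdr3 character vector of amino-acid sequences, all the same length.
#' @param length expected length; defaults to the common length.
#' @return A `consensus_profile`: list with `length`, `n_sequences`,
#'   `consensus` and `conservation` (numeric per position).
#' @examples
#' consensus_profile(c("CARDY", "CARDF"))  # "CARDF", conservation ..., 0.5
#' @export
consensus_profile <- function(cdr3, length = NULL) {
  if (base::length(cdr3) == 0L) stop("consensus of an empty set is undefined")
  lens <- nchar(cdr3)
  if (base::length(unique(lens)) != 1L) {
    stop("sequences have mixed lengths; stratify by length first ",
         "(see modal_length_stratum)")
  }
  L <- lens[1]
  if (!is.null(length) && length != L) {
    stop("sequences have length ", L, ", expected ", length)
  }
  mat <- do.call(rbind, strsplit(cdr3, "", fixed = TRUE))
  cons <- character(L)
  consv <- numeric(L)
  for (p in seq_len(L)) {
    tb <- table(mat[, p])
    best <- sort(names(tb)[tb == max(tb)])[1]  # lexicographic tie-break
    cons[p] <- best
    consv[p] <- max(tb) / base::length(cdr3)
  }
  structure(list(length = L, n_sequences = base::length(cdr3),
                 consensus = paste0(cons, collapse = ""),
                 conservation = consv), class = "consensus_profile")
}

#' Extract the modal-length stratum of a CDR3 set
#'
#' @param cdr3 character vector.
#' @return Character vector of the sequences whose length is the most
#'   frequent one (ties broken toward the shorter length).
#' @export
modal_length_stratum <- function(cdr3) {
  if (length(cdr3) == 0L) return(character(0))
  tb <- table(nchar(cdr3))
  modal <- as.integer(names(tb)[which.max(tb)])
  cdr3[nchar(cdr3) == modal]
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("<consensus_profile> n =", x$n_sequences, "length", x$length, "\n ",
      x$consensus, "\n  conservation:",
      paste(sprintf("%.2f", x$conservation), collapse = " "), "\n")
  invisible(x)
}

#' Pairwise repertoire distance matrix
#'
#' Distances between repertoires from their clonotype content: Jaccard
#' distance `1 - J` on clonotype sets (default), or Bray-Curtis
#' dissimilarity on clonotype read-count frequencies.
#'
#' @param tables named list (>= 2) of `clonotype_table` objects, or (for
#'   `jaccard_distance` only) named list of character vectors.
#' @param metric `"jaccard_distance"` or `"bray_curtis"`.
#' @return Symmetric numeric matrix with zero diagonal, entries in `[0, 1]`,
#'   dimnames = repertoire labels.
#' @export
repertoire_distance <- function(tables,
                                metric = c("jaccard_distance", "bray_curtis")) {
  metric <- match.arg(metric)
  if (length(tables) < 2L) stop("need at least 2 repertoires for distances")
  labels <- names(tables)
  if (is.null(labels)) labels <- paste0("rep", seq_along(tables))

  if (metric == "jaccard_distance") {
    sets <- lapply(tables, function(t)
      if (inherits(t, "clonotype_table")) t$entries$key else unique(t))
    n <- length(sets)
    d <- matrix(0, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- 1 - jaccard(sets[[i]], sets[[j]])
      }
    }
    return(d)
  }
  # bray_curtis on clonotype frequency vectors over the union of keys
  if (!all(vapply(tables, inherits, TRUE, "clonotype_table"))) {
    stop("bray_curtis requires clonotype_table inputs (needs counts)")
  }
  keys <- unique(unlist(lapply(tables, function(t) t$entries$key)))
  freq <- vapply(tables, function(t) {
    v <- setNames(numeric(length(keys)), keys)
    v[t$entries$key] <- t$entries$count / sum(t$entries$count)
    v
  }, numeric(length(keys)))
  d <- as.matrix(vegan::vegdist(t(freq), method = "bray"))
  dimnames(d) <- list(labels, labels)
  d
}

#' UPGMA repertoire-similarity tree
#'
#' Average-linkage (UPGMA) agglomeration of a repertoire distance matrix
#' into an ultrametric tree, with deterministic tie-breaking by label order,
#' returned with a Newick serialization (leaf depth = merge height / 2).
#'
#' @param distance_matrix symmetric matrix, zero diagonal.
#' @param labels leaf labels; default from the matrix dimnames.
#' @return A `tree_result`: list with `labels`, `distance_matrix`, `phylo`
#'   (an [ape::as.phylo()] tree) and `newick`.
#' @export
build_tree <- function(distance_matrix, labels = rownames(distance_matrix)) {
  m <- as.matrix(distance_matrix)
  if (nrow(m) < 2L) stop("need at least 2 repertoires to build a tree")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")
  if (is.null(labels)) labels <- paste0("rep", seq_len(nrow(m)))
  dimnames(m) <- list(labels, labels)
  hc <- hclust(as.dist(m), method = "average")
  phy <- ape::as.phylo(hc)
  newick <- ape::write.tree(phy)
  structure(list(labels = labels, distance_matrix = m, phylo = phy,
                 newick = newick), class = "tree_result")
}

#' @export
print.tree_result <- function(x, ...) {
  cat("<tree_result> ", length(x$labels), " leaves\n  ", x$newick, "\n",
      sep = "")
  invisible(x)
}
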