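v_gene <- function(v_call) sub("\\*.*$", "", v_call)
v_family <- function(v_call) sub("-.*$", "", v_gene(v_call))

#' Build a clonotype table from annotated records
#'
#' Collapses passing records into clonotypes under one of two definitions:
#' `"cdr3_aa"` (key = CDR3 amino-acid sequence, `junction_aa`) or `"vdj_nt"`
#' (key = full VDJ nucleotide sequence over the aligned V-start..J-end span,
#' `vdj_nt`). Records with `pass_filter == FALSE` are excluded and counted in
#' the `dropped` tally.
#'
#' @param records annotated data.frame (from [annotate_sequences()] /
#'   [annotate_file()]).
#' @param mode clonotype definition, `"cdr3_aa"` or `"vdj_nt"`.
#' @param repertoire_id identifier attached to the table.
#' @return A `clonotype_table`: list with `repertoire_id`, `mode`, `entries`
#'   (data.frame `key`, `count`, `v_call`, `mean_mutations`, sorted by
#'   decreasing count then key), `total_reads` and `dropped`.
#' @export
build_clonotypes <- function(records, mode = c("cdr3_aa", "vdj_nt"),
                             repertoire_id = NA_character_) {
  mode <- match.arg(mode)
  keep <- records[isTRUE_v(records$pass_filter), , drop = FALSE]
  dropped <- nrow(records) - nrow(keep)
  key <- switch(mode, cdr3_aa = keep$junction_aa, vdj_nt = keep$vdj_nt)

  if (nrow(keep) == 0L) {
    entries <- data.frame(key = character(0), count = integer(0),
                          v_call = character(0), mean_mutations = numeric(0),
                          stringsAsFactors = FALSE)
  } else {
    if (any(!nzchar(key))) stop("passing record with empty clonotype key")
    sp <- split(seq_along(key), key)
    entries <- data.frame(
      key = names(sp),
      count = lengths(sp),
      v_call = vapply(sp, function(i) modal_value(keep$v_call[i]), ""),
      mean_mutations = vapply(sp, function(i)
        mean(keep$v_mutation_count[i]), 0),
      stringsAsFactors = FALSE)
    entries <- entries[order(-entries$count, entries$key), , drop = FALSE]
    rownames(entries) <- NULL
  }
  structure(list(repertoire_id = repertoire_id, mode = mode,
                 entries = entries, total_reads = nrow(keep),
                 dropped = dropped),
            class = "clonotype_table")
}

isTRUE_v <- function(x) !is.na(x) & x
modal_value <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  names(tb)[1]
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat("<clonotype_table> ", x$repertoire_id, " [", x$mode, "]: ",
      nrow(x$entries), " clonotypes / ", x$total_reads, " reads (",
      x$dropped, " dropped)\n", sep = "")
  invisible(x)
}

#' Read-normalized clonotype diversity
#'
#' The repertoire diversity statistic: unique clonotype count divided by the
#' repertoire's read count, a richness-per-sequencing-depth ratio in
#' `(0, 1]`.
#'
#' @param table a `clonotype_table`.
#' @return A single number, `n_clonotypes / total_reads`.
#' @examples
#' # counts {5, 3, 2}: 3 clonotypes over 10 reads
#' tab <- structure(list(entries = data.frame(key = c("a", "b", "c"),
#'                                            count = c(5L, 3L, 2L)),
#'                       total_reads = 10L), class = "clonotype_table")
#' normalized_diversity(tab)  # 0.3
#' @export
normalized_diversity <- function(table) {
  if (nrow(table$entries) == 0L || table$total_reads < 1L) {
    stop("diversity is undefined for an empty repertoire")
  }
  nrow(table$entries) / table$total_reads
}

#' V-gene usage frequencies
#'
#' Fraction of clonotypes using each V gene (allele suffixes stripped). The
#' default weights every clonotype equally, so clonal expansion does not
#' inflate the usage of expanded clones' V genes; `read_weighted = TRUE`
#' weights clonotypes by read count instead.
#'
#' @param x a `clonotype_table`, or a data.frame of passing annotated records
#'   (collapsed to CDR3 amino-acid clonotypes first).
#' @param read_weighted logical.
#' @return Named numeric vector of frequencies summing to 1, decreasing.
#' @export
v_usage <- function(x, read_weighted = FALSE) {
  if (!inherits(x, "clonotype_table")) x <- build_clonotypes(x, "cdr3_aa")
  e <- x$entries
  if (nrow(e) == 0L) stop("no passing records: V usage undefined")
  w <- if (read_weighted) e$count else rep(1L, nrow(e))
  f <- tapply(w, v_gene(e$v_call), sum)
  f <- f / sum(f)
  sort(c(f), decreasing = TRUE)
}

#' Somatic-mutation summaries per V family and overall
#'
#' Means of the per-read V-region substitution counts. The default first
#' collapses reads to clonotypes (CDR3 amino-acid key) and averages the
#' per-clonotype means, so heavily expanded clones do not dominate the
#' repertoire average; `level = "read"` averages over reads directly.
#'
#' @param records annotated data.frame with `v_mutation_count`, `v_call` and
#'   `junction_aa`; non-passing records are excluded.
#' @param level `"clonotype"` (collapse first) or `"read"`.
#' @return List with `mutation_by_family` (named numeric) and
#'   `mean_mutations`.
#' @export
mutation_summary <- function(records, level = c("clonotype", "read")) {
  level <- match.arg(level)
  keep <- records[isTRUE_v(records$pass_filter), , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(list(mutation_by_family = numeric(0), mean_mutations = NaN))
  }
  if (level == "clonotype") {
    sp <- split(seq_len(nrow(keep)), keep$junction_aa)
    mut <- vapply(sp, function(i) mean(keep$v_mutation_count[i]), 0)
    fam <- vapply(sp, function(i) v_family(modal_value(keep$v_call[i])), "")
  } else {
    mut <- keep$v_mutation_count
    fam <- v_family(keep$v_call)
  }
  list(mutation_by_family = c(tapply(mut, fam, mean)),
       mean_mutations = mean(mut))
}

#' Per-repertoire summary profile
#'
#' @param records annotated data.frame for one repertoire.
#' @param mode clonotype definition for the diversity statistic.
#' @param repertoire_id identifier.
#' @return A `repertoire_profile`: list with `repertoire_id`, `mode`,
#'   `n_clonotypes`, `total_reads`, `dropped`, `normalized_diversity`,
#'   `v_usage`, `mutation_by_family`, `mean_mutations`.
#' @export
repertoire_profile <- function(records, mode = c("cdr3_aa", "vdj_nt"),
                               repertoire_id = NA_character_) {
  mode <- match.arg(mode)
  tab <- build_clonotypes(records, mode, repertoire_id)
  ms <- mutation_summary(records)
  structure(list(
    repertoire_id = repertoire_id, mode = mode,
    n_clonotypes = nrow(tab$entries), total_reads = tab$total_reads,
    dropped = tab$dropped,
    normalized_diversity = normalized_diversity(tab),
    v_usage = as.list(v_usage(tab)),
    mutation_by_family = as.list(ms$mutation_by_family),
    mean_mutations = ms$mean_mutations), class = "repertoire_profile")
}

#' Write / read a clonotype table as TSV
#'
#' The TSV carries one row per clonotype (`clonotype_key`, `count`,
#' `v_call`, `mean_mutations`); repertoire id, mode, read total and drop
#' tally travel in `#`-prefixed header comments.
#'
#' @param table a `clonotype_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_clonotypes <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# repertoire_id=%s mode=%s total_reads=%d dropped=%d",
                     table$repertoire_id, table$mode, table$total_reads,
                     table$dropped), con)
  e <- table$entries
  names(e)[names(e) == "key"] <- "clonotype_key"
  write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clonotypes
#' @export
read_clonotypes <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("(\\w+)=([^ ]+)", hdr))[[1]]
  kv <- do.call(rbind, strsplit(meta, "=", fixed = TRUE))
  meta <- setNames(kv[, 2], kv[, 1])
  e <- read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  names(e)[names(e) == "clonotype_key"] <- "key"
  structure(list(repertoire_id = unname(meta["repertoire_id"]),
                 mode = unname(meta["mode"]),
                 entries = e,
                 total_reads = as.integer(meta["total_reads"]),
                 dropped = as.integer(meta["dropped"])),
            class = "clonotype_table")
}
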