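#' Alignment scoring scheme
#'
#' Defaults: match +2, mismatch -2, gap open -6, gap extend -1 (a gap of
#' length L costs 6 + L), with a band of half-width 12 around the best
#' 11-mer seed diagonal; when read and segment share no seed k-mer the full
#' dynamic-programming matrix is used.
#'
#' @param match,mismatch,gap_open,gap_extend integer scores (penalties
#'   negative).
#' @param band_width band half-width in diagonals; `0` disables banding.
#' @param seed_k seed k-mer length for locating the band.
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2L, mismatch = -2L, gap_open = -6L,
                          gap_extend = -1L, band_width = 12L, seed_k = 11L) {
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 band_width = as.integer(band_width),
                 seed_k = as.integer(seed_k)),
            class = "align_scoring")
}

#' Locally align a read against one germline segment
#'
#' Banded local alignment (Gotoh affine gaps) of a read against a single
#' germline segment. Coordinates in the result are 0-based half-open.
#'
#' @param read nucleotide string.
#' @param segment a `germline_segment` or a plain nucleotide string.
#' @param scoring an [align_scoring()].
#' @return A `v_alignment`: list with `segment_name`, `score`, `valid`,
#'   `read_interval`, `germline_interval`, `cigar` (ops `=`/`X`/`I`/`D`),
#'   `substitution_read_pos`, `substitution_germline_pos`, `has_indel`.
#' @export
align_segment <- function(read, segment, scoring = align_scoring()) {
  seg_name <- NA_character_
  if (inherits(segment, "germline_segment")) {
    seg_name <- segment$name
    segment <- segment$sequence
  }
  a <- cpp_align_segment(toupper(read), toupper(segment),
                         scoring$match, scoring$mismatch,
                         -scoring$gap_open, -scoring$gap_extend,
                         scoring$band_width, scoring$seed_k)
  structure(list(
    segment_name = seg_name, score = a$score, valid = a$valid,
    read_interval = c(a$read_start, a$read_end),
    germline_interval = c(a$germline_start, a$germline_end),
    cigar = a$cigar,
    substitution_read_pos = a$substitution_read_pos,
    substitution_germline_pos = a$substitution_germline_pos,
    has_indel = a$has_indel), class = "v_alignment")
}

FAIL_REASONS <- c("no_v", "no_j", "anchor_unmapped", "unproductive_cdr3",
                  "short_read", "indel")

#' Annotate a batch of reads against a germline reference
#'
#' For each read: best-scoring V and J segments (ties broken by longer
#' aligned span, then lexicographic name), CDR3 extraction from the base
#' mapped to the V Cys-104 anchor through the end of the codon mapped to the
#' J Trp/Phe-118 anchor (both anchor codons included), and the count of
#' substitutions within the aligned V span up to the end of the anchor codon
#' (`v_mutation_count`; junction columns beyond the anchor belong to the
#' CDR3 and are excluded, and `v_aligned_length` reports the same window).
#' Reads that cannot be annotated
#' are not errors: `pass_filter` is set `FALSE` with a `fail_reason` code
#' (`no_v`, `no_j`, `anchor_unmapped`, `unproductive_cdr3`, `short_read`,
#' `indel`).
#'
#' @param sequences character vector of read nucleotide sequences.
#' @param reference a `germline_reference`.
#' @param scoring an [align_scoring()].
#' @param min_overlap reads shorter than this are flagged `short_read`.
#' @param v_min_len,j_min_len minimum aligned germline length to accept a
#'   V / J call.
#' @return A data.frame with columns `v_call`, `j_call`, `v_score`,
#'   `j_score`, `v_mutation_count`, `v_aligned_length`, `junction`,
#'   `junction_aa`, `vdj_nt`, `pass_filter`, `fail_reason`.
#' @export
annotate_sequences <- function(sequences, reference,
                               scoring = align_scoring(),
                               min_overlap = 30L,
                               v_min_len = 30L, j_min_len = 12L) {
  sequences <- toupper(sequences)
  # per-read annotation is a pure function of the sequence: compute once per
  # unique sequence (clonal reads are frequent) and expand
  uniq <- unique(sequences)
  if (length(uniq) < length(sequences)) {
    res <- annotate_sequences(uniq, reference, scoring, min_overlap,
                              v_min_len, j_min_len)
    out <- res[match(sequences, uniq), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  vs <- reference$v_segments
  js <- reference$j_segments
  b <- cpp_annotate_batch(
    sequences,
    names(vs), vapply(vs, `[[`, "", "sequence"),
    vapply(vs, `[[`, 0L, "anchor"),
    names(js), vapply(js, `[[`, "", "sequence"),
    vapply(js, `[[`, 0L, "anchor"),
    scoring$match, scoring$mismatch, -scoring$gap_open, -scoring$gap_extend,
    scoring$band_width, scoring$seed_k,
    as.integer(min_overlap), as.integer(v_min_len), as.integer(j_min_len))

  n <- length(sequences)
  junction <- rep("", n)
  ok <- !is.na(b$cdr3_start)
  junction[ok] <- substr(sequences[ok], b$cdr3_start[ok] + 1L, b$cdr3_end[ok])
  junction_aa <- safe_translate(junction)

  fail <- b$fail_code
  # productivity check on the extracted junction
  unprod <- ok & fail == 0L &
    (junction_aa == "" | !grepl("^C", junction_aa) |
       !grepl("[WF]$", junction_aa) | grepl("\\*", junction_aa, fixed = FALSE))
  fail[unprod] <- 4L

  vdj_nt <- rep("", n)
  pass <- fail == 0L
  vdj_nt[pass] <- substr(sequences[pass], b$vdj_start[pass] + 1L,
                         b$vdj_end[pass])

  data.frame(
    v_call = as.character(b$v_call), j_call = as.character(b$j_call),
    v_score = b$v_score, j_score = b$j_score,
    v_mutation_count = b$v_mutation_count,
    v_aligned_length = b$v_aligned_length,
    junction = ifelse(pass, junction, ""),
    junction_aa = ifelse(pass, junction_aa, ""),
    vdj_nt = vdj_nt,
    pass_filter = pass,
    fail_reason = ifelse(fail == 0L, "", FAIL_REASONS[pmax(fail, 1L)]),
    stringsAsFactors = FALSE)
}

#' Annotate one read
#'
#' Single-read convenience wrapper around [annotate_sequences()].
#'
#' @param read nucleotide string.
#' @inheritParams annotate_sequences
#' @return One-row data.frame as in [annotate_sequences()].
#' @export
annotate_read <- function(read, reference, scoring = align_scoring(), ...) {
  annotate_sequences(read, reference, scoring, ...)
}

AIRR_REQUIRED <- c("sequence_id", "sequence")

#' Annotate an AIRR Rearrangement TSV
#'
#' Reads an AIRR TSV, fills/replaces the annotation columns (`v_call`,
#' `j_call`, `junction`, `junction_aa`, `v_mutation_count`, `vdj_nt`,
#' `pass_filter`, `fail_reason`) and writes the result. Row order is
#' preserved; `d_call` and all metadata columns (`c_call`, `sample_id`,
#' `duplicate_count`, ...) are copied through unchanged, so the operation is
#' idempotent.
#'
#' @param airr_in,airr_out input and output TSV paths.
#' @inheritParams annotate_sequences
#' @return Invisibly, the annotated data.frame.
#' @export
annotate_file <- function(airr_in, airr_out, reference,
                          scoring = align_scoring(), ...) {
  df <- read_airr(airr_in)
  miss <- setdiff(AIRR_REQUIRED, names(df))
  if (length(miss)) {
    stop("missing mandatory AIRR column(s): ", paste(miss, collapse = ", "))
  }
  ann <- if (nrow(df)) {
    annotate_sequences(df$sequence, reference, scoring, ...)
  } else {
    annotate_sequences(character(0), reference, scoring, ...)
  }
  keep <- df[, setdiff(names(df), names(ann)), drop = FALSE]
  out <- cbind(keep, ann)
  # stable, AIRR-leading column order
  lead <- intersect(c("sequence_id", "sequence", "v_call", "d_call", "j_call",
                      "junction", "junction_aa", "c_call", "duplicate_count",
                      "sample_id"), names(out))
  out <- out[, c(lead, setdiff(names(out), lead)), drop = FALSE]
  data.table::fwrite(out, airr_out, sep = "\t", quote = FALSE)
  invisible(out)
}

#' Read an AIRR Rearrangement TSV
#' @param path TSV path.
#' @return data.frame (header-only files give zero rows).
#' @export
read_airr <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  data.table = FALSE, showProgress = FALSE))
}
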