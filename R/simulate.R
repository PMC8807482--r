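#' Cohort configuration for the repertoire simulator
#'
#' Builds the configuration object consumed by [simulate_cohort()]. The
#' defaults emulate a two-arm vaccination study read out at two time points
#' in three IgG subclasses: an RNA-adjuvanted-like arm (`rna_loaded`) with
#' high clonal richness, a flat clone-size distribution and IgG2b/IgG2c-
#' dominant class switch, and an adjuvant-free-like arm (`rna_free`) with
#' fewer clones, stronger clonal expansion and IgG1 dominance. Somatic
#' hypermutation load increases between the two time points. These are
#' simulator defaults expressing the qualitative study design, not measured
#' quantities.
#'
#' @param groups named list of per-group settings, each a list with
#'   `n_clones` (clones per sample), `zipf_exponent` (clone-size power-law
#'   exponent over clone ranks), `isotype_proportions` (named probabilities
#'   for IgG1/IgG2b/IgG2c, summing to 1) and `n_public` (number of public
#'   CDR3 clonotypes spiked into every sample of the group).
#' @param time_points character vector of time-point labels.
#' @param n_samples mice per group per time point.
#' @param reads_per_sample exact read budget per sample, split evenly across
#'   the sample's IgG-subclass amplicon libraries (each subclass is amplified
#'   with its own primers and sequenced to comparable depth; isotype
#'   abundance therefore shows in clone counts, not read depth).
#' @param shm_rate named per-base substitution probability per time point.
#' @param v_usage_bias named sampling weight per V segment name; `NULL` puts
#'   weight 0.6 on `IGHV1-7*01` and splits 0.4 over the remaining segments.
#' @param public_reads reads emitted per public clone per repertoire.
#' @param public_igg1_prob probability a public clone is also emitted in the
#'   IgG1 repertoire of a sample (it is always emitted in IgG2b and IgG2c).
#' @param seed integer seed; every draw in [simulate_cohort()] derives from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    groups = list(
      rna_loaded = list(n_clones = 800L, zipf_exponent = 1.1,
                        isotype_proportions = c(IgG1 = 0.25, IgG2b = 0.40, IgG2c = 0.35),
                        n_public = 48L),
      rna_free = list(n_clones = 300L, zipf_exponent = 1.9,
                      isotype_proportions = c(IgG1 = 0.60, IgG2b = 0.30, IgG2c = 0.10),
                      n_public = 12L)),
    time_points = c("d10", "d17"),
    n_samples = 2L,
    reads_per_sample = 2500L,
    shm_rate = c(d10 = 0.006, d17 = 0.015),
    v_usage_bias = NULL,
    public_reads = 3L,
    public_igg1_prob = 0.3,
    seed = 1L) {
  cfg <- structure(
    list(groups = groups, time_points = time_points,
         n_samples = as.integer(n_samples),
         reads_per_sample = as.integer(reads_per_sample),
         shm_rate = shm_rate, v_usage_bias = v_usage_bias,
         public_reads = as.integer(public_reads),
         public_igg1_prob = public_igg1_prob, seed = as.integer(seed)),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(length(cfg$groups) >= 1, cfg$n_samples >= 1,
            cfg$reads_per_sample >= 1, cfg$public_reads >= 1)
  if (!all(cfg$time_points %in% names(cfg$shm_rate))) {
    stop("shm_rate must be named for every time point")
  }
  if (any(cfg$shm_rate < 0 | cfg$shm_rate > 1)) stop("shm_rate must lie in [0, 1]")
  for (g in names(cfg$groups)) {
    gc <- cfg$groups[[g]]
    if (gc$n_clones < 1) stop("group ", g, ": n_clones must be positive")
    p <- gc$isotype_proportions
    if (abs(sum(p) - 1) > 1e-9) {
      stop("group ", g, ": isotype proportions must sum to 1")
    }
    if (any(p < 0)) stop("group ", g, ": negative isotype proportion")
  }
  if (!is.null(cfg$v_usage_bias) && any(cfg$v_usage_bias < 0)) {
    stop("v_usage_bias weights must be non-negative")
  }
  cfg
}

#' Junctional machinery tuning for the rearrangement simulator
#'
#' Trimming lengths follow bounded geometric laws (success probability
#' `trim_p`, upper bounds per segment end); untemplated N1/N2 insertion
#' lengths follow a bounded geometric with `insert_p`. Bounds keep the
#' CDR3-delimiting anchor codons intact and junction lengths realistic
#' (modal CDR3 near 10 amino acids).
#'
#' @param trim_p,insert_p geometric success probabilities.
#' @param max_v_trim,max_d_trim,max_j_trim,max_insert length bounds (nt).
#' @return List of tuning parameters for [simulate_rearrangement()].
#' @export
sim_params <- function(trim_p = 0.35, max_v_trim = 6L, max_d_trim = 5L,
                       max_j_trim = 6L, insert_p = 0.3, max_insert = 8L) {
  list(trim_p = trim_p, max_v_trim = as.integer(max_v_trim),
       max_d_trim = as.integer(max_d_trim), max_j_trim = as.integer(max_j_trim),
       insert_p = insert_p, max_insert = as.integer(max_insert))
}

bounded_geom <- function(p, max) min(stats::rgeom(1L, p), max)

rand_nt <- function(n) {
  if (n == 0L) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate one productive V(D)J rearrangement
#'
#' Draws V, D and J segments, exonuclease trimming lengths (bounded geometric)
#' and untemplated N1/N2 insertions (uniform nucleotides), assembles the
#' variable region and resamples until the junction is productive: CDR3
#' length divisible by 3, translation starting with C (Cys-104), ending with
#' W or F (Trp/Phe-118), and stop-free.
#'
#' @param reference a `germline_reference`.
#' @param v_weights optional named sampling weights over V segment names.
#' @param params junctional tuning from `sim_params()`.
#' @param max_attempts resampling bound before a simulation error is raised.
#' @return A `clone_genotype`: list with segment names, trims, insertions,
#'   `full_nt`, 0-based half-open `cdr3_start`/`cdr3_end`, `cdr3_nt`,
#'   `cdr3_aa` and `productive = TRUE`.
#' @export
simulate_rearrangement <- function(reference, v_weights = NULL,
                                   params = sim_params(), max_attempts = 1000L) {
  v_names <- names(reference$v_segments)
  if (is.null(v_weights)) {
    v_weights <- setNames(rep(1, length(v_names)), v_names)
  }
  v_weights <- v_weights[v_names]
  if (anyNA(v_weights)) stop("v_weights must cover every V segment")

  for (attempt in seq_len(max_attempts)) {
    v <- reference$v_segments[[sample(v_names, 1L, prob = v_weights)]]
    d <- reference$d_segments[[sample(names(reference$d_segments), 1L)]]
    j <- reference$j_segments[[sample(names(reference$j_segments), 1L)]]

    v_len <- nchar(v$sequence); d_len <- nchar(d$sequence); j_len <- nchar(j$sequence)
    # trimming never removes the anchor codons that delimit the CDR3
    v_trim <- bounded_geom(params$trim_p, min(params$max_v_trim, v_len - v$anchor - 3L))
    d_trim5 <- bounded_geom(params$trim_p, params$max_d_trim)
    d_trim3 <- bounded_geom(params$trim_p, min(params$max_d_trim, d_len - d_trim5))
    j_trim <- bounded_geom(params$trim_p, min(params$max_j_trim, j$anchor))
    n1 <- rand_nt(bounded_geom(params$insert_p, params$max_insert))
    n2 <- rand_nt(bounded_geom(params$insert_p, params$max_insert))

    v_part <- substr(v$sequence, 1L, v_len - v_trim)
    d_part <- if (d_trim5 + d_trim3 >= d_len) "" else
      substr(d$sequence, d_trim5 + 1L, d_len - d_trim3)
    j_part <- substr(j$sequence, j_trim + 1L, j_len)
    full <- paste0(v_part, n1, d_part, n2, j_part)

    cdr3_start <- v$anchor
    j_anchor_full <- nchar(v_part) + nchar(n1) + nchar(d_part) + nchar(n2) +
      (j$anchor - j_trim)
    cdr3_end <- j_anchor_full + 3L
    cdr3_nt <- substr(full, cdr3_start + 1L, cdr3_end)

    if (nchar(cdr3_nt) %% 3L != 0L) next
    aa <- translate_nt(cdr3_nt)
    if (!grepl("^C", aa) || !grepl("[WF]$", aa) || grepl("\\*", aa)) next

    return(structure(
      list(v_name = v$name, d_name = d$name, j_name = j$name,
           v_trim = v_trim, d_trim5 = d_trim5, d_trim3 = d_trim3,
           j_trim = j_trim, n1 = n1, n2 = n2,
           full_nt = full, cdr3_start = cdr3_start, cdr3_end = cdr3_end,
           cdr3_nt = cdr3_nt, cdr3_aa = aa, productive = TRUE),
      class = "clone_genotype"))
  }
  stop("no productive rearrangement in ", max_attempts,
       " attempts; check reference anchors")
}

#' Apply somatic hypermutation to a sequence
#'
#' Uniform substitution-only model: every position is independently mutated
#' with probability `shm_rate` to one of the three other bases, uniformly.
#'
#' @param nt_sequence nucleotide string.
#' @param shm_rate per-base substitution probability in `[0, 1]`.
#' @param protect optional integer vector of 0-based positions exempt from
#'   mutation (used to keep spiked public junctions literally public).
#' @return List with `sequence` (mutated string) and `positions` (sorted
#'   0-based substitution positions).
#' @export
apply_shm <- function(nt_sequence, shm_rate, protect = NULL) {
  if (length(shm_rate) != 1 || is.na(shm_rate) || shm_rate < 0 || shm_rate > 1) {
    stop("shm_rate must be a single probability in [0, 1]")
  }
  n <- nchar(nt_sequence)
  if (n == 0L) return(list(sequence = nt_sequence, positions = integer(0)))
  hit <- which(stats::runif(n) < shm_rate)
  if (!is.null(protect)) hit <- setdiff(hit, protect + 1L)
  if (length(hit) == 0L) {
    return(list(sequence = nt_sequence, positions = integer(0)))
  }
  chars <- strsplit(nt_sequence, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  }
  list(sequence = paste0(chars, collapse = ""),
       positions = sort(hit - 1L))
}

# deterministic reverse-translation table (one common codon per residue)
REV_CODON <- c(A = "GCC", R = "AGA", N = "AAC", D = "GAT", C = "TGT",
               Q = "CAG", E = "GAG", G = "GGT", H = "CAT", I = "ATC",
               L = "CTG", K = "AAG", M = "ATG", F = "TTT", P = "CCT",
               S = "AGC", T = "ACC", W = "TGG", Y = "TAT", V = "GTG")

reverse_translate <- function(aa) {
  codons <- REV_CODON[strsplit(aa, "", fixed = TRUE)[[1]]]
  if (anyNA(codons)) stop("cannot reverse-translate: ", aa)
  paste0(codons, collapse = "")
}

# Build n public clone definitions: fixed CDR3 aa strings (modal length 10)
# embedded in a germline V/J context. The junction keeps the V anchor codon,
# an untemplated reverse-translated middle, and the last two J codons before
# the anchor germline-encoded (convergent junctions retain J-encoded ends,
# which also keeps the J call decidable for these clones).
make_public_clones <- function(reference, n, v_weights) {
  if (n == 0L) return(list())
  aa_pool <- setdiff(names(REV_CODON), c("C", "W"))
  lens <- sample(c(9L, 10L, 11L, 12L, 13L), n, replace = TRUE,
                 prob = c(0.12, 0.58, 0.14, 0.10, 0.06))
  lapply(seq_len(n), function(i) {
    v <- reference$v_segments[[sample(names(reference$v_segments), 1L,
                                      prob = v_weights)]]
    j <- reference$j_segments[[sample(names(reference$j_segments), 1L)]]
    middle <- paste0(sample(aa_pool, lens[i] - 4L, replace = TRUE), collapse = "")
    j_take <- 6L  # germline prefix remnant ahead of the anchor codon
    full <- paste0(substr(v$sequence, 1L, v$anchor + 3L),
                   reverse_translate(middle),
                   substr(j$sequence, j$anchor - j_take + 1L, nchar(j$sequence)))
    cdr3_start <- v$anchor
    cdr3_end <- v$anchor + 3L + nchar(middle) * 3L + j_take + 3L
    cdr3_nt <- substr(full, cdr3_start + 1L, cdr3_end)
    list(public_id = sprintf("public_%02d", i),
         v_name = v$name, d_name = NA_character_, j_name = j$name,
         full_nt = full, cdr3_start = cdr3_start,
         cdr3_end = cdr3_end, cdr3_nt = cdr3_nt,
         cdr3_aa = translate_nt(cdr3_nt))
  })
}

default_v_bias <- function(reference, bias = NULL) {
  v_names <- names(reference$v_segments)
  if (!is.null(bias)) {
    w <- bias[v_names]
    if (anyNA(w)) stop("v_usage_bias must name every V segment")
    return(w / sum(w))
  }
  w <- setNames(rep(0.4 / (length(v_names) - 1L), length(v_names)), v_names)
  w["IGHV1-7*01"] <- 0.6
  w / sum(w)
}

#' Simulate a full cohort as AIRR files plus ground truth
#'
#' For every group x time point x mouse, draws `n_clones` rearrangements
#' (V choice proportional to the usage bias), assigns each clone an isotype,
#' and sequences each IgG subclass as its own library: the sample's read
#' budget is split evenly over its subclass libraries, within which clones
#' receive multinomial read counts with probabilities proportional to
#' `rank^-zipf_exponent`. Somatic hypermutation is applied once per clonal
#' lineage at the time point's rate (every read of a clone inherits its
#' lineage's mutations). The group's public CDR3 clonotypes are spiked into
#' every sample (always in IgG2b and IgG2c, in IgG1 with
#' `public_igg1_prob`), each with exactly `public_reads` reads taken out of
#' the library budget. Emitted rows per sample always total
#' `reads_per_sample` exactly (`duplicate_count` is fixed at 1: one AIRR row
#' is one read).
#'
#' Public clones keep their junction unmutated (hypermutation is applied to
#' the framework only); a mutated junction would be a different clonotype,
#' which would defeat the purpose of a spiked public clonotype.
#'
#' @param config a [cohort_config()].
#' @param reference a `germline_reference`.
#' @param out_dir output directory; AIRR TSVs are written under
#'   `out_dir/airr/`, plus `truth.tsv`, `sample_sheet.tsv` and
#'   `public_cdr3.tsv`.
#' @return Invisibly, a list with `airr_files`, `truth_file`,
#'   `sample_sheet_file`, `public_file`, `sample_sheet` (data.frame) and
#'   `public_cdr3` (per-group character vectors).
#' @export
simulate_cohort <- function(config, reference, out_dir) {
  config <- validate_cohort_config(config)
  set.seed(config$seed)
  airr_dir <- file.path(out_dir, "airr")
  dir.create(airr_dir, recursive = TRUE, showWarnings = FALSE)

  v_weights <- default_v_bias(reference, config$v_usage_bias)
  publics <- lapply(names(config$groups), function(g) {
    make_public_clones(reference, config$groups[[g]]$n_public, v_weights)
  })
  names(publics) <- names(config$groups)

  truth_rows <- list()
  airr_rows <- list()
  sheet_rows <- list()

  for (g in names(config$groups)) {
    gcfg <- config$groups[[g]]
    iso_names <- names(gcfg$isotype_proportions)
    for (tp in config$time_points) {
      rate <- config$shm_rate[[tp]]
      for (m in seq_len(config$n_samples)) {
        sample_id <- sprintf("%s_%s_m%d", g, tp, m)

        clones <- lapply(seq_len(gcfg$n_clones), function(i)
          simulate_rearrangement(reference, v_weights))
        iso <- sample(iso_names, gcfg$n_clones, replace = TRUE,
                      prob = gcfg$isotype_proportions)

        # public entries: always IgG2b + IgG2c, IgG1 with fixed probability
        pub_entries <- list()
        for (p in publics[[g]]) {
          isos <- c("IgG2b", "IgG2c",
                    if (stats::runif(1) < config$public_igg1_prob) "IgG1")
          isos <- intersect(isos, iso_names)
          for (pi in isos) pub_entries[[length(pub_entries) + 1L]] <-
              list(clone = p, isotype = pi)
        }
        # Each IgG subclass is amplified and sequenced as its own library
        # (subclass-specific primers), so read depth is comparable across
        # subclass libraries of a sample while isotype abundance shows in
        # clone counts. The sample's read budget is split evenly over the
        # subclass libraries that have any clone, exactly conserving
        # reads_per_sample.
        lib_isos <- iso_names[iso_names %in%
                                c(iso, vapply(pub_entries, `[[`, "", "isotype"))]
        n_lib <- length(lib_isos)
        lib_budget <- rep(config$reads_per_sample %/% n_lib, n_lib)
        rem <- config$reads_per_sample - sum(lib_budget)
        if (rem > 0) lib_budget[seq_len(rem)] <- lib_budget[seq_len(rem)] + 1L
        names(lib_budget) <- lib_isos

        w_all <- seq_len(gcfg$n_clones)^(-gcfg$zipf_exponent)
        entries <- list()
        for (iso_f in lib_isos) {
          pubs_here <- Filter(function(e) e$isotype == iso_f, pub_entries)
          n_pub_reads <- length(pubs_here) * config$public_reads
          budget <- lib_budget[[iso_f]]
          if (n_pub_reads >= budget) {
            stop("library read budget too small for public spike-ins in ",
                 sample_id, " ", iso_f)
          }
          members <- which(iso == iso_f)
          entries <- c(entries, lapply(pubs_here, function(e)
            list(clone = e$clone, isotype = iso_f,
                 n_reads = config$public_reads,
                 clone_id = paste0(sample_id, "_", e$clone$public_id),
                 is_public = TRUE)))
          if (length(members)) {
            counts <- as.integer(stats::rmultinom(
              1L, budget - n_pub_reads, w_all[members]))
            entries <- c(entries, lapply(which(counts > 0L), function(k)
              list(clone = clones[[members[k]]], isotype = iso_f,
                   n_reads = counts[k],
                   clone_id = sprintf("%s_C%04d", sample_id, members[k]),
                   is_public = FALSE)))
          } else if (budget > n_pub_reads && length(pubs_here)) {
            # no private clones in this library: the remainder tops up the
            # public entries round-robin so the budget stays exact
            extra <- budget - n_pub_reads
            base <- length(entries) - length(pubs_here)
            for (t in seq_len(extra)) {
              k <- base + 1L + (t - 1L) %% length(pubs_here)
              entries[[k]]$n_reads <- entries[[k]]$n_reads + 1L
            }
          }
        }
        idx <- rep(seq_along(entries),
                   vapply(entries, `[[`, 0L, "n_reads"))
        n_reads_total <- length(idx)

        # hypermutation accrues along each clonal lineage: one draw per clone
        # entry, inherited by all of the entry's reads (reads are amplicon
        # copies of cells from that lineage)
        ent_seq <- character(length(entries))
        ent_nmut <- integer(length(entries))
        ent_pos <- character(length(entries))
        ent_cdr3 <- character(length(entries))
        for (k in seq_along(entries)) {
          e <- entries[[k]]
          protect <- if (e$is_public)
            seq.int(e$clone$cdr3_start, e$clone$cdr3_end - 1L) else NULL
          mut <- apply_shm(e$clone$full_nt, rate, protect = protect)
          ent_seq[k] <- mut$sequence
          ent_nmut[k] <- length(mut$positions)
          ent_pos[k] <- paste(mut$positions, collapse = ",")
          ent_cdr3[k] <- substr(mut$sequence, e$clone$cdr3_start + 1L,
                                e$clone$cdr3_end)
        }
        seqs <- ent_seq[idx]
        n_mut <- ent_nmut[idx]
        mut_pos <- ent_pos[idx]
        read_cdr3 <- ent_cdr3[idx]
        fld <- function(f, what) vapply(entries, function(e) {
          v <- if (what == "entry") e[[f]] else e$clone[[f]]
          if (is.null(v) || is.na(v[1])) "" else as.character(v)
        }, "")[idx]

        sequence_id <- sprintf("%s_R%05d", sample_id, seq_len(n_reads_total))
        airr_df <- data.frame(
          sequence_id = sequence_id, sequence = seqs,
          v_call = fld("v_name", "clone"), d_call = fld("d_name", "clone"),
          j_call = fld("j_name", "clone"),
          junction = read_cdr3, junction_aa = safe_translate(read_cdr3),
          c_call = fld("isotype", "entry"), duplicate_count = 1L,
          sample_id = sample_id, stringsAsFactors = FALSE)
        truth_rows[[sample_id]] <- data.frame(
          sequence_id = sequence_id, sample_id = sample_id, group = g,
          time_point = tp, clone_id = fld("clone_id", "entry"),
          v_name = fld("v_name", "clone"), d_name = fld("d_name", "clone"),
          j_name = fld("j_name", "clone"),
          n_mutations = n_mut, mutation_positions = mut_pos,
          cdr3_nt = fld("cdr3_nt", "clone"), cdr3_aa = fld("cdr3_aa", "clone"),
          read_cdr3_nt = read_cdr3, isotype = fld("isotype", "entry"),
          is_public = vapply(entries, `[[`, TRUE, "is_public")[idx],
          stringsAsFactors = FALSE)

        for (iso_f in intersect(iso_names, unique(airr_df$c_call))) {
          f <- file.path(airr_dir, sprintf("%s_%s.tsv", sample_id, iso_f))
          sub <- airr_df[airr_df$c_call == iso_f, , drop = FALSE]
          data.table::fwrite(sub, f, sep = "\t", quote = FALSE)
          sheet_rows[[length(sheet_rows) + 1L]] <- data.frame(
            file = basename(f), sample_id = sample_id, group = g,
            time_point = tp, isotype = iso_f,
            repertoire_id = sprintf("%s_%s", sample_id, iso_f),
            n_reads = nrow(sub), stringsAsFactors = FALSE)
        }
      }
    }
  }

  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  sheet <- do.call(rbind, sheet_rows)
  truth_file <- file.path(out_dir, "truth.tsv")
  sheet_file <- file.path(out_dir, "sample_sheet.tsv")
  data.table::fwrite(truth, truth_file, sep = "\t", quote = FALSE)
  data.table::fwrite(sheet, sheet_file, sep = "\t", quote = FALSE)

  pub_df <- do.call(rbind, lapply(names(publics), function(g) {
    if (length(publics[[g]]) == 0) return(NULL)
    data.frame(group = g,
               public_id = vapply(publics[[g]], `[[`, "", "public_id"),
               cdr3_aa = vapply(publics[[g]], `[[`, "", "cdr3_aa"),
               v_name = vapply(publics[[g]], `[[`, "", "v_name"),
               j_name = vapply(publics[[g]], `[[`, "", "j_name"),
               stringsAsFactors = FALSE)
  }))
  public_file <- file.path(out_dir, "public_cdr3.tsv")
  if (is.null(pub_df)) {
    pub_df <- data.frame(group = character(0), public_id = character(0),
                         cdr3_aa = character(0), v_name = character(0),
                         j_name = character(0))
  }
  data.table::fwrite(pub_df, public_file, sep = "\t", quote = FALSE)

  invisible(list(
    airr_files = file.path(airr_dir, sheet$file),
    truth_file = truth_file, sample_sheet_file = sheet_file,
    public_file = public_file, sample_sheet = sheet,
    public_cdr3 = lapply(publics, function(ps) vapply(ps, `[[`, "", "cdr3_aa"))))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Read a cohort configuration from YAML or JSON
#'
#' The file may specify any subset of the [cohort_config()] arguments
#' (`groups`, `time_points`, `n_samples`, `reads_per_sample`, `shm_rate`,
#' `v_usage_bias`, `public_reads`, `public_igg1_prob`, `seed`); unspecified
#' fields keep their defaults. Named numeric blocks (isotype proportions,
#' hypermutation rates, usage bias) are converted to named vectors.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  simple <- c("time_points", "n_samples", "reads_per_sample",
              "public_reads", "public_igg1_prob", "seed")
  for (f in simple) if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  for (f in c("shm_rate", "v_usage_bias")) {
    if (!is.null(raw[[f]])) args[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$groups)) {
    args$groups <- lapply(raw$groups, function(g) {
      g$isotype_proportions <- unlist(g$isotype_proportions)
      g$n_clones <- as.integer(g$n_clones)
      g$n_public <- as.integer(g$n_public)
      g
    })
  }
  do.call(cohort_config, args)
}

# translation that tolerates frameshifted/empty junctions (truth bookkeeping)
safe_translate <- function(nt) {
  vapply(nt, function(x) {
    if (nchar(x) %% 3L != 0L || grepl("[^ACGT]", x)) return("")
    translate_nt(x)
  }, "", USE.NAMES = FALSE)
}
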