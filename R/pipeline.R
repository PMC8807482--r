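#' Pipeline run configuration
#'
#' @param mode `"simulate+analyze"` (run the cohort simulator, then analyze
#'   its output) or `"analyze-only"` (analyze existing AIRR TSVs).
#' @param out_dir output directory (created).
#' @param seed integer seed; in `"simulate+analyze"` mode it overrides the
#'   cohort config's seed so one value controls the whole run.
#' @param cohort a [cohort_config()] (simulate mode).
#' @param input_dir directory of AIRR TSVs (analyze-only mode).
#' @param sample_sheet TSV path with columns `file`, `sample_id`, `group`,
#'   `time_point`, `isotype` (analyze-only mode; the single source of sample
#'   metadata). `NULL` in simulate mode: the simulator writes one.
#' @param germline_fasta,germline_anchors germline reference paths; `NULL`
#'   uses the packaged synthetic mini-reference.
#' @param clonotype_modes clonotype definitions to run.
#' @param share_threshold,top_threshold sharing-spectrum thresholds.
#' @param tree_metric `"jaccard_distance"` or `"bray_curtis"`.
#' @param figures emit PNG figures when ggplot2 is installed.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("simulate+analyze", "analyze-only"),
                       out_dir, seed = 1L,
                       cohort = cohort_config(),
                       input_dir = NULL, sample_sheet = NULL,
                       germline_fasta = NULL, germline_anchors = NULL,
                       clonotype_modes = c("cdr3_aa", "vdj_nt"),
                       share_threshold = 2L, top_threshold = 7L,
                       tree_metric = "jaccard_distance",
                       figures = FALSE) {
  mode <- match.arg(mode)
  if (mode == "analyze-only") {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stop("analyze-only mode requires an existing input_dir")
    }
    if (!is.null(sample_sheet) && !file.exists(sample_sheet)) {
      stop("sample sheet not found: ", sample_sheet)
    }
  }
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 cohort = cohort, input_dir = input_dir,
                 sample_sheet = sample_sheet,
                 germline_fasta = germline_fasta,
                 germline_anchors = germline_anchors,
                 clonotype_modes = match.arg(clonotype_modes,
                                             c("cdr3_aa", "vdj_nt"),
                                             several.ok = TRUE),
                 share_threshold = as.integer(share_threshold),
                 top_threshold = as.integer(top_threshold),
                 tree_metric = tree_metric, figures = figures),
            class = "run_config")
}

#' Run the full repertoire pipeline
#'
#' Executes simulate (optional) -> annotate -> profile -> compare and writes
#' a manifest last. Every output is reproducible from (config, seed). On a
#' stage failure, partial outputs are retained next to a `FAILED` marker
#' naming the stage, and the error is re-raised.
#'
#' Outputs under `out_dir`: `sim/` (AIRR files, truth, sample sheet;
#' simulate mode), `annotated/`, `clonotypes/<mode>/`, `profiles.json`,
#' `comparison.json`, `distance_<metric>.tsv`, `tree.nwk`, `manifest.json`.
#'
#' @param config a [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  manifest <- list(config = config_echo(config),
                   package_version = as.character(utils::packageVersion("bcrpipe")),
                   stages = list())
  written <- character(0)

  result <- tryCatch({
    gl <- if (is.null(config$germline_fasta)) germline_default_paths() else
      c(fasta = config$germline_fasta, anchors = config$germline_anchors)
    reference <- load_germline(gl[["fasta"]], gl[["anchors"]])

    # ---- stage: simulate (or locate inputs) ----
    if (config$mode == "simulate+analyze") {
      stage <- "simulate"
      cohort <- config$cohort
      cohort$seed <- config$seed
      sim <- simulate_cohort(cohort, reference, file.path(out, "sim"))
      sheet <- sim$sample_sheet
      airr_files <- sim$airr_files
      written <- c(written, sim$airr_files, sim$truth_file,
                   sim$sample_sheet_file, sim$public_file)
      manifest$stages$simulate <- list(
        n_files = length(airr_files), n_reads = sum(sheet$n_reads))
    } else {
      stage <- "load-inputs"
      if (!is.null(config$sample_sheet)) {
        sheet <- read.delim(config$sample_sheet, stringsAsFactors = FALSE)
        need <- c("file", "sample_id", "group", "time_point", "isotype")
        miss <- setdiff(need, names(sheet))
        if (length(miss)) stop("sample sheet missing column(s): ",
                               paste(miss, collapse = ", "))
      } else {
        files <- list.files(config$input_dir, pattern = "\\.tsv$")
        if (!length(files)) stop("no AIRR TSV files in ", config$input_dir)
        sheet <- data.frame(file = files,
                            sample_id = sub("\\.tsv$", "", files),
                            group = "all", time_point = "all",
                            isotype = "all", stringsAsFactors = FALSE)
      }
      if (is.null(sheet$repertoire_id)) {
        sheet$repertoire_id <- sub("\\.tsv$", "", sheet$file)
      }
      airr_files <- file.path(config$input_dir, sheet$file)
    }

    # ---- stage: annotate ----
    stage <- "annotate"
    ann_dir <- file.path(out, "annotated")
    dir.create(ann_dir, showWarnings = FALSE)
    ann <- setNames(vector("list", nrow(sheet)), sheet$repertoire_id)
    n_in <- n_pass <- integer(nrow(sheet))
    for (i in seq_len(nrow(sheet))) {
      f_out <- file.path(ann_dir, sheet$file[i])
      a <- annotate_file(airr_files[i], f_out, reference)
      ann[[i]] <- a
      n_in[i] <- nrow(a)
      n_pass[i] <- sum(a$pass_filter)
      written <- c(written, f_out)
    }
    manifest$stages$annotate <- list(
      n_reads_in = sum(n_in), n_pass = sum(n_pass),
      n_dropped = sum(n_in) - sum(n_pass))
    if (config$mode == "simulate+analyze" &&
        sum(n_in) != manifest$stages$simulate$n_reads) {
      stop("row-count mismatch between simulate and annotate stages")
    }

    # ---- stage: profile ----
    stage <- "profile"
    tables <- list()
    profiles <- list()
    for (mode in config$clonotype_modes) {
      cdir <- file.path(out, "clonotypes", mode)
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      tables[[mode]] <- lapply(seq_len(nrow(sheet)), function(i) {
        tab <- build_clonotypes(ann[[i]], mode, sheet$repertoire_id[i])
        f <- file.path(cdir, paste0(sheet$repertoire_id[i], ".tsv"))
        write_clonotypes(tab, f)
        written <<- c(written, f)
        tab
      })
      names(tables[[mode]]) <- sheet$repertoire_id
      profiles[[mode]] <- lapply(seq_len(nrow(sheet)), function(i)
        repertoire_profile(ann[[i]], mode, sheet$repertoire_id[i]))
      names(profiles[[mode]]) <- sheet$repertoire_id
    }
    for (mode in config$clonotype_modes) {
      bad <- vapply(seq_len(nrow(sheet)), function(i) {
        tab <- tables[[mode]][[i]]
        sum(tab$entries$count) + tab$dropped != n_in[i]
      }, TRUE)
      if (any(bad)) stop("clonotype count conservation violated")
    }
    pfile <- file.path(out, "profiles.json")
    jsonlite::write_json(lapply(profiles, function(pp) lapply(pp, unclass)),
                         pfile, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, pfile)
    manifest$stages$profile <- list(
      modes = config$clonotype_modes,
      n_clonotypes = lapply(tables, function(tt)
        setNames(vapply(tt, function(t) nrow(t$entries), 0L), names(tt))))

    # ---- stage: compare ----
    stage <- "compare"
    cdr3_tables <- tables[["cdr3_aa"]]
    if (is.null(cdr3_tables)) {
      cdr3_tables <- lapply(seq_len(nrow(sheet)), function(i)
        build_clonotypes(ann[[i]], "cdr3_aa", sheet$repertoire_id[i]))
      names(cdr3_tables) <- sheet$repertoire_id
    }
    cmp <- if (nrow(sheet) < 2) NULL else
      compare_repertoires(cdr3_tables, sheet,
                               share_threshold = config$share_threshold,
                               top_threshold = config$top_threshold,
                               tree_metric = config$tree_metric)
    if (!is.null(cmp)) {
      cfile <- file.path(out, "comparison.json")
      jsonlite::write_json(comparison_as_json(cmp), cfile, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      dfile <- file.path(out, paste0("distance_", config$tree_metric, ".tsv"))
      write.table(cmp$distance_matrix, dfile, sep = "\t", quote = FALSE)
      tfile <- file.path(out, "tree.nwk")
      writeLines(cmp$tree$newick, tfile)
      written <- c(written, cfile, dfile, tfile)
      manifest$stages$compare <- list(
        universe_size = cmp$sharing_all$universe_size,
        pct_shared = cmp$sharing_all$pct_shared,
        n_top_shared = length(cmp$sharing_all$top_shared))
    } else {
      manifest$stages$compare <- list(skipped = "fewer than 2 repertoires")
    }

    if (isTRUE(config$figures) && !is.null(cmp) &&
        requireNamespace("ggplot2", quietly = TRUE)) {
      stage <- "figures"
      fdir <- file.path(out, "figures")
      dir.create(fdir, showWarnings = FALSE)
      # figures are presentation-only and excluded from the checksum ledger
      pipeline_figures(profiles, cmp, sheet, fdir)
    }

    # ---- manifest, written last ----
    stage <- "manifest"
    sums <- tools::md5sum(written)
    manifest$checksums <- setNames(as.list(unname(sums)),
                                   sub(paste0("^", out, "/?"), "", names(sums)))
    mfile <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, mfile, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    list(manifest = manifest, sheet = sheet, tables = tables,
         profiles = profiles, comparison = cmp)
  }, error = function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)),
               file.path(out, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

config_echo <- function(config) {
  ce <- unclass(config)
  ce$cohort <- if (!is.null(ce$cohort)) unclass(ce$cohort) else NULL
  ce
}

#' Cross-repertoire comparison bundle
#'
#' Computes, from per-repertoire CDR3 clonotype tables and a sample sheet:
#' the overall and per-group sharing spectra, the pairwise distance matrix
#' and UPGMA tree, per-group x time-point isotype Venn partitions, and the
#' plurality consensus of the top-shared CDR3s (modal length stratum).
#'
#' @param cdr3_tables named list of `clonotype_table` (mode `cdr3_aa`).
#' @param sheet sample sheet data.frame (`repertoire_id`, `group`,
#'   `time_point`, `isotype`).
#' @param share_threshold,top_threshold see [sharing_spectrum()].
#' @param tree_metric see [repertoire_distance()].
#' @return List with `sharing_all`, `sharing_by_group`, `distance_matrix`,
#'   `tree`, `venn`, `consensus`.
#' @export
compare_repertoires <- function(cdr3_tables, sheet, share_threshold = 2L,
                                top_threshold = 7L,
                                tree_metric = "jaccard_distance") {
  sets <- lapply(cdr3_tables, function(t) t$entries$key)
  sharing_all <- sharing_spectrum(sets, share_threshold, top_threshold)

  sharing_by_group <- list()
  for (g in unique(sheet$group)) {
    ids <- sheet$repertoire_id[sheet$group == g]
    if (length(ids) >= 2) {
      sharing_by_group[[g]] <- sharing_spectrum(sets[ids], share_threshold,
                                                top_threshold)
    }
  }

  dmat <- repertoire_distance(cdr3_tables, tree_metric)
  tree <- build_tree(dmat)

  venn <- list()
  for (g in unique(sheet$group)) {
    for (tp in unique(sheet$time_point[sheet$group == g])) {
      sub <- sheet[sheet$group == g & sheet$time_point == tp, , drop = FALSE]
      isos <- sort(unique(sub$isotype))
      if (length(isos) != 3L) next
      pooled <- lapply(isos, function(iso) unique(unlist(
        sets[sub$repertoire_id[sub$isotype == iso]], use.names = FALSE)))
      venn[[paste(g, tp, sep = "_")]] <-
        venn3(pooled[[1]], pooled[[2]], pooled[[3]], labels = isos)
    }
  }

  consensus <- NULL
  if (length(sharing_all$top_shared) >= 2) {
    stratum <- modal_length_stratum(sharing_all$top_shared)
    if (length(stratum) >= 2) consensus <- consensus_profile(stratum)
  }

  list(sharing_all = sharing_all, sharing_by_group = sharing_by_group,
       distance_matrix = dmat, tree = tree, venn = venn,
       consensus = consensus)
}

comparison_as_json <- function(cmp) {
  strip <- function(sr) list(
    n_repertoires = sr$n_repertoires, universe_size = sr$universe_size,
    shared_fraction_at_k = as.list(sr$shared_fraction_at_k),
    pct_shared = sr$pct_shared,
    pct_shared_per_repertoire = as.list(sr$pct_shared_per_repertoire),
    n_top_shared = length(sr$top_shared),
    top_shared = sr$top_shared,
    share_threshold = sr$share_threshold, top_threshold = sr$top_threshold)
  list(
    sharing_all = strip(cmp$sharing_all),
    sharing_by_group = lapply(cmp$sharing_by_group, strip),
    venn = lapply(cmp$venn, function(v) list(
      labels = v$labels, regions = as.list(v$regions),
      pairwise = as.list(v$pairwise), union_size = v$union_size)),
    consensus = if (is.null(cmp$consensus)) NULL else list(
      length = cmp$consensus$length,
      n_sequences = cmp$consensus$n_sequences,
      consensus = cmp$consensus$consensus,
      conservation = cmp$consensus$conservation),
    newick = cmp$tree$newick)
}

#' Import external clonotype exports
#'
#' Reads clonotype-level exports into `clonotype_table` objects. Two
#' dialects: `"airr_tsv"` (AIRR Rearrangement rows; clonotypes counted over
#' `junction_aa`, read counts from `duplicate_count` when present) and
#' `"mixcr_export_tsv"` (clone tables with `cloneCount`, `aaSeqCDR3` and
#' `allVHitsWithScore`-style columns). Repertoire ids are taken from file
#' names.
#'
#' @param path a file or a directory of TSV files.
#' @param dialect `"airr_tsv"` or `"mixcr_export_tsv"`.
#' @return Named list of `clonotype_table` (mode `cdr3_aa`).
#' @export
import_external_clonotypes <- function(path,
                                       dialect = c("airr_tsv",
                                                   "mixcr_export_tsv")) {
  dialect <- match.arg(dialect)
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(tsv|txt)$", full.names = TRUE)
  } else path
  if (!length(files)) stop("no TSV files found at ", path)

  tabs <- lapply(files, function(f) {
    df <- read_airr(f)
    id <- sub("\\.(tsv|txt)$", "", basename(f))
    if (dialect == "airr_tsv") {
      if (!all(c("junction_aa", "sequence_id") %in% names(df))) {
        stop("file ", basename(f), " lacks AIRR columns; expected at least: ",
             "sequence_id, junction_aa (got: ",
             paste(names(df), collapse = ", "), ")")
      }
      counts <- if ("duplicate_count" %in% names(df)) df$duplicate_count else
        rep(1L, nrow(df))
      keep <- nzchar(df$junction_aa) & !is.na(df$junction_aa)
      agg <- tapply(counts[keep], df$junction_aa[keep], sum)
      vc <- if ("v_call" %in% names(df)) {
        vapply(split(df$v_call[keep], df$junction_aa[keep]), modal_value, "")
      } else setNames(rep(NA_character_, length(agg)), names(agg))
      entries <- data.frame(key = names(agg), count = as.integer(agg),
                            v_call = unname(vc[names(agg)]),
                            mean_mutations = NA_real_, stringsAsFactors = FALSE)
    } else {
      if (!all(c("cloneCount", "aaSeqCDR3") %in% names(df))) {
        stop("file ", basename(f), " lacks MiXCR clone-table columns; ",
             "expected at least: cloneCount, aaSeqCDR3 (got: ",
             paste(names(df), collapse = ", "), ")")
      }
      vhits <- if ("allVHitsWithScore" %in% names(df)) {
        sub("\\(.*$", "", sub(",.*$", "", df$allVHitsWithScore))
      } else rep(NA_character_, nrow(df))
      entries <- data.frame(key = df$aaSeqCDR3,
                            count = as.integer(round(df$cloneCount)),
                            v_call = vhits, mean_mutations = NA_real_,
                            stringsAsFactors = FALSE)
    }
    entries <- entries[order(-entries$count, entries$key), , drop = FALSE]
    rownames(entries) <- NULL
    structure(list(repertoire_id = id, mode = "cdr3_aa", entries = entries,
                   total_reads = sum(entries$count), dropped = 0L),
              class = "clonotype_table")
  })
  names(tabs) <- vapply(tabs, `[[`, "", "repertoire_id")
  tabs
}
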