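#' Pipeline run configuration
#'
#' Bundles every threshold and switch of a full analysis run so that
#' a run is a pure function of (config, inputs). The config is
#' serialized into the output bundle for provenance.
#'
#' @param input Path to a contig file, or a [contig_table()] already
#'   in memory.
#' @param format Input dialect, `"10x"` or `"airr"` (ignored when
#'   `input` is a contig table).
#' @param metadata Path to a per-cell metadata table, or a data
#'   frame, or `NULL` if the contig table is already joined.
#' @param out_dir Output directory for the report bundle.
#' @param filter A [filter_config()].
#' @param clone_mode Clone identity: `"nt"`, `"aa"` or `"v_cdr3"`.
#' @param alpha Significance threshold for post hoc tests and the
#'   cluster screen.
#' @param fold_threshold Fold-change threshold of the cluster screen.
#' @param screen_subset Subset the cluster screen runs in (default
#'   `"CD8"`, the compartment where dual expansion concentrates).
#' @param tissue_map Optional tissue vocabulary mapping passed to
#'   [attach_metadata()].
#' @param seed Seed recorded for any resampling step (the core
#'   pipeline is deterministic).
#' @return A `run_config` object.
#' @export
run_config <- function(input, format = c("10x", "airr"), metadata = NULL,
                       out_dir = "dualtcr_run", filter = filter_config(),
                       clone_mode = c("nt", "aa", "v_cdr3"),
                       alpha = 0.05, fold_threshold = 2,
                       screen_subset = "CD8", tissue_map = NULL,
                       seed = 1L) {
  format <- match.arg(format)
  clone_mode <- match.arg(clone_mode)
  stopifnot(alpha > 0, alpha < 1, fold_threshold >= 1)
  structure(list(input = input, format = format, metadata = metadata,
                 out_dir = out_dir, filter = filter,
                 clone_mode = clone_mode, alpha = alpha,
                 fold_threshold = fold_threshold,
                 screen_subset = screen_subset, tissue_map = tissue_map,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Plain-text config covering the same fields as [run_config()];
#' unknown keys are rejected so typos never silently fall back to
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("input", "format", "metadata", "out_dir", "filter",
             "clone_mode", "alpha", "fold_threshold", "screen_subset",
             "tissue_map", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$filter)) raw$filter <- do.call(filter_config, raw$filter)
  if (!is.null(raw$tissue_map)) raw$tissue_map <- unlist(raw$tissue_map)
  do.call(run_config, raw)
}

serialize_run_config <- function(config, path) {
  out <- config
  out$input <- if (is.character(out$input)) out$input else "<in-memory>"
  out$metadata <- if (is.null(out$metadata) || is.character(out$metadata))
    out$metadata else "<in-memory>"
  out$filter <- unclass(out$filter)
  out$tissue_map <- as.list(out$tissue_map)
  yaml::write_yaml(lapply(unclass(out), function(x)
    if (is.null(x)) NULL else x), path)
  invisible(path)
}

welch_gh_block <- function(sizes, strata_cols) {
  strata <- sizes |> distinct(dplyr::across(dplyr::all_of(strata_cols)))
  omnibus <- list()
  posthoc <- list()
  for (i in seq_len(nrow(strata))) {
    sel <- sizes
    for (col in strata_cols) {
      sel <- filter(sel, .data[[col]] == strata[[col]][i])
    }
    counts <- table(sel$class)
    usable <- names(counts)[counts >= 2]
    sel <- filter(sel, .data$class %in% usable)
    label <- paste(unlist(strata[i, ]), collapse = "/")
    if (length(usable) < 2 ||
        any(tapply(sel$size, droplevels(factor(sel$class)),
                   stats::var) == 0)) {
      omnibus[[i]] <- tibble(stratum = label, F = NA_real_,
                             df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                             k = length(usable), untestable = TRUE)
      next
    }
    w <- welch_anova(sel$size, as.character(sel$class))
    omnibus[[i]] <- dplyr::mutate(w, stratum = label, untestable = FALSE,
                                  .before = 1)
    gh <- games_howell(sel$size, as.character(sel$class))
    posthoc[[i]] <- dplyr::mutate(gh, stratum = label, .before = 1)
  }
  list(omnibus = dplyr::bind_rows(omnibus),
       posthoc = dplyr::bind_rows(posthoc))
}

#' Run the full dual TCR analysis pipeline
#'
#' Ingest, classify, clonotype, and test in one call, writing a
#' report bundle of plain TSV tables: the cell- and clone-level
#' allele-class partitions, unique clone counts per tissue
#' compartment, clone-size statistics with Welch ANOVA and
#' Games-Howell post hoc per tissue and per blood/tissue x CD4/CD8
#' stratum, the per-cluster fold-change screen, V-gene usage tables
#' for both loci, the dropped-secondary-allele diversity comparison,
#' the per-cell classification, a run log and a copy of the config.
#' Identical config and inputs yield byte-identical tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all computed objects (`profiles`,
#'   `clones`, `class_summary`, `clone_summary`, `table1`,
#'   `size_tests`, `subset_tests`, `screen`, `usage`, `diversity`).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  table <- config$input
  if (is.character(table)) {
    table <- switch(config$format,
                    "10x" = read_10x_contigs(table),
                    "airr" = read_airr_rearrangements(table))
  }
  stopifnot(inherits(table, "contig_table"))
  if (!is.null(config$metadata)) {
    table <- attach_metadata(table, config$metadata,
                             tissue_map = config$tissue_map)
  }
  log_msg("ingest: ", nrow(table$contigs), " contigs over ",
          dplyr::n_distinct(table$contigs$barcode), " barcodes")

  profiles <- build_cell_profiles(table, config$filter)
  class_summary <- summarize_classes(profiles)
  log_msg("classify: ",
          paste(class_summary$class, class_summary$n, collapse = ", "))

  ct <- tabulate_clones(profiles, mode = config$clone_mode)
  clone_summary <- summarize_clone_classes(ct)
  table1 <- clone_counts_by_stratum(ct)
  log_msg("clonotype: ", nrow(ct$clones), " unique clones")

  sizes_tissue <- clone_size_samples(ct, strata = "tissue")
  tissue_tests <- welch_gh_block(sizes_tissue, "tissue")

  sizes_subset <- clone_size_samples(ct, strata = c("compartment", "subset"))
  subset_tests <- welch_gh_block(sizes_subset, c("compartment", "subset"))

  screen_sizes <- clone_size_samples(ct, strata = c("subset", "cluster")) |>
    filter(.data$subset == config$screen_subset)
  screen <- dplyr::bind_rows(
    dplyr::mutate(cluster_screen(screen_sizes, dual_class = "DUAL_ALPHA",
                                 alpha = config$alpha,
                                 fold_threshold = config$fold_threshold),
                  dual_class = "DUAL_ALPHA", .before = 1),
    dplyr::mutate(cluster_screen(screen_sizes, dual_class = "DUAL_BETA",
                                 alpha = config$alpha,
                                 fold_threshold = config$fold_threshold),
                  dual_class = "DUAL_BETA", .before = 1)
  )
  log_msg("screen: ", sum(screen$flagged), " flagged cluster/class pairs")

  usage <- list(TRA = gene_usage_table(ct, "TRA"),
                TRB = gene_usage_table(ct, "TRB"))
  divcmp <- dual_drop_comparison(profiles, mode = config$clone_mode)
  log_msg("diversity: dropped/full richness ratio ",
          sprintf("%.4f", divcmp$ratio["richness"]))

  out <- function(name) file.path(config$out_dir, name)
  readr::write_tsv(class_summary, out("class_proportions.tsv"),
                   progress = FALSE)
  readr::write_tsv(clone_summary, out("clone_proportions.tsv"),
                   progress = FALSE)
  t1 <- as_tibble(table1, rownames = "class")
  readr::write_tsv(t1, out("clone_counts_by_tissue.tsv"), progress = FALSE)
  readr::write_tsv(tissue_tests$omnibus, out("clone_size_welch_tissue.tsv"),
                   progress = FALSE)
  readr::write_tsv(tissue_tests$posthoc,
                   out("clone_size_posthoc_tissue.tsv"), progress = FALSE)
  readr::write_tsv(subset_tests$omnibus, out("clone_size_welch_subset.tsv"),
                   progress = FALSE)
  readr::write_tsv(subset_tests$posthoc,
                   out("clone_size_posthoc_subset.tsv"), progress = FALSE)
  readr::write_tsv(screen, out("cluster_screen.tsv"), progress = FALSE)
  readr::write_tsv(usage$TRA, out("usage_TRA.tsv"), progress = FALSE)
  readr::write_tsv(usage$TRB, out("usage_TRB.tsv"), progress = FALSE)
  readr::write_tsv(divcmp$comparison, out("diversity_dual_drop.tsv"),
                   progress = FALSE)
  write_classification_tsv(profiles, out("cell_classification.tsv"))
  serialize_run_config(config, out("config.yaml"))
  writeLines(log_lines, out("run_log.txt"))

  invisible(list(profiles = profiles, clones = ct,
                 class_summary = class_summary,
                 clone_summary = clone_summary, table1 = table1,
                 size_tests = tissue_tests, subset_tests = subset_tests,
                 screen = screen, usage = usage, diversity = divcmp))
}
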