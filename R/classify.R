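#' Chain acceptance filter configuration
#'
#' Controls which contigs count as evidence for an expressed TCR
#' allele before cells are classified. The defaults reproduce the
#' strictest common convention: only productive (in-frame) chains,
#' any UMI support, and cells with more than two distinct chains at a
#' locus capped to the top two by UMI count.
#'
#' @param frame_policy `"productive_only"` (default) keeps only
#'   productive contigs; `"include_nonproductive"` also counts
#'   out-of-frame and pseudogene-containing transcripts, which are
#'   known to persist in expanded dual-alpha cells and in
#'   TRBV21-1-bearing rearrangements.
#' @param min_umis Minimum UMI count for a collapsed chain to be
#'   retained (default 1).
#' @param min_umi_fraction_of_top Minimum UMI count as a fraction of
#'   the most-supported chain at the same locus in the same cell
#'   (default 0, i.e. no relative filter). Raising this suppresses
#'   weakly supported secondary alleles.
#' @param max_chains_policy What to do with cells carrying three or
#'   more distinct chains at one locus: `"cap_at_two_by_umis"`
#'   (default) keeps the top two by UMIs (ties broken
#'   lexicographically on the CDR3 nucleotide sequence) so the class
#'   partition stays exhaustive; `"exclude_cell"` sends the whole cell
#'   to the excluded class.
#' @return A `filter_config` object.
#' @export
filter_config <- function(frame_policy = c("productive_only",
                                           "include_nonproductive"),
                          min_umis = 1L,
                          min_umi_fraction_of_top = 0,
                          max_chains_policy = c("cap_at_two_by_umis",
                                                "exclude_cell")) {
  frame_policy <- match.arg(frame_policy)
  max_chains_policy <- match.arg(max_chains_policy)
  stopifnot(length(min_umis) == 1, min_umis >= 0,
            length(min_umi_fraction_of_top) == 1,
            min_umi_fraction_of_top >= 0, min_umi_fraction_of_top <= 1)
  structure(list(frame_policy = frame_policy,
                 min_umis = as.integer(min_umis),
                 min_umi_fraction_of_top = min_umi_fraction_of_top,
                 max_chains_policy = max_chains_policy),
            class = "filter_config")
}

#' Classify cells from per-locus chain counts
#'
#' Vectorized allele-class assignment from the number of accepted
#' alpha- and beta-chains per cell (counts already capped at two per
#' locus). A cell with one chain of each locus is a conventional
#' single TCR cell; two alpha-chains with one beta is dual TCR-alpha;
#' one alpha with two betas is dual TCR-beta. Cells with two (or
#' more) chains at both loci are excluded, because they cannot be
#' distinguished from cell-capture doublets; cells missing either
#' locus are incomplete and never enter any denominator.
#'
#' @param n_alpha,n_beta Integer vectors of accepted chain counts.
#' @param excluded Optional logical vector forcing cells into the
#'   excluded class (used by the `"exclude_cell"` chain-cap policy).
#' @return A factor with levels `SINGLE`, `DUAL_ALPHA`, `DUAL_BETA`,
#'   `MULTI_BOTH_EXCLUDED`, `INCOMPLETE`.
#' @export
classify_counts <- function(n_alpha, n_beta, excluded = FALSE) {
  cls <- dplyr::case_when(
    excluded ~ "MULTI_BOTH_EXCLUDED",
    n_alpha == 0 | n_beta == 0 ~ "INCOMPLETE",
    n_alpha >= 2 & n_beta >= 2 ~ "MULTI_BOTH_EXCLUDED",
    n_alpha >= 2 ~ "DUAL_ALPHA",
    n_beta >= 2 ~ "DUAL_BETA",
    TRUE ~ "SINGLE"
  )
  factor(cls, levels = ALLELE_CLASSES)
}

#' Build per-cell chain profiles and allele classes
#'
#' Collapses duplicate contigs (same barcode, locus, V, J and CDR3
#' nucleotide sequence) by summing UMIs, applies the chain acceptance
#' filter, orders chains within each cell by descending UMIs (ties
#' broken lexicographically on CDR3), caps chains per locus according
#' to the configured policy, and classifies every cell.
#'
#' @param table A metadata-joined [contig_table()].
#' @param config A [filter_config()].
#' @return A `cell_profiles` object: list with `cells` (one row per
#'   barcode: chain counts, `class`, metadata columns), `chains` (the
#'   retained, ordered chains, `rank` 1 = primary) and `config`.
#' @export
build_cell_profiles <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "contig_table"),
            inherits(config, "filter_config"))
  x <- table$contigs
  # collapse identical transcripts observed as multiple contigs
  chains <- x |>
    group_by(.data$barcode, .data$locus, .data$v_gene, .data$j_gene,
             .data$cdr3_nt) |>
    summarise(
      cdr3_aa = .data$cdr3_aa[1],
      productive = any(.data$productive),
      umis = sum(.data$umis),
      .groups = "drop"
    )
  if (config$frame_policy == "productive_only") {
    chains <- filter(chains, .data$productive)
  }
  chains <- filter(chains, .data$umis >= config$min_umis)
  if (config$min_umi_fraction_of_top > 0) {
    chains <- chains |>
      group_by(.data$barcode, .data$locus) |>
      filter(.data$umis >= config$min_umi_fraction_of_top *
               max(.data$umis)) |>
      ungroup()
  }
  chains <- chains |>
    arrange(.data$barcode, .data$locus, dplyr::desc(.data$umis),
            .data$cdr3_nt) |>
    group_by(.data$barcode, .data$locus) |>
    mutate(rank = dplyr::row_number(), n_at_locus = dplyr::n()) |>
    ungroup()

  counts <- chains |>
    group_by(.data$barcode) |>
    summarise(
      n_alpha_raw = sum(.data$locus == "TRA"),
      n_beta_raw = sum(.data$locus == "TRB"),
      .groups = "drop"
    )
  # barcodes whose every contig was filtered out still exist as cells
  all_bc <- tibble(barcode = unique(x$barcode))
  cells <- all_bc |>
    left_join(counts, by = "barcode") |>
    mutate(
      n_alpha_raw = tidyr::replace_na(.data$n_alpha_raw, 0L),
      n_beta_raw = tidyr::replace_na(.data$n_beta_raw, 0L),
      n_alpha = pmin(.data$n_alpha_raw, 2L),
      n_beta = pmin(.data$n_beta_raw, 2L)
    )
  excluded <- if (config$max_chains_policy == "exclude_cell") {
    cells$n_alpha_raw > 2L | cells$n_beta_raw > 2L
  } else {
    FALSE
  }
  cells$class <- classify_counts(cells$n_alpha, cells$n_beta, excluded)
  if (!is.null(table$metadata)) {
    cells <- left_join(cells, table$metadata, by = "barcode")
  } else {
    cells$patient_id <- NA_character_
    cells$tissue <- NA_character_
    cells$subset <- NA_character_
    cells$cluster <- NA_character_
  }
  chains <- filter(chains, .data$rank <= 2L) |>
    select(-"n_at_locus")
  chains <- dplyr::arrange(chains, .data$barcode, .data$locus, .data$rank)
  cells <- dplyr::arrange(cells, .data$barcode)
  structure(list(cells = cells, chains = chains, config = config),
            class = "cell_profiles")
}

#' @export
print.cell_profiles <- function(x, ...) {
  cat("<cell_profiles> ", nrow(x$cells), " cells\n", sep = "")
  print(table(x$cells$class))
  invisible(x)
}

#' Summarize allele-class proportions
#'
#' Counts cells per allele class and computes fractions over the
#' "cells with TCRs" denominator: cells with at least one accepted
#' alpha- and one beta-chain. Incomplete cells are counted but never
#' enter the denominator; excluded multi-both cells do (they are
#' cells with TCRs whose origin is just ambiguous).
#'
#' @param profiles A [build_cell_profiles()] result.
#' @param by Optional character vector of metadata columns to
#'   stratify by (e.g. `"tissue"`).
#' @return A tibble with columns `class`, `n`, `fraction` (plus the
#'   `by` columns when stratified). `fraction` is `NA` for the
#'   incomplete class.
#' @export
summarize_classes <- function(profiles, by = NULL) {
  stopifnot(inherits(profiles, "cell_profiles"))
  cells <- profiles$cells
  if (nrow(cells) == 0) {
    warning("no cells to summarize", call. = FALSE)
    return(tibble(class = factor(ALLELE_CLASSES, ALLELE_CLASSES),
                  n = 0L, fraction = 0))
  }
  grp <- c(by, "class")
  out <- cells |>
    group_by(dplyr::across(dplyr::all_of(grp))) |>
    summarise(n = dplyr::n(), .groups = "drop") |>
    tidyr::complete(class = factor(ALLELE_CLASSES, ALLELE_CLASSES),
                    !!!rlang::syms(by %||% character()),
                    fill = list(n = 0L))
  out <- out |>
    group_by(dplyr::across(dplyr::all_of(by %||% character()))) |>
    mutate(
      denom = sum(.data$n[.data$class != "INCOMPLETE"]),
      fraction = ifelse(.data$class == "INCOMPLETE", NA_real_,
                        ifelse(.data$denom > 0, .data$n / .data$denom, 0))
    ) |>
    ungroup() |>
    select(-"denom")
  if (all(is.na(out$fraction) | out$fraction == 0) &&
      sum(out$n[out$class != "INCOMPLETE"]) == 0) {
    warning("all cells are incomplete (missing a chain at one locus); ",
            "class fractions are undefined", call. = FALSE)
  }
  out[, c(by, "class", "n", "fraction")]
}

#' Write the per-cell classification table
#'
#' Emits one row per cell with its class, chain counts, top-chain
#' descriptors for each locus and the joined metadata.
#'
#' @param profiles A [build_cell_profiles()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(profiles, path) {
  stopifnot(inherits(profiles, "cell_profiles"))
  ch <- profiles$chains |>
    mutate(slot = paste0(tolower(sub("TR", "", .data$locus)), .data$rank),
           descr = paste(.data$v_gene, .data$j_gene, .data$cdr3_nt,
                         .data$umis, sep = "|")) |>
    select("barcode", "slot", "descr") |>
    tidyr::pivot_wider(names_from = "slot", values_from = "descr",
                       names_prefix = "chain_")
  out <- profiles$cells |> left_join(ch, by = "barcode")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
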