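#' Canonical clonotype keys for classified cells
#'
#' Builds an order-independent clonotype identity from each cell's
#' full retained chain set. Every chain is rendered as
#' `"locus|v_gene|j_gene|cdr3"` and the cell's chains are
#' lexicographically sorted before concatenation, so two cells with
#' the same chain multiset always share a key regardless of contig
#' order or UMI counts, and a dual cell never shares a key with a
#' single cell (the chain counts differ).
#'
#' @param profiles A [build_cell_profiles()] result.
#' @param mode Clone identity resolution: `"nt"` (default) uses
#'   V + J + CDR3 nucleotide sequence; `"aa"` uses V + J + CDR3 amino
#'   acid sequence; `"v_cdr3"` uses V + CDR3 nucleotide only.
#' @param include_excluded Keep excluded multi-both cells? Default
#'   `FALSE` (they are outside the analysis); `TRUE` raises an error,
#'   reflecting that no defensible clone identity exists for possible
#'   doublets.
#' @return A tibble `barcode`, `class`, `clone_key` covering cells in
#'   the single / dual-alpha / dual-beta classes.
#' @export
clone_keys <- function(profiles, mode = c("nt", "aa", "v_cdr3"),
                       include_excluded = FALSE) {
  stopifnot(inherits(profiles, "cell_profiles"))
  mode <- match.arg(mode)
  if (isTRUE(include_excluded)) {
    stop("excluded multi-both cells cannot be assigned a clonotype: ",
         "they may be doublets", call. = FALSE)
  }
  keep <- profiles$cells |>
    filter(.data$class %in% c("SINGLE", "DUAL_ALPHA", "DUAL_BETA")) |>
    select("barcode", "class")
  ch <- profiles$chains |> semi_join(keep, by = "barcode")
  ch$chain_str <- switch(
    mode,
    nt = paste(ch$locus, ch$v_gene, ch$j_gene, ch$cdr3_nt, sep = "|"),
    aa = {
      if (anyNA(ch$cdr3_aa)) {
        stop("amino-acid clone keys requested but cdr3_aa is missing ",
             "for some chains", call. = FALSE)
      }
      paste(ch$locus, ch$v_gene, ch$j_gene, ch$cdr3_aa, sep = "|")
    },
    v_cdr3 = paste(ch$locus, ch$v_gene, ch$cdr3_nt, sep = "|")
  )
  keys <- ch |>
    group_by(.data$barcode) |>
    summarise(clone_key = paste(sort(.data$chain_str), collapse = ";"),
              .groups = "drop")
  left_join(keep, keys, by = "barcode")
}

#' Tabulate clonotypes with per-stratum cell counts
#'
#' Groups classified cells into clones and counts cells per clone in
#' total and within each tissue compartment, CD4/CD8 subset and the
#' patient set. One row per (clone key, allele class); because the key
#' encodes the full chain multiset, each key maps to exactly one
#' class.
#'
#' @inheritParams clone_keys
#' @return A `clone_table` object: list with `clones` (one row per
#'   clone), `cells` (per-cell key + metadata, the raw material for
#'   [clone_size_samples()]) and `mode`.
#' @export
tabulate_clones <- function(profiles, mode = c("nt", "aa", "v_cdr3")) {
  mode <- match.arg(mode)
  keys <- clone_keys(profiles, mode = mode)
  cells <- keys |>
    left_join(profiles$cells |>
                select("barcode", "patient_id", "tissue", "subset",
                       "cluster"),
              by = "barcode")
  clones <- cells |>
    group_by(.data$clone_key, .data$class) |>
    summarise(
      n_cells = dplyr::n(),
      n_P = sum(.data$tissue == "P", na.rm = TRUE),
      n_N = sum(.data$tissue == "N", na.rm = TRUE),
      n_T = sum(.data$tissue == "T", na.rm = TRUE),
      n_CD4 = sum(.data$subset == "CD4", na.rm = TRUE),
      n_CD8 = sum(.data$subset == "CD8", na.rm = TRUE),
      n_patients = dplyr::n_distinct(.data$patient_id),
      .groups = "drop"
    ) |>
    arrange(dplyr::desc(.data$n_cells), .data$clone_key)
  structure(list(clones = clones, cells = cells, mode = mode),
            class = "clone_table")
}

#' @export
print.clone_table <- function(x, ...) {
  cat("<clone_table> ", nrow(x$clones), " unique clones from ",
      nrow(x$cells), " cells (", x$mode, " identity)\n", sep = "")
  invisible(x)
}

#' Clone-level allele-class proportions
#'
#' Fraction of unique clones in each allele class (the clone-level
#' analogue of [summarize_classes()]).
#'
#' @param ct A [tabulate_clones()] result.
#' @return A tibble `class`, `n_clones`, `fraction`.
#' @export
summarize_clone_classes <- function(ct) {
  stopifnot(inherits(ct, "clone_table"))
  ct$clones |>
    group_by(.data$class) |>
    summarise(n_clones = dplyr::n(), .groups = "drop") |>
    mutate(fraction = .data$n_clones / sum(.data$n_clones))
}

#' Unique clone counts per allele class and tissue
#'
#' Counts distinct clones with at least one cell in each tissue
#' compartment, by class. A clone spanning compartments contributes to
#' each, so rows need not sum to the all-tissue unique totals.
#'
#' @param ct A [tabulate_clones()] result.
#' @return An integer matrix, classes x tissues (`P`, `N`, `T`).
#' @export
clone_counts_by_stratum <- function(ct) {
  stopifnot(inherits(ct, "clone_table"))
  classes <- c("SINGLE", "DUAL_ALPHA", "DUAL_BETA")
  m <- matrix(0L, nrow = length(classes), ncol = length(TISSUES),
              dimnames = list(classes, TISSUES))
  tab <- ct$cells |>
    filter(!is.na(.data$tissue)) |>
    distinct(.data$clone_key, .data$class, .data$tissue) |>
    dplyr::count(.data$class, .data$tissue)
  for (i in seq_len(nrow(tab))) {
    m[as.character(tab$class[i]), tab$tissue[i]] <- tab$n[i]
  }
  m
}

#' Within-stratum clone sizes
#'
#' Computes, for each requested stratum, the number of cells each
#' clone has inside that stratum (a clone's blood cells never inflate
#' its tumor clone size). These per-clone counts are the samples on
#' which clonal-expansion statistics are run.
#'
#' @param ct A [tabulate_clones()] result.
#' @param strata Character vector of grouping columns among
#'   `"tissue"`, `"subset"`, `"cluster"`, `"patient_id"`, or the
#'   derived `"compartment"` (`P` vs merged `NT` tissue).
#' @return A tibble with the strata columns, `class`, `clone_key` and
#'   `size`; cells with `NA` in any stratum column are dropped.
#' @export
clone_size_samples <- function(ct, strata = "tissue") {
  stopifnot(inherits(ct, "clone_table"))
  cells <- ct$cells
  if ("compartment" %in% strata) {
    cells$compartment <- ifelse(cells$tissue == "P", "P", "NT")
  }
  bad <- setdiff(strata, names(cells))
  if (length(bad) > 0) {
    stop("unknown strata column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cells <- tidyr::drop_na(cells, dplyr::all_of(strata))
  cells |>
    group_by(dplyr::across(dplyr::all_of(c(strata, "class", "clone_key")))) |>
    summarise(size = dplyr::n(), .groups = "drop")
}

#' Summarize clone-size samples per stratum and class
#'
#' Mean, variance and clone count per (stratum, class) group, with a
#' flag for groups too small to enter any variance-based test.
#'
#' @param samples Output of [clone_size_samples()].
#' @return A tibble with the strata columns, `class`, `n_clones`,
#'   `n_cells`, `mean_size`, `var_size`, `untestable` (fewer than two
#'   clones).
#' @export
summarize_clone_sizes <- function(samples) {
  strata <- setdiff(names(samples), c("class", "clone_key", "size"))
  samples |>
    group_by(dplyr::across(dplyr::all_of(c(strata, "class")))) |>
    summarise(
      n_clones = dplyr::n(),
      n_cells = sum(.data$size),
      mean_size = mean(.data$size),
      var_size = if (dplyr::n() > 1) stats::var(.data$size) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(untestable = .data$n_clones < 2)
}
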