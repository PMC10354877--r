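#' Repertoire diversity indices
#'
#' Richness, Shannon entropy (natural log), Gini-Simpson index and
#' normalized clonality for a vector of clone sizes. Clonality is
#' `1 - shannon / ln(richness)` (0 for a repertoire of one clone):
#' 0 means a perfectly even repertoire, 1 a monoclonal one.
#'
#' @param counts Numeric vector of per-clone cell counts, all >= 1.
#' @return A one-row tibble: `richness`, `shannon`, `simpson`,
#'   `clonality`.
#' @export
diversity_indices <- function(counts) {
  if (length(counts) == 0) {
    stop("cannot compute diversity of an empty repertoire", call. = FALSE)
  }
  if (any(counts < 1)) {
    stop("clone sizes must be >= 1", call. = FALSE)
  }
  p <- counts / sum(counts)
  shannon <- -sum(p * log(p))
  richness <- length(counts)
  tibble(
    richness = richness,
    shannon = shannon,
    simpson = 1 - sum(p^2),
    clonality = if (richness <= 1) 0 else 1 - shannon / log(richness)
  )
}

# Dropped-chain keying: within each full clone, keep only the
# primary chain per locus -- the chain with the highest UMI support
# summed over the clone's cells, ties broken lexicographically on the
# chain string. Aggregating the UMI vote over the clone (rather than
# per cell) makes the reduced key a deterministic function of the
# full key, so dropping secondary alleles merges clones and can only
# ever lower richness; a per-cell vote could split a clone whenever
# UMI ranks flip between its cells.
primary_chain_keys <- function(profiles, full_keys, mode = "nt") {
  ch <- profiles$chains |>
    inner_join(select(full_keys, "barcode", "clone_key"), by = "barcode")
  ch$chain_str <- switch(
    mode,
    nt = paste(ch$locus, ch$v_gene, ch$j_gene, ch$cdr3_nt, sep = "|"),
    aa = paste(ch$locus, ch$v_gene, ch$j_gene, ch$cdr3_aa, sep = "|"),
    v_cdr3 = paste(ch$locus, ch$v_gene, ch$cdr3_nt, sep = "|")
  )
  key_map <- ch |>
    group_by(.data$clone_key, .data$locus, .data$chain_str) |>
    summarise(total_umis = sum(.data$umis), .groups = "drop") |>
    group_by(.data$clone_key, .data$locus) |>
    arrange(dplyr::desc(.data$total_umis), .data$chain_str,
            .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    ungroup() |>
    group_by(.data$clone_key) |>
    summarise(dropped_key = paste(sort(.data$chain_str), collapse = ";"),
              .groups = "drop")
  full_keys |>
    left_join(key_map, by = "clone_key") |>
    transmute(barcode = .data$barcode, class = .data$class,
              clone_key = .data$dropped_key)
}

#' Diversity underestimation from discarding secondary alleles
#'
#' Quantifies how much repertoire diversity is lost when each cell is
#' reduced to its single most-supported chain per locus before
#' clonotyping -- the reduction most single-cell workflows apply
#' silently. Both keyings are computed on the same cell set, so every
#' difference is attributable to the dropped secondary chains. The
#' dropped keying merges clones (it maps full keys many-to-one), so
#' its richness can never exceed the full richness.
#'
#' @inheritParams clone_keys
#' @return A `dual_drop_comparison` object: list with `comparison`
#'   (two-row tibble, full vs dropped keying), `delta`
#'   (full - dropped per metric) and `ratio` (dropped / full).
#' @export
dual_drop_comparison <- function(profiles, mode = c("nt", "aa", "v_cdr3")) {
  stopifnot(inherits(profiles, "cell_profiles"))
  mode <- match.arg(mode)
  full_keys <- clone_keys(profiles, mode = mode)
  drop_keys <- primary_chain_keys(profiles, full_keys, mode = mode)
  if (nrow(full_keys) == 0) {
    stop("no classifiable cells: nothing to compare", call. = FALSE)
  }
  div_of <- function(keys) {
    diversity_indices(as.integer(table(keys$clone_key)))
  }
  full <- div_of(full_keys)
  dropped <- div_of(drop_keys)
  stopifnot(dropped$richness <= full$richness)
  comparison <- dplyr::bind_rows(
    dplyr::mutate(full, keying = "full", .before = 1),
    dplyr::mutate(dropped, keying = "dropped", .before = 1)
  )
  metrics <- c("richness", "shannon", "simpson", "clonality")
  f <- unlist(full[1, metrics])
  d <- unlist(dropped[1, metrics])
  structure(list(
    comparison = comparison,
    delta = f - d,
    ratio = d / f
  ), class = "dual_drop_comparison")
}

#' @export
print.dual_drop_comparison <- function(x, ...) {
  cat("<dual_drop_comparison>\n")
  print(as.data.frame(x$comparison))
  cat("richness retained after dropping secondary alleles: ",
      sprintf("%.1f%%", 100 * x$ratio["richness"]), "\n", sep = "")
  invisible(x)
}
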