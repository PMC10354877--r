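# Normalised contig schema shared by both input dialects.
CONTIG_COLS <- c("barcode", "contig_id", "locus", "v_gene", "j_gene",
                 "cdr3_nt", "cdr3_aa", "productive", "umis", "reads",
                 "sample_id")

#' Construct a normalized contig table
#'
#' Low-level constructor used by the readers and the simulator. Most
#' users will call [read_10x_contigs()] or [read_airr_rearrangements()]
#' instead. Validates the schema, checks that the declared locus agrees
#' with the V-gene prefix (TRAV/TRBV), and warns about productive CDR3
#' nucleotide sequences whose length is not a multiple of 3 (a known
#' annotation quirk in some upstream tools; such rows are kept).
#'
#' @param contigs A data frame with columns `barcode`, `contig_id`,
#'   `locus` (`"TRA"` or `"TRB"`), `v_gene`, `j_gene`, `cdr3_nt`,
#'   `productive` (logical), `umis` (non-negative integer); optionally
#'   `cdr3_aa`, `reads`, `sample_id`.
#' @param metadata Optional per-cell metadata tibble (see
#'   [attach_metadata()]), or `NULL`.
#' @param provenance A list recording where the data came from
#'   (dialect, path, drop counts).
#' @return An object of class `contig_table`: a list with elements
#'   `contigs` (tibble), `metadata` (tibble or `NULL`) and
#'   `provenance` (list).
#' @export
contig_table <- function(contigs, metadata = NULL, provenance = list()) {
  contigs <- as_tibble(contigs)
  if (!"cdr3_aa" %in% names(contigs)) contigs$cdr3_aa <- NA_character_
  if (!"reads" %in% names(contigs)) contigs$reads <- NA_integer_
  if (!"sample_id" %in% names(contigs)) contigs$sample_id <- "sample1"
  if (!"contig_id" %in% names(contigs)) {
    contigs$contig_id <- paste0(contigs$barcode, "_contig_",
                                seq_len(nrow(contigs)))
  }
  missing <- setdiff(CONTIG_COLS, names(contigs))
  if (length(missing) > 0) {
    stop("contig table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  contigs <- contigs[, CONTIG_COLS]
  bad_locus <- !contigs$locus %in% c("TRA", "TRB")
  if (any(bad_locus)) {
    stop("locus values outside {TRA, TRB}: ",
         paste(unique(contigs$locus[bad_locus]), collapse = ", "),
         call. = FALSE)
  }
  if (any(contigs$umis < 0, na.rm = TRUE)) {
    stop("negative UMI counts are not allowed", call. = FALSE)
  }
  # Locus must agree with the V-gene prefix when the prefix is informative.
  pref <- substr(contigs$v_gene, 1, 4)
  informative <- pref %in% c("TRAV", "TRBV")
  implied <- ifelse(pref == "TRAV", "TRA", "TRB")
  mismatch <- informative & implied != contigs$locus
  if (any(mismatch)) {
    stop(sum(mismatch), " contig(s) have a V gene whose prefix ",
         "contradicts the declared locus", call. = FALSE)
  }
  frame_odd <- contigs$productive & !is.na(contigs$cdr3_nt) &
    nchar(contigs$cdr3_nt) %% 3L != 0L
  if (any(frame_odd)) {
    warning(sum(frame_odd), " productive contig(s) have a CDR3 ",
            "nucleotide length not divisible by 3; kept as-is",
            call. = FALSE)
  }
  structure(list(contigs = contigs, metadata = metadata,
                 provenance = provenance),
            class = "contig_table")
}

#' @export
print.contig_table <- function(x, ...) {
  cat("<contig_table> ", nrow(x$contigs), " contigs over ",
      dplyr::n_distinct(x$contigs$barcode), " barcodes",
      if (!is.null(x$metadata)) paste0("; metadata for ",
                                       nrow(x$metadata), " cells"),
      "\n", sep = "")
  if (length(x$provenance) > 0) {
    cat("  source: ", x$provenance$dialect %||% "constructed",
        if (!is.null(x$provenance$path)) paste0(" (", x$provenance$path, ")"),
        "\n", sep = "")
  }
  invisible(x)
}

parse_flag <- function(x) {
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

parse_umis <- function(x, what = "umis") {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) & !(is.na(x) | x == ""))
  if (length(bad) > 0) {
    stop("unparseable ", what, " value at row ", bad[1], ": '",
         x[bad[1]], "'", call. = FALSE)
  }
  out
}

keep_tcr_loci <- function(df, locus_col) {
  keep <- df[[locus_col]] %in% c("TRA", "TRB")
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropped ", n_dropped,
            " contig(s) from non-alpha/beta loci (",
            paste(sort(unique(df[[locus_col]][!keep])), collapse = ", "),
            ")")
  }
  list(df = df[keep, , drop = FALSE], n_dropped = n_dropped)
}

#' Read a 10x Genomics filtered contig annotation CSV
#'
#' Parses the `filtered_contig_annotations.csv` dialect produced by
#' Cell Ranger into a normalized [contig_table()]. Only TRA/TRB
#' contigs are retained (other loci are dropped with a message); the
#' dialect's `"True"`/`"False"`/`"None"` productive vocabulary is
#' mapped to logical, with only `"True"` counting as productive.
#'
#' @param path Path to the CSV file.
#' @param require_cell Keep only rows with `is_cell` true (when the
#'   column is present). Default `TRUE`.
#' @param require_high_confidence Keep only rows with
#'   `high_confidence` true (when the column is present). Default
#'   `TRUE`.
#' @param sample_id Optional sample label. When supplied, barcodes are
#'   prefixed with `"<sample_id>_"` so that barcodes are globally
#'   unique across samples.
#' @return A [contig_table()].
#' @export
read_10x_contigs <- function(path, require_cell = TRUE,
                             require_high_confidence = TRUE,
                             sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  # cdr3 column naming varies slightly across Cell Ranger versions
  if (!"cdr3_nt" %in% names(raw) && "cdr3_nt_seq" %in% names(raw)) {
    raw$cdr3_nt <- raw$cdr3_nt_seq
  }
  required <- c("barcode", "chain", "v_gene", "j_gene", "cdr3_nt",
                "productive", "umis")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("10x contig file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n_in <- nrow(raw)
  if (require_cell && "is_cell" %in% names(raw)) {
    raw <- raw[parse_flag(raw$is_cell), , drop = FALSE]
  }
  if (require_high_confidence && "high_confidence" %in% names(raw)) {
    raw <- raw[parse_flag(raw$high_confidence), , drop = FALSE]
  }
  filt <- keep_tcr_loci(raw, "chain")
  raw <- filt$df
  barcode <- raw$barcode
  if (!is.null(sample_id)) barcode <- paste0(sample_id, "_", barcode)
  contigs <- tibble(
    barcode = barcode,
    contig_id = if ("contig_id" %in% names(raw)) raw$contig_id else
      paste0(barcode, "_contig_", seq_along(barcode)),
    locus = raw$chain,
    v_gene = raw$v_gene,
    j_gene = raw$j_gene,
    cdr3_nt = raw$cdr3_nt,
    cdr3_aa = if ("cdr3" %in% names(raw)) raw$cdr3 else NA_character_,
    # 10x vocabulary: "True" / "False" / "None"; only "True" is productive
    productive = raw$productive %in% c("True", "TRUE", "true"),
    umis = parse_umis(raw$umis),
    reads = if ("reads" %in% names(raw))
      suppressWarnings(as.integer(raw$reads)) else NA_integer_,
    sample_id = sample_id %||% "sample1"
  )
  contig_table(contigs, provenance = list(
    dialect = "10x", path = path, n_input_rows = n_in,
    n_non_tcr_dropped = filt$n_dropped))
}

#' Read an AIRR Rearrangement TSV
#'
#' Parses a single-cell AIRR Rearrangement file into a normalized
#' [contig_table()]. The file must carry `cell_id` (bulk AIRR files
#' without cell identity cannot be used for paired-chain analysis).
#' V/J calls are stripped of allele suffixes (`"TRAV1-2*01"` becomes
#' `"TRAV1-2"`): dual TCR analysis counts distinct rearranged gene
#' transcripts per cell, identified at gene resolution.
#'
#' @inheritParams read_10x_contigs
#' @return A [contig_table()].
#' @export
read_airr_rearrangements <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"cell_id" %in% names(raw)) {
    stop("AIRR file lacks the 'cell_id' field: single-cell pairing ",
         "is required (bulk rearrangement files are unusable here)",
         call. = FALSE)
  }
  required <- c("locus", "v_call", "j_call", "junction", "productive")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("AIRR file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  umi_col <- intersect(c("duplicate_count", "consensus_count"), names(raw))
  if (length(umi_col) == 0) {
    stop("AIRR file needs 'duplicate_count' or 'consensus_count'",
         call. = FALSE)
  }
  n_in <- nrow(raw)
  filt <- keep_tcr_loci(raw, "locus")
  raw <- filt$df
  barcode <- raw$cell_id
  if (!is.null(sample_id)) barcode <- paste0(sample_id, "_", barcode)
  contigs <- tibble(
    barcode = barcode,
    contig_id = if ("sequence_id" %in% names(raw)) raw$sequence_id else
      paste0(barcode, "_contig_", seq_along(barcode)),
    locus = raw$locus,
    v_gene = sub("\\*.*$", "", raw$v_call),
    j_gene = sub("\\*.*$", "", raw$j_call),
    cdr3_nt = raw$junction,
    cdr3_aa = if ("junction_aa" %in% names(raw)) raw$junction_aa else
      NA_character_,
    productive = parse_flag(raw$productive),
    umis = parse_umis(raw[[umi_col[1]]], what = umi_col[1]),
    reads = if ("reads" %in% names(raw))
      suppressWarnings(as.integer(raw$reads)) else NA_integer_,
    sample_id = if ("sample_id" %in% names(raw)) raw$sample_id else
      sample_id %||% "sample1"
  )
  contig_table(contigs, provenance = list(
    dialect = "airr", path = path, n_input_rows = n_in,
    n_non_tcr_dropped = filt$n_dropped))
}

#' Attach per-cell metadata to a contig table
#'
#' Joins a per-cell annotation table (patient, tissue compartment,
#' CD4/CD8 subset, phenotype cluster) onto a contig table by barcode.
#' Contigs whose barcode has no metadata row are retained but counted
#' and reported; downstream strata for those cells are `NA`.
#'
#' @param table A [contig_table()].
#' @param meta A data frame or path to a CSV/TSV file with a `barcode`
#'   column and optionally `patient_id`, `tissue`, `subset`, `cluster`.
#' @param tissue_map Optional named character vector mapping the file's
#'   tissue vocabulary onto the canonical `P` (peripheral blood),
#'   `N` (normal adjacent) and `T` (tumor) codes, e.g.
#'   `c(Tumor = "T", Blood = "P")`.
#' @return The contig table with `metadata` filled in and join counts
#'   recorded in `provenance`.
#' @export
attach_metadata <- function(table, meta, tissue_map = NULL) {
  stopifnot(inherits(table, "contig_table"))
  if (is.character(meta) && length(meta) == 1) {
    reader <- if (grepl("\\.csv$", meta)) readr::read_csv else readr::read_tsv
    meta <- reader(meta, col_types = readr::cols(.default = "c"),
                   progress = FALSE)
  }
  meta <- as_tibble(meta)
  if (!"barcode" %in% names(meta)) {
    stop("metadata must have a 'barcode' column", call. = FALSE)
  }
  for (col in c("patient_id", "tissue", "subset", "cluster")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  }
  meta <- meta[, c("barcode", "patient_id", "tissue", "subset", "cluster")]
  if (anyDuplicated(meta$barcode) > 0) {
    dedup <- dplyr::distinct(meta)
    if (anyDuplicated(dedup$barcode) > 0) {
      bad <- dedup$barcode[duplicated(dedup$barcode)][1]
      stop("conflicting duplicate metadata rows for barcode '", bad, "'",
           call. = FALSE)
    }
    meta <- dedup
  }
  if (!is.null(tissue_map)) {
    mapped <- unname(tissue_map[meta$tissue])
    meta$tissue <- ifelse(is.na(mapped), meta$tissue, mapped)
  }
  bad_tissue <- !is.na(meta$tissue) & !meta$tissue %in% TISSUES
  if (any(bad_tissue)) {
    stop("tissue values outside {P, N, T} after mapping: ",
         paste(unique(meta$tissue[bad_tissue]), collapse = ", "),
         call. = FALSE)
  }
  bcs <- unique(table$contigs$barcode)
  n_joined <- sum(bcs %in% meta$barcode)
  n_unjoined <- length(bcs) - n_joined
  if (n_unjoined > 0) {
    message(n_unjoined, " barcode(s) have contigs but no metadata; ",
            "retained with NA annotations")
  }
  table$metadata <- meta
  table$provenance$n_barcodes_joined <- n_joined
  table$provenance$n_barcodes_unjoined <- n_unjoined
  table
}

#' Write a contig table as AIRR-flavored TSV
#'
#' Serializes the normalized table using AIRR Rearrangement field
#' names (`cell_id`, `locus`, `v_call`, `junction`,
#' `duplicate_count`, ...), plus `reads` and `sample_id` as extension
#' fields so that [read_airr_rearrangements()] round-trips the content
#' exactly.
#'
#' @param table A [contig_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contigs_airr <- function(table, path) {
  stopifnot(inherits(table, "contig_table"))
  x <- table$contigs
  out <- tibble(
    cell_id = x$barcode,
    sequence_id = x$contig_id,
    locus = x$locus,
    v_call = x$v_gene,
    j_call = x$j_gene,
    junction = x$cdr3_nt,
    junction_aa = x$cdr3_aa,
    productive = ifelse(x$productive, "T", "F"),
    duplicate_count = x$umis,
    reads = x$reads,
    sample_id = x$sample_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a contig table as 10x-flavored CSV
#'
#' @inheritParams write_contigs_airr
#' @return `path`, invisibly.
#' @export
write_contigs_10x <- function(table, path) {
  stopifnot(inherits(table, "contig_table"))
  x <- table$contigs
  out <- tibble(
    barcode = x$barcode,
    is_cell = "True",
    contig_id = x$contig_id,
    high_confidence = "True",
    chain = x$locus,
    v_gene = x$v_gene,
    j_gene = x$j_gene,
    cdr3 = x$cdr3_aa,
    cdr3_nt = x$cdr3_nt,
    productive = ifelse(x$productive, "True", "False"),
    umis = x$umis,
    reads = x$reads
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
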