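# in-code fixture builders shared across test files

ch_a <- function(bc, v = "TRAV1-2", j = "TRAJ3", cdr3 = "TGTGCTGTGAGC",
                 umis = 5L, productive = TRUE) {
  tibble::tibble(barcode = bc, locus = "TRA", v_gene = v, j_gene = j,
                 cdr3_nt = cdr3, productive = productive,
                 umis = as.integer(umis))
}

ch_b <- function(bc, v = "TRBV2", j = "TRBJ1-1", cdr3 = "TGTGCCAGCAGC",
                 umis = 5L, productive = TRUE) {
  tibble::tibble(barcode = bc, locus = "TRB", v_gene = v, j_gene = j,
                 cdr3_nt = cdr3, productive = productive,
                 umis = as.integer(umis))
}

mk_meta <- function(bcs, tissue = "T", subset = "CD8", cluster = "c1",
                    patient = "p1") {
  tibble::tibble(barcode = bcs, patient_id = patient, tissue = tissue,
                 subset = subset, cluster = cluster)
}

mk_table <- function(..., meta = NULL) {
  contigs <- dplyr::bind_rows(...)
  if (is.null(meta)) meta <- mk_meta(unique(contigs$barcode))
  contig_table(contigs, metadata = meta)
}

# small 10x-dialect CSV written to a temp file
write_10x_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  header <- paste("barcode,is_cell,contig_id,high_confidence,chain",
                  "v_gene,j_gene,cdr3,cdr3_nt,productive,umis,reads",
                  sep = ",")
  writeLines(c(header, lines), path)
  path
}

# small AIRR-dialect TSV written to a temp file
write_airr_fixture <- function(lines, header = NULL) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  header <- header %||% paste("cell_id", "sequence_id", "locus", "v_call",
                              "j_call", "junction", "junction_aa",
                              "productive", "duplicate_count", sep = "\t")
  writeLines(c(header, lines), path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent re-implementation of the secondary-allele drop rule
# (plain base-R loops): full and dropped clone richness for a profile
drop_oracle_richness <- function(prof) {
  keys <- clone_keys(prof)
  ch <- merge(as.data.frame(prof$chains), as.data.frame(keys),
              by = "barcode")
  ch$str <- paste(ch$locus, ch$v_gene, ch$j_gene, ch$cdr3_nt, sep = "|")
  dropped <- vapply(unique(ch$clone_key), function(k) {
    sub <- ch[ch$clone_key == k, ]
    picks <- character(0)
    for (loc in unique(sub$locus)) {
      s2 <- sub[sub$locus == loc, ]
      tot <- tapply(s2$umis, s2$str, sum)
      best <- names(tot)[order(-tot, names(tot))][1]
      picks <- c(picks, best)
    }
    paste(sort(picks), collapse = ";")
  }, "")
  c(full = length(unique(ch$clone_key)),
    dropped = length(unique(dropped)))
}
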