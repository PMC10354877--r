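test_that("10x reader keeps TCR loci and maps the productive vocabulary", {
  path <- write_10x_fixture(c(
    "BC1-1,True,BC1-1_c1,True,TRA,TRAV1-2,TRAJ3,CAV,TGTGCTGTGAGC,True,5,80",
    "BC1-1,True,BC1-1_c2,True,TRB,TRBV2,TRBJ1-1,CAS,TGTGCCAGCAGC,None,3,50",
    "BC2-1,True,BC2-1_c1,True,IGH,IGHV1-2,IGHJ4,CAR,TGTGCGAGAGGG,True,7,90",
    "BC2-1,True,BC2-1_c2,True,TRA,TRAV2,TRAJ5,CAX,TGTGCTTTTAGC,False,2,30"
  ))
  tb <- suppressMessages(read_10x_contigs(path))
  expect_s3_class(tb, "contig_table")
  expect_equal(nrow(tb$contigs), 3L)       # IGH dropped
  expect_equal(tb$provenance$n_non_tcr_dropped, 1L)
  # dialect vocabulary: only "True" is productive
  expect_equal(tb$contigs$productive, c(TRUE, FALSE, FALSE))
  expect_equal(tb$contigs$umis, c(5L, 3L, 2L))
})

test_that("10x reader honors is_cell/high_confidence flags and sample prefixing", {
  path <- write_10x_fixture(c(
    "BC1-1,True,c1,True,TRA,TRAV1-2,TRAJ3,CAV,TGTGCTGTGAGC,True,5,80",
    "BC9-1,False,c2,True,TRA,TRAV2,TRAJ5,CAX,TGTGCTTTTAGC,True,4,60",
    "BC8-1,True,c3,False,TRB,TRBV2,TRBJ1-1,CAS,TGTGCCAGCAGC,True,4,60"
  ))
  tb <- suppressMessages(read_10x_contigs(path, sample_id = "s1"))
  expect_equal(nrow(tb$contigs), 1L)
  expect_equal(tb$contigs$barcode, "s1_BC1-1")
  tb2 <- suppressMessages(read_10x_contigs(path, require_cell = FALSE,
                                           require_high_confidence = FALSE))
  expect_equal(nrow(tb2$contigs), 3L)
})

test_that("empty 10x file with a valid header yields zero records", {
  path <- write_10x_fixture(character(0))
  tb <- read_10x_contigs(path)
  expect_equal(nrow(tb$contigs), 0L)
})

test_that("missing mandatory columns and unparseable UMIs are fatal", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("barcode,chain,j_gene,cdr3_nt,productive,umis",
               "BC1,TRA,TRAJ3,TGTGCTGTGAGC,True,5"), path)
  expect_error(read_10x_contigs(path), "v_gene")
  path2 <- write_10x_fixture(c(
    "BC1-1,True,c1,True,TRA,TRAV1-2,TRAJ3,CAV,TGTGCTGTGAGC,True,five,80"
  ))
  expect_error(suppressMessages(read_10x_contigs(path2)), "row 1")
})

test_that("AIRR reader strips allele suffixes and demands cell_id", {
  path <- write_airr_fixture(c(
    paste("CELL1", "r1", "TRA", "TRAV1-2*01", "TRAJ3*01", "TGTGCTGTGAGC",
          "CAVS", "T", "5", sep = "\t"),
    paste("CELL1", "r2", "TRB", "TRBV2*02", "TRBJ1-1*01", "TGTGCCAGCAGC",
          "CASS", "T", "3", sep = "\t"),
    paste("CELL2", "r3", "TRA", "TRAV2*01", "TRAJ5*01", "TGTGCTTTTAGC",
          "CAFS", "T", "2", sep = "\t"),
    paste("CELL2", "r4", "TRB", "TRBV9*01", "TRBJ2-7*01", "TGTGCCTTTAGC",
          "CAFT", "T", "4", sep = "\t")
  ))
  tb <- read_airr_rearrangements(path)
  expect_equal(nrow(tb$contigs), 4L)
  expect_equal(dplyr::n_distinct(tb$contigs$barcode), 2L)
  expect_equal(tb$contigs$v_gene[1], "TRAV1-2")
  expect_equal(tb$contigs$j_gene[1], "TRAJ3")
  # bulk files without cell identity are unusable
  no_cell <- write_airr_fixture(
    paste("r1", "TRA", "TRAV1-2*01", "TRAJ3*01", "TGTGCTGTGAGC", "CAVS",
          "T", "5", sep = "\t"),
    header = paste("sequence_id", "locus", "v_call", "j_call", "junction",
                   "junction_aa", "productive", "duplicate_count",
                   sep = "\t"))
  expect_error(read_airr_rearrangements(no_cell), "cell_id")
})

test_that("metadata join maps tissue vocabulary, flags unmatched barcodes, rejects conflicts", {
  tb <- mk_table(ch_a("BC1"), ch_b("BC1"), ch_a("BC2"), ch_b("BC2"),
                 ch_a("BC3"), ch_b("BC3"), meta = mk_meta("BC0"))
  meta <- tibble::tibble(barcode = c("BC1", "BC2"),
                         patient_id = "p1",
                         tissue = c("Tumor", "Blood"),
                         subset = "CD8", cluster = "c1")
  expect_message(
    joined <- attach_metadata(tb, meta,
                              tissue_map = c(Tumor = "T", Blood = "P")),
    "1 barcode")
  expect_equal(sort(joined$metadata$tissue), c("P", "T"))
  expect_equal(joined$provenance$n_barcodes_unjoined, 1L)
  # unmapped vocabulary is fatal, not silently passed through
  expect_error(attach_metadata(tb, meta), "Tumor")
  # conflicting duplicate rows are fatal
  dup <- dplyr::bind_rows(meta, dplyr::mutate(meta[1, ], tissue = "Spleen"))
  expect_error(
    attach_metadata(tb, dup, tissue_map = c(Tumor = "T", Blood = "P",
                                            Spleen = "N")),
    "conflicting")
})

test_that("locus must agree with the V-gene prefix", {
  expect_error(
    mk_table(tibble::tibble(barcode = "BC1", locus = "TRA",
                            v_gene = "TRBV2", j_gene = "TRAJ3",
                            cdr3_nt = "TGTGCTGTGAGC", productive = TRUE,
                            umis = 5L)),
    "prefix")
})

test_that("AIRR round-trip is record-identical and dialects agree downstream", {
  sim <- simulate_repertoire(sim_config(n_cells = 300, seed = 5))
  airr_path <- withr::local_tempfile(fileext = ".tsv")
  tenx_path <- withr::local_tempfile(fileext = ".csv")
  write_contigs_airr(sim$table, airr_path)
  write_contigs_10x(sim$table, tenx_path)
  back <- read_airr_rearrangements(airr_path)
  expect_equal(back$contigs, sim$table$contigs)
  # the same repertoire read through either dialect classifies identically
  ten <- read_10x_contigs(tenx_path)
  ten$metadata <- sim$table$metadata
  back$metadata <- sim$table$metadata
  p_airr <- build_cell_profiles(back)
  p_tenx <- build_cell_profiles(ten)
  expect_equal(p_airr$cells$class, p_tenx$cells$class)
  expect_equal(p_airr$chains[, c("barcode", "locus", "v_gene", "j_gene",
                                 "cdr3_nt", "umis", "rank")],
               p_tenx$chains[, c("barcode", "locus", "v_gene", "j_gene",
                                 "cdr3_nt", "umis", "rank")])
})

test_that("contig row order never changes downstream results", {
  sim <- simulate_repertoire(sim_config(n_cells = 400, seed = 9))
  shuffled <- sim$table
  set.seed(1)
  shuffled$contigs <- shuffled$contigs[sample(nrow(shuffled$contigs)), ]
  p1 <- build_cell_profiles(sim$table)
  p2 <- build_cell_profiles(shuffled)
  expect_equal(summarize_classes(p1), summarize_classes(p2))
  expect_equal(tabulate_clones(p1)$clones, tabulate_clones(p2)$clones)
})
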