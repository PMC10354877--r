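# Synthetic paired-chain repertoire generator. Emits contig tables in
# the same normalized form the readers produce, plus per-barcode
# ground truth, so classification, clonotyping, diversity and the
# expansion statistics can all be validated end-to-end without any
# external dataset.

default_v_usage <- function() {
  trav <- paste0("TRAV", c("1-1", "1-2", "2", "3", "4", "5", "6", "8-1",
                           "8-2", "8-3", "8-4", "8-6", "9-2", "10", "12-1",
                           "12-2", "12-3", "13-1", "13-2", "14", "16", "17",
                           "19", "20", "21", "22", "23", "24", "25", "26-1",
                           "26-2", "27", "29", "30", "34", "35", "36", "38-1",
                           "38-2", "39", "40", "41"))
  trbv <- c("TRBV2", "TRBV4-1", "TRBV5-1", "TRBV6-1", "TRBV6-5", "TRBV7-2",
            "TRBV7-9", "TRBV9", "TRBV10-3", "TRBV11-2", "TRBV12-3",
            "TRBV13", "TRBV14", "TRBV15", "TRBV16", "TRBV18", "TRBV19",
            "TRBV20-1", "TRBV21-1", "TRBV24-1", "TRBV25-1", "TRBV27",
            "TRBV28", "TRBV29-1", "TRBV30")
  w_a <- 1 / seq_along(trav)
  w_b <- 1 / seq_along(trbv)
  # the pseudogene is rare among conventionally annotated rearrangements
  w_b[trbv == "TRBV21-1"] <- 0.2 * min(w_b)
  list(TRA = setNames(w_a / sum(w_a), trav),
       TRB = setNames(w_b / sum(w_b), trbv))
}

default_clusters <- function() {
  list(
    CD4 = c("naive CD4" = 0.30, "Treg" = 0.20, "Tfh" = 0.15,
            "Th17" = 0.15, "GZMK+ Tem CD4" = 0.20),
    CD8 = c("naive CD8" = 0.15, "GZMK+ early Tem" = 0.25,
            "ZNF683+CXCR6+ Trm" = 0.20, "terminal Tex" = 0.20,
            "Temra" = 0.20)
  )
}

#' Simulator configuration
#'
#' Parameters of the synthetic paired-chain repertoire. The default
#' rates reproduce the observed cell-level partition of a large
#' pan-cancer T cell atlas: 9.3% dual-alpha cells, 3.2% dual-beta
#' cells and 1.7% unresolvable 2-alpha/2-beta barcodes treated as
#' doublets, with dual clones expanded about twofold in tissue
#' compartments relative to blood.
#'
#' @param n_cells Number of barcodes to emit.
#' @param tissue_mix Named fractions over compartments `P` (blood),
#'   `N` (normal adjacent), `T` (tumor); must sum to 1.
#' @param subset_mix Named fractions over `CD4` / `CD8`.
#' @param cluster_labels List with `CD4` and `CD8` named probability
#'   vectors of phenotype cluster labels.
#' @param dual_alpha_rate,dual_beta_rate,doublet_rate Fractions of
#'   emitted barcodes that are dual-alpha cells, dual-beta cells, and
#'   cell-capture doublets.
#' @param clone_size_law Clone-size distribution; currently
#'   `list(law = "geometric", prob = p)`: sizes are
#'   `1 + Geometric(p)` so the mean baseline clone size is `1/p`.
#' @param dual_expansion Named per-tissue multipliers applied to the
#'   mean clone size of dual clones (the clonal-expansion effect under
#'   study).
#' @param cd8_expansion Multiplier on mean clone size for CD8 clones
#'   of every class (CD8 cells are more expanded than CD4 overall).
#' @param cluster_expansion Optional named multipliers applied to dual
#'   clones in specific phenotype clusters (used to plant per-cluster
#'   expansion signals).
#' @param v_usage List with `TRA` and `TRB` named V-gene frequency
#'   vectors; defaults to a rank-skewed usage profile with the
#'   TRBV21-1 pseudogene rare.
#' @param pseudogene_skew Weight multiplier for TRBV21-1 when drawing
#'   the secondary beta-chain of dual-beta clones (default 10),
#'   emulating failed first rearrangements that stay transcribed.
#' @param shadow_rate Probability that a dual clone is accompanied by
#'   a "shadow" single-TCR clonotype carrying exactly its primary
#'   alpha- and beta-chain (default 0.25). This emulates
#'   secondary-allele capture dropout, which makes the same lineage
#'   appear in the data both as a dual clonotype and as the
#'   corresponding single clonotype; it is what makes dual-aware
#'   clonotyping genuinely richer than primary-chain-only
#'   clonotyping.
#' @param umi_law List with `primary` and `secondary` Poisson means;
#'   a chain's UMI count is `1 + Poisson(mean)`, with secondary
#'   chains drawn lower than primary ones.
#' @param n_patients Number of patients to spread clones over.
#' @param seed Integer seed; the whole simulation is deterministic
#'   given the config.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_cells = 20000,
                       tissue_mix = c(P = 0.25, N = 0.35, T = 0.40),
                       subset_mix = c(CD4 = 0.55, CD8 = 0.45),
                       cluster_labels = default_clusters(),
                       dual_alpha_rate = 0.093,
                       dual_beta_rate = 0.032,
                       doublet_rate = 0.017,
                       clone_size_law = list(law = "geometric", prob = 0.65),
                       dual_expansion = c(P = 1, N = 2, T = 2),
                       cd8_expansion = 1.5,
                       cluster_expansion = NULL,
                       v_usage = default_v_usage(),
                       pseudogene_skew = 10,
                       shadow_rate = 0.25,
                       umi_law = list(primary = 3, secondary = 1),
                       n_patients = 8,
                       seed = 1L) {
  rates <- c(dual_alpha_rate, dual_beta_rate, doublet_rate)
  if (any(rates < 0 | rates > 1) || sum(rates) >= 1) {
    stop("class rates must lie in [0,1] and sum to < 1", call. = FALSE)
  }
  for (mix in list(tissue_mix, subset_mix)) {
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
      stop("inconsistent mix: fractions must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  if (!setequal(names(tissue_mix), TISSUES)) {
    stop("tissue_mix must be named over P, N, T", call. = FALSE)
  }
  stopifnot(clone_size_law$law == "geometric",
            clone_size_law$prob > 0, clone_size_law$prob <= 1,
            all(dual_expansion >= 1), cd8_expansion >= 1,
            shadow_rate >= 0, shadow_rate <= 1,
            umi_law$primary >= umi_law$secondary)
  structure(list(
    n_cells = as.integer(n_cells), tissue_mix = tissue_mix,
    subset_mix = subset_mix, cluster_labels = cluster_labels,
    dual_alpha_rate = dual_alpha_rate, dual_beta_rate = dual_beta_rate,
    doublet_rate = doublet_rate, clone_size_law = clone_size_law,
    dual_expansion = dual_expansion, cd8_expansion = cd8_expansion,
    cluster_expansion = cluster_expansion, v_usage = v_usage,
    pseudogene_skew = pseudogene_skew, shadow_rate = shadow_rate,
    umi_law = umi_law,
    n_patients = as.integer(n_patients), seed = as.integer(seed)
  ), class = "sim_config")
}

# random in-frame CDR3 nucleotide strings (27-45 nt, multiple of 3);
# sequence content is irrelevant downstream, identity is what matters
random_cdr3 <- function(n) {
  if (n == 0) return(character(0))
  len <- 3L * sample(9:15, n, replace = TRUE)
  chars <- sample(c("A", "C", "G", "T"), sum(len), replace = TRUE)
  s <- paste(chars, collapse = "")
  end <- cumsum(len)
  substring(s, end - len + 1L, end)
}

# draw clone sizes for one (class, tissue, subset) stratum until the
# stratum's cell budget M is covered; the boundary clone is kept whole
# (truncating it would size-bias the realized clone-size law and drag
# mean clone sizes below their configured expectation in small strata)
draw_stratum_clones <- function(M, class, tissue, subset, cfg) {
  if (M <= 0) return(NULL)
  probs <- cfg$cluster_labels[[subset]]
  base_p <- cfg$clone_size_law$prob
  sizes <- integer(0)
  clusters <- character(0)
  while (sum(sizes) < M) {
    b <- max(16L, ceiling((M - sum(sizes)) * base_p))
    cl <- sample(names(probs), b, replace = TRUE, prob = probs)
    mult <- rep(1, b)
    if (class != "SINGLE") {
      mult <- mult * cfg$dual_expansion[[tissue]]
      if (!is.null(cfg$cluster_expansion)) {
        extra <- cfg$cluster_expansion[cl]
        extra[is.na(extra)] <- 1
        mult <- mult * unname(extra)
      }
    }
    if (subset == "CD8") mult <- mult * cfg$cd8_expansion
    p_eff <- pmin(1, base_p / mult)
    sizes <- c(sizes, rgeom(b, p_eff) + 1L)
    clusters <- c(clusters, cl)
  }
  cum <- cumsum(sizes)
  keep <- seq_len(which(cum >= M)[1])
  tibble(class = class, tissue = tissue, subset = subset,
         cluster = clusters[keep], size = sizes[keep])
}

draw_class_clones <- function(class, n_target, cfg) {
  if (n_target <= 0) return(NULL)
  grid <- expand.grid(tissue = names(cfg$tissue_mix),
                      subset = names(cfg$subset_mix),
                      stringsAsFactors = FALSE)
  pr <- as.vector(outer(cfg$tissue_mix, cfg$subset_mix))
  alloc <- as.vector(rmultinom(1, n_target, pr))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    draw_stratum_clones(alloc[i], class, grid$tissue[i], grid$subset[i], cfg)
  })
  dplyr::bind_rows(out)
}

# one chain row per (clone, chain slot)
make_clone_chains <- function(clones, cfg) {
  if (is.null(clones) || nrow(clones) == 0) {
    return(tibble(clone_id = character(0), locus = character(0),
                  v_gene = character(0), j_gene = character(0),
                  cdr3_nt = character(0), secondary = logical(0)))
  }
  n_alpha <- ifelse(clones$class == "DUAL_ALPHA", 2L, 1L)
  n_beta <- ifelse(clones$class == "DUAL_BETA", 2L, 1L)
  rows <- list()
  draw_chains <- function(idx, locus, secondary) {
    n <- length(idx)
    if (n == 0) return(NULL)
    w <- cfg$v_usage[[locus]]
    if (secondary && locus == "TRB" && cfg$pseudogene_skew != 1) {
      if ("TRBV21-1" %in% names(w)) {
        w["TRBV21-1"] <- w["TRBV21-1"] * cfg$pseudogene_skew
        w <- w / sum(w)
      }
    }
    j_pool <- if (locus == "TRA") paste0("TRAJ", 1:56) else
      paste0("TRBJ", c("1-1", "1-2", "1-3", "1-4", "1-5", "1-6",
                       "2-1", "2-2", "2-3", "2-4", "2-5", "2-6", "2-7"))
    tibble(
      clone_id = clones$clone_id[idx],
      locus = locus,
      v_gene = sample(names(w), n, replace = TRUE, prob = w),
      j_gene = sample(j_pool, n, replace = TRUE),
      cdr3_nt = random_cdr3(n),
      secondary = secondary
    )
  }
  rows <- dplyr::bind_rows(
    draw_chains(seq_len(nrow(clones)), "TRA", secondary = FALSE),
    draw_chains(which(n_alpha == 2L), "TRA", secondary = TRUE),
    draw_chains(seq_len(nrow(clones)), "TRB", secondary = FALSE),
    draw_chains(which(n_beta == 2L), "TRB", secondary = TRUE)
  )
  arrange(rows, .data$clone_id, .data$locus, .data$secondary)
}

#' Simulate a paired-chain single-cell TCR repertoire
#'
#' Draws clones per (allele class, tissue, subset) stratum with
#' geometric clone sizes scaled by the configured expansion
#' multipliers, gives every clone a V/J/CDR3 chain set (two
#' alpha-chains for dual-alpha clones, two beta-chains for dual-beta),
#' expands clones into cells, emits one contig row per chain per cell
#' with Poisson UMI counts (secondary chains lower), and finally
#' merges pairs of extra single cells into 2-alpha/2-beta doublet
#' barcodes at the configured rate. Deterministic given the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return A list with `table` (a metadata-joined [contig_table()]),
#'   `truth` (tibble: `barcode`, `true_class`, `clone_id`,
#'   `is_doublet`, `constituents`) and `config`.
#' @export
simulate_repertoire <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  d <- round(config$doublet_rate * n)
  n_da <- round(config$dual_alpha_rate * n)
  n_db <- round(config$dual_beta_rate * n)
  n_single <- n - d - n_da - n_db
  stopifnot(n_single >= 0)

  dual_clones <- dplyr::bind_rows(
    draw_class_clones("DUAL_ALPHA", n_da, config),
    draw_class_clones("DUAL_BETA", n_db, config)
  )
  if (nrow(dual_clones) > 0) {
    dual_clones$clone_id <- paste0("dual", seq_len(nrow(dual_clones)))
    dual_clones$patient_id <- paste0(
      "patient", sample.int(config$n_patients, nrow(dual_clones),
                            replace = TRUE))
  }
  dual_chains <- make_clone_chains(dual_clones, config)

  # shadow clonotypes: the primary chain pair of a dual clone also
  # observed on its own, as capture dropout of the secondary allele
  # produces it in real data
  shadow_clones <- NULL
  shadow_chains <- NULL
  if (nrow(dual_clones) > 0 && config$shadow_rate > 0) {
    is_shadow <- runif(nrow(dual_clones)) < config$shadow_rate
    if (any(is_shadow)) {
      parents <- dual_clones[is_shadow, ]
      mult <- ifelse(parents$subset == "CD8", config$cd8_expansion, 1)
      p_eff <- pmin(1, config$clone_size_law$prob / mult)
      shadow_clones <- parents |>
        mutate(class = "SINGLE",
               size = rgeom(nrow(parents), p_eff) + 1L,
               parent_id = .data$clone_id,
               clone_id = paste0("shadow", dplyr::row_number()))
      # keep the single-cell budget exact: shadows spend it first
      budget <- n_single
      cum <- cumsum(shadow_clones$size)
      shadow_clones <- shadow_clones[cum <= budget, ]
      if (nrow(shadow_clones) > 0) {
        shadow_chains <- dual_chains |>
          filter(!.data$secondary,
                 .data$clone_id %in% shadow_clones$parent_id)
        shadow_chains$clone_id <- shadow_clones$clone_id[
          match(shadow_chains$clone_id, shadow_clones$parent_id)]
      }
      shadow_clones$parent_id <- NULL
    }
  }
  n_shadow_cells <- if (is.null(shadow_clones)) 0L else
    sum(shadow_clones$size)

  single_clones <- draw_class_clones("SINGLE", n_single - n_shadow_cells,
                                     config)
  if (!is.null(single_clones)) {
    single_clones$clone_id <- paste0("clone", seq_len(nrow(single_clones)))
    single_clones$patient_id <- paste0(
      "patient", sample.int(config$n_patients, nrow(single_clones),
                            replace = TRUE))
  }
  single_chains <- make_clone_chains(single_clones, config)

  # shadows are the same lineage as their parent, hence same patient
  clones <- dplyr::bind_rows(single_clones, shadow_clones, dual_clones)
  chains <- dplyr::bind_rows(single_chains, shadow_chains, dual_chains)

  # expand clones into cells
  cells <- clones[rep(seq_len(nrow(clones)), clones$size), ]
  cells$barcode <- sprintf("SIMBC%07d-1", seq_len(nrow(cells)))

  # doublet source cells: d pairs of fresh singleton single-TCR cells
  # captured in the same sample (same patient and tissue)
  if (d > 0) {
    pair_tissue <- sample(names(config$tissue_mix), d, replace = TRUE,
                          prob = config$tissue_mix)
    pair_patient <- paste0("patient", sample.int(config$n_patients, d,
                                                 replace = TRUE))
    src <- tibble(
      class = "SINGLE",
      tissue = rep(pair_tissue, each = 2),
      subset = sample(names(config$subset_mix), 2 * d, replace = TRUE,
                      prob = config$subset_mix),
      patient_id = rep(pair_patient, each = 2),
      size = 1L
    )
    src$cluster <- vapply(src$subset, function(s) {
      probs <- config$cluster_labels[[s]]
      sample(names(probs), 1, prob = probs)
    }, "")
    src$clone_id <- paste0("dsrc", seq_len(nrow(src)))
    src_chains <- make_clone_chains(src, config)
    src$barcode <- sprintf("SIMBC%07d-1", nrow(cells) + seq_len(2 * d))
  } else {
    src <- NULL
    src_chains <- NULL
  }

  all_cells <- dplyr::bind_rows(cells, src)
  all_chains <- dplyr::bind_rows(chains, src_chains)
  contigs <- all_cells |>
    select("barcode", "clone_id") |>
    inner_join(all_chains, by = "clone_id",
               relationship = "many-to-many") |>
    arrange(.data$barcode, .data$locus, .data$secondary)
  lam <- ifelse(contigs$secondary, config$umi_law$secondary,
                config$umi_law$primary)
  contigs$umis <- 1L + rpois(nrow(contigs), lam)
  contigs$reads <- contigs$umis * (20L + rpois(nrow(contigs), 10))
  contigs <- contigs |>
    group_by(.data$barcode) |>
    mutate(contig_id = paste0(.data$barcode, "_contig_",
                              dplyr::row_number())) |>
    ungroup() |>
    mutate(productive = TRUE, cdr3_aa = NA_character_,
           sample_id = "sim") |>
    select("barcode", "contig_id", "locus", "v_gene", "j_gene",
           "cdr3_nt", "cdr3_aa", "productive", "umis", "reads",
           "sample_id")

  metadata <- all_cells |>
    select("barcode", "patient_id", "tissue", "subset", "cluster")
  truth <- all_cells |>
    transmute(barcode = .data$barcode, true_class = .data$class,
              clone_id = .data$clone_id, is_doublet = FALSE,
              constituents = NA_character_)

  table <- contig_table(contigs, metadata = metadata,
                        provenance = list(dialect = "simulated",
                                          seed = config$seed))
  if (d > 0) {
    merged <- merge_barcode_pairs(table, truth,
                                  matrix(src$barcode, nrow = 2))
    table <- merged$table
    truth <- merged$truth
  }
  list(table = table, truth = truth, config = config)
}

# merge pre-chosen barcode pairs (columns of `pairs`) into doublets:
# the first barcode of each pair absorbs the second's contigs
merge_barcode_pairs <- function(table, truth, pairs) {
  keep_bc <- pairs[1, ]
  drop_bc <- pairs[2, ]
  map <- setNames(keep_bc, drop_bc)
  contigs <- table$contigs
  hit <- contigs$barcode %in% drop_bc
  contigs$barcode[hit] <- unname(map[contigs$barcode[hit]])
  contigs <- arrange(contigs, .data$barcode, .data$locus, .data$contig_id)
  metadata <- table$metadata
  if (!is.null(metadata)) {
    metadata <- filter(metadata, !.data$barcode %in% drop_bc)
  }
  old <- truth
  constituents <- paste(old$clone_id[match(keep_bc, old$barcode)],
                        old$clone_id[match(drop_bc, old$barcode)],
                        sep = ";")
  truth <- filter(old, !.data$barcode %in% drop_bc)
  idx <- match(keep_bc, truth$barcode)
  truth$true_class[idx] <- NA_character_
  truth$clone_id[idx] <- NA_character_
  truth$is_doublet[idx] <- TRUE
  truth$constituents[idx] <- constituents
  table$contigs <- contigs
  table$metadata <- metadata
  list(table = table, truth = truth)
}

#' Merge random cell pairs into doublet barcodes
#'
#' Emulates droplet capture doublets: randomly chosen barcode pairs
#' are merged under one barcode, concatenating their contigs and
#' keeping all UMIs. Merging two single TCR cells from distinct
#' clones produces the 2-alpha/2-beta profile the classifier must
#' exclude.
#'
#' @param table A [contig_table()] (typically from
#'   [simulate_repertoire()]).
#' @param truth The matching truth tibble.
#' @param rate Fraction of barcodes to turn into doublets.
#' @param seed Optional seed for pair selection.
#' @return A list with the updated `table` and `truth`.
#' @export
inject_doublets <- function(table, truth, rate, seed = NULL) {
  stopifnot(inherits(table, "contig_table"), rate >= 0, rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  bcs <- unique(table$contigs$barcode)
  d <- round(rate * length(bcs))
  if (d == 0) return(list(table = table, truth = truth))
  if (2 * d > length(bcs)) {
    stop("doublet rate too high for the number of available cells",
         call. = FALSE)
  }
  chosen <- sample(bcs, 2 * d)
  merge_barcode_pairs(table, truth, matrix(chosen, nrow = 2))
}
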