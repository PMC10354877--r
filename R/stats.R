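# Inferential layer for clone-size comparisons: Welch's
# heteroscedastic ANOVA, the studentized-range distribution, and the
# Games-Howell post hoc test. Implemented here from first principles;
# the test suite cross-checks against stats::oneway.test and
# stats::ptukey.

group_summaries <- function(values, groups) {
  groups <- as.character(groups)
  if (anyNA(values) || anyNA(groups)) {
    stop("values and groups must not contain NA", call. = FALSE)
  }
  labs <- unique(groups)
  n <- vapply(labs, function(g) sum(groups == g), 0L, USE.NAMES = FALSE)
  means <- vapply(labs, function(g) mean(values[groups == g]), 0,
                  USE.NAMES = FALSE)
  vars <- vapply(labs, function(g) stats::var(values[groups == g]), 0,
                 USE.NAMES = FALSE)
  list(labels = labs, n = n, mean = means, var = vars)
}

check_groups <- function(n, vars) {
  k <- length(n)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(n < 2)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  if (any(vars <= 0)) {
    stop("group with zero variance (all values tied); variance-based ",
         "tests are undefined -- consider pooling or jittering exact ties",
         call. = FALSE)
  }
  invisible(k)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Tests equality of group means without assuming equal variances,
#' using variance-weighted group means and the Welch (1951) F
#' approximation with fractional denominator degrees of freedom.
#' This is the omnibus test used for clone-size comparisons, where
#' clone-size distributions are strongly heteroscedastic across
#' allele classes.
#'
#' @param values Numeric vector of observations (e.g. clone sizes).
#' @param groups Grouping vector, same length as `values`.
#' @return A one-row tibble: `F`, `df1`, `df2`, `p`, `k`.
#' @seealso [welch_anova_summary()] to test from per-group summaries,
#'   [games_howell()] for the pairwise post hoc.
#' @export
welch_anova <- function(values, groups) {
  s <- group_summaries(values, groups)
  welch_anova_summary(s$n, s$mean, s$var)
}

#' Welch's ANOVA from per-group summaries
#'
#' @param n Integer vector of group sizes (each >= 2).
#' @param means Numeric vector of group means.
#' @param vars Numeric vector of unbiased group variances (each > 0).
#' @return A one-row tibble: `F`, `df1`, `df2`, `p`, `k`.
#' @export
welch_anova_summary <- function(n, means, vars) {
  n <- unname(n); means <- unname(means); vars <- unname(vars)
  k <- check_groups(n, vars)
  w <- n / vars
  W <- sum(w)
  grand <- sum(w * means) / W
  A <- sum(w * (means - grand)^2) / (k - 1)
  lambda <- sum((1 - w / W)^2 / (n - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  Fstat <- A / B
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  tibble(F = Fstat, df1 = df1, df2 = df2,
         p = stats::pf(Fstat, df1, df2, lower.tail = FALSE), k = k)
}

# P(range of k iid N(0,1) variables <= w)
normal_range_cdf <- function(w, k) {
  if (w <= 0) return(0)
  f <- function(z) k * dnorm(z) * (pnorm(z) - pnorm(z - w))^(k - 1)
  integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-13)$value
}

#' Upper tail of the studentized range distribution
#'
#' Computes `P(Q >= q)` for the studentized range of `k` independent
#' standard-normal means with `df` error degrees of freedom, by
#' numerical integration of the classical double integral: the normal
#' range probability integrated over the scaled-chi distribution of
#' the pooled standard deviation estimate. Absolute accuracy is well
#' inside 1e-4 over `q` in \[0, 10\], `k` up to 20 and `df` >= 2.
#' This is the reference distribution of the Games-Howell test.
#'
#' @param q Quantile(s), >= 0.
#' @param k Number of groups (>= 2).
#' @param df Error degrees of freedom (> 0; may be fractional or
#'   `Inf`).
#' @return Upper-tail probability, same length as `q`.
#' @export
studentized_range_sf <- function(q, k, df) {
  if (any(!is.finite(q)) || !is.finite(k) || is.na(df)) {
    stop("non-finite q or k", call. = FALSE)
  }
  stopifnot(k >= 2, df > 0)
  one <- function(qi) {
    if (qi < 0) stop("q must be >= 0", call. = FALSE)
    if (qi == 0) return(1)
    if (is.infinite(df)) {
      cdf <- normal_range_cdf(qi, k)
    } else {
      # s = sqrt(chi^2_df / df); density 2 (df/2)^(df/2)/Gamma(df/2)
      #   * s^(df-1) exp(-df s^2 / 2)
      log_c <- log(2) + (df / 2) * log(df / 2) - lgamma(df / 2)
      integrand <- function(s) {
        vapply(s, function(si) {
          if (si <= 0) return(0)
          dens <- exp(log_c + (df - 1) * log(si) - df * si^2 / 2)
          dens * normal_range_cdf(qi * si, k)
        }, 0)
      }
      cdf <- integrate(integrand, 0, Inf, rel.tol = 1e-8)$value
    }
    min(1, max(0, 1 - cdf))
  }
  vapply(q, one, 0)
}

star_labels <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Games-Howell pairwise post hoc test
#'
#' All pairwise mean comparisons under unequal variances and sizes:
#' each pair gets a Welch-type standard error and Welch-Satterthwaite
#' degrees of freedom, and its statistic is referred to the
#' studentized range distribution for the full number of groups,
#' which is what controls the familywise error across the pairs.
#'
#' @inheritParams welch_anova
#' @return A tibble with one row per unordered pair: `group1`,
#'   `group2`, `mean_diff` (`group1 - group2`), `se`, `t`, `df`,
#'   `p_adj`, `stars` (`ns` / `*` / `**` / `***` at 0.05 / 0.01 /
#'   0.001).
#' @export
games_howell <- function(values, groups) {
  s <- group_summaries(values, groups)
  games_howell_summary(s$n, s$mean, s$var, s$labels)
}

#' Games-Howell from per-group summaries
#'
#' @inheritParams welch_anova_summary
#' @param labels Optional group labels.
#' @return See [games_howell()].
#' @export
games_howell_summary <- function(n, means, vars, labels = NULL) {
  n <- unname(n); means <- unname(means); vars <- unname(vars)
  k <- check_groups(n, vars)
  labels <- labels %||% paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(idx) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    vi <- vars[i] / n[i]; vj <- vars[j] / n[j]
    se <- sqrt(vi + vj)
    tstat <- abs(means[i] - means[j]) / se
    df_ws <- (vi + vj)^2 / (vi^2 / (n[i] - 1) + vj^2 / (n[j] - 1))
    p <- studentized_range_sf(tstat * sqrt(2), k, df_ws)
    tibble(group1 = labels[i], group2 = labels[j],
           mean_diff = means[i] - means[j], se = se, t = tstat,
           df = df_ws, p_adj = p)
  })
  out <- dplyr::bind_rows(out)
  out$stars <- star_labels(out$p_adj)
  out
}

#' Per-cluster dual-vs-single clone-size screen
#'
#' For each phenotype cluster, compares the mean clone size of a dual
#' allele class against single TCR clones and flags clusters where
#' the difference is both significant and greater than a fold-change
#' threshold -- the screen used to pick out the expanded
#' effector-memory / tissue-resident / exhausted phenotypes. With two
#' groups per cluster the Games-Howell statistic reduces exactly to
#' the two-sided Welch t test.
#'
#' @param samples A tibble of per-clone sizes with columns `cluster`,
#'   `class` and `size` (see [clone_size_samples()]).
#' @param dual_class Which dual class to screen (default
#'   `"DUAL_BETA"`).
#' @param single_class Reference class (default `"SINGLE"`).
#' @param alpha Significance threshold (default 0.05).
#' @param fold_threshold Minimum dual/single mean-size ratio (default
#'   2).
#' @return A tibble with one row per cluster: clone counts, means,
#'   `fold`, `p_adj`, `stars`, `flagged`, and `untestable` for
#'   clusters with fewer than two clones in either group (reported,
#'   never silently dropped).
#' @export
cluster_screen <- function(samples, dual_class = "DUAL_BETA",
                           single_class = "SINGLE", alpha = 0.05,
                           fold_threshold = 2) {
  stopifnot(all(c("cluster", "class", "size") %in% names(samples)))
  samples <- filter(samples, .data$class %in% c(dual_class, single_class))
  clusters <- sort(unique(samples$cluster))
  out <- lapply(clusters, function(cl) {
    x <- filter(samples, .data$cluster == cl)
    dual <- x$size[x$class == dual_class]
    single <- x$size[x$class == single_class]
    untestable <- length(dual) < 2 || length(single) < 2 ||
      (length(dual) > 1 && stats::var(dual) == 0) ||
      (length(single) > 1 && stats::var(single) == 0)
    mean_dual <- if (length(dual)) mean(dual) else NA_real_
    mean_single <- if (length(single)) mean(single) else NA_real_
    fold <- mean_dual / mean_single
    p <- if (untestable) NA_real_ else {
      games_howell_summary(
        n = c(length(dual), length(single)),
        means = c(mean_dual, mean_single),
        vars = c(stats::var(dual), stats::var(single)),
        labels = c("dual", "single"))$p_adj
    }
    tibble(cluster = cl, n_dual = length(dual), n_single = length(single),
           mean_dual = mean_dual, mean_single = mean_single,
           fold = fold, p_adj = p,
           stars = ifelse(is.na(p), NA_character_, star_labels(p)),
           untestable = untestable,
           flagged = !untestable & !is.na(p) & p < alpha &
             !is.na(fold) & fold > fold_threshold)
  })
  dplyr::bind_rows(out)
}

# TRBV/TRAV segments annotated as pseudogenes (IMGT functionality);
# TRBV21-1 is the one that matters for the dual-beta usage signal.
PSEUDOGENES <- c(
  "TRBV1", "TRBV3-2", "TRBV5-2", "TRBV7-5", "TRBV8-1", "TRBV8-2",
  "TRBV12-1", "TRBV12-2", "TRBV21-1", "TRBV22-1", "TRBV26",
  "TRAV8-5", "TRAV11", "TRAV15", "TRAV28", "TRAV31", "TRAV32",
  "TRAV33", "TRAV37"
)

#' V-gene usage by allele class over unique clones
#'
#' Tallies V-gene use at one locus across unique clones, per allele
#' class: a dual clone contributes both of its V genes at the dual
#' locus. Frequencies are normalized within class (each class column
#' sums to 1 over observed genes), and each dual class gets an
#' enrichment ratio against the single class, which is how a
#' pseudogene like TRBV21-1 that is over-used among secondary
#' beta-chain rearrangements shows up.
#'
#' @param ct A [tabulate_clones()] result (nucleotide or `v_cdr3`
#'   identity; keys encode the V genes).
#' @param locus `"TRB"` (default) or `"TRA"`.
#' @param pseudogenes Character vector of gene symbols flagged as
#'   pseudogenes; defaults to a bundled IMGT-derived lookup.
#' @return A tibble: `gene`, `is_pseudogene`, one `freq_<class>`
#'   column per observed class, and `enrichment_<dualclass>` columns
#'   (dual frequency / single frequency).
#' @export
gene_usage_table <- function(ct, locus = c("TRB", "TRA"),
                             pseudogenes = PSEUDOGENES) {
  stopifnot(inherits(ct, "clone_table"))
  locus <- match.arg(locus)
  clones <- ct$clones
  chains <- strsplit(clones$clone_key, ";", fixed = TRUE)
  per_clone <- tibble(
    class = rep(clones$class, lengths(chains)),
    chain = unlist(chains)
  )
  parts <- strsplit(per_clone$chain, "|", fixed = TRUE)
  per_clone$locus <- vapply(parts, `[`, "", 1)
  per_clone$gene <- vapply(parts, `[`, "", 2)
  per_clone <- filter(per_clone, .data$locus == !!locus)
  counts <- per_clone |>
    dplyr::count(.data$class, .data$gene) |>
    group_by(.data$class) |>
    mutate(freq = .data$n / sum(.data$n)) |>
    ungroup()
  wide <- counts |>
    select("class", "gene", "freq") |>
    tidyr::pivot_wider(names_from = "class", values_from = "freq",
                       names_prefix = "freq_", values_fill = 0)
  wide$is_pseudogene <- wide$gene %in% pseudogenes
  for (dual in intersect(c("freq_DUAL_ALPHA", "freq_DUAL_BETA"),
                         names(wide))) {
    if ("freq_SINGLE" %in% names(wide)) {
      ratio <- wide[[dual]] / wide$freq_SINGLE
      wide[[sub("freq_", "enrichment_", dual)]] <- ratio
    }
  }
  dplyr::relocate(wide, "gene", "is_pseudogene") |>
    arrange(.data$gene)
}
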