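test_that("welch_anova agrees with the base-R Welch oracle", {
  set.seed(101)
  x <- c(rnorm(20, 0, 1), rnorm(25, 0.5, 2), rnorm(30, 1, 0.5))
  g <- rep(c("a", "b", "c"), c(20, 25, 30))
  ours <- welch_anova(x, g)
  oracle <- stats::oneway.test(x ~ factor(g), var.equal = FALSE)
  expect_equal(ours$F, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(ours$df2, unname(oracle$parameter[2]), tolerance = 1e-12)
  expect_equal(ours$p, oracle$p.value, tolerance = 1e-12)
})

test_that("welch_anova matches an independently computed fixture", {
  # frozen from an external heteroscedastic-ANOVA implementation run
  # on this exact dataset
  a <- c(3.029, 3.642, 3.147, 1.027, 0.607, 2.067, 2.861, 2.509, 3.81,
         2.751)
  b <- c(3.46, 1.403, 0.838, 4.727, 2.573, 3.717, 0.435, 1.845, 0.563,
         1.336, 3.855, 0.279)
  c_ <- c(2.826, 3.315, 2.732, 3.023, 3.045, 3.493, 2.898, 3.391, 3.24,
          3.497, 3.357, 4.36, 2.735, 4.039, 2.918)
  w <- welch_anova(c(a, b, c_), rep(c("a", "b", "c"), c(10, 12, 15)))
  expect_equal(w$F, 4.692571532162, tolerance = 1e-9)
  expect_equal(w$df2, 15.671106535610, tolerance = 1e-9)
  expect_equal(w$p, 2.529214789462e-02, tolerance = 1e-8)
  gh <- games_howell(c(a, b, c_), rep(c("a", "b", "c"), c(10, 12, 15)))
  expect_equal(gh$mean_diff,
               c(0.459083333333, -0.712933333333, -1.172016666667),
               tolerance = 1e-9)
  expect_equal(gh$se, c(0.552306806915, 0.351818244922, 0.458604547371),
               tolerance = 1e-9)
  expect_equal(gh$df, c(19.340708715803, 11.422533122872, 12.638054065943),
               tolerance = 1e-9)
  expect_equal(gh$p_adj,
               c(0.6886335845060, 0.1502110705195, 0.05914038737065),
               tolerance = 1e-6)
})

test_that("identical groups give F = 0 and p = 1", {
  w <- welch_anova_summary(n = c(10, 12), means = c(2, 2), vars = c(1, 2))
  expect_equal(w$F, 0)
  expect_equal(w$p, 1)
})

test_that("degenerate groups are rejected with guidance", {
  expect_error(welch_anova_summary(10, 1, 1), "2 groups")
  expect_error(welch_anova_summary(c(10, 1), c(1, 2), c(1, 1)), "n >= 2")
  expect_error(welch_anova_summary(c(10, 10), c(1, 2), c(1, 0)),
               "zero variance")
  expect_error(welch_anova(c(1, NA, 2, 3), c("a", "a", "b", "b")), "NA")
})

test_that("studentized range upper tail matches base-R ptukey", {
  grid <- expand.grid(q = c(0.5, 1.5, 2.5, 3.5, 5, 8),
                      k = c(2, 3, 5, 10, 20),
                      df = c(2, 5.5, 10, 30, 120))
  for (i in seq_len(nrow(grid))) {
    got <- studentized_range_sf(grid$q[i], grid$k[i], grid$df[i])
    want <- stats::ptukey(grid$q[i], grid$k[i], grid$df[i],
                          lower.tail = FALSE)
    # absolute agreement; ptukey itself is a ~1e-4 approximation
    expect_lt(abs(got - want), 2e-4,
              label = sprintf("sf(q=%g,k=%g,df=%g) vs ptukey", grid$q[i],
                              grid$k[i], grid$df[i]))
  }
  expect_equal(studentized_range_sf(0, 3, 10), 1)
  expect_error(studentized_range_sf(Inf, 3, 10), "non-finite")
})

test_that("studentized range with k = 2 reduces to the two-sided t tail", {
  for (q in c(0.5, 2, 4)) {
    for (df in c(3, 12, 60)) {
      expect_equal(studentized_range_sf(q, 2, df),
                   2 * stats::pt(q / sqrt(2), df, lower.tail = FALSE),
                   tolerance = 1e-7)
    }
  }
})

test_that("studentized range tail is monotone in q and k", {
  qs <- seq(0.5, 6, by = 0.5)
  vals <- studentized_range_sf(qs, 4, 12)
  expect_true(all(diff(vals) <= 0))
  ks <- c(2, 3, 5, 8, 12)
  vals_k <- vapply(ks, function(k) studentized_range_sf(3, k, 12), 0)
  expect_true(all(diff(vals_k) >= 0))
})

test_that("games_howell is symmetric and null on identical groups", {
  gh <- games_howell_summary(n = c(10, 10), means = c(2, 2),
                             vars = c(1.5, 1.5), labels = c("x", "y"))
  expect_equal(gh$mean_diff, 0)
  expect_equal(gh$p_adj, 1)
  set.seed(7)
  x <- rnorm(30)
  g <- rep(c("a", "b", "c"), 10)
  fwd <- games_howell(x, g)
  bwd <- games_howell(rev(x), rev(g))
  key <- function(df) paste(pmin(df$group1, df$group2),
                            pmax(df$group1, df$group2))
  fwd <- fwd[order(key(fwd)), ]
  bwd <- bwd[order(key(bwd)), ]
  expect_equal(fwd$p_adj, bwd$p_adj, tolerance = 1e-12)
  expect_equal(abs(fwd$mean_diff), abs(bwd$mean_diff), tolerance = 1e-12)
})

test_that("games_howell agrees with a ptukey-based reference implementation", {
  set.seed(11)
  x <- c(rlnorm(15, 0, 0.8), rlnorm(20, 0.4, 1), rlnorm(25, 0.9, 0.6))
  g <- rep(c("a", "b", "c"), c(15, 20, 25))
  ours <- games_howell(x, g)
  ref <- do.call(rbind, lapply(list(c("a", "b"), c("a", "c"), c("b", "c")),
    function(pr) {
      xi <- x[g == pr[1]]; xj <- x[g == pr[2]]
      vi <- var(xi) / length(xi); vj <- var(xj) / length(xj)
      tstat <- abs(mean(xi) - mean(xj)) / sqrt(vi + vj)
      df <- (vi + vj)^2 / (vi^2 / (length(xi) - 1) + vj^2 / (length(xj) - 1))
      data.frame(p = stats::ptukey(tstat * sqrt(2), 3, df,
                                   lower.tail = FALSE))
    }))
  expect_equal(ours$p_adj, ref$p, tolerance = 1e-6)
})

test_that("significance stars follow the 0.05/0.01/0.001 thresholds", {
  gh <- games_howell_summary(
    n = c(200, 200), means = c(1, 1.001), vars = c(1, 1))
  expect_equal(gh$stars, "ns")
  big <- games_howell_summary(
    n = c(200, 200), means = c(1, 3), vars = c(1, 1))
  expect_equal(big$stars, "***")
})

test_that("cluster screen requires both significance and fold change", {
  set.seed(31)
  base <- rgeom(200, 0.5) + 1
  samples <- dplyr::bind_rows(
    # identical distributions: significant never, fold ~ 1
    tibble::tibble(cluster = "flat", class = "SINGLE", size = base),
    tibble::tibble(cluster = "flat", class = "DUAL_BETA", size = sample(base)),
    # large significant fold
    tibble::tibble(cluster = "hot", class = "SINGLE", size = base),
    tibble::tibble(cluster = "hot", class = "DUAL_BETA",
                   size = rgeom(150, 0.15) + 1),
    # large fold but hopeless power: two clones only
    tibble::tibble(cluster = "tiny", class = "SINGLE", size = base),
    tibble::tibble(cluster = "tiny", class = "DUAL_BETA", size = c(9, 11))
  )
  scr <- cluster_screen(samples)
  scr <- scr[order(scr$cluster), ]
  expect_equal(scr$flagged[scr$cluster == "flat"], FALSE)
  expect_equal(scr$flagged[scr$cluster == "hot"], TRUE)
  expect_equal(scr$flagged[scr$cluster == "tiny"], FALSE)
  # a huge fold with weak evidence must not flag
  weak <- cluster_screen(dplyr::bind_rows(
    tibble::tibble(cluster = "w", class = "SINGLE", size = c(1, 1, 2, 1)),
    tibble::tibble(cluster = "w", class = "DUAL_BETA", size = c(1, 20))))
  expect_false(weak$flagged)
  # under-sized clusters are reported, not dropped
  under <- cluster_screen(dplyr::bind_rows(
    tibble::tibble(cluster = "u", class = "SINGLE", size = c(1, 2, 1)),
    tibble::tibble(cluster = "u", class = "DUAL_BETA", size = 5)))
  expect_true(under$untestable)
  expect_equal(nrow(under), 1L)
})

test_that("a planted per-cluster expansion is flagged in exactly that cluster", {
  cfg <- sim_config(
    n_cells = 12000, seed = 37,
    dual_expansion = c(P = 1, N = 1, T = 1),
    cluster_expansion = c("ZNF683+CXCR6+ Trm" = 3))
  sim <- simulate_repertoire(cfg)
  ct <- tabulate_clones(build_cell_profiles(sim$table))
  sizes <- clone_size_samples(ct, strata = c("subset", "cluster"))
  sizes <- sizes[sizes$subset == "CD8", ]
  scr <- cluster_screen(sizes, dual_class = "DUAL_ALPHA")
  expect_equal(scr$cluster[scr$flagged], "ZNF683+CXCR6+ Trm")
})

test_that("gene usage frequencies normalize per class and recover pseudogene skew", {
  # a strongly planted skew so the enrichment estimate has power at
  # this repertoire size (dual-beta clones are the rarest class)
  sim <- simulate_repertoire(sim_config(n_cells = 12000, seed = 17,
                                        pseudogene_skew = 50))
  ct <- tabulate_clones(build_cell_profiles(sim$table))
  usage <- gene_usage_table(ct, locus = "TRB")
  freq_cols <- grep("^freq_", names(usage), value = TRUE)
  for (col in freq_cols) {
    expect_equal(sum(usage[[col]]), 1, tolerance = 1e-12)
  }
  expect_true(usage$is_pseudogene[usage$gene == "TRBV21-1"])
  enr <- usage$enrichment_DUAL_BETA[usage$gene == "TRBV21-1"]
  expect_gt(enr, 5)
  # a dual-alpha clone contributes both alpha V genes
  rows <- list(ch_a("BC1", v = "TRAV1-2"),
               ch_a("BC1", v = "TRAV2", cdr3 = "TGTAAAGTGAGC", umis = 2),
               ch_b("BC1"))
  tb <- do.call(mk_table, c(rows, list(meta = mk_meta("BC1"))))
  u1 <- gene_usage_table(tabulate_clones(build_cell_profiles(tb)), "TRA")
  expect_equal(sort(u1$gene), c("TRAV1-2", "TRAV2"))
  expect_equal(u1$freq_DUAL_ALPHA, c(0.5, 0.5))
})
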