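th <- derive_gate_thresholds()

test_that("gating is a partition of 20 bins with tie-to-higher boundaries", {
  # extremes land in the corner bins
  hi <- assign_clusters(tibble::tibble(gfp_mfi = 1e6, bfp_mfi = 1e6), th)
  expect_identical(as.character(hi$gfp_level), "high")
  expect_identical(as.character(hi$bfp_level), "high")
  lo <- assign_clusters(tibble::tibble(gfp_mfi = 0, bfp_mfi = 0), th)
  expect_identical(as.character(lo$gfp_level), "neg")
  expect_identical(as.character(lo$bfp_level), "neg")
  # an event exactly on a boundary gates into the higher level
  tie <- assign_clusters(tibble::tibble(gfp_mfi = th$gfp_cuts[2],
                                        bfp_mfi = th$bfp_cuts[1]), th)
  expect_identical(as.character(tie$gfp_level), "low")
  expect_identical(as.character(tie$bfp_level), "low")
  # 100,000 random events partition with exact mass conservation
  withr::with_seed(103, {
    ev <- tibble::tibble(gfp_mfi = exp(runif(1e5, 0, 12)),
                         bfp_mfi = exp(runif(1e5, 0, 12)))
  })
  gated <- assign_clusters(ev, th)
  counts <- table(gated$bfp_level, gated$gfp_level)
  expect_identical(dim(counts), c(4L, 5L))
  expect_identical(sum(counts), 100000L)
  h <- cluster_heatmap(ev, th)
  expect_equal(sum(unclass(h)), 100, tolerance = 1e-6)
  expect_error(assign_clusters(tibble::tibble(gfp_mfi = -1, bfp_mfi = 1), th),
               class = "allelescope_invalid_event")
  expect_error(assign_clusters(tibble::tibble(gfp_mfi = NaN, bfp_mfi = 1), th),
               class = "allelescope_invalid_event")
})

test_that("gate thresholds validate their shape", {
  expect_error(gate_thresholds(c(1, 2, 3), c(1, 2, 3)),
               class = "allelescope_config_error")
  expect_error(gate_thresholds(c(1, 2, 3, 3), c(1, 2, 3)),
               class = "allelescope_config_error")
  expect_silent(gate_thresholds(c(1, 2, 3, 4), c(1, 2, 3)))
})

test_that("cluster heatmaps concentrate mass where events are", {
  one_bin <- tibble::tibble(gfp_mfi = rep(1e5, 50), bfp_mfi = rep(1e5, 50))
  h <- cluster_heatmap(one_bin, th)
  expect_equal(unclass(h)["high", "high"], 100)
  expect_equal(sum(unclass(h)), 100)
  expect_error(cluster_heatmap(one_bin[0, ], th),
               class = "allelescope_empty_input")
  # simulated mock (unedited) population: nearly all GFP-high/BFP-high
  cfg <- sim_config(seed = 107, n_cells = 3000,
                    genotype_distribution = c(
                      UNMODIFIED = 1, HDR = 0, IN_FRAME = 0, FRAMESHIFT = 0,
                      LD = 0, LOA = 0))
  ev <- simulate_flow(simulate_cells(cfg, fix_ref), cfg)
  hm <- cluster_heatmap(ev, derive_gate_thresholds(cfg$optics))
  expect_gte(unclass(hm)["high", "high"], 99)
  expect_identical(length(unclass(hm)), 20L)
})

test_that("fold changes are elementwise with undefined empty-bin ratios", {
  a_ev <- tibble::tibble(gfp_mfi = c(rep(1e5, 50), rep(1, 50)),
                         bfp_mfi = c(rep(1e5, 50), rep(1, 50)))
  a <- cluster_heatmap(a_ev, th)
  expect_true(all(unclass(fold_change(a, a)) %in% c(1, NaN)))
  # double one occupied bin, halve the other
  b_ev <- tibble::tibble(gfp_mfi = c(rep(1e5, 80), rep(1, 20)),
                         bfp_mfi = c(rep(1e5, 80), rep(1, 20)))
  b <- cluster_heatmap(b_ev, th)
  fc <- fold_change(a, b)
  expect_equal(unclass(fc)["high", "high"], 1.6)
  expect_equal(unclass(fc)["neg", "neg"], 0.4)
  expect_true(is.nan(unclass(fc)["med", "med"]))
  small <- cluster_heatmap(a_ev, th)
  dimnames(small) <- NULL
  expect_error(fold_change(a, small), class = "allelescope_shape_error")
})

test_that("a simulated enrichment scenario recovers its fold change", {
  dist_a <- c(UNMODIFIED = 0.85, HDR = 0, IN_FRAME = 0, FRAMESHIFT = 0,
              LD = 0, LOA = 0.15)
  dist_b <- c(UNMODIFIED = 0.70, HDR = 0, IN_FRAME = 0, FRAMESHIFT = 0,
              LD = 0, LOA = 0.30)
  cfg_a <- sim_config(seed = 109, n_cells = 20000,
                      genotype_distribution = dist_a)
  cfg_b <- sim_config(seed = 113, n_cells = 20000,
                      genotype_distribution = dist_b)
  cells_a <- simulate_cells(cfg_a, fix_ref)
  cells_b <- simulate_cells(cfg_b, fix_ref)
  ha <- cluster_heatmap(simulate_flow(cells_a, cfg_a), th)
  hb <- cluster_heatmap(simulate_flow(cells_b, cfg_b), th)
  fc <- fold_change(ha, hb)
  # truth from predicted clusters of the genotype pairs
  share <- function(cells) {
    wide <- tidyr::pivot_wider(cells[, c("cell_id", "allele", "class")],
                               names_from = "allele", values_from = "class")
    pred <- predict_cluster(wide$GFP, wide$BFP)
    mean(pred$gfp_level == "neg" & pred$bfp_level == "high")
  }
  truth_fc <- share(cells_b) / share(cells_a)
  got <- unclass(fc)["high", "neg"]
  expect_lt(abs(got - truth_fc) / truth_fc, 0.10)
})

test_that("per-cluster phenotype rates honour the binomial model", {
  withr::with_seed(127, {
    ev <- tibble::tibble(gfp_mfi = exp(runif(20000, 2, 11)),
                         bfp_mfi = exp(runif(20000, 2, 11)),
                         all_pos = TRUE,
                         coin = runif(20000) < 0.3)
  })
  h_all <- phenotype_by_cluster(ev, th, "all_pos")
  vals <- unclass(h_all)
  expect_true(all(vals[!is.nan(vals)] == 100))
  h_coin <- phenotype_by_cluster(ev, th, "coin", min_events = 50)
  n_bin <- table(assign_clusters(ev, th)$bfp_level,
                 assign_clusters(ev, th)$gfp_level)
  vals <- unclass(h_coin)
  lowc <- attr(h_coin, "low_confidence")
  for (i in 1:4) for (j in 1:5) {
    if (!lowc[i, j]) {
      se <- 100 * sqrt(0.3 * 0.7 / n_bin[i, j])
      expect_lt(abs(vals[i, j] - 30), 3 * se + 1e-9)
    }
  }
  expect_error(phenotype_by_cluster(ev, th, "gfp_mfi"),
               class = "allelescope_parse_error")
})

test_that("simulated per-genotype HbF rates surface in genotype-pure bins", {
  # biallelic unmodified population: every bin rate near the (IN, IN) rate
  cfg <- sim_config(seed = 131, n_cells = 5000,
                    genotype_distribution = c(
                      UNMODIFIED = 1, HDR = 0, IN_FRAME = 0, FRAMESHIFT = 0,
                      LD = 0, LOA = 0))
  ev <- simulate_flow(simulate_cells(cfg, fix_ref), cfg)
  h <- phenotype_by_cluster(ev, th, "hbf_pos", min_events = 100)
  rate <- unclass(h)["high", "high"]
  p <- cfg$phenotype_rates$p_hbf[
    cfg$phenotype_rates$gfp_class == "IN" &
      cfg$phenotype_rates$bfp_class == "IN"]
  n_hi <- sum(assign_clusters(ev, th)$gfp_level == "high" &
                assign_clusters(ev, th)$bfp_level == "high")
  expect_lt(abs(rate - 100 * p), 3 * 100 * sqrt(p * (1 - p) / n_hi))
})

test_that("predicted clusters follow the class-to-level map with BFP collapse", {
  pred <- predict_cluster(c("IN", "LD", "IN", "NS_EARLY", "LOA_CLASS"),
                          c("IN", "NS_EARLY", "LD", "NS_LATE", "LOA_CLASS"))
  expect_identical(as.character(pred$gfp_level),
                   c("high", "dim", "high", "med", "neg"))
  # BFP has no dim level: LD on the BFP channel collapses into neg
  expect_identical(as.character(pred$bfp_level),
                   c("high", "med", "neg", "low", "neg"))
})

test_that("end-to-end genotype-to-cluster concordance reaches 90%", {
  cfg <- sim_config(seed = 137, n_cells = 5000)
  cells <- simulate_cells(cfg, fix_ref)
  ev <- simulate_flow(cells, cfg)
  gated <- assign_clusters(ev, derive_gate_thresholds(cfg$optics))
  pred <- predict_cluster(gated$gfp_class, gated$bfp_class)
  agree <- gated$gfp_level == pred$gfp_level &
    gated$bfp_level == pred$bfp_level
  expect_gte(mean(agree), 0.90)
  # misassignments concentrate at adjacent levels
  off <- abs(as.integer(gated$gfp_level) - as.integer(pred$gfp_level)) +
    abs(as.integer(gated$bfp_level) - as.integer(pred$bfp_level))
  expect_gte(mean(off[!agree] == 1), 0.8)
})
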