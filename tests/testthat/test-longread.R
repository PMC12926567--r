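mk <- fix_ref$marker_interval
cut <- fix_ref$cut_site

read_row <- function(read_id, del_start = NA_integer_, del_end = NA_integer_,
                     marker = "TAC") {
  tibble::tibble(read_id = read_id, del_start = del_start,
                 del_end = del_end, marker = marker)
}

test_that("read calling follows marker and deletion geometry", {
  calls <- call_reads(dplyr::bind_rows(
    read_row("perfect_gfp"),
    read_row("bfp_150del", del_start = cut, del_end = cut + 150L,
             marker = "CAT"),
    read_row("loss_1800", del_start = cut, del_end = cut + 1800L,
             marker = NA_character_),
    read_row("noisy_marker", marker = "TAG"),
    read_row("partial_marker_del", del_start = mk[1], del_end = mk[1] + 1L,
             marker = NA_character_)
  ), fix_ref)
  expect_identical(calls$allele,
                   c("GFP", "BFP", "LOSS_Y66H", "AMBIGUOUS", "LOSS_Y66H"))
  expect_identical(calls$del_size,
                   c(0L, 150L, 1800L, 0L, 1L))
  expect_identical(calls$is_ld, c(FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("deletions not touching the marker are never LOSS_Y66H", {
  withr::with_seed(61, {
    sizes <- sample(1:5000, 300, replace = TRUE)
    starts <- sample(0:(6000 - 5001), 300, replace = TRUE)
    ends <- starts + sizes
    # keep only spans that avoid the marker codon entirely
    keep <- ends <= mk[1] | starts >= mk[2]
    reads <- tibble::tibble(read_id = as.character(seq_len(sum(keep))),
                            del_start = starts[keep], del_end = ends[keep],
                            marker = "CAT")
    calls <- call_reads(reads, fix_ref)
    expect_true(all(calls$allele == "BFP"))
  })
})

test_that("read fractions reproduce the worked GFP-neg cluster example", {
  expect_error(read_fractions(call_reads(read_row(character(0))[0, ],
                                         fix_ref)),
               class = "allelescope_empty_input")
  all_gfp <- call_reads(read_row(sprintf("r%d", 1:40)), fix_ref)
  f <- read_fractions(all_gfp)
  expect_identical(c(f$f_gfp, f$f_bfp, f$f_loss, f$f_ambiguous),
                   c(1, 0, 0, 0))
  # 15 GFP / 68 BFP / 17 Loss-of-Y66H in 100 reads
  calls <- dplyr::bind_rows(
    call_reads(read_row(sprintf("g%d", 1:15)), fix_ref),
    call_reads(read_row(sprintf("b%d", 1:68), marker = "CAT"), fix_ref),
    call_reads(read_row(sprintf("l%d", 1:17), del_start = cut,
                        del_end = cut + 1700L, marker = NA_character_),
               fix_ref))
  f <- read_fractions(calls)
  expect_equal(c(f$f_gfp, f$f_bfp, f$f_loss), c(0.15, 0.68, 0.17))
})

test_that("the dropout estimator reproduces the printed 52.9% worked example", {
  f <- c(f_gfp = 0.15, f_bfp = 0.68, f_loss = 0.17)
  est <- estimate_loa(f, affected = "GFP")
  expect_equal(est$r, 0.32, tolerance = 1e-12)
  expect_equal(est$estimate, 0.36 / 0.68, tolerance = 1e-12)
  expect_equal(round(100 * est$estimate, 1), 52.9)
})

test_that("estimator boundary behaviour: balance, total loss, clamping", {
  # r = 0.5 (balanced reads): no dropout
  est <- estimate_loa(c(f_gfp = 0.5, f_bfp = 0.5, f_loss = 0), "GFP")
  expect_equal(est$estimate, 0)
  # r = 0: complete loss of the affected allele
  est <- estimate_loa(c(f_gfp = 0, f_bfp = 1, f_loss = 0), "GFP")
  expect_equal(est$estimate, 1)
  # r above 0.5 clamps to zero with a warning
  expect_warning(
    est <- estimate_loa(c(f_gfp = 0.6, f_bfp = 0.4, f_loss = 0), "GFP"),
    class = "allelescope_clamp")
  expect_equal(est$estimate, 0)
  # internal-reference condition: intact allele must contribute reads
  expect_error(estimate_loa(c(f_gfp = 0.8, f_bfp = 0, f_loss = 0.2), "GFP"),
               class = "allelescope_domain_error")
})

test_that("estimator inverts the forward read-ratio model exactly", {
  grid <- seq(0, 0.999, by = 0.001)
  err <- vapply(grid, function(a) {
    r <- (1 - a) / (2 - a)
    est <- estimate_loa(c(f_gfp = r, f_bfp = 1 - r, f_loss = 0), "GFP")
    abs(est$estimate - a)
  }, numeric(1))
  expect_lt(max(err), 1e-12)
  # strictly decreasing in r on (0, 0.5]
  rs <- seq(0.01, 0.5, by = 0.01)
  ests <- vapply(rs, function(r) {
    estimate_loa(c(f_gfp = r, f_bfp = 1 - r, f_loss = 0), "GFP")$estimate
  }, numeric(1))
  expect_true(all(diff(ests) < 0))
})

test_that("relabelling GFP and BFP flips roles without changing the estimate", {
  f <- c(f_gfp = 0.15, f_bfp = 0.68, f_loss = 0.17)
  swapped <- c(f_gfp = 0.68, f_bfp = 0.15, f_loss = 0.17)
  expect_equal(estimate_loa(f, "GFP")$estimate,
               estimate_loa(swapped, "BFP")$estimate, tolerance = 1e-12)
})

test_that("estimator recovers a simulated 25% GFP loss within 0.02", {
  n <- 2000
  withr::with_seed(71, {
    gfp_kinds <- ifelse(runif(n) < 0.25, "LOA", "UNMODIFIED")
  })
  cells <- make_cells(gfp_kinds, rep("UNMODIFIED", n))
  truth <- mean(gfp_kinds == "LOA")
  n_amp <- sum(cells$kind != "LOA")
  cfg <- sim_config(seed = 73, n_cells = n,
                    long_read_depth = 20000 / n_amp)
  reads <- simulate_long_reads(cells, fix_ref, cfg)
  expect_equal(nrow(reads), 20000L, tolerance = 1)
  est <- estimate_loa(read_fractions(call_reads(reads, fix_ref)), "GFP")
  expect_lt(abs(est$estimate - truth), 0.02)
  expect_lt(abs(est$estimate - 0.25), 0.02)
  # seeded bootstrap interval brackets the estimate and is reproducible
  f <- read_fractions(call_reads(reads, fix_ref))
  e1 <- estimate_loa(f, "GFP", conf_level = 0.95, seed = 5)
  e2 <- estimate_loa(f, "GFP", conf_level = 0.95, seed = 5)
  expect_identical(e1$conf_int, e2$conf_int)
  expect_true(e1$conf_int[1] <= est$estimate &&
                est$estimate <= e1$conf_int[2])
})

test_that("LD summary tabulates per-allele fractions and size bins", {
  calls <- call_reads(dplyr::bind_rows(
    read_row(sprintf("g%d", 1:10)),
    read_row("g_ld", del_start = cut, del_end = cut + 300L),
    read_row("b_ld", del_start = cut, del_end = cut + 800L, marker = "CAT"),
    read_row("l_ld", del_start = cut, del_end = cut + 2500L,
             marker = NA_character_)
  ), fix_ref)
  s <- ld_summary(calls)
  by <- s$by_allele
  expect_equal(by$ld_fraction[by$allele == "GFP"], 1 / 11)
  expect_equal(by$ld_fraction[by$allele == "BFP"], 1)
  expect_equal(by$ld_fraction[by$allele == "LOSS_Y66H"], 1)
  expect_identical(s$histogram$n, c(1L, 1L, 1L))
  # no deletions anywhere: zero LD fractions, empty histogram
  s0 <- ld_summary(call_reads(read_row(sprintf("r%d", 1:5)), fix_ref))
  expect_true(all(s0$by_allele$ld_fraction == 0))
  expect_identical(nrow(s0$histogram), 0L)
})

test_that("every marker-spanning deletion read is a large LD", {
  # reads losing the marker deleted at least cut -> marker span (1,662 bp),
  # so all LOSS_Y66H reads are LD and exceed the 500-bp bin
  cells <- tibble::tibble(
    cell_id = seq_len(20), allele = "GFP", category = "LD",
    kind = "DELETION", position = NA_integer_, ins_seq = NA_character_,
    del_start = cut, del_end = cut + seq(1663L, 3563L, by = 100L))
  cells <- classify_lesions(cells, fix_ref)
  cells$marker <- "TAC"
  reads <- simulate_long_reads(cells, fix_ref,
                               sim_config(seed = 79, n_cells = 20))
  calls <- call_reads(reads, fix_ref)
  expect_true(all(calls$allele == "LOSS_Y66H"))
  expect_true(all(calls$is_ld))
  expect_true(all(calls$del_size > 500))
})

test_that("simulated geometric LD sizes histogram matches truth exactly", {
  dist <- c(UNMODIFIED = 0.5, HDR = 0, IN_FRAME = 0, FRAMESHIFT = 0,
            LD = 0.5, LOA = 0)
  cfg <- sim_config(seed = 83, n_cells = 500, long_read_depth = 4)
  cells <- simulate_cells(sim_config(seed = 83, n_cells = 500,
                                     genotype_distribution = dist),
                          fix_ref)
  reads <- simulate_long_reads(cells, fix_ref, cfg)
  calls <- call_reads(reads, fix_ref)
  s <- ld_summary(calls)
  truth <- table(cut(reads$del_end - reads$del_start,
                     c(200, 500, 2000, Inf), right = FALSE))
  expect_identical(as.integer(s$histogram$n), as.integer(truth))
})

test_that("sequence-level calling agrees with the tabular route", {
  cells <- tibble::tibble(
    cell_id = 1:3, allele = c("GFP", "BFP", "GFP"),
    category = c("UNMODIFIED", "FRAMESHIFT", "LD"),
    kind = c("UNMODIFIED", "DELETION", "DELETION"),
    position = NA_integer_, ins_seq = NA_character_,
    del_start = c(NA, cut, cut), del_end = c(NA, cut + 150L, cut + 1800L))
  cells <- classify_lesions(cells, fix_ref)
  cells$marker <- unname(fix_ref$marker_alleles[cells$allele])
  cfg <- sim_config(seed = 89, n_cells = 3, long_read_depth = 1)
  reads <- simulate_long_reads(cells, fix_ref, cfg)
  tab_calls <- call_reads(reads, fix_ref) |> dplyr::arrange(read_id)

  fa <- tempfile(fileext = ".fasta")
  write_reads_fasta(reads, fix_ref, cells, fa)
  seq_calls <- call_reads_fasta(fa, fix_ref) |> dplyr::arrange(read_id)
  expect_identical(seq_calls$allele, tab_calls$allele)
  expect_identical(seq_calls$is_ld, tab_calls$is_ld)
  expect_equal(seq_calls$del_size, tab_calls$del_size, tolerance = 0)
})
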