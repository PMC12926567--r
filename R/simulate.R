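#' Simulation configuration
#'
#' Bundles every knob of the forward simulator. Defaults emulate a diploid
#' reporter population edited with RNP plus a corrective ssODN donor:
#' per-allele outcome probabilities over unmodified / HDR / in-frame indel /
#' frameshift indel / large deletion (LD) / loss of allele (LOA); optional
#' coupling of the two alleles' outcome categories; a decreasing-frequency
#' (truncated geometric) LD size law on 201..6,000 bp; long-read depth per
#' amplifiable allele; droplet counts and occupancy for the ddPCR stage; and
#' per-class lognormal fluorescence optics with GFP-into-BFP spillover.
#'
#' @param seed Integer seed; mandatory, drives every generator.
#' @param n_cells Number of diploid cells.
#' @param genotype_distribution Named probabilities over
#'   `UNMODIFIED`, `HDR`, `IN_FRAME`, `FRAMESHIFT`, `LD`, `LOA`; must sum
#'   to 1.
#' @param allele_correlation In `[0, 1]`: probability that the second
#'   allele's outcome category copies the first's (0 = independent alleles).
#' @param ld_size_model List with `min`, `max`, `mean`: truncated geometric
#'   deletion-size law (non-increasing mass in size).
#' @param long_read_depth Mean long reads per amplifiable allele.
#' @param n_droplets Droplets per ddPCR channel.
#' @param mean_copies_per_droplet Reference-channel mean copies per droplet.
#' @param optics List with `meanlog` (named per expression class, log-MFI
#'   location), `sdlog`, and `spillover` (additive fraction of the GFP
#'   signal leaking into the BFP channel).
#' @param phenotype_rates Tibble with columns `gfp_class`, `bfp_class`,
#'   `p_hbf`, `p_annexin`: per-genotype-pair positivity rates. Defaults via
#'   [default_phenotype_rates()].
#' @param marker_error_rate Per-base substitution rate applied to the marker
#'   codon of simulated reads (sequencing-noise hook; default 0).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_cells = 5000,
                       genotype_distribution = c(
                         UNMODIFIED = 0.10, HDR = 0.30, IN_FRAME = 0.10,
                         FRAMESHIFT = 0.30, LD = 0.15, LOA = 0.05),
                       allele_correlation = 0,
                       ld_size_model = list(min = 201L, max = 6000L, mean = 900),
                       long_read_depth = 30,
                       n_droplets = 20000,
                       mean_copies_per_droplet = 0.8,
                       optics = default_optics(),
                       phenotype_rates = default_phenotype_rates(),
                       marker_error_rate = 0) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop_allelescope("config_error", "a seed is mandatory")
  }
  p <- genotype_distribution
  needed <- c("UNMODIFIED", "HDR", "IN_FRAME", "FRAMESHIFT", "LD", "LOA")
  if (!all(needed %in% names(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-9) {
    stop_allelescope("config_error",
                     "genotype_distribution must cover all six categories and sum to 1")
  }
  if (allele_correlation < 0 || allele_correlation > 1) {
    stop_allelescope("config_error", "allele_correlation must lie in [0, 1]")
  }
  structure(list(
    seed = as.integer(seed), n_cells = as.integer(n_cells),
    genotype_distribution = p[needed],
    allele_correlation = allele_correlation,
    ld_size_model = ld_size_model,
    long_read_depth = long_read_depth,
    n_droplets = as.integer(n_droplets),
    mean_copies_per_droplet = mean_copies_per_droplet,
    optics = optics, phenotype_rates = phenotype_rates,
    marker_error_rate = marker_error_rate
  ), class = "sim_config")
}

#' Default fluorescence optics
#'
#' Lognormal per-class MFI models on both channels, medians ordered
#' neg < dim < low < med < high with at least 4-fold separation between
#' adjacent classes (30 / 150 / 700 / 3,000 / 13,000 arbitrary MFI units,
#' sdlog 0.35), plus an additive GFP-into-BFP spillover coefficient sized so
#' that spillover from a bright GFP allele is comparable to the BFP dim
#' mode -- the mechanism that collapses the BFP dim and neg populations into
#' four resolvable BFP levels.
#'
#' @param spillover Additive fraction of GFP signal entering the BFP channel.
#' @return List with `meanlog`, `sdlog`, `spillover`.
#' @export
default_optics <- function(spillover = 0.01) {
  list(
    meanlog = log(c(LOA_CLASS = 30, LD = 150, NS_LATE = 700,
                    NS_EARLY = 3000, IN = 13000)),
    sdlog = 0.25,
    spillover = spillover
  )
}

#' Default per-genotype-pair phenotype rates
#'
#' HbF positivity rises with the number of disrupted (non-`IN`) alleles
#' (biallelic HBB disruption relieves gamma-globin competition most), and
#' Annexin V positivity is elevated for genotypes carrying large deletions
#' or allele loss.
#'
#' @return Tibble with `gfp_class`, `bfp_class`, `p_hbf`, `p_annexin`
#'   covering all 25 class pairs.
#' @export
default_phenotype_rates <- function() {
  grid <- tidyr::expand_grid(gfp_class = EXPRESSION_CLASSES,
                             bfp_class = EXPRESSION_CLASSES)
  n_disrupted <- (grid$gfp_class != "IN") + (grid$bfp_class != "IN")
  has_loss <- grid$gfp_class %in% c("LD", "LOA_CLASS") |
    grid$bfp_class %in% c("LD", "LOA_CLASS")
  grid$p_hbf <- c(0.05, 0.35, 0.60)[n_disrupted + 1]
  grid$p_annexin <- ifelse(has_loss, 0.25, c(0.05, 0.10, 0.15)[n_disrupted + 1])
  grid
}

# draw one allele's lesion fields for a drawn outcome category
draw_lesions <- function(category, cut, ref, cfg) {
  n <- length(category)
  kind <- rep("UNMODIFIED", n)
  position <- rep(NA_integer_, n)
  ins_seq <- rep(NA_character_, n)
  del_start <- rep(NA_integer_, n)
  del_end <- rep(NA_integer_, n)

  kind[category == "HDR"] <- "HDR"
  kind[category == "LOA"] <- "LOA"

  i <- which(category == "IN_FRAME")
  if (length(i)) {
    size <- 3L * sample(1:5, length(i), replace = TRUE)
    off <- floor(runif(length(i)) * (size + 1L))  # span covers the cut
    kind[i] <- "DELETION"
    del_start[i] <- cut - size + off
    del_end[i] <- cut + off
  }

  i <- which(category == "FRAMESHIFT")
  if (length(i)) {
    is_del <- runif(length(i)) < 0.6
    del_sizes <- setdiff(1:15, seq(3, 15, 3))
    size <- sample(del_sizes, length(i), replace = TRUE)
    off <- floor(runif(length(i)) * (size + 1L))
    kind[i] <- ifelse(is_del, "DELETION", "INSERTION")
    del_start[i][is_del] <- (cut - size + off)[is_del]
    del_end[i][is_del] <- (cut + off)[is_del]
    # +1/+2 insertions duplicate the base(s) immediately 5' of the cut
    dup <- sample(1:2, length(i), replace = TRUE)
    position[i][!is_del] <- cut
    ins_seq[i][!is_del] <- substring(ref$seq, cut - dup + 1L, cut)[!is_del]
  }

  i <- which(category == "LD")
  if (length(i)) {
    m <- cfg$ld_size_model
    prob <- 1 / (m$mean - m$min + 1)
    size <- m$min + rgeom(length(i), prob)
    resample <- size > m$max
    while (any(resample)) {
      size[resample] <- m$min + rgeom(sum(resample), prob)
      resample <- size > m$max
    }
    lo <- pmax(0L, cut - size)
    hi <- pmin(cut, nchar(ref$seq) - size)
    start <- lo + floor(runif(length(i)) * (hi - lo + 1L))
    kind[i] <- "DELETION"
    del_start[i] <- as.integer(start)
    del_end[i] <- as.integer(start + size)
  }

  tibble(category = category, kind = kind, position = position,
         ins_seq = ins_seq, del_start = del_start, del_end = del_end)
}

#' Simulate a diploid edited cell population
#'
#' Draws per-allele outcome categories from `genotype_distribution` (the
#' second allele copies the first's category with probability
#' `allele_correlation`, otherwise draws independently), realises a concrete
#' lesion for each allele (indels placed across the cut site, LD sizes from
#' the truncated-geometric law, +1/+2 insertions as duplications of the
#' bases 5' of the cut), and annotates every allele with its NS codon and
#' expression class. The GFP allele carries marker codon `TAC`, the BFP
#' allele `CAT`.
#'
#' @param config A [sim_config()].
#' @param ref A [reference_amplicon()]; default [hbb_reference()].
#' @return Tibble with one row per allele: `cell_id`, `allele`
#'   (`GFP`/`BFP`), drawn `category`, lesion columns, `del_size`,
#'   `ns_codon`, `class`.
#' @export
simulate_cells <- function(config, ref = hbb_reference()) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    p <- cfg$genotype_distribution
    n <- cfg$n_cells
    cats <- names(p)
    a1 <- sample(cats, n, replace = TRUE, prob = p)
    a2 <- sample(cats, n, replace = TRUE, prob = p)
    copy <- runif(n) < cfg$allele_correlation
    a2[copy] <- a1[copy]
    cells <- tibble(
      cell_id = rep(seq_len(n), 2L),
      allele = rep(c("GFP", "BFP"), each = n),
      category = c(a1, a2)
    )
    lesions <- draw_lesions(cells$category, ref$cut_site, ref, cfg)
    cells <- dplyr::bind_cols(cells[, c("cell_id", "allele")], lesions)
    cells <- classify_lesions(cells, ref)
    cells$marker <- unname(ref$marker_alleles[cells$allele])
    arrange(cells, .data$cell_id, dplyr::desc(.data$allele))
  })
}

#' Simulate long amplicon reads with truth labels
#'
#' Emits reads from every amplifiable allele (`LOA` alleles emit none) with
#' multinomial per-allele counts at the configured depth. Each read carries
#' the observable features a caller can see: the largest deletion span (in
#' reference coordinates) and the marker codon, which is `NA` when the
#' deletion removes any marker base. Truth columns (`cell_id`, `allele`,
#' `category`, `class`) are retained for recovery testing; callers must use
#' only the observable columns.
#'
#' @param cells Output of [simulate_cells()].
#' @param ref The same [reference_amplicon()] used to simulate.
#' @param config The [sim_config()].
#' @return Tibble with one row per read: `read_id`, observable
#'   `del_start`, `del_end`, `ins_len`, `marker`, plus truth columns.
#' @export
simulate_long_reads <- function(cells, ref, config) {
  cfg <- config
  withr::with_seed(cfg$seed + 1L, {
    amp <- cells[cells$kind != "LOA", ]
    if (nrow(amp) == 0) {
      return(tibble(read_id = character(), del_start = integer(),
                    del_end = integer(), ins_len = integer(),
                    marker = character(), cell_id = integer(),
                    allele = character(), category = character(),
                    class = character()))
    }
    total <- round(cfg$long_read_depth * nrow(amp))
    counts <- as.integer(rmultinom(1, total, rep(1, nrow(amp))))
    idx <- rep(seq_len(nrow(amp)), counts)
    reads <- amp[idx, ]
    mk <- ref$marker_interval
    overlaps <- !is.na(reads$del_start) &
      reads$del_start < mk[2] & reads$del_end > mk[1]
    marker <- if_else(overlaps, NA_character_, reads$marker)
    if (cfg$marker_error_rate > 0) {
      hit <- which(!is.na(marker) & runif(length(marker)) <
                     3 * cfg$marker_error_rate)
      for (j in hit) {
        pos <- sample(3L, 1)
        base <- sample(setdiff(c("A", "C", "G", "T"),
                               substr(marker[j], pos, pos)), 1)
        substr(marker[j], pos, pos) <- base
      }
    }
    tibble(
      read_id = sprintf("read_%06d", seq_along(idx)),
      del_start = reads$del_start, del_end = reads$del_end,
      ins_len = if_else(is.na(reads$ins_seq), 0L,
                        nchar(reads$ins_seq)),
      marker = marker,
      cell_id = reads$cell_id, allele = reads$allele,
      category = reads$category, class = reads$class
    )
  })
}

#' Simulate ddPCR droplet counts
#'
#' Partitions template copies into droplets by Poisson occupancy. The
#' reference channel sees two copies of the diploid reference gene per cell
#' at the configured mean occupancy; the target channel sees only the HBB
#' alleles amplifiable by the short amplicon, which excludes both LD
#' (deletion spanning the cut site longer than 200 bp) and LOA alleles.
#'
#' @param cells Output of [simulate_cells()].
#' @param config The [sim_config()].
#' @return Tibble with columns `channel` (`target`/`reference`),
#'   `positive`, `total`.
#' @export
simulate_droplets <- function(cells, config) {
  cfg <- config
  withr::with_seed(cfg$seed + 2L, {
    n_cells <- length(unique(cells$cell_id))
    n_drop <- cfg$n_droplets
    if (n_cells == 0) {
      return(tibble(channel = c("target", "reference"),
                    positive = c(0L, 0L), total = c(n_drop, n_drop)))
    }
    amplifiable <- cells$kind != "LOA" & cells$del_size <= LD_MIN_SIZE
    lambda_ref <- cfg$mean_copies_per_droplet
    lambda_tgt <- lambda_ref * sum(amplifiable) / (2 * n_cells)
    pos <- function(lam) rbinom(1, n_drop, 1 - exp(-lam))
    tibble(channel = c("target", "reference"),
           positive = c(pos(lambda_tgt), pos(lambda_ref)),
           total = c(n_drop, n_drop))
  })
}

#' Simulate flow-cytometry events
#'
#' Draws each cell's GFP and BFP signals from the lognormal model of its
#' alleles' expression classes, adds the GFP-into-BFP spillover to the BFP
#' channel (the mechanism that blurs the BFP dim/neg boundary), and draws
#' HbF and Annexin V positivity from the per-genotype-pair rates.
#'
#' @param cells Output of [simulate_cells()].
#' @param config The [sim_config()].
#' @return Tibble with one row per cell: `cell_id`, `gfp_mfi`, `bfp_mfi`,
#'   `hbf_pos`, `annexin_pos`, plus truth columns `gfp_class`, `bfp_class`.
#' @export
simulate_flow <- function(cells, config) {
  cfg <- config
  withr::with_seed(cfg$seed + 3L, {
    wide <- tidyr::pivot_wider(cells[, c("cell_id", "allele", "class")],
                               names_from = "allele", values_from = "class")
    names(wide)[names(wide) == "GFP"] <- "gfp_class"
    names(wide)[names(wide) == "BFP"] <- "bfp_class"
    op <- cfg$optics
    n <- nrow(wide)
    gfp_sig <- rlnorm(n, op$meanlog[wide$gfp_class], op$sdlog)
    bfp_sig <- rlnorm(n, op$meanlog[wide$bfp_class], op$sdlog)
    rates <- left_join(wide, cfg$phenotype_rates,
                       by = c("gfp_class", "bfp_class"))
    tibble(
      cell_id = wide$cell_id,
      gfp_mfi = gfp_sig,
      bfp_mfi = bfp_sig + op$spillover * gfp_sig,
      hbf_pos = runif(n) < rates$p_hbf,
      annexin_pos = runif(n) < rates$p_annexin,
      gfp_class = wide$gfp_class, bfp_class = wide$bfp_class
    )
  })
}

#' Derive short-amplicon edit records from simulated cells
#'
#' Produces the TSV-dialect edit records the short-read genotyper consumes
#' (one row per intact allele: `record_id`, `op`, `position`, `length`,
#' `seq`). LD and LOA alleles do not amplify in the short assay and emit no
#' record -- matching the assay the records emulate.
#'
#' @param cells Output of [simulate_cells()].
#' @param ref The [reference_amplicon()] used to simulate.
#' @return Tibble of edit records.
#' @export
simulate_edit_records <- function(cells, ref) {
  intact <- cells[cells$kind != "LOA" & cells$del_size <= LD_MIN_SIZE, ]
  op <- dplyr::case_when(
    intact$kind == "UNMODIFIED" ~ "none",
    intact$kind == "HDR" ~ "sub",
    intact$kind == "DELETION" ~ "del",
    intact$kind == "INSERTION" ~ "ins"
  )
  tibble(
    record_id = sprintf("rec_%06d", seq_len(nrow(intact))),
    op = op,
    position = dplyr::case_when(
      op == "sub" ~ ref$sickle_position,
      op == "del" ~ intact$del_start,
      op == "ins" ~ intact$position,
      TRUE ~ NA_integer_),
    length = dplyr::case_when(
      op == "sub" ~ 1L,
      op == "del" ~ intact$del_size,
      op == "ins" ~ nchar(intact$ins_seq),
      TRUE ~ 0L),
    seq = dplyr::case_when(
      op == "sub" ~ ref$donor_base,
      op == "ins" ~ intact$ins_seq,
      TRUE ~ NA_character_)
  )
}

#' Write simulated reads as FASTA
#'
#' Materialises each read's full sequence: the reference amplicon with the
#' read's allele marker codon substituted and its lesion applied. Mainly
#' for exercising the sequence-level caller ([call_reads_fasta()]) and for
#' export; large simulations normally stay in the tabular representation.
#'
#' @param reads Tibble from [simulate_long_reads()].
#' @param ref The [reference_amplicon()] used to simulate.
#' @param cells The cell table the reads derive from (provides lesion
#'   details per `cell_id`/`allele`).
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_reads_fasta <- function(reads, ref, cells, path) {
  key <- c("cell_id", "allele")
  les <- cells[, c(key, "kind", "position", "ins_seq",
                   "del_start", "del_end", "marker")]
  merged <- left_join(reads[, c("read_id", key)], les, by = key)
  uniq <- distinct(merged[, setdiff(names(merged), c("read_id", key))])
  uniq$seq <- purrr::pmap_chr(uniq, function(kind, position, ins_seq,
                                             del_start, del_end, marker) {
    seq <- ref$seq
    mk <- ref$marker_interval
    substr(seq, mk[1] + 1L, mk[2]) <- marker
    ref2 <- ref
    ref2$seq <- seq
    edit_amplicon(ref2, allele_lesion(
      kind = kind, position = position, ins_seq = ins_seq,
      del_start = del_start, del_end = del_end))$seq
  })
  merged <- left_join(merged, uniq,
                      by = setdiff(names(uniq), "seq"))
  dna <- Biostrings::DNAStringSet(merged$seq)
  names(dna) <- merged$read_id
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}
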