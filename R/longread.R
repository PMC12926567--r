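#' Attribute long reads to alleles via the Y66H marker codon
#'
#' Calls each read's allele of origin: a read whose deletion removes any
#' base of the 3-nt marker codon is a `LOSS_Y66H` read (allele identity
#' unreadable); otherwise the observed marker codon maps `TAC` to `GFP` and
#' `CAT` to `BFP`, and anything else (sequencing noise at the marker) is
#' `AMBIGUOUS`. `del_size` is the single largest deletion per read, and
#' reads with `del_size` > 200 bp carry the `is_ld` flag.
#'
#' @param reads Tibble of reads with observable columns `read_id`,
#'   `del_start`, `del_end` (`NA` when no deletion) and `marker`
#'   (3-nt string, `NA` when deleted), e.g. from [simulate_long_reads()] or
#'   [call_reads_fasta()].
#' @param ref A [reference_amplicon()].
#' @return Tibble of read calls: `read_id`, `allele`
#'   (`GFP`/`BFP`/`LOSS_Y66H`/`AMBIGUOUS`), `del_size`, `is_ld`.
#' @export
call_reads <- function(reads, ref) {
  if (!all(c("read_id", "del_start", "del_end", "marker") %in% names(reads))) {
    stop_allelescope("parse_error",
                     "reads need columns read_id, del_start, del_end, marker")
  }
  mk <- ref$marker_interval
  del_size <- if_else(is.na(reads$del_start), 0L,
                      as.integer(reads$del_end - reads$del_start))
  overlaps <- !is.na(reads$del_start) &
    reads$del_start < mk[2] & reads$del_end > mk[1]
  gfp <- unname(ref$marker_alleles[["GFP"]])
  bfp <- unname(ref$marker_alleles[["BFP"]])
  allele <- dplyr::case_when(
    overlaps | is.na(reads$marker) ~ "LOSS_Y66H",
    reads$marker == gfp ~ "GFP",
    reads$marker == bfp ~ "BFP",
    TRUE ~ "AMBIGUOUS"
  )
  tibble(read_id = reads$read_id, allele = allele,
         del_size = del_size, is_ld = del_size > LD_MIN_SIZE)
}

#' Call reads directly from FASTA sequences
#'
#' Aligns each read globally to the reference amplicon (affine gap
#' penalties, so a single long deletion is preferred over scattered
#' mismatches), extracts the largest deletion span in reference
#' coordinates, reads the marker codon through the alignment, and delegates
#' to [call_reads()]. Intended for modest read sets; large simulations use
#' the tabular route.
#'
#' @param reads A `DNAStringSet` or path to a FASTA file.
#' @param ref A [reference_amplicon()].
#' @return Tibble of read calls, as [call_reads()].
#' @export
call_reads_fasta <- function(reads, ref) {
  if (is.character(reads)) reads <- Biostrings::readDNAStringSet(reads)
  if (length(reads) == 0) stop_allelescope("empty_input", "no reads")
  subject <- Biostrings::DNAString(ref$seq)
  mk <- ref$marker_interval
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  rows <- purrr::map(seq_along(reads), function(i) {
    aln <- Biostrings::pairwiseAlignment(
      reads[[i]], subject, type = "global",
      substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.05)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ref_pos <- cumsum(s != "-")          # 1-based reference coordinate
    is_del <- p == "-" & s != "-"
    del_start <- NA_integer_; del_end <- NA_integer_
    if (any(is_del)) {
      r <- rle(is_del)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      len <- r$lengths[runs]
      k <- runs[which.max(len)]
      del_start <- ref_pos[starts[k]] - 1L   # 0-based
      del_end <- ref_pos[ends[k]]
    }
    cols <- match(seq(mk[1] + 1L, mk[2]), ref_pos * as.integer(s != "-"))
    marker_chars <- p[cols]
    marker <- if (anyNA(cols) || any(marker_chars == "-")) {
      NA_character_
    } else {
      paste(marker_chars, collapse = "")
    }
    tibble(read_id = names(reads)[i] %||% sprintf("read_%d", i),
           del_start = del_start, del_end = del_end, marker = marker)
  })
  call_reads(dplyr::bind_rows(rows), ref)
}

#' Summarise read calls into allele fractions
#'
#' @param calls Tibble of read calls from [call_reads()].
#' @return A `read_fractions` object: one-row tibble with `f_gfp`, `f_bfp`,
#'   `f_loss`, `f_ambiguous`, `n_reads`. The four fractions sum to 1;
#'   ambiguous reads are reported but excluded by the estimator.
#' @export
read_fractions <- function(calls) {
  if (nrow(calls) == 0) stop_allelescope("empty_input", "no read calls")
  n <- nrow(calls)
  out <- tibble(
    f_gfp = sum(calls$allele == "GFP") / n,
    f_bfp = sum(calls$allele == "BFP") / n,
    f_loss = sum(calls$allele == "LOSS_Y66H") / n,
    f_ambiguous = sum(calls$allele == "AMBIGUOUS") / n,
    n_reads = n
  )
  structure(out, class = c("read_fractions", class(out)))
}

#' Estimate the loss-of-allele fraction from distorted read ratios
#'
#' In a diploid population the two marker alleles contribute reads 1:1.
#' Alleles lost entirely (LOA: lesions that abolish amplification) emit no
#' reads, so the affected allele's share shrinks. With all Loss-of-Y66H
#' reads attributed to the affected allele (an upper-bound attribution) and
#' the intact allele serving as internal reference, the affected-side read
#' ratio of a population where a fraction `a` of the affected allele's
#' copies is lost is `r = (1 - a) / (2 - a)`; equivalently, per 100 total
#' alleles, `r = (50 - x) / (100 - x)` with `x = 50 a` lost copies.
#' Inverting gives `a = (1 - 2 r) / (1 - r)`, reported per affected-allele
#' copies. Ambiguous reads are excluded from the ratio.
#'
#' @param fractions A `read_fractions` row, or a named vector/list with
#'   `f_gfp`, `f_bfp`, `f_loss` (optionally `n_reads`).
#' @param affected Which allele the loss is attributed to (`"GFP"` or
#'   `"BFP"`); its reads plus all Loss-of-Y66H reads form the numerator.
#' @param conf_level If non-`NULL`, percentile bootstrap confidence level.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap resampler.
#' @return A `loa_estimate`: list with `estimate` (fraction of the affected
#'   allele's copies lost), `r` (affected-side read ratio), `affected`,
#'   `n_reads`, and optionally `conf_int`.
#' @export
estimate_loa <- function(fractions, affected = c("GFP", "BFP"),
                         conf_level = NULL, n_boot = 1000, seed = NULL) {
  affected <- match.arg(affected)
  f <- as.list(fractions)
  f_aff <- if (affected == "GFP") f$f_gfp else f$f_bfp
  f_other <- if (affected == "GFP") f$f_bfp else f$f_gfp
  f_loss <- f$f_loss %||% 0
  denom <- f_aff + f_other + f_loss
  if (is.na(denom) || denom <= 0) {
    stop_allelescope("domain_error", "no unambiguous reads to estimate from")
  }
  if (f_other <= 0) {
    stop_allelescope("domain_error",
                     "internal-reference condition violated: no reads from the intact allele")
  }
  r <- (f_aff + f_loss) / denom
  if (r >= 1) stop_allelescope("domain_error", "read ratio must be below 1")
  a <- (1 - 2 * r) / (1 - r)
  if (r > 0.5) {
    warn_allelescope("clamp",
                     sprintf("read ratio %.3f exceeds the balanced 0.5; clamping estimate to 0", r))
    a <- 0
  }
  a <- min(max(a, 0), 1)
  est <- structure(list(estimate = a, r = r, affected = affected,
                        n_reads = f$n_reads %||% NA_integer_,
                        conf_int = NULL, conf_level = conf_level),
                   class = "loa_estimate")
  if (!is.null(conf_level)) {
    n <- f$n_reads
    if (is.null(n) || is.na(n)) {
      stop_allelescope("domain_error", "bootstrap CI needs n_reads")
    }
    counts <- round(c(f_aff, f_other, f_loss) * n)
    boot_fun <- function() {
      b <- as.integer(rmultinom(1, sum(counts), counts))
      rb <- (b[1] + b[3]) / sum(b)
      if (rb >= 1) return(NA_real_)
      min(max((1 - 2 * rb) / (1 - rb), 0), 1)
    }
    draws <- if (is.null(seed)) {
      replicate(n_boot, boot_fun())
    } else {
      withr::with_seed(seed, replicate(n_boot, boot_fun()))
    }
    alpha <- (1 - conf_level) / 2
    est$conf_int <- unname(quantile(draws, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  est
}

#' @export
print.loa_estimate <- function(x, ...) {
  cat(sprintf(
    "<loa_estimate> %.1f%% of %s-allele copies lost (read ratio r = %.3f%s)\n",
    100 * x$estimate, x$affected, x$r,
    if (!is.null(x$conf_int)) {
      sprintf("; %d%% CI %.3f-%.3f", round(100 * x$conf_level),
              x$conf_int[1], x$conf_int[2])
    } else ""))
  cat("  all Loss-of-Y66H reads attributed to the affected allele (upper bound)\n")
  invisible(x)
}

#' Summarise large deletions across allele categories
#'
#' Reports, for each allele category of the read calls, the fraction of
#' reads flagged LD (deletion > 200 bp), plus a size histogram of LD reads
#' over configurable bins (defaults: below 500 bp, 500 up to 2,000 bp,
#' above 2,000 bp).
#'
#' @param calls Tibble of read calls from [call_reads()].
#' @param breaks Interior bin boundaries for the LD size histogram.
#' @return List with `by_allele` (tibble: `allele`, `n_reads`, `n_ld`,
#'   `ld_fraction`) and `histogram` (tibble: `bin`, `n`).
#' @export
ld_summary <- function(calls, breaks = c(500, 2000)) {
  if (nrow(calls) == 0) stop_allelescope("empty_input", "no read calls")
  by_allele <- calls |>
    group_by(.data$allele) |>
    summarise(n_reads = n(), n_ld = sum(.data$is_ld),
              ld_fraction = mean(.data$is_ld), .groups = "drop")
  sizes <- calls$del_size[calls$is_ld]
  edges <- c(LD_MIN_SIZE, breaks, Inf)
  labels <- c(paste0("<", breaks[1]),
              if (length(breaks) > 1) {
                paste(breaks[-length(breaks)], breaks[-1], sep = "-")
              },
              paste0(">", breaks[length(breaks)]))
  binned <- cut(sizes, edges, labels = labels, right = FALSE)
  counts <- as.integer(table(factor(binned, levels = labels)))
  hist <- tibble(bin = labels, n = counts)
  if (length(sizes) == 0) hist <- hist[0, ]
  list(by_allele = by_allele, histogram = hist)
}
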