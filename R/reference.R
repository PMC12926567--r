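#' Reference amplicon model
#'
#' A `reference_amplicon` bundles everything downstream stages need to
#' interpret edits on the long-range HBB amplicon: the nucleotide sequence,
#' the coding intervals whose concatenation is the spliced CDS, the Cas9 cut
#' site of the guide the fixture was designed around, the position of the
#' sickle base together with the corrective donor base, and the 3-nt Y66H
#' marker codon that discriminates the GFP-tagged allele (`TAC`) from the
#' BFP-tagged allele (`CAT`).
#'
#' All coordinates are 0-based, half-open; cut sites are inter-base indices
#' (a cut at index `i` falls between bases `i - 1` and `i`).
#'
#' @param seq Amplicon sequence, uppercase ACGT string.
#' @param cds_intervals Integer matrix (or list of pairs) of `[start, end)`
#'   intervals, ascending and non-overlapping; their concatenation must begin
#'   with `ATG` and have length divisible by 3.
#' @param cut_site Inter-base cut index of the designing guide.
#' @param marker_interval `[start, end)` interval of the marker codon
#'   (length 3).
#' @param marker_alleles Named character vector mapping `GFP` and `BFP` to
#'   their marker codons.
#' @param sickle_position 0-based position of the sickle base, or `NA`.
#' @param donor_base Corrective base installed by the HDR donor, or `NA`.
#' @param name Amplicon name.
#'
#' @return An object of class `reference_amplicon`.
#' @export
reference_amplicon <- function(seq, cds_intervals, cut_site, marker_interval,
                               marker_alleles = c(GFP = "TAC", BFP = "CAT"),
                               sickle_position = NA_integer_,
                               donor_base = NA_character_,
                               name = "amplicon") {
  seq <- toupper(seq)
  if (!grepl("^[ACGT]+$", seq)) {
    stop_allelescope("config_error", "amplicon sequence must be uppercase ACGT")
  }
  iv <- cds_intervals
  if (is.list(iv)) iv <- do.call(rbind, lapply(iv, as.integer))
  iv <- matrix(as.integer(iv), ncol = 2,
               dimnames = list(NULL, c("start", "end")))
  if (any(iv[, "end"] <= iv[, "start"]) ||
      is.unsorted(as.vector(t(iv)), strictly = FALSE) ||
      any(iv < 0) || any(iv > nchar(seq))) {
    stop_allelescope("config_error",
                     "cds_intervals must be ascending, non-overlapping, in range")
  }
  cds_len <- sum(iv[, "end"] - iv[, "start"])
  if (cds_len %% 3L != 0L) {
    stop_allelescope("config_error", "spliced CDS length must be divisible by 3")
  }
  marker_interval <- as.integer(marker_interval)
  if (diff(marker_interval) != 3L) {
    stop_allelescope("config_error", "marker_interval must have length 3")
  }
  ref <- structure(list(
    name = name,
    seq = seq,
    cds_intervals = iv,
    cut_site = as.integer(cut_site),
    marker_interval = marker_interval,
    marker_alleles = marker_alleles,
    sickle_position = as.integer(sickle_position),
    donor_base = donor_base
  ), class = "reference_amplicon")
  cds <- spliced_cds(ref)
  if (substr(cds, 1, 3) != "ATG") {
    stop_allelescope("config_error", "spliced CDS must begin with ATG")
  }
  ref
}

#' Extract the spliced coding sequence of a reference amplicon
#'
#' @param ref A [reference_amplicon()].
#' @return Character scalar, the concatenation of the CDS intervals.
#' @export
spliced_cds <- function(ref) {
  iv <- ref$cds_intervals
  paste(substring(ref$seq, iv[, "start"] + 1L, iv[, "end"]), collapse = "")
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat(sprintf("<reference_amplicon> %s: %d bp, CDS %d nt in %d intervals\n",
              x$name, nchar(x$seq),
              sum(x$cds_intervals[, "end"] - x$cds_intervals[, "start"]),
              nrow(x$cds_intervals)))
  cat(sprintf("  cut site %d; marker [%d,%d) %s; sickle base at %d\n",
              x$cut_site, x$marker_interval[1], x$marker_interval[2],
              paste(names(x$marker_alleles), x$marker_alleles,
                    sep = "=", collapse = " "),
              x$sickle_position))
  invisible(x)
}

#' Load a reference amplicon from a FASTA file plus JSON sidecar
#'
#' @param fasta Path to a single-record FASTA file.
#' @param json Path to the JSON sidecar holding coordinates (CDS intervals,
#'   cut site, marker locus and alleles, sickle position).
#' @return A [reference_amplicon()].
#' @export
load_reference <- function(fasta, json) {
  dna <- Biostrings::readDNAStringSet(fasta)
  meta <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  reference_amplicon(
    seq = as.character(dna[[1]]),
    cds_intervals = meta$cds_intervals,
    cut_site = meta$cut_site,
    marker_interval = meta$marker_interval,
    marker_alleles = unlist(meta$marker_alleles),
    sickle_position = meta$sickle_position %||% NA_integer_,
    donor_base = meta$donor_base %||% NA_character_,
    name = meta$name %||% names(dna)[1]
  )
}

#' Built-in sickle HBB reporter amplicon
#'
#' Loads the packaged synthetic 6-kb amplicon modelling the long-range PCR
#' product of the dual-fluorescent sickle reporter line: the HBB coding
#' sequence carrying the sickle mutation (mature codon 6, GAG to GTG),
#' intronic/filler sequence, and the GFP/BFP-discriminating Y66H marker
#' codon placed 1,662 bp downstream of the R-66S cut site. Everything
#' outside the coding/guide/marker loci is synthetic filler.
#'
#' @return A [reference_amplicon()].
#' @export
hbb_reference <- function() {
  load_reference(
    system.file("extdata", "hbb_amplicon.fasta", package = "allelescope"),
    system.file("extdata", "hbb_amplicon.json", package = "allelescope")
  )
}

#' Guide definitions
#'
#' `load_guides()` reads guide definitions from JSON; `hbb_guides()` returns
#' the packaged R-66S and R-02 guides targeting early HBB exon 1. Each guide
#' is a 20-nt protospacer with its NGG PAM and target strand; SpCas9 cuts
#' bluntly 3 nt 5' of the PAM.
#'
#' @param json Path to a JSON array of guide records
#'   (`name`, `protospacer`, `pam`, `strand`).
#' @return A tibble with columns `name`, `protospacer`, `pam`, `strand`.
#' @export
load_guides <- function(json) {
  g <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  as_tibble(g)
}

#' @rdname load_guides
#' @export
hbb_guides <- function() {
  load_guides(system.file("extdata", "hbb_guides.json", package = "allelescope"))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Locate the blunt Cas9 cut site of a guide on a reference
#'
#' Finds the unique occurrence of protospacer+PAM on the stated strand and
#' returns the inter-base cut index 3 nt 5' of the PAM (SpCas9 blunt-cut
#' geometry), in plus-strand amplicon coordinates.
#'
#' @param guide One-row tibble (or list) with `protospacer`, `pam`, `strand`;
#'   e.g. one row of [hbb_guides()].
#' @param ref A [reference_amplicon()].
#' @return Integer inter-base cut index (0-based).
#' @export
locate_cut_site <- function(guide, ref) {
  if (is.data.frame(guide)) {
    if (nrow(guide) != 1) {
      stop_allelescope("config_error", "supply a single guide (one row)")
    }
    guide <- as.list(guide)
  }
  target <- paste0(guide$protospacer, guide$pam)
  pattern <- if (identical(guide$strand, "-")) revcomp(target) else target
  hits <- gregexpr(pattern, ref$seq, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  if (length(hits) == 0) {
    stop_allelescope("not_found",
                     sprintf("guide %s: protospacer+PAM not found on strand %s",
                             guide$name %||% "?", guide$strand))
  }
  if (length(hits) > 1) {
    stop_allelescope("ambiguous_target",
                     sprintf("guide %s: %d protospacer+PAM matches",
                             guide$name %||% "?", length(hits)))
  }
  p <- hits[1] - 1L  # 0-based match start
  if (identical(guide$strand, "-")) {
    # plus-strand layout: [revcomp(PAM) | revcomp(protospacer)]; the cut sits
    # 3 nt into the protospacer from its PAM-proximal (left) end
    p + 3L + 3L
  } else {
    p + 17L
  }
}
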