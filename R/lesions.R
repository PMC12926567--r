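#' Describe a single allele's lesion
#'
#' An `allele_lesion` records one allele's editing outcome on the amplicon:
#' `UNMODIFIED`, `HDR` (corrective substitution at the sickle base),
#' `INSERTION`, `DELETION`, `COMPLEX` (deletion plus inserted sequence at the
#' breakpoint), or `LOA` (loss of allele: the lesion prevents amplification,
#' so no reads or droplets derive from it). Coordinates are 0-based;
#' deletions are `[del_start, del_end)` and are left-aligned (shifted to the
#' smallest equivalent start) before any downstream computation so that
#' homopolymer-adjacent deletions map to reproducible NS positions.
#'
#' @param kind One of `UNMODIFIED`, `HDR`, `INSERTION`, `DELETION`,
#'   `COMPLEX`, `LOA`.
#' @param position Insertion point (inter-base, for `INSERTION`).
#' @param ins_seq Inserted sequence (`INSERTION`/`COMPLEX`).
#' @param del_start,del_end Deletion span (`DELETION`/`COMPLEX`).
#' @return An object of class `allele_lesion`.
#' @export
allele_lesion <- function(kind = c("UNMODIFIED", "HDR", "INSERTION",
                                   "DELETION", "COMPLEX", "LOA"),
                          position = NA_integer_, ins_seq = NA_character_,
                          del_start = NA_integer_, del_end = NA_integer_) {
  kind <- match.arg(kind)
  if (kind %in% c("DELETION", "COMPLEX") &&
      (is.na(del_start) || is.na(del_end) || del_end <= del_start)) {
    stop_allelescope("invalid_lesion", "deletion span required and non-empty")
  }
  if (kind %in% c("INSERTION", "COMPLEX") &&
      (is.na(ins_seq) || nchar(ins_seq) == 0)) {
    stop_allelescope("invalid_lesion", "inserted sequence required")
  }
  if (kind == "INSERTION" && is.na(position)) {
    stop_allelescope("invalid_lesion", "insertion position required")
  }
  structure(list(kind = kind, position = as.integer(position),
                 ins_seq = ins_seq, del_start = as.integer(del_start),
                 del_end = as.integer(del_end)),
            class = "allele_lesion")
}

#' Left-align a deletion
#'
#' Shifts a `[start, end)` deletion to its smallest equivalent start: while
#' the base preceding the span equals the last base of the span, the whole
#' span slides one base left without changing the edited sequence.
#'
#' @param seq Reference sequence the span lies on.
#' @param start,end 0-based half-open deletion span.
#' @return Integer vector `c(start, end)` of the left-aligned span.
#' @export
left_align_deletion <- function(seq, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  while (start > 0L &&
         substr(seq, start, start) == substr(seq, end, end)) {
    start <- start - 1L
    end <- end - 1L
  }
  c(start, end)
}

# Apply a lesion to the full amplicon, remapping CDS and marker intervals.
# Returns list(seq, cds_intervals, marker_interval); a degenerate (deleted)
# marker interval has end <= start.
edit_amplicon <- function(ref, lesion) {
  if (lesion$kind == "LOA") {
    stop_allelescope("invalid_lesion",
                     "LOA alleles yield no amplifiable sequence")
  }
  L <- nchar(ref$seq)
  seq <- ref$seq
  iv <- ref$cds_intervals
  mk <- ref$marker_interval

  apply_del <- function(ds, de) {
    if (ds < 0 || de > L || de <= ds) {
      stop_allelescope("coordinate_error", "deletion span out of range")
    }
    al <- left_align_deletion(seq, ds, de)
    ds <- al[1]; de <- al[2]
    seq <<- paste0(substr(seq, 1, ds), substring(seq, de + 1L))
    shift <- function(x) ifelse(x <= ds, x, ifelse(x >= de, x - (de - ds), ds))
    iv <<- {
      m <- cbind(start = shift(iv[, "start"]), end = shift(iv[, "end"]))
      m[m[, "end"] > m[, "start"], , drop = FALSE]
    }
    mk <<- as.integer(shift(mk))
    ds
  }

  apply_ins <- function(p, s) {
    if (p < 0 || p > nchar(seq)) {
      stop_allelescope("coordinate_error", "insertion position out of range")
    }
    n <- nchar(s)
    seq <<- paste0(substr(seq, 1, p), s, substring(seq, p + 1L))
    # inserted bases join the CDS only when strictly inside a coding interval
    iv <<- cbind(
      start = ifelse(iv[, "start"] >= p, iv[, "start"] + n, iv[, "start"]),
      end = ifelse(iv[, "end"] > p, iv[, "end"] + n, iv[, "end"])
    )
    mk <<- as.integer(c(ifelse(mk[1] >= p, mk[1] + n, mk[1]),
                        ifelse(mk[2] > p, mk[2] + n, mk[2])))
  }

  switch(lesion$kind,
    UNMODIFIED = NULL,
    HDR = {
      p <- ref$sickle_position
      if (is.na(p) || p < 0 || p >= L) {
        stop_allelescope("coordinate_error", "sickle position undefined")
      }
      substr(seq, p + 1L, p + 1L) <- ref$donor_base
    },
    DELETION = apply_del(lesion$del_start, lesion$del_end),
    INSERTION = apply_ins(lesion$position, lesion$ins_seq),
    COMPLEX = {
      ds <- apply_del(lesion$del_start, lesion$del_end)
      apply_ins(ds, lesion$ins_seq)
    }
  )
  list(seq = seq, cds_intervals = iv, marker_interval = mk)
}

#' Apply a lesion and return the edited spliced CDS
#'
#' Applies the lesion to the amplicon (deletions left-aligned first),
#' remaps the coding intervals across the edit, and returns their
#' concatenation. Deleted coding bases shorten the CDS; bases inserted
#' strictly inside a coding interval join it.
#'
#' @param ref A [reference_amplicon()].
#' @param lesion An [allele_lesion()] (kind other than `LOA`).
#' @return Character scalar: the edited spliced CDS.
#' @export
apply_lesion <- function(ref, lesion) {
  ed <- edit_amplicon(ref, lesion)
  iv <- ed$cds_intervals
  paste(substring(ed$seq, iv[, "start"] + 1L, iv[, "end"]), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Map the premature stop (NS) codon of an edited CDS
#'
#' Scans complete codons from the initiator ATG and reports the position of
#' the first stop codon in mature-protein numbering (initiator Met excluded,
#' first post-Met residue = 1; the sickle codon is therefore codon 6). A
#' stop occupying the final in-frame codon of the sequence is the natural
#' terminator, not a premature stop, and yields `NA` -- as does a sequence
#' with no stop at all (a run-off frameshift).
#'
#' @param edited_cds CDS string beginning with ATG.
#' @return Integer mature-protein codon number of the first premature stop,
#'   or `NA_integer_`.
#' @export
ns_codon <- function(edited_cds) {
  n <- nchar(edited_cds)
  if (is.na(edited_cds) || n < 3L) {
    stop_allelescope("invalid_cds", "CDS shorter than one codon")
  }
  if (substr(edited_cds, 1, 3) != "ATG") {
    stop_allelescope("invalid_cds", "CDS must begin with ATG")
  }
  starts <- seq(1L, n - 2L, by = 3L)
  codons <- substring(edited_cds, starts, starts + 2L)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit) == 0) return(NA_integer_)
  k <- hit[1]
  natural <- (n %% 3L == 0L) && (k == length(codons))
  if (natural) NA_integer_ else k - 1L  # codon index incl Met minus the Met
}

#' Assign an expression class to a lesion
#'
#' Maps a lesion to the five-way expression class used throughout:
#' `IN` (no frame change and no premature stop: unmodified, HDR, small
#' in-frame indels), `NS_EARLY` (premature stop before mature codon 19,
#' partial NMD escape, medium fluorescence), `NS_LATE` (stop at or after
#' codon 19, efficient NMD, low fluorescence), `LD` (amplifiable deletion
#' longer than 200 bp, dim fluorescence; takes precedence over NS classes),
#' and `LOA_CLASS` (loss of allele, no expression).
#'
#' @param lesion An [allele_lesion()].
#' @param ref A [reference_amplicon()].
#' @return Character scalar, one of
#'   `c("IN", "NS_EARLY", "NS_LATE", "LD", "LOA_CLASS")`.
#' @export
expression_class <- function(lesion, ref) {
  if (lesion$kind == "LOA") return("LOA_CLASS")
  if (lesion$kind %in% c("DELETION", "COMPLEX") &&
      (lesion$del_end - lesion$del_start) > LD_MIN_SIZE) {
    return("LD")
  }
  if (lesion$kind %in% c("UNMODIFIED", "HDR")) return("IN")
  cds <- apply_lesion(ref, lesion)
  if (substr(cds, 1, 3) != "ATG") {
    # initiator codon destroyed: no productive translation, grouped with
    # the low-expression NS_LATE class
    return("NS_LATE")
  }
  ns <- ns_codon(cds)
  if (is.na(ns)) "IN" else if (ns < NS_LATE_BOUNDARY) "NS_EARLY" else "NS_LATE"
}

# tibble-of-lesions helpers -------------------------------------------------

lesion_from_row <- function(row) {
  allele_lesion(kind = row$kind, position = row$position,
                ins_seq = row$ins_seq, del_start = row$del_start,
                del_end = row$del_end)
}

#' Annotate a tibble of lesions with NS codon and expression class
#'
#' Vectorised companion to [expression_class()]: takes a tibble with lesion
#' columns (`kind`, `position`, `ins_seq`, `del_start`, `del_end`) and adds
#' `del_size`, `ns_codon` and `class`. Distinct lesions are classified once
#' and joined back, so large simulated populations with a small lesion
#' spectrum classify quickly.
#'
#' @param lesions Tibble of lesion rows.
#' @param ref A [reference_amplicon()].
#' @return The input tibble with `del_size`, `ns_codon`, `class` columns.
#' @export
classify_lesions <- function(lesions, ref) {
  key <- c("kind", "position", "ins_seq", "del_start", "del_end")
  uniq <- distinct(lesions[, key])
  ann <- purrr::pmap(uniq, function(kind, position, ins_seq, del_start, del_end) {
    les <- allele_lesion(kind = kind, position = position, ins_seq = ins_seq,
                         del_start = del_start, del_end = del_end)
    cls <- expression_class(les, ref)
    ns <- NA_integer_
    if (cls %in% c("NS_EARLY", "NS_LATE")) {
      ns <- ns_codon(apply_lesion(ref, les))
    }
    tibble(ns_codon = ns, class = cls)
  })
  uniq <- dplyr::bind_cols(uniq, dplyr::bind_rows(ann))
  out <- left_join(lesions, uniq, by = key)
  out$del_size <- if_else(is.na(out$del_start), 0L, out$del_end - out$del_start)
  out
}
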