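#' Classify short-amplicon edit records
#'
#' Consumes the simple TSV dialect of per-allele edit records
#' (`record_id`, `op` in `none`/`sub`/`del`/`ins`, `position`, `length`,
#' `seq`) and assigns each record to `HDR`, `UNMODIFIED`, `IN_FRAME` or
#' `FRAMESHIFT`. A record is `HDR` when its substitution installs the
#' corrective donor base at the sickle position and no indel lies within
#' 10 bp of the cut (single-op records encode that condition implicitly);
#' any other substitution-only or empty record is `UNMODIFIED`; indels are
#' classified by frame, deletions being left-aligned first, and frameshifts
#' carry the NS codon mapped on the reconstructed coding sequence.
#'
#' @param records Tibble of edit records.
#' @param ref A [reference_amplicon()].
#' @param guide Guide row used to locate the cut (defaults to the cut site
#'   stored on `ref`).
#' @return The records tibble with `class` and `ns_codon` columns.
#' @export
classify_edit_records <- function(records, ref, guide = NULL) {
  needed <- c("record_id", "op", "position", "length", "seq")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop_allelescope("parse_error",
                     "records need columns record_id, op, position, length, seq")
  }
  if (!all(records$op %in% c("none", "sub", "del", "ins"))) {
    stop_allelescope("parse_error", "op must be one of none/sub/del/ins")
  }
  cut <- if (is.null(guide)) ref$cut_site else locate_cut_site(guide, ref)

  classify_one <- function(op, position, length, seq) {
    if (op == "none") return(list(class = "UNMODIFIED", ns = NA_integer_))
    if (op == "sub") {
      hdr <- !is.na(ref$sickle_position) && position == ref$sickle_position &&
        identical(seq, ref$donor_base)
      return(list(class = if (hdr) "HDR" else "UNMODIFIED", ns = NA_integer_))
    }
    lesion <- if (op == "del") {
      allele_lesion("DELETION", del_start = position,
                    del_end = position + length)
    } else {
      allele_lesion("INSERTION", position = position, ins_seq = seq)
    }
    if (length %% 3L == 0L) {
      return(list(class = "IN_FRAME", ns = NA_integer_))
    }
    ns <- ns_codon(apply_lesion(ref, lesion))
    list(class = "FRAMESHIFT", ns = ns)
  }

  uniq <- distinct(records[, c("op", "position", "length", "seq")])
  ann <- purrr::pmap(uniq, function(op, position, length, seq) {
    r <- classify_one(op, position, length, seq)
    tibble(class = r$class, ns_codon = r$ns)
  })
  uniq <- dplyr::bind_cols(uniq, dplyr::bind_rows(ann))
  left_join(records, uniq, by = c("op", "position", "length", "seq"))
}

#' Build a per-class allelic fraction table
#'
#' Tabulates classified records into fractions over
#' `UNMODIFIED` / `HDR` / `IN_FRAME` / `FRAMESHIFT` / `LD` on the
#' `intact_alleles` basis (the denominator is the amplifiable alleles the
#' short assay sees, so the `LD` entry is 0 until
#' [normalize_to_total_alleles()] folds in the drop-off fraction).
#'
#' @param records Classified records (output of [classify_edit_records()]),
#'   or a character vector of classes.
#' @return A `fraction_table`: tibble with `class` and `fraction`, carrying
#'   `basis` and `n` attributes.
#' @export
fraction_table <- function(records) {
  classes <- if (is.data.frame(records)) records$class else records
  if (length(classes) == 0) {
    stop_allelescope("empty_input", "no records to tabulate")
  }
  lev <- c("UNMODIFIED", "HDR", "IN_FRAME", "FRAMESHIFT", "LD")
  counts <- table(factor(classes, levels = lev))
  out <- tibble(class = lev, fraction = as.numeric(counts) / length(classes))
  structure(out, class = c("fraction_table", class(out)),
            basis = "intact_alleles", n = length(classes))
}

#' Renormalize intact-allele fractions to all alleles
#'
#' Rescales a fraction table measured on amplifiable (intact) alleles to the
#' total-allele basis using the ddPCR drop-off fraction: every intact-class
#' fraction is multiplied by `1 - ld_fraction` and the `LD` entry becomes
#' `ld_fraction` (the drop-off pools large deletions and allele loss, which
#' the short assay cannot distinguish). Output fractions sum to 1.
#'
#' @param table A `fraction_table` on the `intact_alleles` basis.
#' @param ld_fraction Drop-off fraction in `[0, 1)`, e.g. from
#'   [dropoff_fraction()].
#' @return A `fraction_table` on the `total_alleles` basis.
#' @export
normalize_to_total_alleles <- function(table, ld_fraction) {
  if (!inherits(table, "fraction_table") ||
      !identical(attr(table, "basis"), "intact_alleles")) {
    stop_allelescope("domain_error",
                     "table must be a fraction_table on the intact_alleles basis")
  }
  if (is.numeric(ld_fraction) && inherits(ld_fraction, "dropoff_estimate")) {
    ld_fraction <- ld_fraction$dropoff
  }
  if (!is.numeric(ld_fraction) || ld_fraction < 0 || ld_fraction >= 1) {
    stop_allelescope("domain_error", "ld_fraction must lie in [0, 1)")
  }
  out <- table
  intact <- out$class != "LD"
  out$fraction[intact] <- out$fraction[intact] * (1 - ld_fraction)
  out$fraction[!intact] <- ld_fraction
  attr(out, "basis") <- "total_alleles"
  out
}

#' @export
print.fraction_table <- function(x, ...) {
  cat(sprintf("<fraction_table> basis = %s, n = %s\n",
              attr(x, "basis"), attr(x, "n") %||% "?"))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Read / write edit records as TSV
#'
#' @param path File path.
#' @param records Tibble of edit records.
#' @return `read_edit_records()` returns the records tibble.
#' @export
read_edit_records <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    record_id = readr::col_character(),
                    op = readr::col_character(),
                    position = readr::col_integer(),
                    length = readr::col_integer(),
                    seq = readr::col_character()))
}

#' @rdname read_edit_records
#' @export
write_edit_records <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}
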