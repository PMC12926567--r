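# shared fixture objects and independent oracles used across test files

fix_ref <- hbb_reference()
fix_guides <- hbb_guides()
fix_cds <- spliced_cds(fix_ref)

# brute-force scan for protospacer+PAM by direct substring comparison;
# returns all 0-based cut indices implied by blunt-cut geometry
oracle_scan_cuts <- function(protospacer, pam, strand, seq) {
  target <- paste0(protospacer, pam)
  if (strand == "-") {
    target <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(target)))
  }
  w <- nchar(target)
  hits <- integer(0)
  for (i in seq_len(nchar(seq) - w + 1)) {
    if (substr(seq, i, i + w - 1) == target) hits <- c(hits, i - 1L)
  }
  if (strand == "-") hits + 6L else hits + 17L
}

# independent premature-stop oracle: Biostrings translation, first '*'
# before the in-frame terminal codon (mature numbering, Met excluded)
oracle_first_stop <- function(cds) {
  n <- nchar(cds)
  usable <- 3L * (n %/% 3L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, usable)),
    if.fuzzy.codon = "solve"))
  k <- regexpr("*", aa, fixed = TRUE)[[1]]
  if (k < 0) return(NA_integer_)
  if (n %% 3L == 0L && k == nchar(aa)) return(NA_integer_)
  k - 1L
}

# independent string-surgery oracle for edits confined to exon 1 of the
# fixture: edits the spliced CDS directly (coding exon 1 spans amplicon
# [600, 692) = CDS [0, 92))
oracle_exon1_edit <- function(cds, lesion) {
  to_cds <- function(x) x - 600L
  if (lesion$kind == "DELETION") {
    s <- to_cds(lesion$del_start)
    e <- to_cds(lesion$del_end)
    while (s > 0 && substr(cds, s, s) == substr(cds, e, e)) {
      s <- s - 1L
      e <- e - 1L
    }
    paste0(substr(cds, 1, s), substring(cds, e + 1L))
  } else {
    p <- to_cds(lesion$position)
    paste0(substr(cds, 1, p), lesion$ins_seq, substring(cds, p + 1L))
  }
}

# random exon-1 indel generator for property tests (spans stay inside the
# coding part of exon 1 so the string-surgery oracle applies)
random_exon1_lesions <- function(n, seed) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      size <- sample(1:30, 1)
      if (runif(1) < 0.5) {
        # keep the initiator ATG (amplicon 600..602) intact
        start <- sample(603:(692 - size), 1)
        allele_lesion("DELETION", del_start = start, del_end = start + size)
      } else {
        pos <- sample(603:691, 1)
        ins <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
                     collapse = "")
        allele_lesion("INSERTION", position = pos, ins_seq = ins)
      }
    })
  })
}

# quick single-class cell table builder (bypasses the category sampler)
make_cells <- function(gfp_kinds, bfp_kinds, ref = fix_ref, ...) {
  n <- length(gfp_kinds)
  stopifnot(length(bfp_kinds) == n)
  build <- function(kinds, allele) {
    tibble::tibble(
      cell_id = seq_len(n), allele = allele, category = kinds,
      kind = kinds, position = NA_integer_, ins_seq = NA_character_,
      del_start = NA_integer_, del_end = NA_integer_
    )
  }
  cells <- dplyr::bind_rows(build(gfp_kinds, "GFP"), build(bfp_kinds, "BFP"))
  cells <- classify_lesions(cells, ref)
  cells$marker <- unname(ref$marker_alleles[cells$allele])
  cells
}
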