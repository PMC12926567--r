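# One-time generator for the packaged synthetic fixture (inst/extdata).
# Everything outside the coding/guide/marker coordinates is random filler;
# re-running reproduces the frozen files byte-identically.
set.seed(66021)
CDS_WT <- paste0(
"ATGGTGCATCTGACTCCTGAGGAGAAGTCTGCCGTTACTGCCCTGTGGGGCAAGGTGAACGTGGATGAAGTTGGTGGTGAGGCCCTGGGCAGG",
"CTGCTGGTGGTCTACCCTTGGACCCAGAGGTTCTTTGAGTCCTTTGGGGATCTGTCCACTCCTGATGCTGTTATGGGCAACCCTAAGGTGAAG",
"GCTCATGGCAAGAAAGTGCTCGGTGCCTTTAGTGATGGCCTGGCTCACCTGGACAACCTCAAGGGCACCTTTGCCACACTGAGTGAGCTGCAC",
"TGTGACAAGCTGCACGTGGATCCTGAGAACTTCAGGCTCCTGGGCAACGTGCTGGTCTGTGTGCTGGCCCATCACTTTGGCAAAGAATTCACC",
"CCACCAGTGCAGGCTGCCTATCAGAAAGTGGTGGCTGGTGTGGCTAATGCCCTGGCCCACAAGTATCACTAA")
stopifnot(nchar(CDS_WT) == 444)
# sickle: mature codon 6 (codon 7 incl Met), nt 19 (1-based 20) A->T: GAG->GTG
cds <- CDS_WT
substr(cds, 20, 20) <- "T"
stopifnot(substr(cds, 19, 21) == "GTG")
rand <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")
pad5    <- rand(600)
intron1 <- rand(130)
intron2 <- rand(850)
ex1 <- substr(cds, 1, 92); ex2 <- substr(cds, 93, 315); ex3 <- substr(cds, 316, 444)
body <- paste0(pad5, ex1, intron1, ex2, intron2, ex3)
stopifnot(nchar(body) == 2024)
# marker TAC at [2283,2286) (0-based): cut 621 + 1662
gap <- rand(2283 - 2024)
tail_len <- 6000 - 2286
amp <- paste0(body, gap, "TAC", rand(tail_len))
stopifnot(nchar(amp) == 6000)
# checks: guides unique on stated strand, marker only at intended locus context
g66_plus <- "CCTGTGGAGAAGTCTGCCGTTAC"  # revcomp(PAM)+revcomp(protospacer)
g02_plus <- "GTCTGCCGTTACTGCCCTGTGGG"   # protospacer+PAM
cnt <- function(p, x) length(gregexpr(p, x, fixed = TRUE)[[1]][gregexpr(p, x, fixed=TRUE)[[1]] > 0])
stopifnot(cnt(g66_plus, amp) == 1, cnt(g02_plus, amp) == 1)
stopifnot(regexpr(g66_plus, amp, fixed=TRUE)[[1]] == 616)  # 0-based 615 -> cut 621
stopifnot(substr(amp, 2284, 2286) == "TAC")
stopifnot(substr(amp, 620, 620) == "T")  # sickle base (0-based 619)
# write FASTA (wrapped) + JSON sidecars
lines <- c(">HBB_GFP_amplicon synthetic 6-kb allele-resolved editing fixture",
           {st <- seq(1, 6000, 80); substring(amp, st, pmin(st + 79, 6000))})
writeLines(lines, "/root/pkg/inst/extdata/hbb_amplicon.fasta")
writeLines(jsonlite::toJSON(list(
  name = "HBB_GFP_amplicon",
  length = 6000L,
  cds_intervals = list(c(600L, 692L), c(822L, 1045L), c(1895L, 2024L)),
  cut_site = 621L,
  sickle_position = 619L,
  donor_base = "A",
  marker_interval = c(2283L, 2286L),
  marker_alleles = list(GFP = "TAC", BFP = "CAT")
), auto_unbox = TRUE, pretty = TRUE), "/root/pkg/inst/extdata/hbb_amplicon.json")
writeLines(jsonlite::toJSON(list(
  list(name = "R-66S", protospacer = "GTAACGGCAGACTTCTCCAC", pam = "AGG", strand = "-"),
  list(name = "R-02",  protospacer = "GTCTGCCGTTACTGCCCTGT", pam = "GGG", strand = "+")
), auto_unbox = TRUE, pretty = TRUE), "/root/pkg/inst/extdata/hbb_guides.json")
cat("fixture written\n")
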