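# per 3' UTR SNP calling and haplotype classification.
#
# Six sites are scored in the Australian material: SNP1-SNP4 plus Af1 and Af3.
# SNP2 and Af1 fall inside the dmpi8 intron, SNP1 is 5' of it and Af3 3' of
# it. Classification rule: SNP3 = G is dominant and defines its own class
# (all SNP3G lines share one sequence); among SNP3 = A lines the
# SNP1/SNP2/Af1/Af3 string "C/A/T/T" is the major tropical haplotype
# (p3'AusTrop), "T/T/C/A" the major temperate one (p3'AusTemp), and any other
# combination is reported verbatim as "other:<string>".
#
# Real-data use requires site offsets taken from a supplementary reference;
# the bundled reference (utr_reference()) is synthetic: a fixed 497-bp
# sequence with arbitrary offsets that respect the published intron topology.

HAPLO_SITES <- c("SNP1", "SNP2", "SNP3", "SNP4", "Af1", "Af3")

#' Synthetic per 3' UTR reference
#'
#' A deterministic 497-bp stand-in for the UTR span (the real span runs from
#' gene position 6872 to 7368), carrying a dmpi8-like intron with fixed
#' suboptimal 5'/3' splice-site substrings and the six scored SNP sites at
#' arbitrary offsets consistent with the published topology (SNP2 and Af1
#' inside the intron, SNP1 upstream, Af3 downstream). The reference alleles
#' are those of the SNP3G haplotype. Offsets are 0-based internally;
#' `gene_coord = offset + 6872` is also reported for cross-reference.
#'
#' @return list with `seq` (character), `snps` (data.frame: `name`, `offset`,
#'   `gene_coord`, `ref`, `alt`), `intron` (0-based half-open span),
#'   `ss5`/`ss3` (splice-site substrings and their spans), `origin` (gene-numbering
#'   coordinate of position 0).
#' @export
utr_reference <- function() {
  base <- c("A", "C", "G", "T")
  # deterministic pseudo-random background, independent of the session RNG
  idx <- (cumsum(rep_len(c(7, 1, 3, 5, 1, 7, 3, 1, 5, 3), 497)) %% 4) + 1
  s <- base[idx]
  intron <- c(160L, 249L)              # [160, 249): 89-nt intron
  ss5 <- "GTATGT"                      # weak donor (canonical GT retained)
  ss3 <- "TTGCAG"                      # weak acceptor (canonical AG retained)
  s[(intron[1] + 1):(intron[1] + 6)] <- strsplit(ss5, "")[[1]]
  s[(intron[2] - 5):intron[2]] <- strsplit(ss3, "")[[1]]
  snps <- data.frame(
    name = HAPLO_SITES,
    offset = c(120L, 200L, 310L, 400L, 230L, 330L),
    ref = c("T", "T", "G", "C", "C", "A"),
    alt = c("C", "A", "A", "T", "T", "T"),
    stringsAsFactors = FALSE)
  snps$gene_coord <- snps$offset + 6872L
  s[snps$offset + 1] <- snps$ref
  list(seq = paste(s, collapse = ""), snps = snps, intron = intron,
       ss5 = list(seq = ss5, span = c(intron[1], intron[1] + 6L)),
       ss3 = list(seq = ss3, span = c(intron[2] - 6L, intron[2])),
       origin = 6872L)
}

#' Haplotype definitions of the synthetic Australian cohort
#'
#' The six haplotype classes with their alleles at the scored sites and the
#' regional line counts used by the deterministic generator. The printed
#' constraints are honoured exactly: 42 lines, 12 SNP3G (one shared sequence),
#' C/A/T/T in 9 tropical + 2 temperate lines, T/T/C/A in 3 tropical + 6
#' temperate lines, six classes in total. The split of the remaining ten
#' SNP3A lines across three minor haplotypes is synthetic (the source figure
#' is not machine-readable), chosen to match the regional margins (25
#' tropical, 17 temperate).
#'
#' @return data.frame: `haplotype`, alleles at the six sites, `n_tropical`,
#'   `n_temperate`.
#' @export
australian_haplotypes <- function() {
  h <- rbind(
    c("SNP3G",   "T", "T", "G", "C", "C", "A", 8, 4),
    c("C/A/T/T", "C", "A", "A", "T", "T", "T", 9, 2),
    c("T/T/C/A", "T", "T", "A", "T", "C", "A", 3, 6),
    c("C/A/C/A", "C", "A", "A", "T", "C", "A", 3, 1),
    c("T/T/T/T", "T", "T", "A", "T", "T", "T", 1, 2),
    c("C/T/C/A", "C", "T", "A", "T", "C", "A", 1, 2))
  out <- data.frame(haplotype = h[, 1], stringsAsFactors = FALSE)
  out[HAPLO_SITES] <- h[, 2:7]
  out$n_tropical <- as.integer(h[, 8])
  out$n_temperate <- as.integer(h[, 9])
  out
}

.as_seq_char <- function(sequence) {
  if (inherits(sequence, "DNAString") || inherits(sequence, "DNAStringSet"))
    sequence <- as.character(sequence)
  toupper(as.character(sequence)[1])
}

#' Call alleles at the scored SNP sites
#'
#' Reads the base at each scored offset of a UTR sequence. The sequence must
#' match the reference length (substitution-only; indel-bearing sequences are
#' an alignment error). A base outside a site's allele set is reported as an
#' unknown allele, never coerced; IUPAC ambiguity codes are an error.
#'
#' @param sequence character or `Biostrings::DNAString`.
#' @param reference a [utr_reference()]-style list.
#' @return named character vector of alleles (one per scored site), with
#'   attribute `unknown` naming sites whose base is outside the allele set.
#' @export
call_snps <- function(sequence, reference = utr_reference()) {
  s <- .as_seq_char(sequence)
  if (nchar(s) != nchar(reference$seq))
    stop("alignment error: sequence length ", nchar(s),
         " != reference length ", nchar(reference$seq),
         " (indels are not scored)")
  bases <- substring(s, reference$snps$offset + 1, reference$snps$offset + 1)
  if (any(!bases %in% c("A", "C", "G", "T")))
    stop("ambiguity code at scored site ",
         reference$snps$name[which(!bases %in% c("A", "C", "G", "T"))[1]])
  names(bases) <- reference$snps$name
  unknown <- reference$snps$name[!(bases == reference$snps$ref |
                                     bases == reference$snps$alt)]
  attr(bases, "unknown") <- unknown
  bases
}

#' Classify a haplotype from called alleles
#'
#' @param alleles named character vector with at least SNP1, SNP2, SNP3, Af1,
#'   Af3 (as from [call_snps()]).
#' @return class label: `"SNP3G"`, `"C/A/T/T"` (the major tropical class),
#'   `"T/T/C/A"` (the major temperate class), or `"other:<string>"`.
#' @export
classify_haplotype <- function(alleles) {
  need <- c("SNP1", "SNP2", "SNP3", "Af1", "Af3")
  if (!all(need %in% names(alleles)) || anyNA(alleles[need]))
    stop("missing allele at: ",
         paste(setdiff(need, names(alleles)[!is.na(alleles)]), collapse = ", "))
  if (alleles[["SNP3"]] == "G") return("SNP3G")
  s <- paste(alleles[["SNP1"]], alleles[["SNP2"]], alleles[["Af1"]],
             alleles[["Af3"]], sep = "/")
  if (s %in% c("C/A/T/T", "T/T/C/A")) s else paste0("other:", s)
}

#' Check the dmpi8 splice sites of a sequence
#'
#' All natural UTR sequences share identical suboptimal 5' and 3' splice
#' sites; this verifies a sequence against the canonical substrings.
#'
#' @inheritParams call_snps
#' @return `TRUE` if both sites match; otherwise `FALSE` with attribute
#'   `report` naming the mismatching site(s) and positions.
#' @export
check_splice_sites <- function(sequence, reference = utr_reference()) {
  s <- .as_seq_char(sequence)
  if (nchar(s) < reference$intron[2])
    stop("intron not locatable: sequence shorter than the intron span")
  got5 <- substring(s, reference$ss5$span[1] + 1, reference$ss5$span[2])
  got3 <- substring(s, reference$ss3$span[1] + 1, reference$ss3$span[2])
  bad <- character()
  if (got5 != reference$ss5$seq)
    bad <- c(bad, sprintf("5'ss at offset %d: %s != %s",
                          reference$ss5$span[1], got5, reference$ss5$seq))
  if (got3 != reference$ss3$seq)
    bad <- c(bad, sprintf("3'ss at offset %d: %s != %s",
                          reference$ss3$span[1], got3, reference$ss3$seq))
  ok <- length(bad) == 0
  attr(ok, "report") <- bad
  ok
}

#' Call and classify haplotypes for a whole FASTA
#'
#' @param fasta path to a FASTA file or a `Biostrings::DNAStringSet`. Record
#'   ids of the form `<line>|<region>` (as written by the generator) populate
#'   the region column; otherwise supply `regions`.
#' @param reference a [utr_reference()]-style list.
#' @param regions optional named character vector line_id -> region.
#' @return data.frame: `line_id`, `region`, the six allele columns,
#'   `haplotype`, `splice_sites_ok`.
#' @export
call_haplotypes <- function(fasta, reference = utr_reference(), regions = NULL) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  ids <- names(seqs)
  parts <- strsplit(ids, "|", fixed = TRUE)
  line_id <- vapply(parts, `[`, "", 1)
  region <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  if (!is.null(regions)) region <- unname(regions[line_id])
  rows <- lapply(seq_along(seqs), function(i) {
    al <- call_snps(seqs[[i]], reference)
    d <- as.data.frame(as.list(al), stringsAsFactors = FALSE)
    d$line_id <- line_id[i]
    d$region <- region[i]
    d$haplotype <- classify_haplotype(al)
    d$splice_sites_ok <- as.logical(check_splice_sites(seqs[[i]], reference))
    d
  })
  out <- do.call(rbind, rows)
  out[, c("line_id", "region", HAPLO_SITES, "haplotype", "splice_sites_ok")]
}

#' Build the 2x2 class-by-region contingency table
#'
#' Counts lines of the two focal haplotype classes in the two regions; lines
#' of any other class are excluded. Input order does not affect the table.
#'
#' @param calls data.frame with `haplotype` and `region` columns (as from
#'   [call_haplotypes()]).
#' @param classes two class labels (rows); default the major tropical and
#'   temperate haplotypes.
#' @param regions two region labels (columns).
#' @return 2x2 integer matrix with dimnames.
#' @export
build_contingency <- function(calls, classes = c("C/A/T/T", "T/T/C/A"),
                              regions = c("tropical", "temperate")) {
  stopifnot(length(classes) == 2, length(regions) == 2)
  sel <- calls$haplotype %in% classes & calls$region %in% regions
  if (!any(sel)) stop("no lines of the requested classes/regions")
  tab <- table(factor(calls$haplotype[sel], levels = classes),
               factor(calls$region[sel], levels = regions))
  m <- matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
  m
}
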