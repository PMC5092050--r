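#' Construct a gene model from a coding sequence and exon segmentation
#'
#' A gene model bundles a coding sequence (CDS, coding orientation, including
#' the terminal stop codon) with its exon segmentation expressed in 1-based
#' CDS coordinates. All downstream operations (theoretical change enumeration,
#' exon assignment of observed mutations, frameshift stop mapping) work in this
#' coordinate space; genomic coordinates and strand are deliberately out of
#' scope.
#'
#' @param cds Single character string over A/C/G/T. Length must be a multiple
#'   of three and translation must end with exactly one stop codon, located at
#'   the final codon.
#' @param exons Data frame with columns `exon_label` (integer), `cds_start`,
#'   `cds_end` (1-based, inclusive). Segments must be non-overlapping, strictly
#'   increasing, and exactly cover `1..nchar(cds)`.
#' @param symbol Gene identifier string.
#'
#' @return An object of class `gene_model` with elements `symbol`, `cds`,
#'   `exons`, and `protein_length` (residue count excluding the stop).
#' @examples
#' m <- gene_model("ATGAAATAA", data.frame(exon_label = 1, cds_start = 1, cds_end = 9))
#' m$protein_length  # 2
#' @export
gene_model <- function(cds, exons, symbol = "GENE") {
  if (!is.character(cds) || length(cds) != 1L || is.na(cds)) {
    stop("'cds' must be a single character string")
  }
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) {
    stop("malformed sequence: CDS contains characters outside A/C/G/T")
  }
  L <- nchar(cds)
  if (L %% 3L != 0L) {
    stop("CDS length (", L, ") is not a multiple of 3")
  }
  aa <- .translate_codons(cds)
  n_codon <- length(aa)
  if (aa[n_codon] != "*") {
    stop("CDS does not end in a stop codon (last codon translates to '",
         aa[n_codon], "')")
  }
  if (any(aa[-n_codon] == "*")) {
    stop("CDS contains an internal stop codon at codon ",
         which(aa[-n_codon] == "*")[1L])
  }

  req <- c("exon_label", "cds_start", "cds_end")
  if (!is.data.frame(exons) || !all(req %in% names(exons))) {
    stop("'exons' must be a data frame with columns exon_label, cds_start, cds_end")
  }
  exons <- exons[order(exons$cds_start), req, drop = FALSE]
  exons$exon_label <- as.integer(exons$exon_label)
  exons$cds_start <- as.integer(exons$cds_start)
  exons$cds_end <- as.integer(exons$cds_end)
  if (anyNA(exons)) stop("exon table contains missing values")
  if (any(exons$cds_start > exons$cds_end)) {
    stop("exon table has a segment with cds_start > cds_end")
  }
  if (anyDuplicated(exons$exon_label)) stop("duplicated exon labels")
  if (exons$cds_start[1L] != 1L) {
    stop("exon segments do not cover the CDS: first segment starts at ",
         exons$cds_start[1L], ", expected 1")
  }
  if (exons$cds_end[nrow(exons)] != L) {
    stop("exon segments do not cover the CDS: last segment ends at ",
         exons$cds_end[nrow(exons)], ", expected ", L)
  }
  if (nrow(exons) > 1L) {
    nxt <- exons$cds_start[-1L]
    prv <- exons$cds_end[-nrow(exons)]
    if (any(nxt > prv + 1L)) stop("exon table has a gap after position ",
                                  prv[which(nxt > prv + 1L)[1L]])
    if (any(nxt < prv + 1L)) stop("exon table has overlapping segments near position ",
                                  nxt[which(nxt < prv + 1L)[1L]])
  }

  exon_by_pos <- rep.int(exons$exon_label, exons$cds_end - exons$cds_start + 1L)
  starts <- 3L * seq_len(n_codon) - 2L
  structure(
    list(symbol = symbol,
         cds = cds,
         exons = exons,
         protein_length = n_codon - 1L,
         .exon_by_pos = exon_by_pos,
         .codons = substring(cds, starts, starts + 2L),
         .protein = aa),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$symbol, ": CDS ", nchar(x$cds), " nt, ",
      x$protein_length, " aa, ", nrow(x$exons), " exon segment(s) [",
      paste(x$exons$exon_label, collapse = ","), "]\n", sep = "")
  invisible(x)
}

#' Load a gene model from a FASTA CDS and an exon-map TSV
#'
#' @param cds_path Path to a single-record FASTA file holding the CDS.
#' @param exon_table_path Path to a TSV with header
#'   `exon_label<TAB>cds_start<TAB>cds_end` (1-based inclusive CDS coordinates).
#' @param symbol Gene symbol; defaults to the first word of the FASTA header.
#' @return A validated [gene_model].
#' @examples
#' m <- load_gene_model(
#'   system.file("extdata", "tp53_cds.fa", package = "mutenrich"),
#'   system.file("extdata", "tp53_exons.tsv", package = "mutenrich"))
#' m$protein_length  # 393
#' @export
load_gene_model <- function(cds_path, exon_table_path, symbol = NULL) {
  seqs <- Biostrings::readDNAStringSet(cds_path)
  if (length(seqs) != 1L) {
    stop("expected exactly one FASTA record in '", cds_path, "', found ",
         length(seqs))
  }
  if (is.null(symbol)) {
    symbol <- strsplit(names(seqs)[1L], "[ \t]")[[1L]][1L]
  }
  exons <- utils::read.delim(exon_table_path, sep = "\t",
                             stringsAsFactors = FALSE)
  gene_model(as.character(seqs[[1L]]), exons, symbol = symbol)
}

#' The packaged TP53 gene model
#'
#' Loads the TP53 fixture shipped with the package: the canonical 1182-nt CDS
#' (393 residues plus terminal stop) and its ten coding exon segments
#' (labels 2-11; exon 1 of the gene is non-coding).
#'
#' @return A [gene_model] for TP53.
#' @export
tp53_gene_model <- function() {
  load_gene_model(
    system.file("extdata", "tp53_cds.fa", package = "mutenrich"),
    system.file("extdata", "tp53_exons.tsv", package = "mutenrich"),
    symbol = "TP53")
}

#' Locate the codon covering a CDS position
#'
#' @param model A [gene_model].
#' @param cds_pos 1-based CDS position (scalar).
#' @return List with `codon_index` (1-based), `offset` (0..2 within the codon)
#'   and `codon` (the reference triplet).
#' @export
codon_at <- function(model, cds_pos) {
  .check_pos(model, cds_pos)
  ci <- (cds_pos + 2L) %/% 3L
  list(codon_index = as.integer(ci),
       offset = as.integer((cds_pos - 1L) %% 3L),
       codon = model$.codons[ci])
}

#' Exon label containing a CDS position
#'
#' @param model A [gene_model].
#' @param cds_pos Vector of 1-based CDS positions.
#' @return Integer vector of exon labels.
#' @export
exon_of <- function(model, cds_pos) {
  .check_pos(model, cds_pos)
  model$.exon_by_pos[cds_pos]
}

.check_pos <- function(model, cds_pos) {
  if (length(cds_pos) == 0L) return(invisible(TRUE))
  if (anyNA(cds_pos) ||
      any(cds_pos < 1L) || any(cds_pos > nchar(model$cds))) {
    stop("CDS position out of range 1..", nchar(model$cds))
  }
  invisible(TRUE)
}

# Standard-code translation of a codon vector; internal workhorse.
.translate_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  starts <- 3L * seq_len(n) - 2L
  unname(Biostrings::GENETIC_CODE[substring(seq, starts, starts + 2L)])
}

#' Translate a nucleotide string under the standard genetic code
#'
#' Stop codons translate to `"*"` and do not terminate translation, so callers
#' can locate the first stop in a frameshifted sequence. An incomplete trailing
#' codon is ignored.
#'
#' @param cds_fragment Character string over A/C/G/T (may be empty).
#' @return Amino-acid string (one-letter code, `"*"` for stop).
#' @examples
#' translate_cds("ATGAAATAA")  # "MK*"
#' @export
translate_cds <- function(cds_fragment) {
  if (!is.character(cds_fragment) || length(cds_fragment) != 1L) {
    stop("'cds_fragment' must be a single character string")
  }
  s <- toupper(cds_fragment)
  if (nchar(s) == 0L) return("")
  if (grepl("[^ACGT]", s)) {
    stop("invalid characters in nucleotide sequence (expected A/C/G/T)")
  }
  paste(.translate_codons(s), collapse = "")
}
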