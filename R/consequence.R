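#' Consequence classes recognized by the pipeline
#'
#' Substitution classes (`synonymous`, `missense`, `nonsense`, `nonstop`) are
#' assigned by translation; `frameshift`, `inframe_indel` and `splice` come
#' from catalog annotations or indel length; `other` covers unrecognized
#' annotations and `none` marks wild-type placeholder rows used to carry
#' per-cohort sample totals.
#'
#' @return Character vector of class names.
#' @export
consequence_classes <- function() {
  c("synonymous", "missense", "nonsense", "nonstop",
    "frameshift", "inframe_indel", "splice", "other", "none")
}

#' Enumerate all theoretical single-nucleotide changes of a gene model
#'
#' The enumeration is the expected-case null for class composition: every one
#' of the `3 * L` possible substitutions of an `L`-nt CDS, classified by
#' comparing the reference and mutant codon translations. Stop-to-stop changes
#' are synonymous; stop-to-amino-acid changes are nonstop (stop-loss).
#'
#' @param model A [gene_model].
#' @return Data frame sorted by (`cds_pos`, `alt`) with columns `cds_pos`,
#'   `ref`, `alt`, `codon_index`, `ref_aa`, `alt_aa`, `consequence`,
#'   `exon_label`, `protein_change`.
#' @examples
#' theo <- enumerate_theoretical_snvs(tp53_gene_model())
#' nrow(theo)  # 3546
#' @export
enumerate_theoretical_snvs <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  L <- nchar(model$cds)
  refs <- strsplit(model$cds, "")[[1L]]
  alt_of <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
  pos <- rep(seq_len(L), each = 3L)
  alt <- unlist(alt_of[refs], use.names = FALSE)
  ref <- refs[pos]
  ci <- (pos + 2L) %/% 3L
  off <- (pos - 1L) %% 3L
  ref_codon <- model$.codons[ci]
  mut_codon <- paste0(substr(ref_codon, 1L, off), alt,
                      substr(ref_codon, off + 2L, 3L))
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[mut_codon])
  consequence <- ifelse(ref_aa == alt_aa, "synonymous",
                 ifelse(alt_aa == "*", "nonsense",
                 ifelse(ref_aa == "*", "nonstop", "missense")))
  data.frame(
    cds_pos = pos, ref = ref, alt = alt, codon_index = ci,
    ref_aa = ref_aa, alt_aa = alt_aa, consequence = consequence,
    exon_label = model$.exon_by_pos[pos],
    protein_change = paste0(ref_aa, ci,
                            ifelse(consequence == "synonymous", "=", alt_aa)),
    stringsAsFactors = FALSE
  )
}

#' Classify one single-nucleotide substitution
#'
#' @param model A [gene_model].
#' @param cds_pos 1-based CDS position of the substituted base.
#' @param alt_base Alternate base, different from the reference base.
#' @return One-row data frame in the layout of [enumerate_theoretical_snvs()].
#' @examples
#' classify_snv(tp53_gene_model(), 637, "T")  # R213*, nonsense, exon 6
#' @export
classify_snv <- function(model, cds_pos, alt_base) {
  .check_pos(model, cds_pos)
  alt_base <- toupper(alt_base)
  if (!alt_base %in% c("A", "C", "G", "T")) {
    stop("invalid alternate base '", alt_base, "'")
  }
  ref <- substr(model$cds, cds_pos, cds_pos)
  if (alt_base == ref) {
    stop("alternate base equals the reference base at position ", cds_pos)
  }
  ca <- codon_at(model, cds_pos)
  mut_codon <- ca$codon
  substr(mut_codon, ca$offset + 1L, ca$offset + 1L) <- alt_base
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ca$codon])
  alt_aa <- unname(code[mut_codon])
  consequence <- if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "nonsense"
    else if (ref_aa == "*") "nonstop"
    else "missense"
  data.frame(
    cds_pos = as.integer(cds_pos), ref = ref, alt = alt_base,
    codon_index = ca$codon_index, ref_aa = ref_aa, alt_aa = alt_aa,
    consequence = consequence,
    exon_label = exon_of(model, cds_pos),
    protein_change = paste0(ref_aa, ca$codon_index,
                            if (consequence == "synonymous") "=" else alt_aa),
    stringsAsFactors = FALSE
  )
}

#' Describe an insertion or deletion in CDS coordinates
#'
#' Deletions remove `length` bases starting at `cds_pos`; insertions place
#' `inserted_seq` immediately after `cds_pos`.
#'
#' @param cds_pos 1-based anchor position.
#' @param kind `"insertion"` or `"deletion"`.
#' @param length Positive integer; for insertions it must equal
#'   `nchar(inserted_seq)`.
#' @param inserted_seq Inserted nucleotide string (insertions only).
#' @return An object of class `indel_spec`.
#' @export
indel_spec <- function(cds_pos, kind = c("deletion", "insertion"),
                       length = 1L, inserted_seq = NULL) {
  kind <- match.arg(kind)
  cds_pos <- as.integer(cds_pos)
  length <- as.integer(length)
  if (is.na(cds_pos) || cds_pos < 1L) stop("indel anchor must be a positive position")
  if (is.na(length) || length < 1L) stop("indel length must be positive")
  if (kind == "insertion") {
    if (is.null(inserted_seq)) stop("insertions require 'inserted_seq'")
    inserted_seq <- toupper(inserted_seq)
    if (grepl("[^ACGT]", inserted_seq)) stop("inserted_seq contains invalid characters")
    if (nchar(inserted_seq) != length) {
      stop("insertion length (", length, ") does not equal nchar(inserted_seq) (",
           nchar(inserted_seq), ")")
    }
  }
  structure(list(cds_pos = cds_pos, kind = kind, length = length,
                 inserted_seq = inserted_seq),
            class = "indel_spec")
}

#' Locate the premature stop codon introduced by a frameshift indel
#'
#' Builds the mutant CDS, translates it from the start, and reports where the
#' first stop codon begins: its codon index in mutant coordinates and the exon
#' containing the corresponding reference position. Mutant positions downstream
#' of a deletion shift back into reference space by the deleted length;
#' positions inside an inserted run map to the insertion anchor; the mapped
#' position is clamped into `1..nchar(cds)`.
#'
#' @param model A [gene_model].
#' @param indel An [indel_spec] whose length is not a multiple of three.
#' @return List with `stop_codon_index`, `exon_label` and `stop_ref_pos`, all
#'   `NA` when translation runs off the end of the mutant sequence without
#'   encountering a stop (readthrough).
#' @examples
#' m <- gene_model("ATGAAATAA", data.frame(exon_label = 1, cds_start = 1, cds_end = 9))
#' premature_stop_codon(m, indel_spec(3, "insertion", 1, "T"))$stop_codon_index  # 2
#' @export
premature_stop_codon <- function(model, indel) {
  stopifnot(inherits(model, "gene_model"), inherits(indel, "indel_spec"))
  if (indel$length %% 3L == 0L) {
    stop("in-frame indel (length ", indel$length,
         "): no frameshift stop mapping; classify as inframe_indel instead")
  }
  L <- nchar(model$cds)
  if (indel$kind == "deletion") {
    p <- indel$cds_pos
    if (p + indel$length - 1L > L) stop("indel outside CDS")
    mutant <- paste0(substr(model$cds, 1L, p - 1L),
                     substr(model$cds, p + indel$length, L))
  } else {
    a <- indel$cds_pos
    if (a > L) stop("indel outside CDS")
    mutant <- paste0(substr(model$cds, 1L, a), indel$inserted_seq,
                     substr(model$cds, a + 1L, L))
  }
  aa <- .translate_codons(mutant)
  k <- which(aa == "*")[1L]
  if (is.na(k)) {
    return(list(stop_codon_index = NA_integer_, exon_label = NA_integer_,
                stop_ref_pos = NA_integer_))
  }
  m <- 3L * k - 2L  # first mutant base of the stop codon
  ref_pos <- if (indel$kind == "deletion") {
    if (m >= indel$cds_pos) m + indel$length else m
  } else {
    a <- indel$cds_pos
    if (m <= a) m else if (m <= a + indel$length) a else m - indel$length
  }
  ref_pos <- min(max(ref_pos, 1L), L)
  list(stop_codon_index = as.integer(k),
       exon_label = exon_of(model, ref_pos),
       stop_ref_pos = as.integer(ref_pos))
}

#' Does a mutation truncate the protein within a given exon?
#'
#' Implements the truncation definition used throughout the pipeline: a record
#' counts as an exon-`k` truncation when it is a nonsense mutation located in
#' exon `k`, or a frameshift indel whose introduced premature stop codon falls
#' in exon `k`. Frameshift records without a CDS-level description cannot be
#' stop-mapped; they return `FALSE` and are tallied in the
#' `"unmapped_frameshifts"` attribute of the result.
#'
#' @param model A [gene_model].
#' @param records Normalized catalog records (see [read_catalog()]); exon
#'   labels must already be assigned.
#' @param exon Exon label to test against (default 6, TP53's hotspot exon).
#' @return Logical vector, one element per record, with attribute
#'   `unmapped_frameshifts`.
#' @export
is_exon_truncation <- function(model, records, exon = 6L) {
  stopifnot(is.data.frame(records))
  lab <- records$exon_label
  out <- (records$consequence == "nonsense" & !is.na(lab) & lab == exon) |
         (records$consequence == "frameshift" & !is.na(lab) & lab == exon)
  out[is.na(out)] <- FALSE
  attr(out, "unmapped_frameshifts") <-
    sum(records$consequence == "frameshift" & is.na(lab), na.rm = TRUE)
  out
}

#' @rdname is_exon_truncation
#' @export
is_exon6_truncation <- function(model, records) {
  is_exon_truncation(model, records, exon = 6L)
}
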