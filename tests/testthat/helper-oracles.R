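# Shared fixtures and independent oracles for the test suite.

toy_model <- function() {
  gene_model("ATGAAATAA",
             data.frame(exon_label = 1L, cds_start = 1L, cds_end = 9L),
             symbol = "TOY")
}

toy_model_mke <- function() {
  gene_model("ATGAAAGAATAA",
             data.frame(exon_label = c(1L, 2L), cds_start = c(1L, 7L),
                        cds_end = c(6L, 12L)),
             symbol = "MKE")
}

tp53 <- tp53_gene_model()
theo_tp53 <- enumerate_theoretical_snvs(tp53)

# TP53 codons split across exon junctions (where mutated-base and
# codon-first-base exon conventions legitimately differ).
tp53_junction_codons <- c(25L, 187L, 261L, 307L, 367L)

# Brute-force consequence oracle: mutate the full CDS, translate it entirely
# with Biostrings, and diff the two proteins character by character.
oracle_translate <- function(seqs) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(seqs),
                                     no.init.codon = TRUE))
}

oracle_classify <- function(model, cds_pos, alt) {
  s <- model$cds
  mutant <- paste0(substr(s, 1L, cds_pos - 1L), alt,
                   substr(s, cds_pos + 1L, nchar(s)))
  a <- strsplit(oracle_translate(s), "")[[1L]]
  b <- strsplit(oracle_translate(mutant), "")[[1L]]
  d <- which(a != b)
  if (length(d) == 0L) return("synonymous")
  if (b[d] == "*") return("nonsense")
  if (a[d] == "*") return("nonstop")
  "missense"
}

# Frameshift oracle: independently build the mutant sequence, translate it
# fully, locate the first stop, and map its first base back to reference
# coordinates (deletion: downstream positions shift by the deleted length;
# insertion: inserted positions collapse to the anchor), then look the exon up
# straight from the exon table.
oracle_premature_stop <- function(model, kind, pos, len, ins = NULL) {
  chars <- strsplit(model$cds, "")[[1L]]
  mutant_chars <- if (kind == "deletion") {
    chars[-(pos:(pos + len - 1L))]
  } else {
    append(chars, strsplit(ins, "")[[1L]], after = pos)
  }
  mutant <- paste(mutant_chars, collapse = "")
  aa <- strsplit(oracle_translate(substr(mutant, 1L,
                                         3L * (nchar(mutant) %/% 3L))), "")[[1L]]
  k <- which(aa == "*")[1L]
  if (is.na(k)) return(list(stop_codon_index = NA_integer_,
                            exon_label = NA_integer_))
  m <- 3L * k - 2L
  ref <- if (kind == "deletion") {
    if (m >= pos) m + len else m
  } else {
    if (m <= pos) m else if (m <= pos + len) pos else m - len
  }
  ref <- min(max(ref, 1L), nchar(model$cds))
  ex <- model$exons
  lab <- ex$exon_label[ref >= ex$cds_start & ref <= ex$cds_end]
  list(stop_codon_index = k, exon_label = lab)
}

# Exhaustive two-sided Fisher oracle: sum hypergeometric point probabilities
# no larger than the observed table's (with the conventional relative guard
# against floating-point ties).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Write a raw MAF-minimal catalog file from parallel vectors.
write_toy_maf <- function(path, sample, class, hgvsp = "", hgvsc = "",
                          gene = "TP53", cancer_type = "SIM", site = "") {
  n <- length(sample)
  d <- data.frame(Hugo_Symbol = rep_len(gene, n),
                  Tumor_Sample_Barcode = sample,
                  Variant_Classification = rep_len(class, n),
                  HGVSp_Short = rep_len(hgvsp, n),
                  HGVSc = rep_len(hgvsc, n),
                  Cancer_Type = rep_len(cancer_type, n),
                  Sample_Site = rep_len(site, n),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
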