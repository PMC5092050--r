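# MAF-minimal catalog ingestion and normalization.
#
# Internal record layout (one row per catalog row after normalization):
#   gene, sample_id, cancer_type, sample_site, raw_class, consequence,
#   hgvsp, hgvsc, protein_ref, protein_pos, protein_alt,
#   cds_pos, cds_op (sub|del|ins), cds_len, cds_ref, cds_alt, ins_seq,
#   exon_label, change_key
# Wild-type placeholder rows (raw class "None"/"Wild_Type"/empty) carry the
# consequence "none"; they contribute sample totals but never mutation counts.

.maf_vocab <- c(
  Nonsense_Mutation = "nonsense",
  Missense_Mutation = "missense",
  Frame_Shift_Del = "frameshift",
  Frame_Shift_Ins = "frameshift",
  In_Frame_Del = "inframe_indel",
  In_Frame_Ins = "inframe_indel",
  Splice_Site = "splice",
  Splice_Region = "splice",
  Silent = "synonymous",
  Nonstop_Mutation = "nonstop",
  None = "none",
  Wild_Type = "none"
)

#' Map a raw MAF classification string onto a consequence class
#'
#' Standard MAF vocabulary (`Nonsense_Mutation`, `Missense_Mutation`,
#' `Frame_Shift_Del`/`Ins`, `In_Frame_Del`/`Ins`, `Splice_Site`, `Silent`,
#' `Nonstop_Mutation`) maps onto the package's classes; empty strings,
#' `"None"` and `"Wild_Type"` mark wild-type placeholder rows (`"none"`);
#' anything unrecognized becomes `"other"`.
#'
#' @param raw Character vector of raw classification strings.
#' @return Character vector of consequence classes.
#' @export
normalize_class <- function(raw) {
  out <- unname(.maf_vocab[as.character(raw)])
  blank <- is.na(raw) | trimws(as.character(raw)) == ""
  out[blank] <- "none"
  out[is.na(out) & !blank] <- "other"
  out
}

#' Parse short-form HGVS protein changes
#'
#' Handles substitutions (`"G245D"`), stop-gains (`"R213*"`), synonymous
#' notation (`"R213="`) and frameshift notation (`"T125Tfs*8"`, `"R213fs"`),
#' with an optional leading `"p."`. Unparseable strings yield `ok = FALSE`
#' (the record is kept; its class then comes from the raw classification
#' only).
#'
#' @param text Character vector of protein-change strings.
#' @return Data frame with columns `ref_aa`, `position`, `alt` (`"*"` stop,
#'   `"="` synonymous, `"fs"` frameshift) and `ok`.
#' @export
parse_protein_change <- function(text) {
  x <- sub("^p\\.", "", trimws(as.character(text)))
  x[is.na(x)] <- ""
  pat_sub <- "^([A-Z*])([0-9]+)([A-Z*=])$"
  pat_fs <- "^([A-Z*])([0-9]+)[A-Za-z]*fs(\\*[0-9]+)?$"
  is_sub <- grepl(pat_sub, x)
  is_fs <- !is_sub & grepl(pat_fs, x)
  ref <- rep(NA_character_, length(x))
  pos <- rep(NA_integer_, length(x))
  alt <- rep(NA_character_, length(x))
  ref[is_sub] <- sub(pat_sub, "\\1", x[is_sub])
  pos[is_sub] <- as.integer(sub(pat_sub, "\\2", x[is_sub]))
  alt[is_sub] <- sub(pat_sub, "\\3", x[is_sub])
  ref[is_fs] <- sub(pat_fs, "\\1", x[is_fs])
  pos[is_fs] <- as.integer(sub(pat_fs, "\\2", x[is_fs]))
  alt[is_fs] <- "fs"
  data.frame(ref_aa = ref, position = pos, alt = alt, ok = is_sub | is_fs,
             stringsAsFactors = FALSE)
}

#' Parse short-form HGVS CDS changes
#'
#' Handles substitutions (`"c.637C>T"`), deletions (`"c.455del"`,
#' `"c.455delC"`, `"c.372_380del"`), insertions (`"c.455_456insT"`) and
#' duplications (`"c.100_102dup"`, normalized to insertions by callers with a
#' gene model in hand). The leading `"c."` is optional.
#'
#' @param text Character vector of CDS-change strings.
#' @return Data frame with columns `cds_pos` (anchor), `op`
#'   (`sub`/`del`/`ins`/`dup`), `cds_len`, `cds_ref`, `cds_alt`, `ins_seq`,
#'   `ok`.
#' @export
parse_cds_change <- function(text) {
  x <- sub("^c\\.", "", trimws(as.character(text)))
  x[is.na(x)] <- ""
  n <- length(x)
  pos <- rep(NA_integer_, n); op <- rep(NA_character_, n)
  len <- rep(NA_integer_, n); ref <- rep(NA_character_, n)
  alt <- rep(NA_character_, n); ins <- rep(NA_character_, n)

  pat_sub <- "^([0-9]+)([ACGT])>([ACGT])$"
  i <- grepl(pat_sub, x)
  pos[i] <- as.integer(sub(pat_sub, "\\1", x[i]))
  ref[i] <- sub(pat_sub, "\\2", x[i])
  alt[i] <- sub(pat_sub, "\\3", x[i])
  op[i] <- "sub"; len[i] <- 1L

  pat_del <- "^([0-9]+)(_([0-9]+))?del([ACGT]*)$"
  i <- is.na(op) & grepl(pat_del, x)
  start <- as.integer(sub(pat_del, "\\1", x[i]))
  end <- suppressWarnings(as.integer(sub(pat_del, "\\3", x[i])))
  seqs <- sub(pat_del, "\\4", x[i])
  dlen <- ifelse(!is.na(end), end - start + 1L,
                 ifelse(nchar(seqs) > 0L, nchar(seqs), 1L))
  pos[i] <- start; op[i] <- "del"; len[i] <- as.integer(dlen)

  pat_ins <- "^([0-9]+)_([0-9]+)ins([ACGT]+)$"
  i <- is.na(op) & grepl(pat_ins, x)
  pos[i] <- as.integer(sub(pat_ins, "\\1", x[i]))
  ins[i] <- sub(pat_ins, "\\3", x[i])
  op[i] <- "ins"; len[i] <- nchar(ins[i])

  pat_dup <- "^([0-9]+)(_([0-9]+))?dup([ACGT]*)$"
  i <- is.na(op) & grepl(pat_dup, x)
  start <- as.integer(sub(pat_dup, "\\1", x[i]))
  end <- suppressWarnings(as.integer(sub(pat_dup, "\\3", x[i])))
  pos[i] <- start; op[i] <- "dup"
  len[i] <- ifelse(!is.na(end), end - start + 1L, 1L)

  bad <- is.na(op) & !is.na(len)
  len[bad] <- NA_integer_
  data.frame(cds_pos = pos, op = op, cds_len = len, cds_ref = ref,
             cds_alt = alt, ins_seq = ins, ok = !is.na(op),
             stringsAsFactors = FALSE)
}

.dialect_columns <- list(
  maf = c(gene = "Hugo_Symbol", sample_id = "Tumor_Sample_Barcode",
          raw_class = "Variant_Classification", hgvsp = "HGVSp_Short",
          hgvsc = "HGVSc", cancer_type = "Cancer_Type",
          sample_site = "Sample_Site"),
  cbioportal = c(gene = "Gene", sample_id = "Sample ID",
                 raw_class = "Mutation Type", hgvsp = "Protein Change",
                 hgvsc = "HGVSc", cancer_type = "Cancer Type",
                 sample_site = "Sample Type")
)

.normalize_site <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("primary", "primary tumor", "p")] <- "primary"
  out[x %in% c("metastasis", "metastatic", "met", "m")] <- "metastasis"
  out
}

#' Read a somatic mutation catalog in a MAF-minimal dialect
#'
#' Reads a tab-separated catalog, maps dialect-specific column names onto the
#' internal layout, normalizes classes, parses HGVS protein/CDS descriptions,
#' assigns exons on the supplied gene model and derives unique-change keys.
#' Rows for genes other than `model$symbol` are dropped and counted in the
#' attached log. Dialects are explicit, never sniffed.
#'
#' @param path Path to the TSV file.
#' @param model A [gene_model] used for exon assignment and frameshift stop
#'   mapping.
#' @param dialect `"maf"` (columns `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#'   `Variant_Classification`, `HGVSp_Short`, optional `HGVSc`, `Cancer_Type`,
#'   `Sample_Site`) or `"cbioportal"` (`Gene`, `Sample ID`, `Mutation Type`,
#'   `Protein Change`, ...).
#' @return Data frame of normalized records with a `"log"` attribute listing
#'   rows read, rows dropped for other genes, parse failures, exon-unknown
#'   rows and unmapped frameshifts.
#' @export
read_catalog <- function(path, model, dialect = c("maf", "cbioportal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read catalog file '", path, "'")
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL, quote = "")
  cols <- .dialect_columns[[dialect]]
  required <- cols[c("sample_id", "raw_class", "hgvsp")]
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing required columns in '", path, "' (dialect ", dialect, "): ",
         paste(missing, collapse = ", "))
  }
  std <- data.frame(row_id = seq_len(nrow(df)), stringsAsFactors = FALSE)
  for (k in names(cols)) {
    std[[k]] <- if (cols[[k]] %in% names(df)) df[[cols[[k]]]]
                else rep(NA_character_, nrow(df))
  }
  normalize_catalog(std, model)
}

#' Normalize a standardized catalog data frame into records
#'
#' Workhorse behind [read_catalog()] and the simulator, exposed so in-memory
#' catalogs can be normalized without a file round trip. Expects columns
#' `gene`, `sample_id`, `raw_class`, `hgvsp`, `hgvsc`, `cancer_type`,
#' `sample_site` (missing ones are tolerated as all-`NA`).
#'
#' @param std Data frame in the standardized column layout.
#' @param model A [gene_model].
#' @return Normalized records with a `"log"` attribute (see [read_catalog()]).
#' @export
normalize_catalog <- function(std, model) {
  for (k in c("gene", "sample_id", "raw_class", "hgvsp", "hgvsc",
              "cancer_type", "sample_site")) {
    if (is.null(std[[k]])) std[[k]] <- rep(NA_character_, nrow(std))
  }
  rows_read <- nrow(std)
  other <- !is.na(std$gene) & trimws(std$gene) != "" &
           std$gene != model$symbol
  if (any(other)) {
    message("dropping ", sum(other), " row(s) for genes other than ",
            model$symbol)
  }
  std <- std[!other, , drop = FALSE]

  pp <- parse_protein_change(std$hgvsp)
  pc <- parse_cds_change(std$hgvsc)
  records <- data.frame(
    gene = ifelse(is.na(std$gene) | std$gene == "", model$symbol, std$gene),
    sample_id = std$sample_id,
    cancer_type = ifelse(is.na(std$cancer_type) | std$cancer_type == "",
                         NA_character_, std$cancer_type),
    sample_site = .normalize_site(std$sample_site),
    raw_class = ifelse(is.na(std$raw_class), "", std$raw_class),
    consequence = normalize_class(std$raw_class),
    hgvsp = ifelse(is.na(std$hgvsp), "", std$hgvsp),
    hgvsc = ifelse(is.na(std$hgvsc), "", std$hgvsc),
    protein_ref = pp$ref_aa, protein_pos = pp$position, protein_alt = pp$alt,
    cds_pos = pc$cds_pos, cds_op = pc$op, cds_len = pc$cds_len,
    cds_ref = pc$cds_ref, cds_alt = pc$cds_alt, ins_seq = pc$ins_seq,
    stringsAsFactors = FALSE
  )

  # duplications become insertions of the duplicated reference run
  L <- nchar(model$cds)
  dup <- which(!is.na(records$cds_op) & records$cds_op == "dup" &
               records$cds_pos >= 1L &
               records$cds_pos + records$cds_len - 1L <= L)
  if (length(dup) > 0L) {
    records$ins_seq[dup] <- substr(rep(model$cds, length(dup)),
                                   records$cds_pos[dup],
                                   records$cds_pos[dup] + records$cds_len[dup] - 1L)
    records$cds_pos[dup] <- records$cds_pos[dup] + records$cds_len[dup] - 1L
    records$cds_op[dup] <- "ins"
  }
  records$cds_op[!is.na(records$cds_op) & records$cds_op == "dup"] <- NA_character_

  mismatch <- rep(FALSE, nrow(records))
  chk <- which(!is.na(records$cds_op) & records$cds_op == "sub" &
                 records$cds_pos >= 1L & records$cds_pos <= L)
  if (length(chk) > 0L) {
    mismatch[chk] <- substring(model$cds, records$cds_pos[chk],
                               records$cds_pos[chk]) != records$cds_ref[chk]
  }
  if (any(mismatch, na.rm = TRUE)) {
    message(sum(mismatch, na.rm = TRUE),
            " substitution(s) with reference base not matching the gene model")
  }

  records <- assign_exon(model, records)
  records$change_key <- unique_change_key(records)

  mut <- records$consequence != "none"
  attr(records, "log") <- list(
    rows_read = rows_read,
    kept = nrow(records),
    dropped_other_gene = sum(other),
    protein_parse_failures = sum(records$hgvsp != "" & !pp$ok),
    cds_parse_failures = sum(records$hgvsc != "" & !pc$ok),
    cds_ref_mismatches = sum(mismatch, na.rm = TRUE),
    exon_unknown = sum(mut & is.na(records$exon_label)),
    unmapped_frameshifts = sum(records$consequence == "frameshift" &
                                 is.na(records$exon_label))
  )
  records
}

#' Assign exon labels to normalized records
#'
#' Substitutions with a parsed CDS position use the exon of the mutated base;
#' substitutions known only at the protein level use the exon of the codon's
#' first base; frameshift indels with CDS detail use the exon of the premature
#' stop codon they introduce (via [premature_stop_codon()]); in-frame indels
#' use the exon of their anchor base. Records whose position falls outside the
#' model, and frameshifts lacking CDS detail, keep `NA`.
#'
#' @param model A [gene_model].
#' @param records Normalized record data frame.
#' @return The records with an `exon_label` column filled in.
#' @export
assign_exon <- function(model, records) {
  L <- nchar(model$cds)
  n <- nrow(records)
  exon <- rep(NA_integer_, n)
  if (n == 0L) { records$exon_label <- exon; return(records) }

  has_sub <- !is.na(records$cds_op) & records$cds_op == "sub" &
    !is.na(records$cds_pos) & records$cds_pos >= 1L & records$cds_pos <= L
  exon[has_sub] <- exon_of(model, records$cds_pos[has_sub])

  sub_classes <- c("synonymous", "missense", "nonsense", "nonstop")
  pl <- model$protein_length
  fallback <- is.na(exon) & records$consequence %in% sub_classes &
    !is.na(records$protein_pos) & records$protein_pos >= 1L &
    records$protein_pos <= pl + 1L
  exon[fallback] <- exon_of(model, 3L * records$protein_pos[fallback] - 2L)

  fs <- which(records$consequence == "frameshift" & !is.na(records$cds_op) &
              records$cds_op %in% c("del", "ins") & !is.na(records$cds_pos))
  for (i in fs) {
    len <- records$cds_len[i]
    if (is.na(len) || len %% 3L == 0L) next
    if (records$cds_op[i] == "ins" &&
        (is.na(records$ins_seq[i]) || records$ins_seq[i] == "")) next
    res <- tryCatch({
      spec <- indel_spec(records$cds_pos[i],
                         if (records$cds_op[i] == "del") "deletion" else "insertion",
                         len,
                         if (records$cds_op[i] == "ins") records$ins_seq[i] else NULL)
      premature_stop_codon(model, spec)
    }, error = function(e) NULL)
    if (!is.null(res)) exon[i] <- res$exon_label
  }

  inframe <- which(records$consequence == "inframe_indel" & is.na(exon) &
                   !is.na(records$cds_pos) & records$cds_pos >= 1L &
                   records$cds_pos <= L)
  exon[inframe] <- exon_of(model, records$cds_pos[inframe])

  records$exon_label <- exon
  records
}

#' Canonical unique-change key of each record
#'
#' The key identifies one biological change across samples: the CDS-level
#' description when present, else the protein-level description, else the raw
#' class plus consequence. Wild-type placeholder rows key as `"none"`.
#'
#' @param records Normalized record data frame.
#' @return Character vector of keys.
#' @export
unique_change_key <- function(records) {
  key <- ifelse(records$hgvsc != "",
                paste0("c:", sub("^c\\.", "", records$hgvsc)),
         ifelse(records$hgvsp != "",
                paste0("p:", sub("^p\\.", "", records$hgvsp)),
                paste0("class:", records$raw_class, "/", records$consequence)))
  key[records$consequence == "none"] <- "none"
  key
}

#' Deduplicated mutation instances of a catalog
#'
#' One instance is one distinct (sample, unique-change key) pair; exact
#' duplicate rows within a sample collapse, and wild-type placeholder rows are
#' excluded.
#'
#' @param records Normalized record data frame.
#' @return Subset of `records` with one row per instance.
#' @export
count_instances <- function(records) {
  mut <- records[records$consequence != "none", , drop = FALSE]
  mut[!duplicated(paste(mut$sample_id, mut$change_key, sep = "\r")), ,
      drop = FALSE]
}

#' Restrict a catalog to adequately powered cancer types
#'
#' Retains cancer types with strictly more than `min_samples_per_type`
#' distinct samples and at least `min_mutant_tumors` distinct mutated samples
#' (the study-inclusion rule used for cohort selection).
#'
#' @param records Normalized record data frame (wild-type placeholder rows
#'   count toward sample totals).
#' @param min_samples_per_type Minimum distinct samples per type (exclusive).
#' @param min_mutant_tumors Minimum distinct mutated samples (inclusive).
#' @return List with `records` (the retained subset) and `report` (per-type
#'   counts and kept/dropped status).
#' @export
filter_studies <- function(records, min_samples_per_type = 100L,
                           min_mutant_tumors = 10L) {
  if (min_samples_per_type <= 0L || min_mutant_tumors <= 0L) {
    stop("study-filter thresholds must be positive")
  }
  if (nrow(records) == 0L) {
    return(list(records = records,
                report = data.frame(cancer_type = character(0),
                                    n_samples = integer(0),
                                    n_mutant = integer(0),
                                    kept = logical(0))))
  }
  type <- ifelse(is.na(records$cancer_type), "<NA>", records$cancer_type)
  n_samples <- tapply(records$sample_id, type,
                      function(x) length(unique(x)))
  mut <- records$consequence != "none"
  n_mutant <- tapply(records$sample_id[mut], type[mut],
                     function(x) length(unique(x)))
  types <- names(n_samples)
  n_mut <- ifelse(types %in% names(n_mutant), n_mutant[types], 0L)
  kept <- (n_samples > min_samples_per_type) & (n_mut >= min_mutant_tumors)
  report <- data.frame(cancer_type = types,
                       n_samples = as.integer(n_samples),
                       n_mutant = as.integer(n_mut),
                       kept = as.logical(kept),
                       row.names = NULL, stringsAsFactors = FALSE)
  keep_rows <- type %in% types[kept]
  list(records = records[keep_rows, , drop = FALSE], report = report)
}

#' Write normalized records back to a MAF-minimal TSV
#'
#' The output round-trips through [read_catalog()] losslessly for all
#' normalized fields. Unknown values serialize as empty strings.
#'
#' @param records Normalized record data frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_catalog <- function(records, path) {
  out <- data.frame(
    Hugo_Symbol = records$gene,
    Tumor_Sample_Barcode = records$sample_id,
    Variant_Classification = records$raw_class,
    HGVSp_Short = records$hgvsp,
    HGVSc = records$hgvsc,
    Cancer_Type = ifelse(is.na(records$cancer_type), "", records$cancer_type),
    Sample_Site = ifelse(records$sample_site == "unknown", "",
                         records$sample_site),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
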