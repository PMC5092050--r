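# Observed-vs-expected class/region statistics.
#
# A stratum is a (consequence class, region) pair; region is the whole gene
# (exon = NA) or one exon. The theoretical SNV enumeration supplies the
# expected composition; observed composition comes from deduplicated mutation
# instances.

#' Define class-by-region strata
#'
#' @param class Character vector of consequence classes.
#' @param exon Integer vector (recycled) of exon labels; `NA` means whole
#'   gene.
#' @return Data frame with columns `class`, `exon`, `stratum` (a label such as
#'   `"nonsense:exon6"`).
#' @export
make_strata <- function(class, exon = NA_integer_) {
  d <- data.frame(class = class, exon = as.integer(exon),
                  stringsAsFactors = FALSE)
  d$stratum <- ifelse(is.na(d$exon), d$class,
                      paste0(d$class, ":exon", d$exon))
  d
}

#' Default strata: the four substitution classes genome-wide plus exon-6
#' nonsense
#'
#' @return A strata data frame (see [make_strata()]).
#' @export
default_strata <- function() {
  make_strata(c("synonymous", "missense", "nonsense", "nonstop", "nonsense"),
              c(NA, NA, NA, NA, 6L))
}

.stratum_match <- function(class_vec, exon_vec, class, exon) {
  m <- class_vec == class
  if (!is.na(exon)) m <- m & !is.na(exon_vec) & exon_vec == exon
  m & !is.na(m)
}

.theoretical_counts <- function(theoretical, strata) {
  vapply(seq_len(nrow(strata)), function(i) {
    sum(.stratum_match(theoretical$consequence, theoretical$exon_label,
                       strata$class[i], strata$exon[i]))
  }, integer(1))
}

#' Expected stratum fractions under the theoretical null
#'
#' The default denominator is the plain SNV space: every stratum fraction is
#' its share of the `3 * L` enumerated substitutions. The `"extended"`
#' denominator additionally counts, per CDS position, one 1-nt insertion and
#' one 1-nt deletion as frameshift pseudo-events (`2 * L` extra events), for
#' analyses that treat indels as part of the expected change space.
#'
#' @param theoretical Enumeration from [enumerate_theoretical_snvs()].
#' @param strata Strata data frame from [make_strata()].
#' @param denominator `"snv"` or `"extended"`.
#' @return Named numeric vector of fractions (names are stratum labels).
#' @export
expected_fractions <- function(theoretical, strata = default_strata(),
                               denominator = c("snv", "extended")) {
  denominator <- match.arg(denominator)
  if (nrow(theoretical) == 0L) stop("empty theoretical enumeration")
  counts <- .theoretical_counts(theoretical, strata)
  L <- max(theoretical$cds_pos)
  total <- nrow(theoretical)
  if (denominator == "extended") {
    total <- total + 2L * L
    counts[strata$class == "frameshift" & is.na(strata$exon)] <- 2L * L
  }
  stats::setNames(counts / total, strata$stratum)
}

#' Observed stratum fractions of a catalog
#'
#' Fractions of deduplicated mutation instances. Records of unknown class
#' (`"other"`) stay in the denominator but no class numerator; wild-type
#' placeholder rows are excluded entirely.
#'
#' @param records Normalized record data frame.
#' @param strata Strata data frame.
#' @return Named numeric vector of fractions.
#' @export
observed_fractions <- function(records, strata = default_strata()) {
  inst <- count_instances(records)
  if (nrow(inst) == 0L) stop("empty mutation catalog")
  counts <- vapply(seq_len(nrow(strata)), function(i) {
    sum(.stratum_match(inst$consequence, inst$exon_label,
                       strata$class[i], strata$exon[i]))
  }, integer(1))
  stats::setNames(counts / nrow(inst), strata$stratum)
}

#' Fold enrichment of observed over expected fractions
#'
#' @param observed,expected Numeric vectors of fractions (recycled).
#' @return `observed / expected`; zero observed gives 0, zero expected is an
#'   error (the ratio is undefined).
#' @export
fold_enrichment <- function(observed, expected) {
  if (any(expected == 0)) {
    stop("fold enrichment undefined: expected fraction is zero")
  }
  observed / expected
}

#' Recurrence frequency per stratum
#'
#' Instances per unique change (how often the same change recurs across
#' tumors), with a per-sample-normalized secondary column.
#'
#' @param records Normalized record data frame.
#' @param strata Strata data frame.
#' @param n_samples Number of samples for the normalized column; defaults to
#'   the distinct samples present in `records`.
#' @return Data frame with `stratum`, `instances`, `unique_changes`,
#'   `recurrence` (0 with a `flagged_empty` marker for empty strata) and
#'   `per_sample`.
#' @export
recurrence_frequency <- function(records, strata = default_strata(),
                                 n_samples = NULL) {
  inst <- count_instances(records)
  if (is.null(n_samples)) n_samples <- length(unique(records$sample_id))
  out <- strata
  out$instances <- vapply(seq_len(nrow(strata)), function(i) {
    sum(.stratum_match(inst$consequence, inst$exon_label,
                       strata$class[i], strata$exon[i]))
  }, integer(1))
  out$unique_changes <- vapply(seq_len(nrow(strata)), function(i) {
    m <- .stratum_match(inst$consequence, inst$exon_label,
                        strata$class[i], strata$exon[i])
    length(unique(inst$change_key[m]))
  }, integer(1))
  out$recurrence <- ifelse(out$unique_changes > 0L,
                           out$instances / out$unique_changes, 0)
  out$flagged_empty <- out$unique_changes == 0L
  out$per_sample <- if (n_samples > 0L) out$recurrence / n_samples else NA_real_
  out
}

#' Fisher's exact test of observed versus theoretical composition
#'
#' Two-sided exact test on the 2x2 table contrasting observed instances inside
#' and outside a stratum against theoretical changes inside and outside it.
#'
#' @param obs_in,obs_out Observed instances inside / outside the stratum.
#' @param theo_in,theo_out Theoretical changes inside / outside the stratum.
#' @return List with `p_value`, `odds_ratio`, `table` and `degenerate`
#'   (`TRUE`, with `p_value = 1`, when a table margin is zero).
#' @export
enrichment_test <- function(obs_in, obs_out, theo_in, theo_out) {
  m <- matrix(c(obs_in, theo_in, obs_out, theo_out), nrow = 2L,
              dimnames = list(c("observed", "theoretical"),
                              c("in_stratum", "out_stratum")))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(p_value = 1, odds_ratio = NA_real_, table = m,
                degenerate = TRUE))
  }
  ft <- stats::fisher.test(m, alternative = "two.sided")
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate), table = m,
       degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] applied within one report family.
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Vector of q-values (empty input gives empty output).
#' @export
adjust_bh <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Per-stratum enrichment table for a catalog
#'
#' The headline analysis: for each stratum, the expected fraction under the
#' theoretical null, the observed instance fraction, fold enrichments on both
#' the instance and the unique-change scale, the two-sided Fisher exact test
#' of observed-vs-theoretical composition, and BH-adjusted q-values within
#' this family of strata.
#'
#' @param model A [gene_model].
#' @param records Normalized record data frame.
#' @param strata Strata data frame.
#' @param denominator Passed to [expected_fractions()].
#' @param theoretical Optional precomputed enumeration (to amortize across
#'   repeated calls).
#' @return Data frame with one row per stratum.
#' @export
enrichment_table <- function(model, records, strata = default_strata(),
                             denominator = "snv", theoretical = NULL) {
  if (is.null(theoretical)) theoretical <- enumerate_theoretical_snvs(model)
  inst <- count_instances(records)
  if (nrow(inst) == 0L) stop("empty mutation catalog")
  expected <- expected_fractions(theoretical, strata, denominator)
  theo_counts <- .theoretical_counts(theoretical, strata)
  n_inst <- nrow(inst)
  n_uniq <- length(unique(inst$change_key))
  out <- strata
  out$theoretical_count <- theo_counts
  out$expected_fraction <- as.numeric(expected)
  res <- lapply(seq_len(nrow(strata)), function(i) {
    m <- .stratum_match(inst$consequence, inst$exon_label,
                        strata$class[i], strata$exon[i])
    oi <- sum(m)
    ui <- length(unique(inst$change_key[m]))
    ti <- theo_counts[i]
    test <- enrichment_test(oi, n_inst - oi, ti, nrow(theoretical) - ti)
    c(instances = oi, unique_observed = ui, p = test$p_value,
      or = test$odds_ratio, degenerate = as.numeric(test$degenerate))
  })
  res <- do.call(rbind, res)
  out$instances <- as.integer(res[, "instances"])
  out$unique_observed <- as.integer(res[, "unique_observed"])
  out$observed_fraction <- out$instances / n_inst
  out$fold <- ifelse(out$expected_fraction > 0,
                     out$observed_fraction / out$expected_fraction, NA_real_)
  out$fold_unique <- ifelse(out$expected_fraction > 0 & n_uniq > 0,
                            (out$unique_observed / n_uniq) /
                              out$expected_fraction, NA_real_)
  out$odds_ratio <- res[, "or"]
  out$p_value <- res[, "p"]
  out$q_value <- adjust_bh(out$p_value)
  out$degenerate <- res[, "degenerate"] > 0
  out$obs_in <- out$instances
  out$obs_out <- n_inst - out$instances
  out$theo_in <- out$theoretical_count
  out$theo_out <- nrow(theoretical) - out$theoretical_count
  out
}

#' Per-codon observed instance counts (lollipop-style export)
#'
#' @param records Normalized record data frame.
#' @param model A [gene_model].
#' @return Data frame `codon_index`, `consequence`, `count` for instances with
#'   a known protein position.
#' @export
per_codon_counts <- function(records, model) {
  inst <- count_instances(records)
  ci <- ifelse(!is.na(inst$cds_pos) & !is.na(inst$cds_op) &
                 inst$cds_op == "sub",
               (inst$cds_pos + 2L) %/% 3L, inst$protein_pos)
  keep <- !is.na(ci) & ci >= 1L & ci <= model$protein_length + 1L
  if (!any(keep)) {
    return(data.frame(codon_index = integer(0), consequence = character(0),
                      count = integer(0)))
  }
  tab <- table(codon_index = ci[keep], consequence = inst$consequence[keep])
  d <- as.data.frame(tab, stringsAsFactors = FALSE)
  d <- d[d$Freq > 0L, , drop = FALSE]
  data.frame(codon_index = as.integer(d$codon_index),
             consequence = d$consequence, count = as.integer(d$Freq),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-tumor-type alteration and truncation frequencies
#'
#' For each cancer type: the fraction of samples with any mutation, with a
#' truncating mutation (nonsense, frameshift or splice), and with an exon-6
#' truncation (nonsense in exon 6 or frameshift whose premature stop lands in
#' exon 6).
#'
#' @param records Normalized record data frame.
#' @param samples_per_type Optional named vector of per-type sample totals;
#'   defaults to distinct samples present per type (wild-type placeholder rows
#'   included).
#' @param model A [gene_model] (used for the exon-6 truncation rule).
#' @return Data frame with one row per type.
#' @export
tumor_type_summary <- function(records, samples_per_type = NULL,
                               model = NULL) {
  type <- ifelse(is.na(records$cancer_type), "<NA>", records$cancer_type)
  types <- sort(unique(type))
  inst <- count_instances(records)
  itype <- ifelse(is.na(inst$cancer_type), "<NA>", inst$cancer_type)
  trunc_classes <- c("nonsense", "frameshift", "splice")
  ex6 <- if (is.null(model)) {
    (inst$consequence %in% c("nonsense", "frameshift")) &
      !is.na(inst$exon_label) & inst$exon_label == 6L
  } else {
    is_exon_truncation(model, inst, exon = 6L)
  }
  rows <- lapply(types, function(tt) {
    total <- if (!is.null(samples_per_type) && tt %in% names(samples_per_type)) {
      as.integer(samples_per_type[[tt]])
    } else {
      length(unique(records$sample_id[type == tt]))
    }
    if (is.na(total) || total == 0L) {
      message("excluding cancer type '", tt, "' with zero samples")
      return(NULL)
    }
    sel <- itype == tt
    data.frame(
      cancer_type = tt,
      n_samples = total,
      frac_altered = length(unique(inst$sample_id[sel])) / total,
      frac_truncating = length(unique(
        inst$sample_id[sel & inst$consequence %in% trunc_classes])) / total,
      frac_exon6_truncation = length(unique(
        inst$sample_id[sel & ex6])) / total,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-sample reporting class used by site contrasts
#'
#' Samples with no mutation are `"none"`; samples with two or more distinct
#' changes are `"multiple"`; single-mutation samples take their mutation's
#' class, with nonsense split into `"exon6_nonsense"` and `"other_nonsense"`
#' and frameshift/in-frame indels reported as `"fs_indel"`/`"if_indel"`.
#'
#' @param records Normalized record data frame.
#' @return Data frame `sample_id`, `sample_site`, `cancer_type`, `class`.
#' @export
sample_classes <- function(records) {
  inst <- count_instances(records)
  ids <- unique(records$sample_id)
  nmut <- table(factor(inst$sample_id, levels = ids))
  cls <- rep("none", length(ids))
  names(cls) <- ids
  cls[names(nmut)[nmut >= 2L]] <- "multiple"
  single <- names(nmut)[nmut == 1L]
  if (length(single) > 0L) {
    one <- inst[inst$sample_id %in% single, , drop = FALSE]
    map <- vapply(seq_len(nrow(one)), function(i) {
      switch(one$consequence[i],
        nonsense = if (!is.na(one$exon_label[i]) && one$exon_label[i] == 6L)
          "exon6_nonsense" else "other_nonsense",
        frameshift = "fs_indel",
        inframe_indel = "if_indel",
        splice = "splice",
        missense = "missense",
        synonymous = "synonymous",
        "other")
    }, character(1))
    cls[one$sample_id] <- map
  }
  site <- records$sample_site[match(ids, records$sample_id)]
  ctype <- records$cancer_type[match(ids, records$sample_id)]
  data.frame(sample_id = ids, sample_site = site, cancer_type = ctype,
             class = unname(cls), stringsAsFactors = FALSE)
}

#' Primary-versus-metastasis contrast of mutation classes
#'
#' For each per-sample class, counts over primary and metastasis samples, the
#' metastasis/primary frequency ratio, and a two-sided Fisher exact p-value of
#' the class against the reference group across sites. The default reference
#' is the wild-type (`"none"`) class, i.e. each class is tested for
#' over-representation in metastases with respect to wild-type cases;
#' `reference = "rest"` tests class versus all other samples.
#'
#' @param records Normalized record data frame with `sample_site` labels.
#' @param reference `"none"` or `"rest"`.
#' @return Data frame with one row per class (reference class included, with
#'   `p_value = NA` under the `"none"` reference).
#' @export
compare_sites <- function(records, reference = c("none", "rest")) {
  reference <- match.arg(reference)
  sc <- sample_classes(records)
  sc <- sc[sc$sample_site %in% c("primary", "metastasis"), , drop = FALSE]
  n_prim <- sum(sc$sample_site == "primary")
  n_met <- sum(sc$sample_site == "metastasis")
  if (n_prim == 0L) stop("no samples labeled primary")
  if (n_met == 0L) stop("no samples labeled metastasis")
  classes <- c("splice", "exon6_nonsense", "other_nonsense", "if_indel",
               "fs_indel", "missense", "synonymous", "other", "multiple",
               "none")
  classes <- classes[classes %in% unique(sc$class)]
  none_prim <- sum(sc$class == "none" & sc$sample_site == "primary")
  none_met <- sum(sc$class == "none" & sc$sample_site == "metastasis")
  rows <- lapply(classes, function(cl) {
    cp <- sum(sc$class == cl & sc$sample_site == "primary")
    cm <- sum(sc$class == cl & sc$sample_site == "metastasis")
    fp <- cp / n_prim
    fm <- cm / n_met
    ratio <- if (cp == 0L && cm == 0L) NA_real_ else if (fp == 0) Inf
             else fm / fp
    p <- if (reference == "none") {
      if (cl == "none") NA_real_
      else stats::fisher.test(matrix(c(cp, none_prim, cm, none_met), 2L))$p.value
    } else {
      stats::fisher.test(matrix(c(cp, n_prim - cp, cm, n_met - cm), 2L))$p.value
    }
    data.frame(class = cl, primary_count = cp, primary_total = n_prim,
               metastasis_count = cm, metastasis_total = n_met,
               primary_freq = fp, metastasis_freq = fm,
               frequency_ratio = ratio, p_value = p,
               flagged_absent = cp == 0L && cm == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
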