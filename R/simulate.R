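# Seeded MAF-style catalog simulator with known generative truth.
#
# Mutations are drawn from the theoretical SNV space under a uniform null with
# multiplicative selection weights on class-by-region strata; optional indel
# and splice admixture and primary/metastasis cohort structure. Each sample
# uses a counter-derived RNG substream, so enlarging a cohort never perturbs
# the draws of earlier samples.

.parse_stratum_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
  exon <- NA_integer_
  if (length(parts) > 1L) {
    exon <- suppressWarnings(as.integer(sub("^exon", "", parts[2L])))
    if (is.na(exon)) stop("cannot parse stratum key '", key,
                          "' (expected 'class' or 'class:exon<k>')")
  }
  list(class = parts[1L], exon = exon)
}

.change_weights <- function(theoretical, weight_map) {
  w <- rep(1, nrow(theoretical))
  if (is.null(weight_map) || length(weight_map) == 0L) return(w)
  if (any(unlist(weight_map) < 0)) stop("selection weights must be >= 0")
  for (k in names(weight_map)) {
    s <- .parse_stratum_key(k)
    sel <- .stratum_match(theoretical$consequence, theoretical$exon_label,
                          s$class, s$exon)
    w[sel] <- w[sel] * weight_map[[k]]
  }
  w
}

#' Configuration for the catalog simulator
#'
#' @param n_samples Number of tumor samples (> 0).
#' @param seed Integer seed (mandatory; all draws derive from it).
#' @param cancer_types Named numeric vector of type proportions (normalized).
#' @param mutations_per_sample Poisson mean of mutations per sample.
#' @param weight_map Named numeric vector/list of multiplicative selection
#'   weights on strata, keyed `"class"` or `"class:exon<k>"`
#'   (e.g. `c("nonsense:exon6" = 5)`); unnamed strata keep weight 1.
#' @param indel_rate,splice_rate Per-mutation probabilities of drawing an
#'   indel (length uniform on 1..6, insertion/deletion equiprobable) or a
#'   class-only splice event instead of an SNV.
#' @param metastasis_fraction Fraction of samples labeled metastasis.
#' @param site_weight_map Extra multiplicative weights applied on top of
#'   `weight_map` for metastasis samples only.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200L, seed,
                       cancer_types = c(SIM = 1),
                       mutations_per_sample = 1,
                       weight_map = NULL,
                       indel_rate = 0, splice_rate = 0,
                       metastasis_fraction = 0,
                       site_weight_map = NULL) {
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' is mandatory and must be a single integer")
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) stop("n_samples must be >= 1")
  probs <- c(indel_rate, splice_rate, metastasis_fraction)
  if (any(probs < 0) || any(probs > 1) || indel_rate + splice_rate > 1) {
    stop("rates must lie in [0, 1] with indel_rate + splice_rate <= 1")
  }
  if (mutations_per_sample < 0) stop("mutations_per_sample must be >= 0")
  if (is.null(names(cancer_types)) || any(cancer_types < 0) ||
      sum(cancer_types) <= 0) {
    stop("cancer_types must be a named vector of non-negative proportions")
  }
  structure(list(n_samples = n_samples, seed = as.integer(seed),
                 cancer_types = cancer_types / sum(cancer_types),
                 mutations_per_sample = mutations_per_sample,
                 weight_map = weight_map,
                 indel_rate = indel_rate, splice_rate = splice_rate,
                 metastasis_fraction = metastasis_fraction,
                 site_weight_map = site_weight_map),
            class = "sim_config")
}

.sample_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(i)) %% 2147483629) + 1L
}

.snv_maf_class <- c(synonymous = "Silent", missense = "Missense_Mutation",
                    nonsense = "Nonsense_Mutation",
                    nonstop = "Nonstop_Mutation")

#' Simulate a MAF-style somatic mutation catalog with known truth
#'
#' Each mutation is an SNV drawn from the theoretical change space with
#' probability proportional to its stratum weight (metastasis samples apply
#' `site_weight_map` on top), or, with the configured rates, a uniform indel
#' or a class-only splice event. Samples without mutations emit a wild-type
#' placeholder row so cohort totals survive the catalog round trip. Records
#' carry both HGVS protein and CDS descriptions and are normalized through the
#' same path as [read_catalog()], exercising the parsers end-to-end. Output is
#' deterministic given the configuration (which includes the seed).
#'
#' @param model A [gene_model].
#' @param config A [sim_config].
#' @return List with `records` (normalized), `catalog` (raw MAF-minimal data
#'   frame) and `truth` (see [truth_expected_fold()]).
#' @export
simulate_catalog <- function(model, config) {
  stopifnot(inherits(model, "gene_model"), inherits(config, "sim_config"))
  theoretical <- enumerate_theoretical_snvs(model)
  w_prim <- .change_weights(theoretical, config$weight_map)
  w_met <- w_prim * .change_weights(theoretical, config$site_weight_map)
  if (sum(w_prim) <= 0 || sum(w_met) <= 0) {
    stop("all-zero selection weights leave no positive-probability event")
  }
  L <- nchar(model$cds)
  types <- names(config$cancer_types)

  acc <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    set.seed(.sample_seed(config$seed, i))
    sid <- sprintf("S%06d", i)
    site <- if (stats::runif(1) < config$metastasis_fraction) "metastasis"
            else "primary"
    ctype <- if (length(types) == 1L) types else
      sample(types, 1L, prob = config$cancer_types)
    k <- stats::rpois(1L, config$mutations_per_sample)
    if (k == 0L) {
      acc[[i]] <- data.frame(sample_id = sid, raw_class = "None",
                             hgvsp = "", hgvsc = "", cancer_type = ctype,
                             sample_site = site, stringsAsFactors = FALSE)
      next
    }
    u <- stats::runif(k)
    kind <- ifelse(u < config$splice_rate, "splice",
            ifelse(u < config$splice_rate + config$indel_rate, "indel", "snv"))
    raw_class <- character(k); hgvsp <- character(k); hgvsc <- character(k)
    n_snv <- sum(kind == "snv")
    if (n_snv > 0L) {
      w <- if (site == "metastasis") w_met else w_prim
      idx <- sample.int(nrow(theoretical), n_snv, replace = TRUE, prob = w)
      raw_class[kind == "snv"] <-
        unname(.snv_maf_class[theoretical$consequence[idx]])
      hgvsp[kind == "snv"] <- paste0("p.", theoretical$protein_change[idx])
      hgvsc[kind == "snv"] <- sprintf("c.%d%s>%s", theoretical$cds_pos[idx],
                                      theoretical$ref[idx],
                                      theoretical$alt[idx])
    }
    for (j in which(kind == "indel")) {
      len <- sample.int(6L, 1L)
      del <- stats::runif(1) < 0.5
      fs <- len %% 3L != 0L
      if (del) {
        pos <- sample.int(L - len + 1L, 1L)
        raw_class[j] <- if (fs) "Frame_Shift_Del" else "In_Frame_Del"
        hgvsc[j] <- if (len == 1L) sprintf("c.%ddel", pos)
                    else sprintf("c.%d_%ddel", pos, pos + len - 1L)
        anchor_codon <- (pos + 2L) %/% 3L
      } else {
        pos <- sample.int(L - 1L, 1L)
        seqs <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = "")
        raw_class[j] <- if (fs) "Frame_Shift_Ins" else "In_Frame_Ins"
        hgvsc[j] <- sprintf("c.%d_%dins%s", pos, pos + 1L, seqs)
        anchor_codon <- (pos + 3L) %/% 3L
      }
      hgvsp[j] <- if (fs) paste0("p.", model$.protein[anchor_codon],
                                 anchor_codon, "fs") else ""
    }
    raw_class[kind == "splice"] <- "Splice_Site"
    acc[[i]] <- data.frame(sample_id = sid, raw_class = raw_class,
                           hgvsp = hgvsp, hgvsc = hgvsc, cancer_type = ctype,
                           sample_site = site, stringsAsFactors = FALSE)
  }
  std <- do.call(rbind, acc)
  std$gene <- model$symbol
  records <- normalize_catalog(std, model)
  catalog <- data.frame(
    Hugo_Symbol = std$gene,
    Tumor_Sample_Barcode = std$sample_id,
    Variant_Classification = std$raw_class,
    HGVSp_Short = std$hgvsp,
    HGVSc = std$hgvsc,
    Cancer_Type = std$cancer_type,
    Sample_Site = std$sample_site,
    stringsAsFactors = FALSE
  )
  truth <- truth_expected_fold(config, model, theoretical = theoretical)
  list(records = records, catalog = catalog, truth = truth)
}

#' Closed-form expected folds of a simulation configuration
#'
#' For stratum s with weight w_s, the sampling probability of a change in s is
#' its weight share of the SNV space, and the expected fold is that
#' probability divided by the stratum's null fraction — algebraically
#' `w / (1 - f + w * f)` when a single stratum of null fraction f carries
#' weight w.
#'
#' @param config A [sim_config].
#' @param model A [gene_model].
#' @param theoretical Optional precomputed enumeration.
#' @return Data frame over the default strata plus every weighted stratum:
#'   null fraction, SNV sampling probabilities and expected folds for primary
#'   and metastasis samples.
#' @export
truth_expected_fold <- function(config, model, theoretical = NULL) {
  if (is.null(theoretical)) theoretical <- enumerate_theoretical_snvs(model)
  keys <- unique(c(names(config$weight_map), names(config$site_weight_map)))
  strata <- default_strata()
  for (k in keys) {
    s <- .parse_stratum_key(k)
    lab <- if (is.na(s$exon)) s$class else paste0(s$class, ":exon", s$exon)
    if (!lab %in% strata$stratum) {
      strata <- rbind(strata, make_strata(s$class, s$exon))
    }
  }
  w_prim <- .change_weights(theoretical, config$weight_map)
  w_met <- w_prim * .change_weights(theoretical, config$site_weight_map)
  n <- nrow(theoretical)
  out <- strata
  out$null_fraction <- .theoretical_counts(theoretical, strata) / n
  out$prob_primary <- vapply(seq_len(nrow(strata)), function(i) {
    sel <- .stratum_match(theoretical$consequence, theoretical$exon_label,
                          strata$class[i], strata$exon[i])
    sum(w_prim[sel]) / sum(w_prim)
  }, numeric(1))
  out$prob_metastasis <- vapply(seq_len(nrow(strata)), function(i) {
    sel <- .stratum_match(theoretical$consequence, theoretical$exon_label,
                          strata$class[i], strata$exon[i])
    sum(w_met[sel]) / sum(w_met)
  }, numeric(1))
  out$expected_fold_primary <- ifelse(out$null_fraction > 0,
                                      out$prob_primary / out$null_fraction, 0)
  out$expected_fold_metastasis <- ifelse(out$null_fraction > 0,
                                         out$prob_metastasis / out$null_fraction,
                                         0)
  out
}

#' Read a flat key=value simulation configuration file
#'
#' Recognized keys: `n_samples`, `seed`, `mutations_per_sample`,
#' `indel_rate`, `splice_rate`, `metastasis_fraction`,
#' `weight.<class[:exonK]>` and `site_weight.<class[:exonK]>` for weights, and
#' `cancer_type.<LABEL>` for type proportions. Lines starting with `#` are
#' comments.
#'
#' @param path Path to the configuration file.
#' @return A [sim_config].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed config line: '", lines[bad][1L], "'")
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  getnum <- function(k, default) {
    if (k %in% keys) as.numeric(vals[keys == k][1L]) else default
  }
  pick <- function(prefix) {
    sel <- startsWith(keys, prefix)
    if (!any(sel)) return(NULL)
    stats::setNames(as.numeric(vals[sel]), substring(keys[sel],
                                                     nchar(prefix) + 1L))
  }
  ct <- pick("cancer_type.")
  if (is.null(ct)) ct <- c(SIM = 1)
  sim_config(
    n_samples = getnum("n_samples", 200),
    seed = getnum("seed", NA),
    cancer_types = ct,
    mutations_per_sample = getnum("mutations_per_sample", 1),
    weight_map = as.list(pick("weight.")),
    indel_rate = getnum("indel_rate", 0),
    splice_rate = getnum("splice_rate", 0),
    metastasis_fraction = getnum("metastasis_fraction", 0),
    site_weight_map = as.list(pick("site_weight."))
  )
}
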