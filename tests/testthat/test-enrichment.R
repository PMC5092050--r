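test_that("expected fractions normalize and match brute-force enumeration", {
  m <- toy_model()
  theo <- enumerate_theoretical_snvs(m)
  # independent oracle: classify all 27 changes by full-translation diff
  oracle_counts <- table(vapply(seq_len(nrow(theo)), function(i) {
    oracle_classify(m, theo$cds_pos[i], theo$alt[i])
  }, character(1)))
  strata <- make_strata(names(oracle_counts))
  fr <- expected_fractions(theo, strata)
  expect_equal(as.numeric(fr[names(oracle_counts)]),
               as.numeric(oracle_counts) / 27)
  expect_equal(sum(fr), 1)

  full <- expected_fractions(theo_tp53,
                             make_strata(c("synonymous", "missense",
                                           "nonsense", "nonstop")))
  expect_equal(sum(full), 1)

  ext <- expected_fractions(theo_tp53, make_strata("nonsense"),
                            denominator = "extended")
  expect_lt(ext[["nonsense"]], full[["nonsense"]])
  expect_error(expected_fractions(theo_tp53[0, ], make_strata("nonsense")),
               "empty")
})

test_that("observed fractions count deduplicated instances per stratum", {
  std <- data.frame(
    sample_id = sprintf("s%d", 1:10),
    raw_class = c(rep("Missense_Mutation", 4), rep("Nonsense_Mutation", 3),
                  rep("Silent", 3)),
    hgvsp = paste0("p.", c("G245D", "R175H", "R273H", "V157F",
                           "R213*", "R196*", "R306*",
                           "R213=", "T125=", "L45=")),
    hgvsc = "", cancer_type = "SIM", sample_site = "",
    stringsAsFactors = FALSE)
  rec <- normalize_catalog(std, tp53)
  fr <- observed_fractions(rec, make_strata(c("missense", "nonsense")))
  expect_equal(unname(fr["missense"]), 0.4)
  expect_equal(unname(fr["nonsense"]), 0.3)
  only_ns <- rec[rec$consequence == "nonsense", ]
  expect_equal(unname(observed_fractions(only_ns,
                                         make_strata("nonsense"))["nonsense"]),
               1.0)
  expect_error(observed_fractions(rec[0, ], make_strata("nonsense")), "empty")
})

test_that("fold enrichment is the observed/expected ratio", {
  expect_equal(fold_enrichment(0.084, 0.054), 0.084 / 0.054, tolerance = 1e-12)
  expect_equal(round(fold_enrichment(0.084, 0.054), 2), 1.56)
  expect_equal(fold_enrichment(0.3, 0.3), 1.0)
  expect_equal(fold_enrichment(0, 0.1), 0)
  expect_error(fold_enrichment(0.1, 0), "undefined")
})

test_that("recurrence frequency is instances per unique change", {
  std <- data.frame(
    sample_id = sprintf("s%d", 1:10),
    raw_class = "Nonsense_Mutation",
    hgvsp = c(rep("p.R213*", 6), rep("p.R196*", 4)),
    hgvsc = "", cancer_type = "SIM", sample_site = "",
    stringsAsFactors = FALSE)
  rec <- normalize_catalog(std, tp53)
  r <- recurrence_frequency(rec, make_strata("nonsense"))
  expect_identical(r$instances, 10L)
  expect_identical(r$unique_changes, 2L)
  expect_equal(r$recurrence, 5.0)
  expect_equal(r$per_sample, 0.5)

  # every change unique -> recurrence 1; empty stratum -> 0 with flag
  std$hgvsp <- paste0("p.R", 100 + 1:10, "*")
  rec <- normalize_catalog(std, tp53)
  r <- recurrence_frequency(rec, make_strata(c("nonsense", "missense")))
  expect_equal(r$recurrence, c(1, 0))
  expect_identical(r$flagged_empty, c(FALSE, TRUE))
})

test_that("Fisher enrichment test matches the hypergeometric tail-sum oracle", {
  res <- enrichment_test(10L, 90L, 5L, 995L)
  expect_lt(abs(res$p_value - oracle_fisher_p(10L, 90L, 5L, 995L)), 1e-9)
  expect_false(res$degenerate)

  # composition identical to the null at scale: p ~ 1
  flat <- enrichment_test(100L, 900L, 1000L, 9000L)
  expect_gt(flat$p_value, 0.9)

  degen <- enrichment_test(0L, 0L, 3L, 7L)
  expect_true(degen$degenerate)
  expect_identical(degen$p_value, 1)

  set.seed(404)
  for (r in seq_len(40L)) {
    cells <- sample.int(50L, 4L, replace = TRUE)
    got <- enrichment_test(cells[1], cells[3], cells[2], cells[4])$p_value
    want <- oracle_fisher_p(cells[1], cells[3], cells[2], cells[4])
    expect_lt(abs(got - want), 1e-9)
  }
})

test_that("BH adjustment reproduces hand-computed q-values", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(0.04, 5)), rep(0.04, 5))
  expect_identical(adjust_bh(numeric(0)), numeric(0))
  p <- c(0.001, 0.01, 0.04, 0.8)
  expect_true(all(adjust_bh(p) >= p))
})

test_that("enrichment table ties counts, folds and tests together", {
  cfg <- sim_config(n_samples = 300L, seed = 9L)
  rec <- simulate_catalog(tp53, cfg)$records
  tab <- enrichment_table(tp53, rec, theoretical = theo_tp53)
  expect_identical(tab$obs_in + tab$obs_out,
                   rep(nrow(count_instances(rec)), nrow(tab)))
  expect_identical(tab$theo_in + tab$theo_out, rep(3546L, nrow(tab)))
  expect_true(all(tab$q_value >= tab$p_value - 1e-12))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  # full partition of classes: observed and expected fractions each sum to 1
  part <- enrichment_table(tp53, rec,
                           make_strata(c("synonymous", "missense",
                                         "nonsense", "nonstop")),
                           theoretical = theo_tp53)
  expect_equal(sum(part$expected_fraction), 1)
  expect_equal(sum(part$observed_fraction), 1)
})

test_that("tumor-type summary recovers planted per-type fractions", {
  mk <- function(type, classes, hgvsp, hgvsc = "") {
    data.frame(sample_id = sprintf("%s%03d", type, seq_along(classes)),
               raw_class = classes, hgvsp = hgvsp, hgvsc = hgvsc,
               cancer_type = type, sample_site = "", stringsAsFactors = FALSE)
  }
  # type X: 4 samples, all mutant, 2 truncating (1 in exon 6)
  x <- mk("X", c("Nonsense_Mutation", "Nonsense_Mutation",
                 "Missense_Mutation", "Missense_Mutation"),
          c("p.R213*", "p.W146*", "p.G245D", "p.R175H"))
  # type Y: 4 samples, 2 mutant, no truncations
  y <- mk("Y", c("Missense_Mutation", "Silent", "None", "None"),
          c("p.R273H", "p.R213=", "", ""))
  rec <- normalize_catalog(rbind(x, y), tp53)
  s <- tumor_type_summary(rec, model = tp53)
  sx <- s[s$cancer_type == "X", ]
  expect_equal(sx$frac_altered, 1.0)
  expect_equal(sx$frac_truncating, 0.5)
  expect_equal(sx$frac_exon6_truncation, 0.25)
  sy <- s[s$cancer_type == "Y", ]
  expect_equal(sy$frac_altered, 0.5)
  expect_equal(sy$frac_truncating, 0.0)
})

test_that("site contrast: symmetric cohorts give unit ratios, absences flag", {
  mk <- function(site, n_ns, n_ms, n_wt) {
    data.frame(
      sample_id = sprintf("%s%03d", site, seq_len(n_ns + n_ms + n_wt)),
      raw_class = c(rep("Nonsense_Mutation", n_ns),
                    rep("Missense_Mutation", n_ms), rep("None", n_wt)),
      hgvsp = c(rep("p.R213*", n_ns), rep("p.G245D", n_ms), rep("", n_wt)),
      hgvsc = "", cancer_type = "CRC", sample_site = site,
      stringsAsFactors = FALSE)
  }
  rec <- normalize_catalog(rbind(mk("primary", 5L, 10L, 35L),
                                 mk("metastasis", 5L, 10L, 35L)), tp53)
  ct <- compare_sites(rec)
  expect_equal(ct$frequency_ratio[ct$class == "exon6_nonsense"], 1.0)
  expect_equal(ct$frequency_ratio[ct$class == "missense"], 1.0)
  expect_true(all(ct$p_value[ct$class != "none"] > 0.5, na.rm = TRUE))
  expect_false(any(ct$flagged_absent[ct$class %in%
                                       c("exon6_nonsense", "missense")]))

  only_primary <- normalize_catalog(mk("primary", 2L, 2L, 2L), tp53)
  expect_error(compare_sites(only_primary), "metastasis")
})
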