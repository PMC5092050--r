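test_that("protein-change parsing handles the standard short forms", {
  p <- parse_protein_change(c("R196*", "p.G245D", "W146*", "T125Tfs*8",
                              "R213=", "p.R306*", "R213fs", "?!"))
  expect_identical(p$ok, c(rep(TRUE, 7L), FALSE))
  expect_identical(p$ref_aa[1:4], c("R", "G", "W", "T"))
  expect_identical(p$position[1:4], c(196L, 245L, 146L, 125L))
  expect_identical(p$alt[c(1, 2, 4, 5, 7)], c("*", "D", "fs", "=", "fs"))
})

test_that("CDS-change parsing handles substitutions, deletions, insertions", {
  p <- parse_cds_change(c("c.637C>T", "c.455del", "c.455delC", "c.372_380del",
                          "c.455_456insTT", "c.100_102dup", "garbage"))
  expect_identical(p$ok, c(rep(TRUE, 6L), FALSE))
  expect_identical(p$op[1:6], c("sub", "del", "del", "del", "ins", "dup"))
  expect_identical(p$cds_pos[1:6], c(637L, 455L, 455L, 372L, 455L, 100L))
  expect_identical(p$cds_len[1:6], c(1L, 1L, 1L, 9L, 2L, 3L))
  expect_identical(p$cds_ref[1], "C")
  expect_identical(p$cds_alt[1], "T")
  expect_identical(p$ins_seq[5], "TT")
})

test_that("raw MAF vocabulary maps onto consequence classes", {
  expect_identical(normalize_class(c("Nonsense_Mutation", "Frame_Shift_Del",
                                     "In_Frame_Ins", "Splice_Site", "Silent",
                                     "weird_label", "None", "")),
                   c("nonsense", "frameshift", "inframe_indel", "splice",
                     "synonymous", "other", "none", "none"))
})

test_that("read_catalog normalizes rows, assigns exons, drops other genes", {
  tmp <- tempfile(fileext = ".tsv")
  write_toy_maf(tmp,
    sample = c("s1", "s2", "s3", "s4"),
    class = c("Nonsense_Mutation", "Missense_Mutation", "Frame_Shift_Del",
              "Missense_Mutation"),
    hgvsp = c("p.R213*", "p.G245D", "p.K120fs", "p.V600E"),
    hgvsc = c("c.637C>T", "", "c.358del", ""),
    gene = c("TP53", "TP53", "TP53", "BRAF"))
  expect_message(rec <- read_catalog(tmp, tp53), "dropping 1 row")
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$consequence, c("nonsense", "missense", "frameshift"))
  expect_identical(rec$exon_label[1], 6L)      # mutated base c.637
  expect_identical(rec$protein_pos[1], 213L)
  expect_identical(rec$exon_label[2], exon_of(tp53, 3L * 245L - 2L))
  log <- attr(rec, "log")
  expect_identical(log$rows_read, 4L)
  expect_identical(log$dropped_other_gene, 1L)
  expect_identical(log$rows_read, log$kept + log$dropped_other_gene)
})

test_that("an empty catalog with a header reads as zero records", {
  tmp <- tempfile(fileext = ".tsv")
  write_toy_maf(tmp, sample = character(0), class = character(0))
  rec <- read_catalog(tmp, tp53)
  expect_identical(nrow(rec), 0L)
})

test_that("missing required columns raise a described error", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines("Hugo_Symbol\tHGVSp_Short\nTP53\tp.R213*", tmp)
  expect_error(read_catalog(tmp, tp53), "missing required columns")
})

test_that("the cbioportal dialect maps its own column names", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("Sample ID\tCancer Type\tProtein Change\tMutation Type\tSample Type",
               "s1\tCRC\tR213*\tNonsense_Mutation\tPrimary",
               "s2\tCRC\tG245D\tMissense_Mutation\tMetastasis"), tmp)
  rec <- read_catalog(tmp, tp53, dialect = "cbioportal")
  expect_identical(rec$consequence, c("nonsense", "missense"))
  expect_identical(rec$sample_site, c("primary", "metastasis"))
  expect_identical(rec$exon_label[1], 6L)
})

test_that("write/read round trip preserves all normalized fields", {
  cfg <- sim_config(n_samples = 60L, seed = 77L, indel_rate = 0.15,
                    splice_rate = 0.05, metastasis_fraction = 0.4)
  sim <- simulate_catalog(tp53, cfg)
  tmp <- tempfile(fileext = ".tsv")
  write_catalog(sim$records, tmp)
  back <- read_catalog(tmp, tp53)
  cols <- c("sample_id", "cancer_type", "sample_site", "raw_class",
            "consequence", "hgvsp", "hgvsc", "protein_pos", "cds_pos",
            "cds_op", "exon_label", "change_key")
  for (cl in cols) {
    expect_identical(back[[cl]], sim$records[[cl]])
  }
})

test_that("unique-change keys identify biological changes across samples", {
  tmp <- tempfile(fileext = ".tsv")
  write_toy_maf(tmp, sample = c("s1", "s2", "s1", "s3"),
                class = "Nonsense_Mutation",
                hgvsp = c("p.R213*", "p.R213*", "p.R213*", "p.R196*"))
  rec <- read_catalog(tmp, tp53)
  expect_identical(rec$change_key[1], rec$change_key[2])
  expect_false(rec$change_key[1] == rec$change_key[4])
  inst <- count_instances(rec)
  # s1's duplicate row collapses: 3 instances, 2 unique changes
  expect_identical(nrow(inst), 3L)
  expect_identical(length(unique(inst$change_key)), 2L)
})

test_that("duplicating every row changes no instance or unique counts", {
  cfg <- sim_config(n_samples = 40L, seed = 5L)
  rec <- simulate_catalog(tp53, cfg)$records
  doubled <- rbind(rec, rec)
  expect_identical(nrow(count_instances(doubled)), nrow(count_instances(rec)))
  expect_identical(unique(count_instances(doubled)$change_key),
                   unique(count_instances(rec)$change_key))
})

test_that("protein- and CDS-derived exon assignment agree off junction codons", {
  set.seed(33)
  cand <- theo_tp53[!(theo_tp53$codon_index %in% tp53_junction_codons) &
                      theo_tp53$consequence %in%
                        c("missense", "nonsense", "synonymous"), ]
  pick <- cand[sample.int(nrow(cand), 120L), ]
  raw_cls <- c(missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
               synonymous = "Silent")
  tmp1 <- tempfile(fileext = ".tsv")
  write_toy_maf(tmp1, sample = sprintf("s%d", seq_len(nrow(pick))),
                class = unname(raw_cls[pick$consequence]),
                hgvsp = paste0("p.", pick$protein_change), hgvsc = "")
  tmp2 <- tempfile(fileext = ".tsv")
  write_toy_maf(tmp2, sample = sprintf("s%d", seq_len(nrow(pick))),
                class = unname(raw_cls[pick$consequence]),
                hgvsp = "",
                hgvsc = sprintf("c.%d%s>%s", pick$cds_pos, pick$ref, pick$alt))
  from_protein <- read_catalog(tmp1, tp53)$exon_label
  from_cds <- read_catalog(tmp2, tp53)$exon_label
  expect_identical(from_protein, from_cds)
})

test_that("positions beyond the protein leave the exon unknown with a flag", {
  tmp <- tempfile(fileext = ".tsv")
  write_toy_maf(tmp, sample = "s1", class = "Missense_Mutation",
                hgvsp = "p.G9999D")
  rec <- read_catalog(tmp, tp53)
  expect_true(is.na(rec$exon_label[1]))
  expect_identical(attr(rec, "log")$exon_unknown, 1L)
})

test_that("study filter applies both thresholds per cancer type", {
  mk <- function(type, n_samp, n_mut) {
    data.frame(sample_id = sprintf("%s%03d", type, seq_len(n_samp)),
               raw_class = c(rep("Missense_Mutation", n_mut),
                             rep("None", n_samp - n_mut)),
               hgvsp = c(rep("p.G245D", n_mut), rep("", n_samp - n_mut)),
               hgvsc = "", cancer_type = type, sample_site = "",
               stringsAsFactors = FALSE)
  }
  std <- rbind(mk("A", 150L, 20L), mk("B", 50L, 20L), mk("C", 150L, 5L))
  rec <- normalize_catalog(std, tp53)
  fs <- filter_studies(rec, 100L, 10L)
  expect_identical(fs$report$kept[fs$report$cancer_type == "A"], TRUE)
  expect_identical(fs$report$kept[fs$report$cancer_type == "B"], FALSE)
  expect_identical(fs$report$kept[fs$report$cancer_type == "C"], FALSE)
  expect_setequal(unique(fs$records$cancer_type), "A")

  empty <- filter_studies(rec[0, ], 100L, 10L)
  expect_identical(nrow(empty$records), 0L)
  expect_error(filter_studies(rec, 0L, 10L), "positive")
})
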