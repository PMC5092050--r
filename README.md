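# mutenrich

Observed-versus-expected enrichment analysis of somatic coding mutation
classes, built around the question of whether truncating (stop-gained)
mutations in a cancer gene — TP53's exon-6 nonsense mutations in particular —
occur more often than chance substitution would predict.

## Who this is for

Cancer genomicists and methods developers who want a small, fully testable
pipeline that (1) builds a theoretical null for the class composition of
coding mutations, (2) normalizes MAF-style somatic mutation catalogs, and
(3) tests class-by-region strata for enrichment, recurrence and
primary-versus-metastasis differences — with a seeded simulator so every
stage can be validated against known generative truth, no external downloads
required.

## The model

For a coding sequence of length *L* (terminal stop codon included), the
**theoretical change space** is the set of all 3*L* single-nucleotide
substitutions. Each change is classified by translating its codon: same
residue → synonymous, residue → stop → nonsense (stop-gained), stop → residue
→ nonstop (stop-loss), otherwise missense. Under a uniform substitution null,
the **expected fraction** of a stratum *s* (a consequence class, optionally
restricted to one exon) is

    e_s = T_s / 3L,            T_s = theoretical changes in s.

Given a mutation catalog with *N* deduplicated instances (one instance = one
distinct sample × unique-change pair), the observed fraction is
`o_s = n_s / N` and the **fold enrichment** is `F_s = o_s / e_s` —
equivalently the per-theoretical-site mutation rate of the stratum relative
to all mutations. Departure from the null is tested two-sided with Fisher's
exact test on the 2×2 table

    [ n_s   N − n_s  ]
    [ T_s   3L − T_s ]

with Benjamini–Hochberg adjustment across the strata of one report.
**Exon-6 truncations** follow the standard definition: a nonsense mutation
located in exon 6, or a frameshift indel whose introduced premature stop
codon — located by translating the full mutant CDS — falls in exon 6.

A TP53 gene model ships with the package: the canonical 1182-nt CDS (393
residues) and its ten coding exon segments (labels 2–11) in CDS coordinates.

## Worked example

Plant a 5× selection weight on exon-6 nonsense changes in a simulated
1000-tumor cohort, then recover it:

```r
library(mutenrich)
model <- tp53_gene_model()
#> <gene_model> TP53: CDS 1182 nt, 393 aa, 10 exon segment(s) [2,3,4,5,6,7,8,9,10,11]

theo <- enumerate_theoretical_snvs(model)
round(expected_fractions(theo, default_strata()), 4)
#>     synonymous       missense       nonsense        nonstop nonsense:exon6
#>         0.2343         0.7270         0.0364         0.0023         0.0042

cfg <- sim_config(n_samples = 1000, seed = 42,
                  weight_map = c("nonsense:exon6" = 5))
sim <- simulate_catalog(model, cfg)
tab <- enrichment_table(model, sim$records, theoretical = theo)
tab[, c("stratum", "instances", "observed_fraction", "fold", "p_value", "q_value")]
#>          stratum instances observed_fraction  fold p_value q_value
#> 1     synonymous       257           0.25221 1.076 0.24293 0.30366
#> 2       missense       714           0.70069 0.964 0.10416 0.26040
#> 3       nonsense        46           0.04514 1.241 0.19601 0.30366
#> 4        nonstop         2           0.00196 0.870 1.00000 1.00000
#> 5 nonsense:exon6        15           0.01472 3.480 0.00127 0.00635
```

Only the planted stratum is significant after adjustment. Its estimated fold
(3.48) sits within sampling error of the closed-form truth for this
configuration:

```r
sim$truth[sim$truth$stratum == "nonsense:exon6",
          c("null_fraction", "expected_fold_primary")]
#>   null_fraction expected_fold_primary
#> 5       0.00423                  4.92
```

(With weight *w* on a stratum of null fraction *f*, the expected fold is
`w / (1 − f + w f)`; here 5 / (1 − 0.00423 + 5 × 0.00423) = 4.92.)

Named stop-gains behave as expected on the packaged model:

```r
classify_snv(model, 637, "T")$protein_change   # "R213*" — nonsense, exon 6
exon_of(model, 3 * 196 - 2)                    # 6  (R196)
```

The same stages are scriptable from a shell via
`Rscript inst/cli/mutenrich.R <enumerate|analyze|compare-sites|simulate> ...`
(exit codes: 0 success, 2 validation error, 3 empty result).

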