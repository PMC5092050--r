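---
title: "Observed versus expected enrichment of coding mutation classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observed versus expected enrichment of coding mutation classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutenrich)
```

## The question and the null model

Truncating mutations in tumor suppressors are usually read as simple loss of
function, so their positions along the coding sequence should look like
substitution noise. Whether a class of mutations — say, stop-gains falling in
one particular exon — occurs *more often than chance substitution predicts*
requires an explicit null for class composition. mutenrich builds that null
by exhaustive enumeration: for an `L`-nt CDS (terminal stop codon included)
there are exactly `3L` possible single-nucleotide substitutions, each
classified by translating its codon under the standard genetic code. The
expected fraction of a stratum (a consequence class, optionally restricted to
one exon) is its share of those `3L` changes; observed fractions come from a
catalog of somatic mutations; their ratio is the fold enrichment, and
departure from the null is tested with a two-sided Fisher exact test on
observed-vs-theoretical counts.

The package ships a TP53 gene model (canonical 1182-nt CDS, 393 residues, ten
coding exon segments labeled 2–11 because the gene's first exon is
non-coding). On this model the null is strikingly lopsided:

```{r null}
model <- tp53_gene_model()
theo <- enumerate_theoretical_snvs(model)
round(expected_fractions(theo, default_strata()), 4)
```

Classification conventions worth stating explicitly: the terminal stop codon
is part of the CDS, so substitutions there are classified nonstop
(stop-loss) unless they hit another stop codon, which counts as synonymous.
The TP53 model terminates in TGA, which has 8 single-base changes to a
non-stop codon (a TAA stop would have 7).

A note on published expected fractions: cohort reports sometimes print
expected class frequencies under normalizations they do not spell out, and
such numbers are generally not reproducible from the plain `3L` enumeration
(the plain missense share of any mammalian CDS is near 0.7, for instance).
mutenrich therefore asserts only its own declared null. A second
denominator, `denominator = "extended"`, adds one 1-nt insertion and one
1-nt deletion pseudo-event per CDS position (2`L` frameshift events) for
analyses that want indels inside the expected change space; neither
denominator is privileged beyond being explicit.

## Coordinates and exon assignment

Everything lives in 1-based, inclusive CDS coordinates; genomic positions,
strand and introns are out of scope. Exon segments must exactly tile
`1..L`, which the constructor validates eagerly (gaps, overlaps, missing
terminal stop and internal stops are distinct errors). A codon can span an
exon junction (five TP53 codons do); a substitution is assigned the exon of
its *mutated base* when the CDS position is known, and the exon of the
codon's first base when only a protein position is available. The two
conventions agree everywhere except junction codons, which is why the
package prefers CDS-level detail whenever a catalog provides it.

## Frameshift premature-stop mapping

Truncation analyses need frameshifts placed by where their *premature stop*
arises, not where the indel sits. `premature_stop_codon()` constructs the
mutant CDS, translates it from the start, and takes the first stop codon in
the new reading frame. Its first mutant base is mapped back to reference
space — positions downstream of a deletion shift by the deleted length,
positions inside an inserted run collapse to the insertion anchor — and
clamped into `1..L` before the exon lookup. If translation runs off the end
of the mutant sequence without a stop (readthrough), the mapping returns
nothing rather than guessing. In-frame indels are rejected by precondition.
Frameshift records that arrive without a CDS-level description cannot be
stop-mapped: they count as generic frameshifts, are excluded from exon-level
truncation calls, and are tallied in the ingestion log so their number is
always visible.

## Catalog normalization choices

Catalogs are tab-separated in a MAF-minimal dialect (or the cBioPortal
export layout; the dialect is an explicit flag, never sniffed, because
silent mis-parsing is worse than an error). Normalization parses short-form
HGVS protein and CDS strings, maps the MAF classification vocabulary onto
consequence classes, and keeps unparseable records with the class their raw
annotation implies. Three counting conventions matter downstream:

* **Instances.** One instance is one distinct (sample, unique-change) pair;
  exact duplicate rows within a sample collapse. The unique-change key is
  the CDS description when present, else the protein description, else the
  raw class.
* **Samples with several mutations** contribute one instance per distinct
  change to enrichment denominators (per-mutation counting). A per-sample
  view exists at reporting time: the site-contrast summarizes such samples
  as a `multiple` class.
* **Wild-type placeholder rows** (classification `None`) carry cohort sample
  totals through file round trips; they never enter mutation counts but
  anchor per-sample frequencies, the study filter, and the `none` reference
  class.

The study filter retains cancer types with more than 100 samples and at
least 10 mutated tumors by default — the usual cohort-inclusion rule for
this kind of analysis — and reports kept and dropped types with counts.

## Enrichment statistics

Each stratum's 2×2 table contrasts observed instances inside/outside the
stratum against theoretical changes inside/outside it, tested two-sided via
`stats::fisher.test`; a zero margin returns p = 1 with a degeneracy flag
instead of an error. Benjamini–Hochberg adjustment (`stats::p.adjust`) is
applied within the strata of one call, and raw p-values are always reported
alongside. Because "recurrence" can be read per unique change or per unique
change per sample, both columns are emitted: the headline form is
instances / unique changes, with a per-sample-normalized secondary column.
Fold enrichment is likewise reported on the instance scale and on the
unique-change scale, since either numerator is defensible.

The primary-versus-metastasis contrast classifies each sample (none /
multiple / single-mutation class, with nonsense split into exon-6 and
other), then tests each class against the wild-type (`none`) reference
across sites — i.e. over-representation in metastases with respect to
wild-type cases — with `reference = "rest"` available for class-vs-rest.
The ratio column is the metastasis/primary frequency ratio; classes absent
from both sites are flagged rather than given a ratio.

## The simulator and what it does (not) emulate

`simulate_catalog()` draws, per sample, a Poisson number of mutations; each
mutation is an SNV sampled from the enumerated change space with probability
proportional to a multiplicative stratum weight (metastasis samples apply an
extra site weight map), or — with configurable rates — a uniform indel
(lengths 1–6, insertion or deletion) or a class-only splice record.
Simulated rows carry full HGVS protein and CDS strings and pass through the
same normalization path as files, so the parsers are exercised end-to-end.
Each sample uses an RNG substream derived from the seed by counter, so
enlarging a cohort never changes earlier samples' draws, and identical
configurations are byte-identical on disk.

The generative truth is closed-form: with weight `w` on a stratum of null
fraction `f`, the expected fold is `w / (1 − f + w f)` (weights renormalize
against the whole space, so other strata are slightly depressed below 1).

What the simulator deliberately does **not** model: trinucleotide mutational
signatures and CpG hypermutability, clonal structure, copy number and LOH,
transcript-level effects such as nonsense-mediated decay, and
splice-consequence prediction from sequence. Passing recovery tests
therefore show that the *pipeline arithmetic* is sound under its own null;
they do not show that real tumor catalogs are free of compositional
confounders like mutational signatures, which can themselves concentrate
stop-gains at particular codons.

## Study conditions used by the tests

The validation suite fixes its problem sizes as the package's declared study
conditions:

* **Null calibration:** 500 simulated catalogs of 200 samples with
  Poisson(1) mutations each; the pooled rejection rate at α = 0.05 over
  strata with expected instance counts ≥ 20 is compared to the exact
  binomial interval, and median stratum folds must sit in [0.9, 1.1].
* **Parameter recovery:** 200 replicates of 2500 samples with a 5× weight on
  exon-6 nonsense (closed-form truth fold 4.92); the fold estimate must land
  within ±40% of truth in ≥ 90% of replicates and reject at α = 0.05 in
  ≥ 95%.
* **Site contrast:** one cohort of 16,000 samples, half metastatic, with a
  baseline 5× exon-6 nonsense weight (mirroring the 4–5× enrichment such
  analyses report) and an extra 2× metastasis weight. The cohort size was
  fixed a priori by a power calculation (≥ 99% power for the class-vs-none
  Fisher test at this effect size); the closed-form truth ratio is 1.96 —
  renormalization pulls it slightly below the planted 2 — and the estimate
  is asserted within three binomial standard errors of 2.

Oracles are independent of the code paths they check: consequence classes
against a full-CDS mutate-translate-diff oracle (all 3546 TP53 changes),
frameshift stop mapping against brute-force mutant translation (500 random
indels), Fisher p-values against exhaustive hypergeometric tail sums (200
random tables, agreement to 1e-9).

## Numerical choices and degenerate inputs

Empty strata yield recurrence 0 with a flag; zero expected fractions make
fold enrichment a structured error rather than Inf; degenerate 2×2 margins
give p = 1 flagged; protein positions beyond the protein leave the exon
unknown and are counted in the log; reference-base mismatches between a
catalog's CDS strings and the gene model are reported, not silently fixed.
The ingestion log accounts for every row: read = analyzed + rejected +
deduplicated.

## Known limitations

* Exact tests on discrete 2×2 tables are conservative: in the null
  calibration the empirical type-I error sits near 0.03–0.045 at a nominal
  0.05, brushing the lower edge of the binomial acceptance interval for some
  seed streams. This is a property of Fisher's test at these counts, not of
  the implementation.
* The uniform substitution null ignores mutational-signature structure, so
  enrichment against it conflates selection with mutation-rate
  heterogeneity; interpret folds accordingly.
* Only single-nucleotide substitutions are enumerated as expected cases;
  indels enter the denominator only via the explicit extended mode, and
  splice consequences are taken from catalog annotations, never predicted.
* The gene model assumes one transcript; for TP53 the canonical 393-residue
  transcript is used, consistent with the exon-6 placement of codons 196 and
  213. Coordinates on other isoforms must be lifted before ingestion.
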