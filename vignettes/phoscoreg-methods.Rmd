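---
title: "Phosphosite-centric co-regulation meta-analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphosite-centric co-regulation meta-analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoscoreg)
```

## The problem

Large-scale mass-spectrometry phosphoproteomics has catalogued hundreds of
thousands of phosphorylation sites, but very few have a known function.
One productive way to prioritize them is meta-analysis: collect every
published dataset in which a protein's phosphosites were observed, find
the sites that are detected and differentially regulated most often, and
then ask which phosphosites of *other* proteins move up and down together
with them across independent experiments. Sites that consistently
co-regulate are plausibly wired into the same signaling programs.

`phoscoreg` implements that pipeline for any anchor protein:

1. **Ingestion** of a compendium: many dataset tables (TSV) plus a
   manifest carrying, per dataset, its publication (PMID), an
   experimental-condition code, whether it is a *profile* dataset
   (detections only) or a *differential* dataset (fold change and
   p-value against a control), and the enrichment chemistry (STY/ST/Y).
2. **Class-1 filtering**: only confidently localized sites are retained.
3. **Predominance ranking**: per-site detection and
   differential-regulation frequencies nominate anchor sites.
4. **Co-regulation (CPP) analysis**: directional agreement between the
   anchor and every candidate site on other proteins, with an exact test
   and reproducibility filters.
5. **Co-occurrence**: the same directional statistics between sites
   *within* the anchor protein.
6. **Sequence evidence**: peptide-to-sequence coverage and an in-silico
   tryptic digest.
7. **Overlays**: kinase/phosphatase and known-interactor joins onto the
   CPP table (annotation only).

A seeded simulator generates compendia with known planted structure so
that every stage is testable without any external data.

## Regulation model and thresholds

Each record in a differential dataset carries a linear fold change
(test/control) and a p-value. A site is called **up** when
`fold_change >= 1.3` and `p < 0.05`, **down** when
`fold_change <= 0.76` and `p < 0.05`, and **unregulated** otherwise.
Both fold-change boundaries are inclusive and the significance boundary
is strict; 0.76 is approximately 1/1.3, making the up and down calls
symmetric on the log scale. Missing values are conservative: a record
without a p-value or fold change is unregulated. Inputs on the log2
scale can be declared at ingestion (`log2_fc = TRUE`) and are converted,
because the thresholds are defined on linear ratios.

**Class-1 filtering.** Localization confidence is reported
heterogeneously across studies: some report a localization probability
(in [0, 1]), others an A-score, many only one of the two. A record is
kept when *any reported* metric passes (localization probability >= 0.75
or A-score >= 13). We chose the OR reading because requiring both
metrics would discard most records from studies that only report one; a
stricter AND mode (`mode = "both"` in `filter_class1()`) is available
for sensitivity analysis. Records reporting neither metric are dropped.

**One effective record per dataset.** Duplicate observations of the same
site within one dataset are collapsed before analysis so that no study
can vote twice: profile duplicates keep the maximum localization
metrics; differential duplicates whose directions agree keep the most
extreme fold change, while conflicting directions mark the site
unregulated in that dataset.

## The co-regulation statistic

For an anchor site $a$ and a candidate site $c$, every differential
dataset in which **both** are classified up or down contributes one
count to exactly one of four categories: $n_{UU}$ (both up), $n_{DD}$
(both down), $n_{UD}$ (anchor up, candidate down), $n_{DU}$ (anchor
down, candidate up). Concordant evidence is $n_{pos} = n_{UU} + n_{DD}$
and discordant evidence $n_{neg} = n_{UD} + n_{DU}$; the positive
co-regulation ratio is $n_{pos}/n_{neg}$ and the negative ratio its
reciprocal (with an infinity flag for zero denominators and an
undefined flag for empty tables, which forbid classification).

**Exact test.** Significance is a one-sided Fisher's exact test on the
2x2 table with rows = anchor direction and columns = candidate
direction, $[[n_{UU}, n_{UD}], [n_{DU}, n_{DD}]]$ — the only 2x2 table
the four counts define. The p-value is computed as the closed-form
hypergeometric tail on $n_{UU}$ given the margins
(`stats::phyper`): the upper tail tests concordance excess, the lower
tail discordance excess, and the direction tested is the candidate's
dominant category. An all-zero table returns 1. The test suite verifies
this against both exhaustive same-margin enumeration (every table with
$N \le 12$, agreement to 1e-10) and `stats::fisher.test`.

**High-confidence filter.** A candidate is classified positive
(respectively negative) only when all of the following hold:

* strict dominance: $n_{pos} > n_{neg}$ (resp. $n_{neg} > n_{pos}$);
  ties are never classified;
* FET p-value < 0.05 in the dominant direction (a Benjamini–Hochberg
  mode across all candidates of a run is available but off by default,
  matching common meta-analysis practice of raw exact-test thresholds);
* the dominant count exceeds 10% of the anchor's differential
  frequency. This "10% of the total frequency" rule is interpreted as a
  *count* comparison (dominant count > 0.10 x anchor differential
  frequency): comparing the dimensionless ratio against a frequency
  would be dimensionally inconsistent, and reported high-confidence CPP
  frequencies in this style of analysis are counts;
* reproducibility: at least 3 distinct PMIDs and at least 3 distinct
  experimental-condition codes among the datasets contributing to the
  **dominant** category. Confidence is scoped to the dominant category
  because it is the co-regulation evidence whose independence matters.

Frequencies are counted per *dataset*; experimental-condition
multiplicity is treated as metadata (the experimental-code confidence),
not as the counting unit. The same-protein candidates are excluded from
the CPP table and routed to the co-occurrence module instead.

## Co-occurrence within the anchor protein

For every unordered pair of the protein's sites the same four counts are
accumulated; `pos_freq` ($n_{UU}+n_{DD}$) and `neg_freq`
($n_{UD}+n_{DU}$) form symmetric matrices with zero diagonals, sites
ordered by position. A pair is *co-occurring* when its dominant
frequency strictly exceeds 3 (so 4 is flagged, 3 is not); a tie between
the positive and negative categories above the threshold is reported as
`"ambiguous"` rather than silently assigning a sign. The long-format
export carries a `signed_value` column (`pos_freq` when concordance
dominates or ties, `-neg_freq` otherwise), the numeric encoding of the
violet/green heatmap gradient; no clustering or dendrogram ordering is
applied.

## Sequence coverage and digestion

Coverage is the percentage of residues covered by the union of exact
substring occurrences of the identified peptides; *all* occurrences of a
repeated peptide are marked (a flag to restrict to first occurrences was
considered and rejected as less faithful to peptide-spectrum evidence,
which cannot distinguish copies). No isoleucine/leucine equivalence or
modified-residue mass logic is applied: peptides are mapped to one known
protein. Percentages round half away from zero to one decimal, so
25.25% prints as 25.3 rather than banker's-rounding down. Unmapped and
empty peptides are counted but never touch the mask.

The tryptic digest cleaves after K or R except before P (the Keil
rule); with `missed_cleavages = m` every concatenation of up to `m + 1`
adjacent fragments is returned with coordinates. The extended
PeptideCutter exception set is deliberately not modeled: the simple
Keil rule is the community default for in-silico digests, and the
fragments at `m = 0` provably tile the sequence (tested).

Positions are 1-based and inclusive throughout, matching the standard
S31/S944 site nomenclature; domain containment
(`locate_site_in_domains()`) is inclusive on both boundaries.

## What the simulator emulates — and what it does not

`simulate_corpus()` emulates the *structure* of a real compendium:
sparse per-dataset site detections (independent Bernoulli), direction
labels for an anchor, planted partner sites that agree (or disagree)
with the anchor at a configured probability when co-detected, and
independent background sites; PMIDs and experimental codes are assigned
in contiguous blocks so the reproducibility filters are exercised.
Directions are planted *first* and fold changes then drawn consistently
(lognormal, resampled until the 1.3/0.76 threshold is respected;
p-values uniform below 0.05), so the ground-truth table is exact rather
than approximate. All randomness flows through one seeded generator;
identical seeds give byte-identical corpora.

Defaults are the study conditions used throughout the tests: 100
differential datasets, anchor detection 0.8, 10 positive partners at
concordance 0.95, 5 negative partners at discordance 0.95, 200
background sites, and blocks of 4 datasets per PMID and per
experimental code. Where a value is not dictated by those conditions it
was fixed once on realism grounds: partner detection 0.5 and background
detection 0.25 (most phosphosites appear in a minority of datasets),
fold changes lognormal around 2-fold (sd 0.35 on the log scale), and
80% class-1 records in profile simulations.

The simulator deliberately does **not** model mass-spectrometry
intensity distributions, batch effects, peptide-level missingness
mechanisms, correlated backgrounds, or isoform ambiguity. Passing the
planted-recovery and null-control tests therefore demonstrates that the
counting, testing, and filtering machinery is correct and calibrated
under independence — not that real compendia meet those assumptions.
In particular, correlated background sites (co-regulated modules that
are real but unrelated to the anchor) will pass the filters by design,
because the filters measure co-regulation, not causation.

## Numerical and degenerate-input choices

* Empty direction tables give FET p = 1 and undefined ratios; such
  candidates are never classified.
* An anchor that is never differentially regulated is an error (with a
  pointer to `site_frequency_table()`), not an empty result.
* All tabular outputs are deterministically ordered (documented sort
  keys: classification, dominant frequency, accession, position), so
  repeated runs are byte-identical.
* Written corpora use a canonical column order and canonical numeric
  formatting; a written corpus re-reads to an identical object, and
  write–read cycles are byte-stable after the first canonicalization.
* Ingestion conserves rows: per file, accepted + rejected = input rows,
  with per-reason rejection counts in a JSON ingest report.

## Problem sizes in the test suite

The suite validates the exact test by full enumeration over the 1,820
tables with $N \le 12$; counting by naive re-scans over 200 random
corpora (up to 50 datasets and 30 sites); planted recovery and the null
control over 20 simulated compendia each (100 datasets, 216 sites); and
coverage against the generator's interval-union oracle over 100 random
fixtures. These sizes keep a full run around a minute on one CPU while
leaving each statistical check with thousands of effective trials.

## Known limitations

* The class-1 OR rule is a reading of heterogeneous reporting practice,
  not a community standard; the strict mode exists for comparison.
* One FET is computed per (anchor, candidate) pair over all co-detected
  datasets; no per-condition stratification is attempted.
* Raw (uncorrected) exact-test thresholds are the default; with
  hundreds of candidate sites the expected number of false positives is
  controlled by the joint filter, not by the FET alone (the null-control
  test quantifies this at under 5% of background sites).
* Gene-symbol overlays canonicalize case but do not resolve aliases;
  an alias table can be applied at ingestion.
* No isoform remapping: records are keyed by the accession given.

## A worked example

```{r example, eval = FALSE}
cc <- simulate_corpus(sim_config(seed = 1))
tab <- site_frequency_table(cc$corpus, "SIM-ANCHOR")
head(tab, 1)                      # the anchor is its own top site
res <- run_coregulation(cc$corpus, "ANCHOR_S10")
summary(res)
m <- cooccurrence_matrix(cc$corpus, "SIM-ANCHOR")
flag_cooccurring(m)
```
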