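---
title: "Duplex consensus calling, ctDNA triage and exact trial design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex consensus calling, ctDNA triage and exact trial design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexct)
```

## The problem

Anti-EGFR antibody rechallenge in metastatic colorectal cancer only makes
sense in patients whose tumors have lost the resistance mutations (*RAS*,
*BRAF*, *EGFR* extracellular domain) that emerged under prior EGFR blockade.
Those mutations are monitored in circulating tumor DNA (ctDNA), where mutant
alleles may sit at fractions well below what standard sequencing error rates
allow one to call. `duplexct` implements the three computational layers such
a liquid-biopsy-guided trial needs:

1. **Duplex consensus sequencing** — tag-based error suppression turning raw
   paired-end reads into duplex consensus sequences (DCSs), plus SNV/indel/
   copy-number calling over the consensus with conservative support filters.
2. **ddPCR triage** — droplet digital PCR fractional abundance, sample
   suitability QC, replicate reconciliation, and the *zero-mutation ctDNA
   triage* rule deciding molecular eligibility.
3. **Exact single-stage trial design** — the A'Hern exact-binomial design and
   binomial confidence intervals for response endpoints.

Everything runs on synthetic duplex libraries with known ground truth; no
external sequencing data is needed to exercise or validate any stage.

## Duplex consensus model

Each original double-stranded cfDNA fragment is ligated with a random 12-nt
tag on each end (call them α and β) behind an invariant 5-bp ligation-site
anchor. After amplification and paired-end sequencing, all reads descending
from one strand of one molecule share the merged 24-nt tag α+β and the
fragment's genomic coordinates; reads from the complementary strand carry
the transposed tag β+α. The pipeline:

1. **Pre-processing.** Reads shorter than 150 bases are padded with `N`
   (quality 0). A pair is removed when either mate has a homopolymer run
   strictly longer than 35 nt within its first 50 nt.
2. **Tag parsing.** The 5-bp anchor is matched exactly; the 12-nt tag is
   rejected if it contains a run strictly longer than 9 bases. Tag and
   anchor are stripped and the two mate tags merge into the 24-nt family
   key.
3. **SSCS.** Reads sharing tag and coordinates form a family (minimum 2
   members). Per position, the modal base is kept when at least 70% of
   members agree (inclusive); otherwise `N`. A position where strictly more
   than 30% of members are `N` is `N` regardless.
4. **DCS.** The SSCS with tag α+β is compared position by position against
   the SSCS with tag β+α at the same placement; disagreements and
   strand-`N`s become `N`; a DCS with more than 30% `N` is discarded.
5. **Calling.** DCSs with more than 7 reference mismatches are dropped and
   bases below phred 30 masked. An SNV needs at least 3 distinct supporting
   DCSs at DCS depth ≥ 3, with at least one supporting observation outside
   the 5-base head/tail window. Indels are left-normalized and need ≥ 3
   altered DCSs. A probe region is amplified when
   log2(region median depth / panel median depth) > 1.

```{r thresholds}
pipeline_params()
```

### Design choices where the procedure was open

* **Read-space consensus per mate.** Families are keyed on (merged tag,
  contig, mate interval, orientation) and compared position by position in
  read space. The complementary strand's *opposite* mate reads the same
  reference segment in the same orientation, so transposed-tag pairing at an
  identical placement is exact, and no partial-overlap logic is needed.
* **Boundary semantics.** "At least 70%" is inclusive; "more than 30%" and
  "more than seven mismatches" are strict; comparisons are computed with an
  integer-safe guard so 7/10 is exactly 70%. Every boundary is unit-tested
  from both sides.
* **DCS base qualities.** DCSs have no native qualities. Each SSCS base
  inherits the maximum member quality of the winning base; each DCS base the
  minimum of its two strand qualities; `N` is quality 0. The phred-30 filter
  is then applied at the DCS stage. Mismatches are counted *before* quality
  masking so a damaged low-quality molecule cannot evade the 7-mismatch
  filter.
* **Head/tail window.** No window length is prescribed for end-artifact
  evidence; the default is 5 bases per DCS end (the scale of the
  ligation-site anchor), configurable via `pipeline_params()`.
* **Homopolymer drops.** The 35-nt rule drops the whole pair, not the single
  mate: the duplex workflow is defined on pairs. Padding `N`s neither form
  nor extend a run, since padding is synthetic signal.
* **Indel normalization.** Identical indels are aggregated after
  left-normalization against the reference (VCF convention); the support
  filter is applied to the normalized event.
* **Placement.** The genome aligner is an external contract. In
  self-contained mode placements come from simulator truth;
  `place_reads_naive()` is a deliberately simple near-exact matcher
  (≤ 2 substitutions, no indels) usable only on small synthetic references.

## The synthetic library generator

`sim_config()` / `simulate_duplex_library()` emulate: uniform fragment
placement (167 bp fragments, the modal plasma cfDNA size), random 12-nt tag
pairs re-drawn on same-locus collisions, per-strand family sizes (Poisson
with mean 4 by default, minimum 0 — the empirical family-size distribution
of real libraries is not published, so this is a placeholder, not an
inference), i.i.d. substitution errors per sequenced base, optional
strand-coincident errors (substitutions on the molecule itself, which duplex
agreement *cannot* remove — the positive control for the duplex principle),
spiked variants assigned per molecule as Bernoulli(allele fraction), and
constant phred-37 qualities with optional low-quality injection.

It does **not** emulate: PCR-cycle-level polymerase errors, GC bias, indel
sequencing errors (indels enter only as spiked truth variants), fragment
length variation, or mappability structure of a real genome. Passing tests
therefore demonstrate the *logic* of the error-suppression and filter
cascade, not its operating characteristics on real plasma libraries.

```{r simulate}
set.seed(1)
reference <- c(amplicon = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                                collapse = ""))
cfg <- sim_config(reference, n_molecules = 300, per_base_error_rate = 3e-3,
                  seed = 7)
report <- run_pipeline(sim = cfg)
report$counts[c("pairs_in", "kept", "families", "sscs", "dcs", "dcs_retained")]
```

## ddPCR fractional abundance and triage

Fractional abundance is `F.A.% = 100 * Nmut / (Nmut + Nwt)` over droplet
events; a reaction with fewer than 100 total events is unsuitable. Detection
is count-based: any validated mutant droplet signal makes the patient
ineligible — there is no abundance cutoff, because the trial enrolls on
*zero* detected mutant molecules.

Replicates: the source protocol states that samples run in at least two
technical replicates "to validate" results, but not the combination rule.
The default here calls an assay mutant when **two or more suitable
replicates** are each positive; a permissive mode (any positive suitable
replicate) is available. An assay is unsuitable only when every replicate
fails the 100-event QC, applied per reaction (whether the QC was pooled in
the original workflow is unstated). Verdicts from fewer than two suitable
replicates are flagged low-confidence.

```{r triage}
counts <- synthetic_screening_cohort()
s <- screening_summary(triage_cohort(counts))
c(screened = s$n_screened, mutant = s$n_mutant, pct = s$pct_mutant,
  eligible = s$n_eligible)
s$by_gene
```

## Exact single-stage design

`ahern_design(p0, p1, alpha, power)` searches ascending `n` for the smallest
sample size admitting a response threshold `r` with exact binomial type-I
error at most `alpha` under `p0` and exact power at least `power` under
`p1`; at that `n`, `r` is the smallest threshold meeting the alpha
constraint. The binomial tail is an exact log-space summation, checked
against `stats::pbinom` to 1e-12 in the tests.

```{r design}
ahern_design(0.10, 0.30, alpha = 0.05, power = 0.85)
```

Response endpoints are binomial proportions with Wald, Wilson or
Clopper–Pearson intervals on the percent scale, rounded half-up for display.
The Wald interval reproduces the reported objective-response interval for
8/27 (12–47%); no single standard method reproduces every reported interval,
so Wald is the default and the method is always an explicit argument.

```{r endpoint}
endpoint_estimate(8, 27, "wald")
```

## Numerical and scale choices

* Seeds are explicit everywhere; identical configurations produce
  byte-identical FASTQ/VCF output.
* Coordinates are 0-based half-open internally, 1-based in VCF and reports.
* Consensus tie-breaks cannot affect output: two bases cannot both reach the
  70% floor, and ties below it yield `N`.
* Test and analysis problem sizes — 2,000-molecule libraries, 1% and 0.3%
  error rates, 1% allele-fraction spike-ins over five seeds — were chosen as
  the smallest scales at which the binomial sampling intervals around the
  expected rates are informative.

## Known limitations

* Microsatellite-instability status, germline annotation and survival
  endpoints are out of scope; only proportion endpoints are computed.
* The naive placer cannot place indel-bearing reads; indel-aware analyses
  use truth placements (or an external aligner in real use).
* SSCS-level `N`-budget discarding is ambiguous in the source protocol; the
  package applies the per-position member-`N` rule plus the DCS-level
  discard, and the stricter whole-SSCS reading is not enabled by default.
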