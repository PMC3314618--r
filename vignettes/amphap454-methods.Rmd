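---
title: "Diploid haplotype calling from multiplexed amplicon pyrosequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diploid haplotype calling from multiplexed amplicon pyrosequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Population-level sequencing of nuclear intron (EPIC) markers in non-model
organisms runs into a specific analytical wall: the loci worth sequencing
are highly polymorphic diploid markers, rich in heterozygous sites and
INDELs, and direct Sanger sequencing of such templates produces mixed
chromatograms that can only be resolved by cloning or statistical phasing.
Targeted amplicon pyrosequencing sidesteps this because every read derives
from a single molecule after emulsion PCR — each read *is* a cloned
haplotype. The price is a different error structure (homopolymer
length miscalls, PCR chimeras between the two alleles of a heterozygote,
short junk reads) and a demultiplexing problem: hundreds of samples share
one sequencing run, distinguished only by a MID barcode inside the fusion
primer and by which gasketed plate region they were loaded into.

`amphap454` implements the full downstream path as a reusable pipeline:

1. **demultiplexing** — route each read to (individual, locus, orientation)
   by dual-end MID and locus-specific primer, applying fixed discard rules;
2. **diploid genotype calling** — per individual x locus bin: a
   star-alignment pileup, heterozygous-site detection at a 75% consensus
   rule, homopolymer arbitration, phasing into the two most common
   haplotypes, and removal of recombinant (chimeric) reads;
3. **population curation** — singleton homopolymer correction within
   populations, plus the summary statistics a study of this design reports
   (coverage fractions, unique alleles, heterozygotes, allelic support
   ratios);
4. **a ground-truthed simulator** of multiplexed amplicon libraries, which
   is the package's test harness;
5. **design and cost arithmetic** — tagged-primer counts, equimolar pooling
   volumes, majority-consensus confidence, and the Sanger-versus-454 cost
   model.

# Demultiplexing rules

A read is kept if and only if it survives, in order:

1. **length** — reads strictly below 150 bp are removed (a 150 bp read is
   kept); the same bound is re-applied to the trimmed insert at the end;
2. **mean quality** — the arithmetic mean Phred score of the *raw* read
   must be at least 30 (strictly-below-30 discards);
3. **MID at both ends** — the barcode immediately after the 5' adaptor and
   the reverse-complemented barcode at the 3' end must both match, exactly,
   and identify the same individual. Matching is exact (0 edits): MID sets
   are designed to be error tolerant, and the discard rule is a strict one;
4. **primer** — the complete template-specific primer (forward or reverse,
   fixing orientation) must match immediately after the MID under
   IUPAC-aware exact matching with zero mismatches. Degenerate codes
   expand to base sets. Reads matching two or more loci are discarded as
   ambiguous;
5. **quality trim** — modified-Mott end trimming at an error-probability
   cutoff of 0.05: each base scores `0.05 - P_error` and the first
   maximal-sum contiguous segment is retained.

Two boundary decisions the rules themselves do not pin down, and how this
package resolves them:

* the order of the rules is fixed as above, with the mean-quality rule
  applied to the raw read; both choices are configurable;
* the 150 bp bound is applied both before and after trimming, and the
  report counts the two stages separately.

The partner primer's reverse complement, which sits just before the 3'
MID in every full-length amplicon read, is trimmed *positionally*: once
both MIDs have matched exactly, its location in the read is fully
determined, so a sequencing error inside that copy of the primer is not
grounds for discarding the read. The discard rule applies to the
locus-identifying 5' primer. Sequencing adaptors are tolerated intact,
substitution-damaged (same length), or absent.

Reverse-orientation reads are reverse-complemented (bases and reversed
qualities) into forward orientation before genotyping.

# The pileup

Reads of one bin are assembled reference-free by star alignment. The seed
is the read with the highest mean quality (ties break toward the smallest
read id, making the pileup independent of input order); every other read
is aligned to the seed with ends-free Needleman–Wunsch alignment (match
+1, mismatch −2, gap open −4, gap extend −1; all configurable) and the
pairwise alignments are merged column-wise. Columns are keyed `(p, k)`:
seed position `p` for `k = 0`, or the `k`-th inserted column after `p`.
Read bases extending past the seed's ends are retained as end-insertion
columns keyed by their distance from the seed end — a seed whose own ends
were quality-trimmed must not truncate the called alleles.

Three numerical conventions matter downstream:

* a cell is `NA` where a read does not cover a column and `"-"` where the
  read spans the column but has no base there; only the latter is evidence
  of a deletion;
* at insertion-type columns (`k != 0`) a count tie between a base and the
  gap resolves to the gap: gap cells there carry quality 0 by
  construction, so summed quality must not arbitrate, and writing an
  insertion into a consensus requires strictly positive evidence;
* columns covered by fewer than a quarter of the bin's reads (and never
  fewer than 2) are trimmed inward from the flanks when alleles are
  assembled, and are not eligible as heterozygous sites. Flank columns
  carry no gap evidence from the reads that stop short of them, so a
  single read's end artifact — for example one leaked primer base after a
  homopolymer error shifted the positional trim — would otherwise
  masquerade as sequence.

# Genotype calling

**Heterozygous sites.** A column is heterozygous iff its most frequent
symbol accounts for strictly less than 75% of depth. Gaps count as a
symbol and count in the depth; N bases count in neither. The boundary is
strict in the stated direction: a column at exactly 75% is homozygous.

**Homopolymer arbitration.** If the variation at a site is a length
variant of a single-base run, three criteria arbitrate the run length, in
order: (1) a length class supported by at least 75% of the spanning reads
wins by majority; (2) otherwise the class whose reads have the higher mean
quality across the run wins; (3) quality ties break toward the shorter
run. Below 10x coverage the majority criterion is skipped and quality
decides alone. The exact composition of these three criteria is an
interpretation — the field's practice names majority consensus and
quality without enumerating the decision procedure — and each piece is
exposed as a configuration knob.

Only *anchored* reads testify to a run's length: a read must cover the
nearest non-gap consensus column on each side of the run and agree with
the consensus there. This excludes reads that start inside the run, and
a subtler class: when the seed itself carries a run deletion, a read
missing its leading bases aligns cheaper as a shifted mismatch than as a
gap (one mismatch costs 2, a gap costs 5 under the default scores), and
such out-of-register reads would otherwise report a confident wrong run
length at full base quality.

**Phasing.** Each read is keyed by its symbol vector across the
(non-homopolymer) heterozygous sites; the two most frequent complete keys
become the two allelic states (count ties break to the lexicographically
smaller key). Reads that do not span every site are assigned to the
unique consistent allele or left unassigned. Diploidy is assumed
throughout: exactly two alleles are emitted, and a third-ranked haplotype
is never called.

**Chimera removal.** A read whose key matches allele 1 at one or more of
the sites where the alleles differ *and* allele 2 at one or more others
is a single-crossover recombinant — a PCR/emPCR artifact — and is removed
before the alleles are re-derived. Homozygous calls are never modified.
Removal is idempotent.

**Allele re-derivation.** Each allele is the column-wise consensus of its
read class; at the phased sites the allele is its haplotype key by
definition, and columns with no class coverage fall back to the overall
consensus. Arbitrated homopolymer runs are re-resolved *within each
class*: a substitution at a run edge genuinely shortens one allele's run,
so a single global run length would corrupt one of the two alleles.
Homozygotes report both supports equal to the coverage.

# Population curation

Within each (locus, population) group, an allele observed exactly once
whose alignment to an allele observed at least twice shows exactly one
difference — a single-base INDEL inside a homopolymer run of length >= 2
in the longer sequence — is rewritten to the matched allele, on the
argument that a lone pyrosequencing length error is far more likely than
a genuine singleton one INDEL away from a common allele. Substitution
differences and multi-INDEL differences are out of scope. Eligibility
(singleton = count 1, candidate = count >= 2) and candidate ranking
(highest count, then lexicographic) use the pre-correction counts, which
makes the operation order-independent, idempotent, and count-conserving.

# The simulator

The generator emulates the structure the pipeline assumes, with full
ground truth per read and per genotype. Its defaults are the study
conditions the package is validated under, fixed once:

| parameter | default | rationale |
|---|---|---|
| design | 1 region x 20 individuals x 2 species x 5 loci | one gasketed plate region of the published design (200 bins) |
| intron length | U(400, 600) bp | the markers' design range |
| allele pool | 8 per locus, 1% divergence, pairwise Hamming >= 2 | population-scale allelic richness; two differing sites are the minimum at which phasing and chimera detection are defined |
| heterozygosity | 0.6 / 0.1 per species | the diverse-vs-depauperate species contrast |
| coverage | negative binomial, mean 70.7, size 8 | the published mean; the size reproduces strong between-bin variance |
| substitution error | 1% expected per base | platform-scale error |
| homopolymer error | min(0.01 (L−1), 0.10) per run of length L >= 3 | length-dependent, capped at 10% per run |
| chimeras | 12.5% of reads at heterozygous bins | the observed recombinant-read fraction |
| allelic skew | 13:22 | the observed 13:9 mean allelic ratio |
| truncation | 5% of reads to 50–149 bp | short-read contamination |

Qualities are drawn from a two-level mixture (Q40 / Q10) whose low-quality
fraction is set so the expected per-base error equals the configured
substitution rate; errors are then injected per base at `10^(-Q/10)`. This
keeps the mean-quality filter meaningful: a read's mean quality is ~37
under the defaults, and the filter bites exactly when truncation or
homopolymer damage degrades a read. A run that receives a homopolymer
error is rewritten at Q15 across the run, so the quality criterion of the
arbitration rule sees the signal it would see in real data. Chimeras are
single-crossover at a uniformly random breakpoint between the alleles'
first and last differing sites (a PCR template-switching model).

What the simulator does *not* emulate, and what passing tests therefore do
not show: flowgram-space chemistry (homopolymer errors are drawn per run,
not from flow values), emPCR duplicate structure, per-cycle quality decay,
cross-contamination between samples, and non-target amplification
(mispriming). Results on real libraries additionally depend on those
processes.

Under these conditions roughly 40% of emitted reads are discarded — the
MIDs and the 5' primer must be error-free across 40 bases, and 1%
per-base error makes that a 33% loss on its own — so the analyzed
coverage per bin averages ~42x. The same arithmetic is visible in the
published libraries, where a third of reads were discarded.

# Accuracy under the study conditions

With the default generator the pipeline recovers both alleles exactly in
>= 99% of the 200 bins (fixed seed; the acceptance suite asserts this
end to end). The residual failures are informative, not mysterious:

* at bins whose *kept* coverage lands in the NB distribution's low tail,
  a heterozygote whose minor allele drops below 25% of reads is
  invisible to the 75% rule at every site and collapses to a homozygote;
* three same-base substitution errors landing in one column of a
  low-coverage bin push the majority below 75% and fabricate a het site.

Both are faithful consequences of the stated rules at marginal coverage —
the published design mitigates them with deep coverage at heterozygous
loci (107x average) — and both scale away as coverage grows.

# Problem sizes

The test suite and the acceptance script size their simulations to the
published design: the end-to-end checks run one full plate region (200
bins, ~14,500 reads with flanks of ~560-760 bp) and the property-style
checks run thousands of small randomized cases (10^4 columns for the
threshold law, hundreds of enumerable bins for phasing). A full
simulate–demultiplex–genotype–curate pass at these sizes completes in a
few minutes on one core.

# Known limitations

* Polyploid genotyping, genotype likelihood models, flowgram-space error
  correction and reference-based mapping are out of scope by design; the
  pipeline is reference-free.
* Alleles that differ *only* by homopolymer run length at a site the
  arbitration resolves are collapsed to the arbitrated length unless
  phasing separates them via some other site; this mirrors the stated
  rules, which treat isolated homopolymer length variation as error.
* The 75% rule's sensitivity floor is structural: a minor allele below
  25% of a bin's reads cannot be detected at any site, whatever the
  coverage.
* MID matching is exact; an optional <= 1-substitution mode exists but is
  off by default, since the published rule is a strict match.
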