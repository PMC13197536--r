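---
title: "Genotype-phenotype analysis of apricot skin color with apricotMAS"
author: "apricotMAS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-phenotype analysis of apricot skin color}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apricotMAS)
```

## The problem

Apricot fruit skin color segregates largely as an orange/yellow contrast
controlled by a locus on chromosome 3 inside an AP2/ERF
domain-containing transcription factor gene, a family repeatedly
implicated in carotenoid regulation and ripening. Breeders would like to
select orange- or yellow-skinned seedlings years before the trees fruit,
using genotypes at markers inside this gene. `apricotMAS` implements the
computational side of that program: hue-based phenotyping, marker
concordance scoring, and reconstruction of the gene's alleles and
protein variants.

## Phenotype model

Fruit ground color is measured with a colorimeter in CIELAB space. The
phenotype-bearing quantity is the hue angle

$$h^\circ = \operatorname{atan2}(b^*, a^*) \cdot 180/\pi,$$

wrapped to $[0, 360)$. The two-argument arctangent is used rather than
$\arctan(b^*/a^*)$ so that readings with $a^* \le 0$ remain well defined;
apricot peel sits in the first quadrant ($a^*, b^* > 0$, $h^\circ$
between roughly 50 and 95), where the two agree. Classes are assigned by
threshold: orange below 77, yellow above 83, light orange between. The
published rule leaves the boundary values open on both sides; we assign
exactly 77 and 83 to the transitional light-orange class, since a fruit
measured exactly at a boundary is by definition transitional. The seven
UPOV peel base color categories collapse onto the same three classes
(`upovToClass()`).

The measurement protocol takes two readings per fruit on three fruits.
`aggregateReplicates()` computes hue per reading and then averages;
averaging $a^*$ and $b^*$ first and converting afterwards is a different
statistic (a resultant-vector mean) and would not match the per-fruit
mean-and-sd presentation used in the field. Dispersion is the sample
(n-1) standard deviation, reported as 0 for a single reading.

## Concordance and efficiency

Markers predict a binary outcome, so the three observed classes are
collapsed for scoring: light orange joins the orange group. This is a
substantive choice, not a convenience. Scoring the packaged 57-cultivar
panel under the only alternative binary collapse (light orange with
yellow) gives 53/57 correct, while the orange-side collapse gives 51/57
= 89.5% -- the figure the marker was validated at -- with the six errors
being exactly the C/C cultivars measured below the yellow boundary. The
test suite carries this brute-force collapse comparison as an oracle.

Two statistics are reported. Unweighted efficiency is
$100 \cdot n_\mathrm{correct}/n_\mathrm{scored}$. Weighted efficiency is
$100 \cdot \sum_c w_c \, \mathrm{acc}_c$ over the binary groups with
$w_c = 0.5$ by default, which gives the rarer class (yellow, on most
panels) equal influence. On the packaged panel the recomputed weighted
value is $0.5 \cdot (10/10) + 0.5 \cdot (41/47) = 93.6\%$; the printed
value is 93.5%. We report the recomputed figure and document the
0.1-point gap as a rounding ambiguity in the source rather than forcing
agreement.

Missing calls -- the "X/X" profile produced when no PCR product
amplifies -- are excluded from numerator and denominator, following how
the panel's one failed amplification ('Maya Cot' at Col1) was handled.
Genotypes absent from a rule table are likewise excluded and reported,
never guessed. A positively weighted class with no scored member makes
the weighted statistic undefined; this is an explicit error, not a
silent drop. Percentages are displayed to one decimal with half-up
rounding; raw fractions stay in the report object.

The packaged fixtures carry both the printed phenotype label and the
threshold-derived class. They disagree once: 'Lito', printed light
orange at h° 75.7, which the h° < 77 rule calls orange. The pipeline
computes from hue and surfaces the disagreement
(`runPipeline()$labelDisagreements`) instead of resolving it either way.
Its scoring is unaffected, since both labels fall in the orange group.

## The surrogate locus

The gene's alleles are defined by an intragenic AGC microsatellite
(amplicon sizes 108, 111, 114, 120 bp) and four SNPs
(SNP1 = S3_22924169, SNP2 = S3_22924445, SNP3 = S3_22924252,
SNP4 = S3_22924316), combining into four named haplotypes
(`alleleTable()`). The full nucleotide sequence of the reference allele
is not available as text, so the package generates a surrogate locus
that honours every documented constraint:

* length 1257 bp, matching the 22,923,854-22,925,110 span;
* the Col1 primer sites, unique on the template, spanning a 108 bp
  product in the reference allele (+3 bp per extra AGC unit);
* the AGC tract in reading frame on the minus strand, so each unit
  contributes exactly one alanine;
* SNP offsets preserving the genomic spacing, except SNP4, which is
  shifted 1 bp (offset 461 instead of 462) because histidine and
  tyrosine codons differ only at their first position, and the published
  offsets cannot place both non-synonymous SNPs at a codon-first
  position in any single frame;
* codon contexts making SNP1 and SNP2 synonymous (Leu/Leu, Pro/Pro on
  the coding strand) and SNP3/SNP4 His/Tyr switches (CAT/TAT);
* flanks drawn from a seeded uniform base distribution, then scrubbed of
  AGC-phase tandem duplications and primer words; the default flank seed
  additionally yields flanks whose translation contains no alanine run
  longer than one, so the tract is the unique polyalanine signal at
  every repeat count >= 2.

Positions are handled in two conventions, stated on every record:
genomic coordinates are 1-based (as in the SNP names); internal sequence
indices are 0-based half-open. `simulateAlleleSequence()` validates each
construction (primer uniqueness, tract integrity and uniqueness, SNP
contexts) and rejects colliding specs with a construction error. A
repeat count of 1 is refused: a single motif occurrence is
indistinguishable from background and is not a tandem repeat.

Because the flanks are synthetic, absolute residue numbering on the
translated surrogate does not reproduce the published positions 146 and
195; the two variable residues are therefore located through the SNP
offsets, and "146"/"195" are retained as annotations naming the
published positions. The amino acids themselves (G -> H, A -> Y) are
reproduced exactly.

## Sequence operations

In-silico PCR (`insilicoPCR()`) uses exact primer matching -- the assays
were designed for perfect priming, and exactness keeps the independent
placement oracle trivial. Every pairing of a forward site with a
downstream reverse-complemented reverse site is emitted, capped at a
configurable product length (default 5000 bp); both strands are
searched, and no product is an empty result, not an error.

`findTandemRepeat()` scans all rotations of the motif (AGC/GCA/CAG) and
returns the longest maximal perfect run, leftmost on ties, with a
distinct none-found signal when the motif is absent.

`extractSnpStates()` aligns a query allele to the reference by exact
flank anchoring: the only permitted difference in length is a whole
number of repeat units inside the tract, and every position outside the
SNP offsets must match. Anything else -- a flank indel, a substitution at
a non-SNP position -- raises an alignment-ambiguity error rather than
invoking a heuristic aligner, which is deliberately out of scope: real
resequencing data would be mapped with standard tools before reaching
this package. A base outside {ref, alt} at a SNP offset is returned and
flagged novel, not treated as fatal.

Translation (`translateReverseFrame1()`) is reverse-complement frame 1
with the standard genetic code only. Stop codons are rendered `*` and
translation continues, and initiator-codon special-casing is disabled:
this is variant reconstruction across a fixed frame, not gene
prediction. Codons containing a non-ACGT symbol yield `X`.

`proteinVariant()` anchors the polyalanine arithmetic at four alanines
for the 108 bp allele, which the 4-8 residue range forces given one
alanine per 3 bp unit (111 -> 5, 114 -> 6, 120 -> 8). For whole-number
repeat counts the surrogate sequence is actually built and translated
and the tract measured on it; an SSR size not congruent to 108 mod 3
would shift the frame -- never observed in the named alleles -- and is
flagged with a warning instead of being rendered.

## The cohort simulator

`simulateCohort()` emulates the panel-style validation experiment:
genotypes drawn from configured frequencies (default C/C 0.35, C/T
0.55, T/T 0.10, close to the 57-cultivar panel), the true class given by
the marker rule, and hue replicates drawn from class-conditional
truncated normals, by default orange ~ N(73, 2°) and yellow ~ N(88, 2°)
on (0°, 180°), spanning the ranges the packaged tables print. Six
replicates per individual mirror the two-sides-of-three-fruits protocol.
(a\*, b\*) are back-computed from the drawn hue at a fixed chroma of 50;
hue is the only phenotype-bearing quantity, so chroma and lightness are
constants, not model parameters.

Mislabeling with rate $\varepsilon$ swaps the generating distribution
rather than the genotype -- a phenotyping error model, mirroring the
attribution of real panel mismatches to ripening-stage effects on color
measurement. With the default separation (7.5 sd between the orange mean
and the yellow boundary) boundary crossings are negligible, so the
expected unweighted efficiency is $100(1-\varepsilon)$ and the simulator
recovers it within binomial noise; the test suite checks
$\varepsilon \in \{0, 0.05, 0.1, 0.2\}$ at n = 2000 against the 99%
binomial envelope.

What the simulator does *not* emulate: linkage and pedigree structure of
a real F1 cross, hue-dependent chroma and lightness, replicate
correlation within a fruit, genotyping error (only phenotype mislabels),
and transitional light-orange fruit (hue draws rarely land in 77-83
under the default separation). Passing tests on simulated cohorts
therefore demonstrate the correctness of the statistical machinery under
the stated model, not field performance of the markers; the packaged
real tables are the evidence for the latter.

## Problem sizes and determinism

The property suites run the in-silico PCR oracle on 200 random 1-kb
templates and the translation oracle on 1000 random sequences; cohort
recovery uses 2000 individuals per mislabel rate. These sizes give
stable verdicts (binomial 99% envelopes at n = 2000 are about ±1.7
points wide at $\varepsilon = 0.1$) while keeping the whole suite fast.
All generators are pure functions of (config, seed); the cohort
simulator saves and restores the caller's RNG state.

## Known limitations

* The surrogate locus reproduces documented constraints, not the literal
  genomic sequence; analyses that depend on the true flanking sequence
  (e.g. absolute residue numbering) are out of reach by design.
* Efficiencies for the Col1 and SNP4 markers on the cultivar panel
  cannot be recomputed here because the per-cultivar genotype tables for
  those assays were published only as figures; the SSR and SNP4 rule
  sets themselves are implemented and covered by synthetic round trips.
* The concordance model is single-marker; joint multi-marker models and
  association statistics are intentionally absent.
* No general sequence aligner is included; queries must satisfy the
  exact-anchor precondition.
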