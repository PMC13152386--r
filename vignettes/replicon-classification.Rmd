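---
title: "Characterising and classifying the replicons of multipartite bacterial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising and classifying the replicons of multipartite bacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replichar)
```

## The problem

Many bacteria carry more than one replicon. Beyond the chromosome, a genome
may hold plasmids, megaplasmids (conventionally plasmids larger than about
350 kb), chromids (secondary replicons with chromosome-like nucleotide
composition and core genes but a plasmid-type replication system, typically
conserved across a genus) and — rarely — secondary chromosomes whose
replication machinery is itself chromosome-derived or unidentifiable as a
plasmid replicon. In the Streptomycetaceae these distinctions matter: the
family's linear replicons carry terminal inverted repeats (TIRs), are rich in
biosynthetic gene clusters, and giant secondary replicons blur the classical
chromid/megaplasmid boundary.

`replichar` measures, for every replicon of a genome, the axes on which this
argument is conducted and combines them into a class label with an explicit
rationale:

* size and size ratios;
* G+C content and sliding-window GC-skew structure;
* codon usage and its rank correlation with the chromosome;
* COG functional-category content and its rank correlation;
* terminal inverted repeats and shared terminal homology between replicons;
* replication/partitioning marker genes (dnaA/dnaN, rep1/rep2, parA/parB,
  gyrA/gyrB, tap/tpg) and a derived origin call;
* taxon-rank specificity of every encoded protein from homology
  presence/absence.

## The classification rubric

`classify()` applies a fixed decision order to a replicon's feature vector:

1. the largest replicon is the chromosome;
2. below `megaplasmid_min` (default 350,000 bp) it is a plasmid;
3. without core genes unique to it, it is a megaplasmid;
4. with core genes, chromosome-like composition (ΔG+C ≤ `gc_tol`, default
   1.0 mol%; codon-usage Spearman ρ vs the chromosome ≥ `rho_min`, default
   0.9) and a plasmid-type origin (clustered rep1/rep2), it is a chromid;
5. as (4) but with any non-plasmid origin call — chromosomal,
   incomplete-chromosomal (dnaN or parA without dnaA) or none — it is a
   secondary chromosome;
6. anything else is a megaplasmid, with the conflict recorded in the
   rationale.

The numeric thresholds in (2), (4) and (5) are this package's
operationalisation of criteria that are usually argued qualitatively; only
the 350 kb megaplasmid bound is a published convention. All are exposed via
`classification_thresholds()` and echoed into every report. The codon-usage
ρ-versus-chromosome axis is used as a proxy for "codon usage bias" because no
standard scalar statistic is attached to that rubric row; RSCU is provided as
an additional diagnostic.

## Stage models and parameters

**GC skew.** Skew is (G − C)/(G + C) per window, defined 0 when a window has
no G or C so the cumulative series stays total. With this sign convention the
cumulative-skew minimum falls near the replication origin in genomes with the
usual leading-strand G excess. Defaults are 10 kb windows every 5 kb — fine
enough to localise features at 0.1 Mb resolution, coarse enough to plot.
Windows wrap the junction on circular replicons; on linear replicons a
trailing short window is kept and flagged. `skew_segments()` labels maximal
runs of ≥ `min_run` (default 10) windows with |skew| < `slope_threshold`
(default 0.02) as plateaus, a pattern associated with recent rearrangement.

**Codon usage.** Codons are read in frame from strand-corrected CDS.
CDS flagged partial, or whose length is not a multiple of 3, are excluded
(frameshifted annotations would otherwise pollute the table) and their count
reported. Codons containing ambiguity are skipped and counted. Stop codons
are counted by default because published percentage-abundance plots rarely
state the convention; a toggle excludes them. Correlation is computed on the
64-entry percentage vectors, not raw counts, so replicon size does not
dominate. `spearman_rho()` is a direct implementation of tie-aware Spearman
(average ranks, then the Pearson formula); the suite cross-checks it against
`stats::cor(..., method = "spearman")` to 1e-12.

**COG profiles.** A gene with k category letters contributes once to each of
the k categories (fractional 1/k weighting available). Unannotated genes
("-") are excluded from the percentage denominator but reported, and category
S (function unknown) is retained by default. Both choices are toggles because
published abundance plots do not state their denominators.

**Specificity.** Presence of a qualifying homologue is thresholded at
e-value ≤ 0.001, identity ≥ 25% and query coverage ≥ 50% — the conventional
orthology-screen settings — with coverage skipped (and warned about) when
query lengths are absent from the 12-column hit table. The per-protein score
at a taxon level is fA²/(fA + fB), where fA and fB are the frequencies of
group-A and group-B genomes carrying the protein; group A is the focal
strain, genus or family and a protein always counts as present in its own
genome. The source equation for this score is typographically ambiguous
("f(A)2f(A)+ f(B)" in the only available rendering); fA²/(fA + fB) is the
natural reading as a squared-numerator fraction and maps to [0, 1] with 1 =
group-A-unique and 0.5 = ubiquitous. The alternative reading fA/(2fA + fB)
is implemented behind `formula = "alt"` and reports name the formula used.
Summaries are medians and type-7 (linear interpolation) quartiles.

**Terminal repeats.** `find_tir()` is a deterministic seed-and-extend
procedure: an exact seed of `seed_len` (default 100) bases shared between the
left end and the reverse complement of the right end within the first
`max_scan` (default 10 kb) bases; banded unit-cost alignment (band 50) of the
two inward-reading ends, grown geometrically; termination when identity over
the trailing `window` (default 1000) aligned columns drops below
`min_identity` (default 95%). The alignment is then cut at the column
maximising matches − λ·differences with λ = min_identity/(100 −
min_identity). A literal "trim back to the last column where global identity
≥ threshold" would, for a long high-identity repeat, retain tens of columns
of unrelated flanking sequence (global identity decays slowly past the
boundary) and bias the reported identity low; the score-argmax cut places
the boundary at the point where extension stops paying at the stated
threshold, so the reported identity matches the repeat's actual divergence.
Identity counts indels as differences, column-wise, and every report carries
the full matches/mismatches/indels bookkeeping. When scanning for repeats
expected to be more diverged than ~2% per base, set `min_identity` below the
expected identity by several trailing-window standard deviations (e.g. 90
for 5% divergence), otherwise the trailing window can terminate extension
early inside the repeat.

**Markers.** Marker detection is annotation-text matching against a
configurable regular-expression vocabulary for the ten canonical marker
names, not a profile-HMM search; `cluster_span` (default 5 genes) defines
co-location for the origin call.

## The synthetic genome generator

`generate_genome()` emits genomes in which every measured quantity has a
known truth: intergenic DNA i.i.d. at a target G+C; CDS drawn codon-by-codon
from a weight vector (start forced to ATG, one stop at the end); COG letters
from a category mixture; TIRs implanted by copying the left terminus onto
the right (reverse complemented) with an exact mutation count
round(rate × length), so realized divergence equals the target up to
rounding; motifs implanted at the nearest intergenic position to each
requested site; marker cassettes written as named CDS; and a tiered
pangenome (strain-unique / genus-core / family-core / universal) converted
into a presence/absence matrix over a synthetic taxonomy (1 focal strain, 3
genus, 6 family, 10 outgroup genomes by default) together with a hit table
that passes or fails the presence thresholds accordingly.
`predicted_statistics()` returns the closed-form expectations used as test
oracles.

Codon weight vectors from `gc_codon_weights()` combine a per-position G+C
model with a fixed multiplicative tilt that spreads codons of equal G+C
apart. Without the tilt, same-G+C codons would be exactly equiprobable and
their observed ranks pure sampling noise, capping the Spearman correlation
between two replicons drawn from identical weights well below 1 no matter
how many codons are counted; real genomes have distinct per-codon
preferences, which the tilt emulates.

The `preset_embleya()` conditions mirror the shape of a sequenced
Streptomycetaceae multipartite genome at one tenth linear scale: a 700 kb
linear chromosome and a 420 kb chromosome-like linear secondary replicon,
both at G+C 0.716 with a shared 2.1 kb TIR diverged at 5×10⁻⁴ per base, plus
30 kb linear and 21 kb circular plasmids at G+C 0.691/0.695 with flattened
codon bias, plasmid-like COG mixtures (enriched in replication/repair,
trafficking, defence and unknown function) and predominantly strain-unique
genes. The secondary replicon carries a dnaN/parA cassette without dnaA
(incomplete-chromosomal origin), the circular plasmid a rep1/rep2 cassette
and parS-like palindromic sites, the chromosome a dnaA/dnaN/parA/parB/
gyrA/gyrB cassette and parS sites. `preset_all_classes()` adds a chromid-like
replicon (chromosome-like composition, core genes, rep1/rep2) and a
megaplasmid-like one (divergent composition, no core genes) so all five
labels are exercised.

What the generator deliberately does not emulate: gene-order evolution and
synteny decay, recombination and horizontal transfer, amelioration gradients
within replicons, repeat families beyond the TIRs, sequencing error, and the
covariance structure of real codon bias (expression-level dependence).
Passing tests therefore demonstrate that the estimators recover the
statistical structure they model — not that real annotations are free of the
artefacts (frameshifts, wrong starts, missed genes) the pipeline's
exclusion rules exist to contain.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere; BED-style output is labelled.
* Topology defaults to linear when a GenBank LOCUS line is silent (the
  common case in this family), with a per-record override.
* Zero-(G+C) windows score skew 0; windows larger than the molecule are
  capped at the molecule (with a warning on linear replicons).
* Cumulative-skew ties break toward the smallest center.
* Quantiles are type 7 (linear interpolation), stated in output metadata.
* Empty codon tables and profiles with fewer than three distinct values are
  excluded from correlations with a warning rather than producing NaN.
* `specificity_score(0, 0)` is an error, not 0: a protein absent from both
  groups including its own genome indicates an upstream join problem.
* The generator validates spec feasibility (CDS + TIRs + minimal gaps fit the
  replicon) before writing any file, and audits its own output (CDS
  extraction, TIR divergence, motif placement) at generation time.

## Problem sizes in the test suite

The suite generates everything it tests. Unit tests run the preset at 0.1 to
0.25 of its default scale; the end-to-end recovery property runs 20 seeded
replicates of the five-class preset at 0.2 scale with the size thresholds
scaled alongside (classification takes its thresholds as an explicit
argument, so scaled runs are a configuration, not a code path); the
acceptance script runs the full-size preset. These sizes were chosen so the
statistical tolerances stated in each test (binomial 3σ bounds, ±0.5-point
codon percentages, ±2-point COG percentages, ±0.1-point TIR identity) have
comfortable margins at the corresponding sample sizes.

## Known limitations

* GenBank parsing covers single-interval locations with partial markers;
  compound join/order locations are rejected per feature (with a count), so
  genes spanning a circular origin are not counted.
* Marker detection is text matching; unannotated or renamed markers produce
  origin call "none", which the rubric treats as non-plasmid evidence.
* The TIR detector assumes the repeat starts at (or within one band width
  of) the physical ends of the molecule.
* "Core genes" are whatever single-copy orthologue table the user supplies;
  the package does not infer orthology.
* The specificity stage consumes a pre-computed homology hit table; it never
  runs the search itself, so its results inherit the search's sensitivity.
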