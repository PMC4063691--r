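---
title: "Methods: scheme-driven MLST and population-structure analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scheme-driven MLST and population-structure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlstkit)
```

# The typing model

Multilocus sequence typing characterises an isolate by the exact nucleotide
sequence of a small set of housekeeping-gene fragments. Per locus, every
distinct sequence is an *allele* and receives an integer number; the vector of
allele numbers across all scheme loci is the isolate's *allelic profile*, and
every distinct profile is a *sequence type* (ST). All downstream population
analysis operates on these integers, so two design rules are absolute:

* **Alleles are exact-sequence identities.** A fragment containing an IUPAC
  ambiguity code cannot be compared exactly and is a hard error at assignment
  time (ambiguous bases are accepted, with a warning, on plain FASTA reads so
  that the offending record can be inspected).
* **Indels are out of model.** All alleles of a locus must have equal length;
  the per-locus statistics assume an ungapped alignment. A fragment of
  deviating length is a `length conflict`, never aligned.

The bundled default scheme is the eight-locus *Leuconostoc lactis* scheme
(carB, groEL, murC, pheS, pyrG, recA, rpoB, uvrC) with its published primer
pairs; its amplicon lengths sum to 5,325 bp. Profile columns follow the
scheme's declared locus order, which for the bundled scheme is alphabetical —
the source material lists loci in different orders in different tables, and a
fixed alphabetical order makes every file this package writes deterministic.

## Numbering conventions

Allele and ST numbers are assigned in first-encounter order over the input
(open mode), which makes a run reproducible without a central registry. The
consequence, tested as a property, is that permuting the input order permutes
only the *labels* of novel alleles/STs, never the partition of isolates into
alleles or STs. Closed mode never mutates the database: a novel allele or
profile is signalled instead.

## In-silico amplicon trimming

`trim_to_locus()` mimics the PCR/sequencing step: it locates the forward
primer and the reverse complement of the reverse primer (both with a
configurable mismatch budget, default 1) and returns the fragment between
them, searching the reverse complement of the input if the forward
orientation fails. Primer sites are removed by default because base calls
under sequencing primers are unreliable; `keep_primers = TRUE` retains them.
A trimmed fragment whose length deviates from the expected
`amplicon_length - len(primers)` by more than 10% (configurable; `Inf`
disables) is a "fragment length anomaly". The tolerance is configurable
rather than strict because deposited MLST sequences vary in whether primer
regions were left in.

# Per-locus diversity and selection

* **Polymorphic sites** are alignment columns with at least two residues;
  their sum over loci is the SNP total.
* **GC content** is pooled over all input sequences (so isolates weigh by
  their representation), reported as a percentage.
* **dN/dS** uses the Nei–Gojobori (1986) pathway-counting method, the method
  implemented by the classic MLST analysis tools this package replaces. Per
  codon, the number of synonymous sites is the expected fraction of
  synonymous single-base changes, with mutations to stop codons excluded from
  the possibilities (keeping 3 sites per codon); differences in codons hit at
  2–3 positions are averaged over all minimal mutational pathways, discarding
  pathways through stop codons (if every pathway is discarded, all are used).
  The Jukes–Cantor correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$ maps
  the proportions to distances; $p \ge 3/4$ is a saturation error. Codons
  that are stops in either sequence are dropped with a warning.

Reading frame is assumed to start at position 1 of the trimmed fragment
(true for the synthetic generator by construction); a per-locus
`frame_offset` exists because published schemes rarely state frames.

Reporting conventions follow the field's typing tables: the per-locus dN and
dS are means over all unordered pairs of **distinct alleles** by default
(an allelic-variation table describes alleles, not isolates; isolate
weighting is available via `weighting = "by_isolate"` since either choice is
defensible), and the ratio is reported as 0 when dN = 0 and as undefined
(`NA`) when dS = 0 with dN > 0.

# Linkage disequilibrium and clonality

For every unordered pair of isolates let $K$ be the number of loci at which
their profiles differ. The package computes

* $V_O$: the **population variance** of $K$ over all $n(n-1)/2$ pairs.
  Pairs are not independent draws, so an "unbiased" sample-variance
  denominator has no inferential meaning here; the population variance is
  also the convention under which the package's hand-enumerable four-isolate
  example gives exactly $V_O = 8/9$ and $I_A = 1$.
* $V_E = \sum_j h_j (1 - h_j)$: the expected variance under linkage
  equilibrium, with $h_j = \frac{n}{n-1}\,(1 - \sum_i p_{ij}^2)$ the
  unbiased per-locus diversity. The small-sample correction is the default;
  `ve_method = "biased"` omits it, because different published programs
  differ exactly here and the choice moves the index (never its sign). The
  literature's printed pairs of $I_A$ and $I_A^S$ for the same data often
  come from two programs with the two different $V_E$ estimators, and cannot
  generally be reproduced simultaneously by one estimator.
* $I_A = V_O/V_E - 1$, zero in expectation under free recombination and
  positive under clonality, and the standardized $I_A^S = I_A/(\ell-1)$,
  which removes the dependence on the number of loci $\ell$.

The Monte-Carlo null shuffles the allele column of every locus independently
across isolates — destroying between-locus association while preserving
allele frequencies exactly (so $V_E$ and each $h_j$ are invariant, a tested
property) — and recomputes $V_O$. The tail probability uses the +1
correction, $p = (1 + \#\{V_O^{perm} \ge V_O\})/(1+n)$, so a finite run never
reports the display value "p = 0.000". $V_O$ is computed in $O(n\ell^2)$
from per-locus and per-locus-pair match tallies rather than by enumerating
pairs, which keeps the permutation test fast at hundreds of isolates; the
tally formula is verified against a pair-enumeration oracle in the tests.

# Clonal complexes, founders and the minimum spanning tree

The default grouping rule is the *shared-allele* rule: repeatedly take the
unassigned ST with the most single-locus variants (ties: most double-locus
variants, then isolate frequency, then lowest ST number) as a candidate
central genotype; every unassigned ST sharing at least `threshold` alleles
with it (default 5 of 8) joins its group; groups whose centers share the
threshold are merged. This literal centre-based rule admits double-locus
variants of the founder into a complex, which the classic "share $\ell-1$
with at least one member" single-linkage rule does not; the classic rule is
available as `rule = "slv"` (under which the property "every SLV pair shares
a group" holds by construction). The predicted founder of a group is its
member with the most SLVs, ties broken by DLV count, isolate frequency, then
lowest ST number — fully deterministic.

The minimum spanning tree runs Prim's algorithm on the complete ST graph
weighted by profile Hamming distance, starting from the most frequent ST.
Equal-weight candidate edges are broken by higher isolate frequency of the
new endpoint, then lower new-endpoint ST, then lower tree-side ST, mirroring
the frequency-first priority of the established typing tools while remaining
deterministic. Edge classes (weight 1–2 strong, 3–5 intermediate, ≥6 weak)
are a display convention only and are configurable; published figures are
not fully consistent about them, so they are documented, not "reproduced".
Optimality of the total weight is tested against exhaustive spanning-tree
enumeration (Prüfer sequences) on small instances.

# Distance trees

The dendrogram distance is the proportion of mismatched loci between
profiles by default — the classic typing-tool convention — with uncorrected
p-distance on concatenated fragments as the alternative (the source tools
support both and studies rarely state which they used). UPGMA is implemented
directly so that its tie-break is defined: the closest pair of clusters
merges at height $d/2$ (hence an ultrametric tree, tested to $10^{-9}$),
average linkage is size-weighted, and ties are resolved by the
lexicographically smallest pair of cluster labels, making results
order-independent up to leaf rotation. The implementation is cross-checked
against an independent average-linkage implementation. Neighbour-joining
uses the standard Saitou–Nei algorithm (`ape::nj`), with negative branch
lengths clamped to zero with a warning; on additive metrics it reconstructs
the generating tree exactly (tested). "Two major groups" of a dendrogram are
obtained by the 2-cut convention — removing the $k-1$ highest internal nodes
— since figure-based group designations are otherwise not reproducible.

# Split decomposition

The Bandelt–Dress isolation index of a bipartition $A|B$ is
$$\alpha_{A|B} = \tfrac12 \min_{i,j\in A;\; k,l\in B}
\big[\max(d_{ik}+d_{jl},\; d_{il}+d_{jk},\; d_{ij}+d_{kl}) - d_{ij} - d_{kl}\big],$$
with $i=j$ and $k=l$ allowed. The *d-splits* (splits with $\alpha > 0$) of a
distance matrix form a weakly compatible system; on an additive (tree)
metric they are exactly the tree's edges and reproduce the distances with
zero residual (both tested). Two splits are *incompatible* when all four
intersections of their sides are non-empty — the "parallelogram" of a drawn
split network — and the presence of incompatible pairs is the package's
recombination signal. Splits are enumerated exhaustively up to 12 taxa and
by the incremental taxon-by-taxon construction above that (a d-split
restricted to a taxon subset keeps a positive index, so no split is lost);
the two routes are required to agree on their overlap range in the tests.
The residual is the fraction of the summed input distance not represented by
the split metric. Per-locus split graphs use the distinct alleles as taxa
with uncorrected p-distance (matching how the classic tools draw per-locus
graphs); the combined graph uses distinct STs with concatenated p-distance.
Uncorrected p-distance is adopted because the upstream tools' default
transform is undocumented. Output is a Nexus file with Taxa and Splits
blocks readable by standard split-network viewers; drawing is out of scope.

# The synthetic-data generator

The generator provides ground truth for every analysis module without any
external data:

* `gen_scheme()` draws in-frame coding fragments (no internal stops) at a
  requested GC content with synthesized 18–22 bp primers, so trimming
  round-trips exactly.
* `gen_alleles()` plants exactly `n_sites` segregating sites in distinct
  codons, each synonymous or nonsynonymous per a requested fraction
  (rejection-sampled on the codon effect; stop-creating changes never used).
  Alleles are distinct subsets of the planted substitutions with every site
  carried by at least one allele, so segregating-site counts and
  synonymous-only constructions (dN = 0 exactly) are guaranteed by
  construction. The mutation model is uniform over positions and
  substitutions subject to the effect constraint — the simplest model that
  satisfies the truth-table contract.
* `gen_population()` draws either a *clonal* population — founders pairwise
  maximally separated by default, descendants derived by a geometric number
  (p = 0.5) of single-locus allele changes, yielding the founder-plus-SLV
  star pattern of clonal species — or a *panmictic* one with every locus
  drawn independently, i.e. linkage equilibrium by construction.

What the generator does **not** emulate: homologous recombination tracts
(descendants differ by whole-allele swaps, not mosaics), sequencing error,
within-locus homoplasy, indels, or realistic allele-frequency spectra
(draws are uniform). Passing tests therefore demonstrate that the
statistics and algorithms are computed correctly and are calibrated under
their stated nulls — not that any particular real population is clonal.

# Numerical choices and problem sizes

All randomness flows through explicit integer seeds; generators restore the
caller's RNG state. Tie-breaks everywhere are deterministic (documented
above), so seeded end-to-end runs are byte-identical — itself a tested
property. Test and validation workloads are sized for quick, stable runs:
the dN/dS oracle comparison uses 200 random pairs of ≤30 codons at a
tolerance of $10^{-10}$ on the uncorrected proportions; the linkage null
calibration uses 100 panmictic replicates of 500 isolates × 8 loci with a
99-permutation test (the p-value floor 1/100 sits below the 0.01 criterion);
MST optimality is enumerated on ≤6-ST instances; founder recovery uses 20
seeded 80-isolate populations; ultrametricity is checked on 100 random
matrices. Degenerate inputs have defined behaviour: a single allele gives
all-zero selection statistics; an all-monomorphic profile set is a
"no variation" error for the index of association; an empty population is an
empty table, not an error.

# Known limitations

* dN/dS is NG86 with Jukes–Cantor correction only; no maximum-likelihood
  models, no site-specific selection tests. Alternative dN/dS methods change
  digits, so cross-tool comparisons should state the method.
* The parametric (permutation-free) linkage test and single-ST-per-lineage
  subsampling are not implemented.
* eBURST bootstrap confidence on founders is omitted.
* No bootstrap values on trees; no likelihood or Bayesian phylogenetics.
* Split networks are emitted, not drawn; NeighborNet is out of scope.
* The split-decomposition taxon cap (60) reflects the $O(|A|^2|B|^2)$
  isolation-index evaluation; collapse isolates to distinct STs or alleles
  first, as the classic tools do.
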