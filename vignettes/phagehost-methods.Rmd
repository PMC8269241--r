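---
title: "Methods: host prediction for plasmidome-derived phage contigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host prediction for plasmidome-derived phage contigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagehost)
```

# The problem

Plasmidome sequencing — selective extraction and amplification of a
community's circular extrachromosomal DNA — recovers phage genomes
alongside plasmids, but with no direct information about which bacteria
those phages infect. This package implements the desk side of that
analysis: deciding which assembled scaffolds are complete circular
genomes, predicting bacterial hosts for viral contigs by three
independent signals, curating auxiliary-gene annotations, and merging
everything into a consensus report. Because host-range ground truth for
environmental viruses is unobservable, the package also implements the
study design needed to validate such a pipeline: a synthetic community
in which every detectable signal is planted deliberately.

# Circularity calls

A scaffold assembled from a circular template carries the assembly's
terminal redundancy as a **direct repeat** at its two ends, and sequencing
fragments that straddled the (arbitrary) linearization point leave read
pairs mapping near opposite ends in an outward orientation. A scaffold is
called circular when all three criteria hold:

* length > 2,000 bp (a 2,001-bp scaffold passes, 1,999 fails);
* a terminal direct repeat of ≥ 35 bp (same orientation; an inverted
  end-repeat does not qualify). The repeat test is an exact string
  comparison, which at these lengths is far more stringent than any
  E-value-based homology cutoff; the primary literature for this
  criterion prints its E-value bound with an inverted inequality, which
  we flag here rather than silently "correct" — the exact-match rule is
  deterministic and strictly conservative;
* ≥ 2 read pairs with the plus-strand mate wholly within 500 bp of the
  right end and the minus-strand mate wholly within 500 bp of the left
  end. Reads are placed by exact substring match on either strand;
  ambiguous placements (a read occurring more than once) drop the pair.
  A coordinate-sorted SAM file is accepted as an alternative evidence
  source under the same windows.

All coordinates in the package are 0-based half-open.

One subtlety matters for validation: a wrapped fragment whose *read*
(not just the fragment) crosses the junction has no exact placement on
the bare template, so the generator's truth tables distinguish
`straddles` (fragment wraps the origin; follows the binomial rate
`n_pairs * insert / length`) from `spans_ends` (both mates lie wholly on
opposite sides of the junction — exactly the pairs an end-window counter
can recover). Tests assert count equality against `spans_ends` and rate
agreement against `straddles`.

# Tetranucleotide composition (4-mer) method

Phages tend to resemble their hosts in genome composition. Sequences are
summarized as **canonical tetranucleotide frequencies**: of the 256
4-mers, 16 are reverse-complement palindromes, leaving
(256 − 16)/2 + 16 = 136 canonical features; every 4-bp window is counted
once under the lexicographic minimum of the word and its reverse
complement, making profiles strand-blind. Multi-contig genomes pool
counts before normalization (length-weighting is the unbiased
estimator); windows containing non-ACGT letters are skipped; windows are
never taken across contig joins.

The distance is the mean absolute error
`d = (1/136) Σ|p_i − q_i|` — 1/136 of an L1 metric, bounded by 2/136.
Hosts with `d < 0.001` (strictly) are candidates; the five lowest
distances (ties at the boundary included, for order-independence) are
reduced to their lowest common ancestor. Viruses shorter than 4 kb are
still profiled but flagged low-confidence, since MAE sampling noise
scales as 1/sqrt(length). We require the threshold first and only then
rank — hosts outside the threshold are never rescued by being in the
top 5.

# Shared-region (blast) methods

Prophage integration and horizontal transfer leave a host genome segment
locally similar to the virus. The in-house search is **ungapped
seed-and-extend**: exact 11-mer seeds shared by virus and host anchor
diagonals (a diagonal is kept when two seeds fall within 500 bp of each
other; hyper-frequent seeds are masked like low-complexity words), and
each anchored diagonal is resolved into its maximal-scoring segments
under +2/−3 scoring via an iterated maximal-subarray scan — equivalent to
an X-drop extension for substitution-only divergence. Raw scores convert
to bit scores with ungapped Karlin–Altschul constants
(λ = 0.625, K = 0.41) and `E = m·n·2^(−bit)` with m the virus length and
n the summed host genome length. Ungapped-only alignment is a documented
limitation for real data with indels; for substitution-planted synthetic
truth, identity is then exactly Hamming identity and region length is
unambiguous. A 12-column tabular alignment file from an external aligner
can be substituted for the built-in engine; it feeds the same filters.

* **blast** (genus level): a host qualifies if any region passes bit ≥ 50,
  E ≤ 0.001, length ≥ 4,900 bp, identity ≥ 70%. Each strain is collapsed
  to its best region by bit score before ranking (the de-duplication rule
  when one strain has many regions), the top 5 strains (ties included)
  are reduced to their LCA.
* **blast99** (strain level): regions at identity > 99% with E below
  1e−180 (a literal "E = 0" is a floating-underflow artifact of
  double-precision aligners) are merged on the virus axis; a strain is
  called when the merged spans cover > 99% of the virus. Several strains
  may be called for one virus — whole phages genuinely occur integrated
  in multiple strains of a genus.

# CRISPR spacer method

CRISPR arrays are fossil records of infection. Detection follows CRT
geometry: exact 8-bp words recurring with spacings compatible with
repeat length 19–38 plus spacer length 19–48 are chained (≥ 3 copies)
and the repeat is extended maximally while all copies agree. The
extension tolerance (`max_divergence`, mismatches per copy against the
column consensus) defaults to 0: with only 3–4 repeat copies, a tolerant
extension walks deterministically into random flanking sequence (for 3
copies, a majority exists in ~62% of random columns), destroying
base-exact locus recovery; strict agreement keeps detected loci exact,
and the tolerance remains available for real genomes with degenerate
terminal repeats. Arrays violating the length windows are discarded;
overlapping candidates resolve to the one with more repeats.

Spacer matching replaces a short-word alignment stage with an exhaustive
full-length Hamming scan of each spacer against each virus on both
strands — equivalent-or-stricter for the "0 or 1 mismatch, full length,
ungapped" filter, and exact at desk scale (gapped matches cannot satisfy
a full-length ≤ 1-mismatch rule). Matched spacers are then
**back-validated**: the spacer must still occur exactly (0 mismatches) in
its host genome of origin. Validation is against the host of origin only;
exact occurrences in other hosts are logged but never converted into
predictions. Validated matches aggregate into one strain-rank prediction
per (virus, host), evidence listing the supporting spacers.

# Consensus and cluster consistency

Methods are merged one row per virus. Genus agreement is computed over
the methods that called: each assignment is taken at genus rank (or at
its own rank if shallower), and the calls agree when those points lie on
a single root-to-leaf lineage chain. The best call is the deepest-rank
assignment, ties broken by the methods' established confidence ordering
crispr > blast99 > blast > 4mer. Strain-level methods may emit several
strains for one virus; the per-method consensus column shows their LCA
(the per-strain rows remain in the per-method tables). Disagreements are
reported, never adjudicated — a cluster-level host range is a biological
finding, not an error to resolve. Within a viral cluster (an externally
supplied genus-level grouping), members' best calls are reduced to their
LCA; the LCA's rank is the rank at which the cluster is consistent, with
single-prediction clusters flagged.

Taxonomy is a rank-labelled tree built from a lineage TSV; identical
lineages share nodes, blank intermediate ranks collapse, and the LCA is
reported at the nearest named rank (hosts are legitimately reported at
genus, family, order or class). When top hits only meet at the root, the
root is returned flagged `unresolved` rather than guessing a rank.

# The synthetic community

The generator's design goal is that every signal consumed downstream is
planted explicitly and nothing else correlates virus with host.

* **Composition**: each genus gets an order-3 Markov model whose
  per-context next-base distributions are Dirichlet draws (concentration
  `divergence`). Order 3 puts tetranucleotide statistics under direct
  control — precisely the signal the 4-mer method consumes. With the
  default concentration 1, 100-kb host genomes and 40-kb viruses, the
  same-model virus-host MAE concentrates near 4e-4 while cross-model and
  uniform-background distances sit near 4e-3–6e-3, so the 0.001 rule
  separates the 2×2 design {host-linked, background} × {true-genus,
  other} cleanly. These sizes were fixed by a one-off calibration of the
  emission model and are stated here as the study conditions; strain
  identity within a genus is per-base substitution at rate 0.002.
* **Prophages**: full mode inserts the exact virus (host length grows by
  exactly the virus length); partial mode inserts a ≥ 4.9-kb window
  substitution-mutated to a target identity in [0.70, 1] — substitutions
  only, so planted identity is well-defined Hamming identity (indels are
  deliberately out of scope). Insertion points are uniform, ≥ 1 kb from
  contig ends, keeping planted loci clear of edge effects. Two negative
  controls (4.5 kb at 0.95; 6 kb at 0.65) sit just below the detection
  thresholds; their truth rows are labelled `negative_control` so they
  can never be mistaken for recoverable plantings.
* **CRISPR arrays**: literal repeat-spacer-…-repeat loci with
  CRT-compatible geometry; virus-derived spacers differ from their source
  window by exactly the requested 0/1/2 substitutions. If the repeat
  copies' flanking columns happen to be unanimous, the free host base at
  the insertion point is bumped so the maximal repeat extension ends
  exactly at the planted repeat — spacer bases are never modified, so
  requested mismatch counts stay exact.
* **Reads**: error-free by default (a substitution rate is available),
  insert sizes truncated-normal with minimum `read_len` and a 450-bp cap
  that keeps junction fragments inside the default 500-bp end windows.
* **Reproducibility**: everything is a pure function of (config, seed);
  the master seed expands into per-component child seeds through a
  tagged integer mix, so regenerating one component never perturbs
  another. When stacked insertions share a contig, previously recorded
  truth coordinates are shifted so all loci index the final sequences.

The default community has 13 strains in 6 genera spanning 4 phyla
(including two orders of Proteobacteria, so cluster-consistency reduces
to a phylum-level LCA in the mixed cluster), and 22 viruses: 6
composition-linked, 3 full prophages (one integrated into all three
Acidovorax strains), 4 partial prophages at identities 0.75/0.85/0.95/1.0,
2 negative controls, 3 CRISPR-targeted viruses at 0/1/2 spacer
mismatches, and 4 background viruses.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: indel variation and gapped alignment, repeat-
and mobile-element-rich host genomes (composition is homogeneous within a
genome), sequencing error in the default read libraries, degenerate
CRISPR repeats, amplification bias of the plasmidome protocol, and hosts
absent from the database (every planted virus has its true host present).

# Annotation curation

Externally produced protein-domain hits (HMMER per-domain tabular output;
the per-domain independent E-value and domain bit score are the filtered
fields) are kept at bit ≥ 30 and E ≤ 1e−3, then categorized by an
ordered, user-editable keyword table matched case-insensitively against
target name or description — mirroring manual curation practice. The
shipped defaults put the specific resistance classes (copper resistance,
beta-lactamase, AcrB/AcrD/AcrF efflux, streptomycin adenylyltransferase,
toxin-antitoxin) ahead of generic phage-hallmark and metabolism classes;
unmatched hits fall through to `not_categorized`, so the categories
always partition the filtered hits. The table is a starting set meant to
be extended per study, not an exhaustive curation.

# Numerical and design choices

* Ties at any top-n boundary include all tied candidates before the LCA —
  deterministic and input-order-independent.
* The Kadane segment scan masks found segments with a large finite
  penalty and iterates until the best raw score drops below the reporting
  floor (raw 40, bit ≈ 37), below the bit-50 prediction filter.
* E-values use double precision throughout (`m·n` computed in floating
  point).
* `run_all` writes TSVs plus a JSON manifest (parameters, package
  version, output checksums) with no timestamps, so reruns with one
  config are byte-identical; stages execute serially and the `threads`
  argument cannot change results.
* Problem sizes in the shipped tests (100-kb hosts, 13 strains, 22
  viruses, 100 freshly seeded viruses for the 4-mer recovery rates, 150-
  to 400-pair read libraries) are the package's chosen study conditions:
  large enough that composition statistics are in their asymptotic
  regime, small enough that the full suite and the acceptance script are
  comfortable on a laptop.

# Known limitations

Ungapped alignment only; no gene-content host signals; no Cas-gene or
PAM analysis around arrays; the consensus does not weight methods beyond
the fixed confidence ordering; cluster membership is consumed, never
computed. These mirror the scope of the analysis the package implements.
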