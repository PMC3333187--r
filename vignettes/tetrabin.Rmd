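---
title: "Composition-based taxonomic binning with tetrabin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-based taxonomic binning with tetrabin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrabin)
```

`tetrabin` assigns metagenomic reads to taxa using only sequence
composition: no alignment is performed at any point. This vignette explains
the model and its assumptions, every tunable parameter, the synthetic data
the package tests itself on, and the numerical and design decisions a
maintainer should know about.

## The model

### Composition as a phylogenetic signal

The working premise is that oligonucleotide usage diverges as lineages
diverge: two sequences sampled from organisms whose lowest common ancestor
sits high in the taxonomy are, on average, further apart in composition than
two sequences from congeneric organisms. The composition summary used
throughout is the tetranucleotide relative-frequency vector: all 256 4-mers
counted in overlapping windows over the sequence exactly as given
(forward strand), normalized by the number of counted windows. Windows
containing any non-ACGT symbol are skipped rather than imputed, which keeps
the vector on the probability simplex and keeps the procedure deterministic;
the denominator is therefore the number of *clean* windows, not `L - 3`.
Distance between vectors is the Manhattan (L1) distance, bounded by 2 on the
simplex.

An important departure from "one genome, one model" classifiers: the
reference unit is the 1 kb genome *fragment*, not the genome. Genomes have
internally heterogeneous composition (e.g. repetitive gene families, mobile
elements); comparing a sub-kilobase read to 1 kb fragments compares like
with like and lets a read match the compositionally matching *part* of a
genome.

### The four classification steps

For each read:

1. **Closest-fragment subset.** The index holds all fragment vectors grouped
   by k-means into clusters with stored centroids. The read vector is
   compared to the centroids only; the single nearest cluster is then
   scanned exactly. With `d_min` the distance to the closest fragment in
   that cluster, every fragment with `d <= d_min / (1 - epsilon)` is
   retained (`epsilon = 0.01`, i.e. fragments within about 1 % of the
   minimum). When `d_min = 0`, exactly the zero-distance fragments are
   retained.
2. **Taxonomic level (TL).** `d_min` is translated into the most specific
   rank the assignment may use, through read-length-dependent distance
   thresholds (table below). Longer reads have tighter thresholds because
   their frequency vectors are less noisy.
3. **Normalization.** Taxon proportions `P_i` in the subset at the working
   rank are damped against each taxon's database share `R_i` (percentage of
   all index fragments under that taxon at that rank):
   `N_i' = P_i / (1 + a * log10(1 + R_i))`, then renormalized so the `N_i`
   sum to 100.
4. **Convergence.** Starting at TL and moving rank by rank toward
   superkingdom, the read is assigned to the first taxon whose `N_i`
   reaches `100 * tau`. If no rank converges — including superkingdom — the
   read is *unassigned*. Reads whose vector has no clean 4-mer window are
   *too_short*.

## Parameters

| Parameter | Default | Units / range | Role |
|---|---|---|---|
| `fragment_length` | 1000 | bp | reference window size; the unit of comparison |
| `min_fragment_length` | 500 | bp | shortest trailing window kept when a contig is not a multiple of 1 kb; avoids unstable vectors from tiny tails |
| `k` | `floor(sqrt(N))`, capped at 2048 | clusters | balances the centroid scan against the within-cluster scan; always user-overridable |
| `epsilon` | 0.01 | relative band | width of the closest-subset band around `d_min` |
| `tau` | 0.80 | fraction | convergence threshold on the normalized proportion; strict majority proved too lax in exploratory runs, 0.80 is conservative |
| `a` | auto: 2 (reads >= 150 bp), 0 (shorter) | integer >= 0 | normalization damping weight; 0 disables damping |
| `strand` | `"forward"` | forward / symmetric | 4-mer counting mode; all default thresholds assume forward |

The distance thresholds ship as a configurable table
(`threshold_table()`, overridable from YAML/TSV):

| read-length class | genus | family | class |
|---|---|---|---|
| sanger (>= 600 bp) | < 0.28 | 0.28–0.32 | > 0.32 |
| titanium_400 (300–599 bp) | < 0.35 | 0.35–0.41 | > 0.41 |
| standard_250 (150–299 bp) | < 0.43 | 0.43–0.51 | > 0.51 |
| gs20_100 (< 150 bp) | < 0.6 | > 0.6 | — |

Two boundary conventions are fixed once and tested: a read length on a class
boundary takes the class whose lower bound it meets (the bounds sit at the
midpoints between the technologies' nominal lengths), and a distance landing
exactly on a threshold resolves to the *less specific* rank, the
conservative reading of printed ranges such as "0.28 – 0.32".

Genus is the most specific level the threshold table can produce, so the
classifier never emits species-level calls even where the taxonomy contains
species nodes.

### Normalization form

The damping function is logarithmic in `R_i`, is exactly the identity at
`a = 0`, and — because damping by a constant cancels under renormalization —
is also the identity whenever all `R_i` are equal. Its growth is slow enough
that a genuinely dominant taxon is damped but not driven to negligible
proportions. The form is registered behind a `formula` identifier
(`norm_config()`), so alternative damping functions can be swapped in
without touching the pipeline; `"log_damp"` above is the default and the
only built-in.

### Taxonomy handling

Ranks live on the fixed ladder species < genus < family < order < class <
phylum < superkingdom < root. Lineages may skip ranks (NCBI lineages are
rank-sparse); when a fragment's lineage has no node at the working rank, the
fragment is counted under its nearest *present* ancestor above that rank
rather than dropped, so proportions always sum to 100. `root` (and NCBI's
"cellular organisms") collapse into a single root node that is never
reported: a read whose subset converges only at the root is unassigned.

## The synthetic study design

The package carries its own data generator so every test runs offline.

* **Taxonomy**: a balanced tree, by default 4 phyla × 2 classes × 2 orders ×
  2 families × 2 genera = 64 genera, one genome per genus.
* **Composition models**: each genus gets an order-3 Markov chain over
  A/C/G/T (so 4-mer statistics are directly controlled). The root model's
  64 transition rows are Dirichlet(0.3) draws — deliberately concentrated,
  mimicking the skewed oligonucleotide usage of real genomes; with uniform
  composition the sampling noise of 1 kb fragments alone would exceed the
  genus threshold. Child clades multiply the parent's transition weights by
  log-normal noise with sd 0.4 per rank and renormalize, so expected
  between-genome distance grows with the rank of the lowest common ancestor.
  Under these two defaults the distance from an 800 bp read to the nearest
  fragment of its own genus falls well below the 0.28 genus threshold, while
  sibling genera typically sit beyond the 0.32 family/class boundary —
  the separation regime the classifier is designed for.
* **Genomes**: 200 kb each, assembled from alternating forward and
  reverse-complement 25 kb blocks of the genus model. Real prokaryotic
  genomes approximately obey Chargaff's second rule because coding regions
  switch strands; a raw one-orientation Markov draw does not, and would make
  every reverse-strand read compositionally alien to a forward-counted
  index. Block alternation restores that strand structure while keeping
  forward-only counting (the mode the thresholds assume).
* **Reads**: drawn uniformly over positions and strands, fixed length per
  technology class (800/400/250/100 bp), i.i.d. substitution errors at a
  configurable rate, no indels and no quality model. The truth table records
  source genome, leaf taxon, strand, position and representation status.
* **Leave-clade-out**: `make_leaveout()` excludes all genomes under chosen
  clades from index building while their reads stay in the query set,
  reproducing the "modified reference database" evaluation design: reads
  from a removed genus should escalate to the correct family or higher, not
  be forced into a wrong sibling genus.

All generators are pure functions of their seeds; identical seeds give
byte-identical genomes, reads and indexes.

**What the toy data do not show.** The simulator controls composition
directly, so clade separability is cleaner than in real genomes, where
compositional divergence correlates only loosely with taxonomic rank, where
horizontally transferred regions carry foreign composition, and where the
published thresholds were fit to real training sequences. Passing the
synthetic recovery tests demonstrates that the machinery — search, subset
rule, thresholding, normalization, convergence — behaves correctly in its
intended regime; it does not certify real-data accuracy figures. Real-data
use should treat the threshold table and `tau` as tunable configuration.

## Numerical and design choices

* **The closest-subset rule**: stated as "fragments within 99 % of the
  closest distance", which we implement as the band
  `d <= d_min / (1 - 0.01)`; the subset must consist of the *closest*
  fragments, and a literal ">= 99 % of d_min" reading would retain
  arbitrarily distant fragments.
* **k-means**: Lloyd iterations (`stats::kmeans`, `iter.max = 300`) with our
  own deterministic k-means++ seeding from the recorded seed. Centroids are
  recomputed as coordinate-wise member means after fitting, so the
  stored-centroid invariant holds even if the iteration cap triggers. Empty
  cluster failures are retried from deterministically derived seeds.
  Clustering is Euclidean (standard k-means) while search is Manhattan; the
  centroid scan is a pruning heuristic, and the k = 1 oracle test verifies
  it against an exhaustive scan.
* **Ties**: if two taxa tie exactly at or above `tau`, the classifier
  escalates a rank instead of picking a side, so results cannot depend on
  iteration order.
* **Degenerate inputs**: empty read sets classify to empty outputs; reads
  with no clean window are `too_short` and are counted separately;
  `assigned + unassigned + too_short` always equals the input count.
* **Persistence**: an index is a self-describing directory — JSON metadata
  (format version, k, seed, fragment/strand settings) plus TSV tables.
  Fragment vectors are stored as *integer 4-mer counts*, an exact rational
  representation, so `load_index(save_index(x))` reproduces `x` exactly;
  centroids are written at full (`%.17g`) precision. Loading refuses a
  format-version mismatch, and classifying with a strand mode different
  from the build's is a configuration error, not a silent wrong answer.
* **Problem sizes in the tests**: the automated suite uses the 64-genus /
  200 kb default for the end-to-end recovery and leave-clade-out checks
  (about 12,800 fragments, 2,000 reads) and smaller collections elsewhere;
  these sizes exercise every code path while keeping a full test run within
  a few minutes on a single core.

## Known limitations

* Only the 8-rank ladder is modelled; sub-species ranks and strain-level
  resolution are out of scope, and species-level calls are never produced.
* The k-means pruning scans a single nearest cluster; a read sitting on a
  cluster boundary can in principle miss its true nearest fragment (the
  k = 1 setting disables pruning when exactness matters).
* The read simulator has no indel or homopolymer error model.
* Index updates are rebuild-only.
* Distance thresholds and `a` are consumed as configuration; the package
  does not re-derive them from training data.
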