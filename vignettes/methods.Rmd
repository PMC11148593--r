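---
title: "Methods: post-GWAS gene prioritization across a pangenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-GWAS gene prioritization across a pangenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwaspan)
```

# The problem

A GWAS or QTL study of a crop like rice ends with genomic intervals, not
genes. Everything interesting happens afterwards: which gene models fall
inside the associated loci, what do those genes do, which coexpression
modules do they sit in, are the loci enriched for particular
transcription-factor binding sites, and — increasingly important for
species with strong population structure — what do the corresponding
regions look like in *other* varieties of the species, whose gene content
can differ from the single reference the study was mapped against?

`gwaspan` implements this post-GWAS layer as a set of composable,
data-frame-first functions: interval parsing and gene overlap, lift-over
of loci onto other genomes through precomputed whole-genome alignments
with an ortholog-based comparison of the gene sets, overlapping community
detection on weighted coexpression networks, Fisher/BH enrichment of
modules and annotation terms, a Monte-Carlo shuffle test for binding-site
overlap, literature-annotation queries, and a per-gene summary table that
ranks candidates. A synthetic-data generator produces internally
consistent inputs in every consumed format so that the entire pipeline is
testable without any external database.

# Coordinate conventions

Internally every interval is **0-based half-open** `[start, end)` on a
named chromosome of a named genome. Region strings
(`"Chr01:1,523,625-1,770,814"`), GFF3 and the usual printed conventions
are 1-based inclusive and are converted exactly once, at the I/O
boundary. BED input is already half-open and passes through unchanged.
Overlap always means *at least one shared base pair*; a gene starting
precisely where a locus ends does not overlap it. A printed region whose
start equals its end is rejected as an empty span rather than read as a
single-base interval; single-base loci must be supplied as BED.
Chromosome names are compared within one genome after lowercasing and
stripping a leading `chr`; names from different genomes are never assumed
comparable.

Only records of feature type `gene` are indexed from GFF3 — the analyses
operate at gene-model granularity and mRNA/CDS children are irrelevant to
them.

# Lift-over through one-to-one alignments

Pairwise whole-genome alignments enter as **ungapped one-to-one
segments**: each row maps a source span to an equal-length target span on
either strand. One-to-one means a base of either genome aligns to at most
one base of the other; the loader rejects tables whose segments overlap
on either side, rather than resolving duplications silently. Segments
need not be colinear, so a locus can legitimately project onto several
target chromosomes — this is how interchromosomal rearrangements surface
in the output.

Projection maps the intersection of the query with each segment through
that segment's affine map (`tgt_start + (x - src_start)` forward;
orientation flipped on `-` segments). Abutting or overlapping images on
the same chromosome are merged; images separated by unaligned sequence
are **not** bridged, since bridging would report unaligned sequence as
lifted. Projected intervals of any length are reported; filtering short
fragments is left to the caller.

The pangenome comparison then partitions genes by ortholog group:
ortholog pairs inside both interval sets (`common`); target genes whose
source ortholog exists but lies outside the input loci
(`ortholog_elsewhere` — candidates invisible to a single-reference
analysis, and the reason the pipeline adds their source partners to the
implicated set before enrichment); target genes without any source group
member (`no_ortholog`); and source genes with no ortholog in the lifted
region (`unique_to_source`). The three target-side categories are
exhaustive and disjoint by construction.

# Overlapping module detection

Genes act in multiple processes, so module detectors are allowed to emit
overlapping modules. Two detectors are provided behind one interface.

**Cohesiveness-based greedy growth** (`cluster_one_detect`). The score of
a vertex set \(V\) is

\[ f(V) = \frac{w_{in}(V)}{w_{in}(V) + w_{bound}(V) + p\,|V|} \]

with \(w_{in}\) the internal edge weight, \(w_{bound}\) the boundary edge
weight and \(p\) a per-node penalty representing unobserved external
connections. Seeds are processed in decreasing weighted-degree order
(lexicographic tie-break), skipping covered vertices; each group grows by
the single best addition or removal until no move strictly improves
\(f\); groups below `min_size = 3` or density 0.3 are discarded; groups
with overlap score \(\omega(A,B) = |A\cap B|^2/(|A||B|) \ge 0.8\) are
merged by connected-component union in a single pass (deterministic and
order-independent, unlike iterative re-merging). Defaults: \(p = 2\),
merge threshold 0.8, following the reference implementation conventions
of the cohesiveness algorithm family; the minimum density of 0.3 is the
value used in the rice case studies this package is built around.

A property worth knowing: on the 5-node "bowtie" (two unit triangles
sharing a hub), the unique cohesiveness local optimum is the whole graph
for *every* \(p \ge 0\) — adding the fourth vertex to a triangle raises
\(f\) from \(3/(5+3p)\) to \(4/(6+4p)\), an increase of
\(2/((6+4p)(5+3p)) > 0\). Exhaustive enumeration over all vertex subsets
confirms this, and the unit tests freeze that enumeration result. A
cohesiveness greedy therefore does not split the bowtie into its two
triangles; triangle-level resolution is what the second detector is for.

**Triangle-approximation WCC growth** (`fox_detect`). The weighted
community clustering (WCC) family scores how well each node's triangles
sit inside a community. Counting triangles exactly against every
candidate community is expensive, so — as in the published
approximation algorithms — the per-node triangle count with respect to a
community is approximated from its in-community (weighted) degree
\(k_C\):

\[ \widehat{wcc}(v, C) = \frac{k_C(k_C - 1)}{k(k-1)} \cdot
   \frac{k}{|C| - 1 + (k - k_C)} , \]

zero when \(k < 2\). Communities are seeded from each uncovered node plus
its neighborhood (decreasing degree order), then greedily admit the
boundary node with the largest gain in mean community score while the
gain exceeds `wcc_threshold` (default 0.05, the value used in the rice
analyses); nodes may join several communities. Duplicates are collapsed
and communities under `min_size` dropped. This variant is **normative for
this package**: it preserves the degree-based triangle approximation and
the threshold-gated join of the published algorithms, but it is not a
re-implementation of any reference binary, and its tests check
contract-level properties (disjoint triangles recovered, join gate
monotone, determinism), not binary equivalence.

Both detectors are fully deterministic: every ordering is by
(weighted degree, lexicographic id) and every tie-break is lexicographic.

# Enrichment statistics

**Module enrichment.** For each detected module a 2×2 table counts
implicated × in-module genes. The background is the **union of genes
across detected modules** — not the whole network — and implicated genes
outside that union are dropped (with a message) rather than added, since
adding them would break the table's marginal structure. The one-tailed
Fisher exact p-value \(P(X \ge a)\), \(X \sim\)
Hypergeometric\((N, K, n)\), is summed exactly in log space (`lchoose` +
log-sum-exp); Benjamini–Hochberg adjustment is applied across modules and
a module is enriched at adjusted \(p < 0.05\). The BH step itself
delegates to `stats::p.adjust(method = "BH")` after validation; the test
suite checks it against the explicit step-up formula on every permutation
of short lists.

**Overrepresentation analysis.** Ontology and pathway terms arrive as
GMT-style gene sets. Term gene sets are restricted to the declared
background (for a module: the annotated genes present in the network —
CLI-overridable), terms sharing no gene with the query are excluded from
testing, and BH runs **within each namespace separately** (gene ontology,
trait ontology, plant ontology, pathways are separate test families, so a
dense pathway collection cannot eat the ontology FDR budget).

The discrete Fisher test is conservative; no mid-p variant is offered in
this version.

# Binding-site overlap: a shuffle null

Whether the input loci are enriched for a TF's predicted binding sites is
decided against a **within-chromosome shuffle null**: each locus is
repositioned uniformly at random on its own chromosome, length preserved,
and the site-centric statistic — the number of binding-site intervals
touching any locus — is recomputed per shuffle. With
\(g = \#\{\text{shuffles} \ge \text{observed}\}\) over \(B\) shuffles,
the add-one estimate \(p = (1+g)/(1+B)\) is valid and never below
\(1/(B+1)\). TFs with zero observed overlap are excluded from testing
(there is nothing to explain), and BH runs across the tested TFs. The
default is \(B = 1000\) shuffles and a mandatory seed; the whole
procedure is deterministic given (inputs, \(B\), seed).

The statistic is site-centric (sites hit by any locus) rather than
locus-centric or base-pair overlap; this matches the binding-site
framing of the question and is the package's normative choice. The
shuffle null preserves locus lengths and chromosome assignment but not
local genomic covariates (GC, gene density); with the small fixture
genomes this is immaterial, but on real genomes a covariate-matched null
would be stricter.

# Text-mining annotations

The NER pipeline that produces gene/species/chemical/phenotype mentions
from abstracts is upstream and out of scope; this package consumes its
tabular output. Queries are case-insensitive substring matches against
the mention surfaces of the requested entity types, and gene–query
association is **same-abstract co-occurrence** — deliberately simple,
predictable and testable (no stemming, no fuzzy matching, no
sentence-level windows). The retrieved genes can be fed back into the
module and binding-site analyses.

# The summary table

One row per candidate gene: the number of pathways containing it, the
number of distinct ontology terms or pathways enriched in *any* module
containing it (deduplicated by term id — a term shared by two of a gene's
modules counts once, so multi-membership cannot inflate priority), the
number of articles mentioning it, its module ids, and whether its
ortholog lies inside the lifted target region. Sorting is stable
lexicographic over any sequence of (column, direction) keys, radix-based
so the order does not depend on the session locale.

# The synthetic-data generator

`simulate_bundle()` writes a complete, internally consistent input bundle
and a JSON manifest holding the planted ground truth, so that end-to-end
tests are self-checking without hard-coded values. The default spec is
the package's reference study condition:

* **Genomes**: 2 chromosomes × 1 Mb per genome, 100 genes per genome
  (gene lengths 2–4 kb, gaps 4–8 kb, drawn uniformly — format validity
  and planted signal are the goals, not biological realism).
* **Loci**: two intervals covering 10 implicated genes (6 on Chr1, 4 on
  Chr2).
* **Alignment**: identity segments plus one block (containing a locus
  gene) rearranged onto another target chromosome on the minus strand,
  and one block deleted — so one locus projects onto two chromosomes and
  every ortholog-partition category is populated: with the defaults the
  constructed truth is 8 common pairs, 1 ortholog-elsewhere gene, 1
  no-ortholog gene, 2 unique-to-source genes.
* **Network**: one planted 12-gene module containing the 6 Chr1
  implicated genes (within-module edge probability 0.9, weight 1.0) plus
  six 8-gene background communities (same within-probability, unit
  weights) over Erdős–Rényi noise at edge probability 0.05 with weight
  0.5. Two of these numbers deserve justification. *Background
  communities exist* because coexpression networks are modular and the
  module-enrichment background is the union of detected modules; over
  pure ER noise the cohesiveness detector correctly finds nothing (greedy
  growth either sprawls below the density filter or, at unit noise
  weights, absorbs the whole graph), which would leave the background
  degenerate. *Noise edges carry weight 0.5* because the cohesiveness
  gain of absorbing a noise node with \(k\) cross-edges into the planted
  module is positive at unit weight and negative at weight 0.5 under the
  default penalty \(p = 2\); strong module edges over weaker chance
  correlations is also the realistic shape of a coexpression network.
* **Annotations**: a GO-style term equal to the planted module and a
  pathway containing half of it, among random terms.
* **Binding sites**: five TFs with ~30 sites each; one TF's sites are
  concentrated in the loci at ≥ 5× its genome-wide density.
* **Text**: ~30 abstracts; a planted phenotype surface
  ("preharvest sprouting") co-occurs with mentions of three implicated
  genes.

Everything is a deterministic function of the spec and its seed,
including file bytes.

What passing tests on these fixtures shows — and what it does not: the
machinery is correct (conversions, partitions, statistics, determinism)
and recovers planted signal of realistic shape at small scale. It says
nothing about performance or statistical behaviour on million-edge
networks, real alignment complexity (gapped blocks must be decomposed
upstream), or annotation databases with thousands of terms.

# Numerical and design notes

* Fisher tails are summed in log space; the worst deviation from direct
  brute-force enumeration is checked below 1e−12 on random tables.
* All orderings use radix sorting, making results independent of the
  session locale.
* Degenerate inputs: empty interval lists, edgeless networks, empty
  implicated sets and queries matching nothing all return empty (or
  all-null) results rather than errors; genuinely contradictory input
  (inverted intervals, overlapping alignment segments, a gene in two
  ortholog groups of one genome, p-values outside [0, 1]) errors
  immediately with the offender named.
* Problem sizes in the test suite (100-gene genomes, 20 generator seeds
  for the recovery study, 1,000 calibration replicates at 200 shuffles,
  2,000-site null tracks) were chosen so the planted-signal and
  calibration studies are statistically meaningful at desk scale; the
  calibration fixture's expected overlap count (~240) keeps the discrete
  permutation p close to uniform, which is what the calibration is
  supposed to measure.
* The `n` reported alongside every acceptance quantity is the problem
  size the quantity was computed at (background size, replicate count,
  permutation count), so scale is always visible next to the number.

# Known limitations

* Gapped alignment blocks are not ingested directly; they must be
  decomposed into ungapped segments upstream.
* The shuffle null does not condition on genomic covariates.
* The WCC variant is normative, not a reference re-implementation; its
  absolute module boundaries on dense graphs will differ from other WCC
  implementations, though the contract-level properties hold.
* Only two of the overlapping-community detectors are provided; the
  detector interface takes any function from network and parameters to a
  module table, so others can be plugged in.
* Remote annotation sources (protein databases, pathway servers, PubMed)
  are out of scope; all inputs are local files.
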