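---
title: "Domain-arrangement similarity and orthology search-space reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-arrangement similarity and orthology search-space reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domarch)
```

## The problem

Orthology detection by all-against-all sequence comparison scales
quadratically with the number of proteins, which is what makes multi-proteome
runs expensive. Most proteins, however, are composed of conserved domains,
and the ordered combination of domains along a protein — its *domain
arrangement* (DA) — is a strong, cheap signal of family membership: members
of a family share a DA up to substitution of a domain by an evolutionarily
related one, insertion or loss of a domain, and tandem repeat expansion.

`domarch` exploits this: it measures DA similarity in a *continuous* domain
space (a domain-domain similarity matrix derived from profile-profile
comparison, rather than the binary same/different treatment), clusters the
unique DAs of a dataset into *search sub-spaces*, and runs an orthology
engine independently inside each sub-space. Binary DA comparison would place
`PBC;Homeobox` and `PBC;Homeobox_KN` in different groups even though the two
homeobox domains are close relatives; a continuous similarity keeps them
together.

## The similarity measures

All measures operate on a sparse symmetric matrix $S(a, b) \in [0, 1]$ over
domain accessions with $S(d, d) = 1$ and 0 for unstored pairs. Real matrices
of this kind are produced by all-against-all profile-HMM comparison, where
the probability of a true-positive match serves as the score (natively on a
0–100 scale, hence the loader's `percent` scale); building such a matrix is
outside this package's scope, but its TSV dialect is read, queried and
written here, and `synth_matrix()` generates block-structured stand-ins.
Because profile comparison is directional, the loader symmetrizes (by the
maximum of the two directions by default — the stronger evidence wins; mean
and min are available). Entries below `store_threshold = 0.01` are not
stored, mirroring the extreme sparsity of real matrices where the vast
majority of scores sit at or below 1 on the percent scale.

**Cosine (COS).** For proteins $X, Y$ with unique-domain sets $D_X, D_Y$,
the universe $U_{XY} = D_X \cup D_Y$ is formed and each protein gets a
vector over $U_{XY}$: component $i$ is 1 when the domain is the protein's
own, otherwise $\max_{d \in D_X} S(u_i, d)$ — the similarity to the most
similar own domain. The score is the cosine of the two vectors. Two proteins
with no domains in common (and no cross-similarity) score 0; identical
domain content scores 1 regardless of domain order.

**Maximal-weight matching (MWM).** The two unique-item sets form the sides
of a bipartite graph, edges weighted by $S$; a maximum-weight matching is
computed (each item used at most once; the solver is
`igraph::max_bipartite_match`, verified in the test suite against exhaustive
enumeration of all matchings) and the matched weight is normalized by the
size of the *larger* item set. Normalizing by the larger set penalizes
unmatched domains of the longer protein; vertices are unique items because a
repeated domain adds no new vertex.

**Order 2.** Replacing single domains by ordered pairs of consecutive
domains (`A>B` ≠ `B>A`) injects domain order, which carries phylogenetic
signal. Pair similarity is the mean of the position-wise domain
similarities: $S_p(AB, DB) = \tfrac12 (S(A,D) + S(B,B))$. A single-domain
protein has no pairs, so any comparison involving one falls back to order 1
for that pair of proteins — the order-2 construction is undefined there and
the fallback keeps the measure total.

**Weighting.** Order-2 components are means, which inflates mediocre
matches: a pair sharing one domain of two scores 0.5 even when the other
positions are unrelated. The weighting scheme counteracts this by raising
every component strictly below 1 to a configurable exponent (default 2)
before aggregation — exact matches are fixed points, mediocre components are
damped, monotonicity is preserved, and the weighted score never exceeds the
unweighted one. The exponent-2 default is this package's own concrete
choice for that damping behaviour; the exponent is exposed in
`measure_config()`.

Eight configurations result (COS/MWM × O1/O2 × weighted or not), all
symmetric with self-similarity 1 under every configuration.

**Repeat collapsing.** Tandem repeat expansion is a common DA perturbation;
`collapse_tandem_repeats()` replaces each maximal run of a domain by one
copy (`A B B C B C` → `A B C B C`), preserving non-adjacent repeats, and is
idempotent. It is a per-measure option (`collapse_repeats`) because repeats
are biologically meaningful in some families and noise in others.

## The pipeline

1. Parse domain annotations (pfam_scan dialect or a plain 4-column TSV) into
   per-protein DAs, ordered by envelope start (ties: envelope end, then
   accession — the annotation tool reports envelope coordinates, and start
   order is the natural linearization; overlapping hits are kept as-is).
   Version suffixes are stripped so the matrix is keyed by unversioned
   accessions. Proteins without any hit cannot enter DA space; they are
   reported (`no_hit_proteins()`) rather than silently dropped.
2. Deduplicate to unique DAs and compute their pairwise similarity table
   under one configuration (each unordered pair once).
3. Cluster unique DAs by k-medoids on $d = 1 - s$. Defaults: $k = 100$, or
   `auto` for $\max(1, \mathrm{round}(n/20))$ — one twentieth of the number
   of unique DAs. Initialization is seeded random distinct medoids with 5
   restarts and a greedy best-improvement swap phase; this is implemented
   in-package because reproducibility requires an explicitly seeded
   initialization, and it is cross-checked against `cluster::pam` in the
   tests. Nearest-medoid ties break toward the lowest cluster id, and a
   medoid always anchors its own cluster.
4. Optionally apply a similarity cut-off (typical values 0.5, 0.7): any DA
   whose similarity to its cluster medoid falls strictly below the cut-off
   is spilled into a fresh singleton cluster. Spilling after clustering (as
   opposed to pre-filtering the similarity table) preserves the requested
   cluster count for the well-formed part of the data while guaranteeing no
   protein is forced into a sub-space whose representative it barely
   resembles.
5. Partition proteins by their DA's cluster (a true partition: disjoint,
   covering all annotated proteins) and run the orthology backend inside
   each sub-space. The backend is pluggable — any function from a record
   table to a group table. The built-in `rbh_backend()` is a deliberately
   simple engine for offline use: shared distinct 4-mer counts normalized by
   the shorter sequence, reciprocal best hits between species pairs as
   edges, connected components of size ≥ 2 as groups. It makes no claim to
   reproduce any production engine's semantics; an external engine is
   attached by passing a wrapper function as `backend`.
6. Merge per-sub-space groups into one table (proteinortho-style TSV:
   species count, gene count, connectivity, one column per proteome, `*`
   for absent species). Groups must be disjoint across sub-spaces — an
   overlap indicates a broken partition and aborts. With $k = 1$ the merged
   output is identical to a direct backend run on the whole input, which the
   tests assert end to end.

Intermediate sub-space files can be persisted (`workdir`) and the
backend+merge stages rerun from them (`run_pipeline_from_subspaces()`).

## Evaluation machinery

**Five-category comparison.** A predicted group (PGOP) is compared to
reference groups (RGOPs) as *identical*, *superset* (some RGOP strictly
contained), *subset* (strictly contained in some RGOP), *absent* (no member
referenced at all) or *new* (parts of several RGOPs). The categories are
resolved in that precedence order: identity must precede the strict
containments, and a group that is a superset of one RGOP while overlapping
another counts as superset rather than new — the containment relation is
the more informative statement. This precedence is this package's own
resolution of cases the category definitions leave open (they are stated as
non-overlapping without an explicit order). `category_report()` tallies
counts and percentages.

**ROC/AUC benchmarking.** `benchmark_measures()` scores all unordered
protein pairs per configuration (computed once per unique DA pair and
broadcast), labels pairs by shared family, and computes the AUC by the rank
(Mann–Whitney) method with average ranks for ties; the curve is swept over
the distinct scores. All cross-family pairs are used — no subsampling — so
results are deterministic given the data.

## The synthetic generator

`synth_spec()` defines the world: domains dealt round-robin into blocks;
within-block similarity drawn uniformly ±0.05 around `within_block_sim`,
between-block similarity likewise around `between_block_sim`, except that a
between-block value of exactly 0 means disjoint blocks (no jitter — the
generator's separability dial should reach true zero). Families take blocks
round-robin (block-separated whenever families ≤ blocks), draw a founder DA
of length 1–5 from their block, and mutate each member once per mechanism:
similar-domain substitution (within block, probability 0.3 by default),
single-domain insertion/deletion (0.1), tandem duplication (0.1). Members
spread round-robin over species. `synth_sequences()` gives every accession
a fixed random 30-residue segment and concatenates segments with 5-residue
random linkers — long enough to perturb naive identity, short enough that
shared domain segments dominate the toy backend's k-mer scores.

Default sizes: the pipeline-scale spec is 100 families of 6–10 members over
4 species (~200 proteins per species, ~800 total) on 125 domains in 25
blocks; `synth_benchmark_spec()` is a measure-benchmark-sized 12 families
(4–6 members) over 12 disjoint blocks. These are the problem sizes the test
suite and the reproduction script run at.

What the generator does *not* emulate: realistic amino-acid substitution,
domain-length variation, discontinuous/nested domains, annotation noise
(false or missed hits), clan structure in the similarity matrix, and
lineage-specific family expansion beyond simple multi-copy membership. A
green test suite therefore shows the machinery is correct under the stated
model, not that accuracy figures transfer to real proteomes.

## Numerical and degenerate-input choices

- Cosine values are clipped to $[0, 1]$ against floating-point rounding; a
  zero-norm vector (impossible for nonempty own sets, which contribute 1s)
  is an error rather than a silent 0.
- Matching ties: any maximum-weight matching may be returned; only the score
  is contractual. Zero-weight edges are omitted from the graph — they cannot
  contribute to the optimum.
- k-medoids: restarts are seeded `seed + restart - 1`; the best restart by
  total within-cluster distance wins, earliest on ties. The swap phase costs
  candidates in $O(n)$ via per-row nearest/second-nearest medoid distances.
- Duplicate protein ids across species are disambiguated as
  `species|protein`; duplicates within a species are an error.
- An empty annotation stream parses to an empty table; a length-1 DA has no
  order-2 representation (callers fall back to order 1); groups of size 1
  are never emitted in orthology tables.

## Known limitations

- The pairwise DA similarity table is dense ($n^2$ in the number of unique
  DAs), which bounds practical dataset sizes; the one-twentieth heuristic
  for $k$ is a rule of thumb, not a model-selection procedure.
- The built-in backend is a toy; biological conclusions require plugging in
  a production orthology engine.
- The weighting scheme's exponent-2 default is a design choice documented
  above, not a fitted constant.
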