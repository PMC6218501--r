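# coldregulon

Comparative reconstruction of cold-stress transcriptional regulons across
two related rice genotypes — a cold-tolerant wild relative and a cultivated
reference. Wild *Oryza* species such as *O. officinalis* can carry regulatory
architecture that domestication has eroded in *O. sativa*: both species may
reach similar cold tolerance, yet one runs an intact hub-coupled regulon
(e.g. a BES1-anchored brassinosteroid network) while the other covers the
same physiology with a fragmented set of modules uncoupled from that hub.
`coldregulon` implements the full desk-scale analysis that exposes such a
contrast, for researchers comparing replicated expression time courses
between two genotypes with a known ortholog relationship.

## What the package computes

Starting from gene-level count matrices (two genotypes × timepoints ×
replicates), promoter sequences and a transcript alignment hit table:

1. **Ortholog pairing** (`build_ortholog_map`) — for each query locus the
   longest alignment wins; when several queries claim one target, the most
   stable mapping (identity × query coverage) is kept, yielding a one-to-one
   map.
2. **Differential expression** (`de_table`) — counts are normalized with
   median-of-ratios size factors; per-gene NB dispersion α is estimated by
   method of moments (variance = μ(1 + αμ)) and shrunk 50/50 to the
   genome-wide median; each stress timepoint *t* is tested against 0 h with
   a negative-binomial likelihood-ratio test (shared mean vs separate
   means, χ², 1 df). A gene is `up` if any timepoint has log₂FC > 2 with
   p < 0.01, `down` for the mirrored rule (ties go to the largest |log₂FC|).
3. **Cross-species concordance** (`ortholog_concordance`) — the 3×3
   contingency of response classes over ortholog pairs, with directional
   percentages such as "fraction of genotype-A upregulated genes whose
   ortholog is also upregulated in B".
4. **Temporal clustering** (`nb_kmeans`) — NB model-based K-means (default
   K = 8) on size-factor-adjusted profiles, driven by profile shape rather
   than expression level.
5. **Cis-element analysis** (`extract_promoters`, `scan_motifs`,
   `positional_enrichment`, `density_classes`) — strand-aware TSS-relative
   promoter windows (default −3000..+2000), IUPAC motif scanning on both
   strands, one-sided hypergeometric positional enrichment among
   upregulated genes (windows around −500 and −150..+50), and BRRE copy
   density over −1200..+500 classed as low (< 8), high (8–10) or very high
   (≥ 11).
6. **Regulon networks** (`coexpression_edges`, `assemble_regulon`,
   `core_regulon`, `fragmentation`) — Pearson co-expression (r ≥ 0.8) over
   4-point log₂FC profiles of BRRE-dense upregulated genes, BFS tiers from
   the designated hub (primary/secondary/tertiary), the core regulon
   (hub + tight direct neighbors), and fragmentation metrics (connected
   components, hub-coupled fraction) compared between genotypes.

A synthetic-data module (`synth_config`, `generate_dataset`) plants known
DE sets, cluster shapes, motif placements and an intact-vs-fragmented
regulon pair, so the entire pipeline is testable end to end without any
external data. `compute_eli` and `ses_score` cover the accompanying
phenotype metrics (electrolyte leakage index; 0–10 recovery score).

## Worked example

```r
library(coldregulon)

cfg <- pipeline_config(
  synth = synth_config(n_genes = 300, n_tf = 60, regulon_size = 24,
                       de_fraction = 0.3, fragment_into = 3,
                       promoter_window = c(-1500, 600), seed = 11),
  K = 8, seed = 7)
summary <- run_pipeline(cfg, "demo_out")
```

The summary for this run reports, among other keys:

```
de_class_counts$A        up 58, down 32, unchanged 210
concordance              up A->B 65.5%, up B->A 65.5% (285 pairs)
density_class_counts     low 276, high 24, very_high 0
n_network_genes          24
core_regulon_size        A 20, B 6
fragmentation$A          1 component,  hub_coupled_fraction 1.00 (intact)
fragmentation$B          3 components, hub_coupled_fraction 0.33 (fragmented)
```

Reading it: of 300 genes, 90 were planted as cold-responsive and the DE
stage recovers them (58 up / 32 down). The 24 planted regulon members are
the only promoters with a high BRRE density, so they form the genotype-A
network; its hub reaches every node (one component, 20-gene core regulon).
The orthologous genotype-B node set splits into 3 components with only a
third of the nodes still coupled to the hub — the intact-vs-fragmented
contrast the pipeline is built to detect. `demo_out/` additionally holds
the per-stage TSV tables, GraphML networks, a log and `summary.json`.

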