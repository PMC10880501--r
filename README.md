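# pathtriage

Computational triage of candidate pathway regulators from tumor-versus-normal
single-cell RNA-seq, for computational biologists who want the whole chain —
QC, differential expression, enrichment, co-expression modules, interactome
scoring, clinical validation — as one reproducible, testable R pipeline.

The use case it models: given (a) a gene×cell count matrix of annotated
tumor/normal/border epithelial cells, (b) gene-set collections (GMT), (c) a
binary protein–protein interaction (PPI) edge list, and (d) a per-patient
clinical table, nominate the gene most directly wired into a
tumor-activated signalling pathway (the motivating analysis nominated MDFI
as a PI3K-AKT regulator in colorectal cancer) and validate its clinical
associations. Because the original cohorts are large external downloads,
the package ships a synthetic-data module that generates every input with
planted ground truth, so each stage — and the end-to-end triage — is
verifiable against known answers.

## The statistics under the hood

* **QC / normalization** — per-cell `nCount`, `nFeature`, `percent.mt`
  (strict `< 20%` mitochondrial filter); log-normalization
  `x = ln(1 + c·10⁴/nCount)`; per-gene scaling clipped at ±10, PCA on cells.
* **Differential expression** — two-sided Wilcoxon rank-sum per gene
  (tie-corrected normal approximation; exact distribution for tiny tie-free
  groups), detection fractions `pct.tumor` / `pct.normal`, natural-log
  `avg_logFC` with pseudocount 1, screens `max(pct) > 0.25` and
  `|avg_logFC| > 0.25`, Bonferroni adjustment over tested genes.
* **Enrichment** — hypergeometric over-representation, and weighted
  Kolmogorov–Smirnov GSEA (running sum with increments `|s|^p` over in-set
  genes, decrements `1/(N − n_set)`), gene-label permutation null, NES and
  add-one empirical p, BH q.
* **Co-expression network** — top-variance genes; Pearson correlation `S`;
  soft-threshold adjacency `A_mn = |S_mn|^β` with β chosen as the smallest
  power whose signed scale-free fit R² ≥ 0.85; unsigned topological overlap
  `TOM_mn = (Σ_u A_mu A_un + A_mn) / (min(k_m, k_n) + 1 − A_mn)`;
  average-linkage clustering of `1 − TOM` with a static cut; module
  eigengenes and module–pathway/trait correlation.
* **PPI level score** — breadth-first shortest paths from each candidate to
  the pathway gene set; level 1 = direct partner, level 2 = one
  intermediate, level 3 = two intermediates (each target counted once at
  its shortest level); candidates ranked by the level-count sum.
* **Clinical validation** — Kaplan–Meier at the marker median split with
  the two-group log-rank test; uncorrected Pearson chi-square on 2×2
  tables, `N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))`; Pearson correlation with
  t-test p; Welch tests across stages; ROC/AUC via the Mann–Whitney
  concordance.

## Worked example

```r
library(pathtriage)

rep <- run_triage(sim_config())   # simulate all inputs, run the full triage
rep
#> <triage_report>
#>   cells kept: 1200; DE genes tested: 52 (50 at adj p < 0.05)
#>   top enriched set: PATHWAY_AKT (NES 1.84, q = 0.021)
#>   soft threshold beta = 3; best module: M1 (110 genes)
#>   top-ranked candidate: MDFI (levels 5/5/3, total 13)
#>   clinical: OS log-rank p = 4.41e-16; chi^2 = 6.933 (p = 0.00846); AUC = 0.695

head(tidy(rep), 3)                # the PPI level-count ranking
#> # A tibble: 3 × 6
#>   gene   level1 level2 level3 total  rank
#> 1 MDFI        5      5      3    13     1
#> 2 MOD075      2      5      6    13     2
#> 3 LAMB3       3      5      4    12     3
```

Reading the output: all 1,200 simulated cells pass the mitochondrial QC; 50
of the 52 genes passing the DE screens are significant after Bonferroni
(the generator planted 50); the planted `PATHWAY_AKT` set is the top GSEA
call (positive NES, q = 0.021); the soft-threshold scan settles at β = 3
with scale-free fit R² ≥ 0.85, and module M1 (the planted 100-gene module
plus the pathway genes that share its latent factor) is selected as most
pathway-correlated; ranking M1's genes by their level-1/2/3 counts to the
pathway puts the planted regulator MDFI at rank 1 with 5 direct partners.
The clinical table reproduces its configured effects: above-median marker
expression carries a hazard ratio of 2.5 (log-rank p ≈ 4×10⁻¹⁶), the 2×2
histology table gives the uncorrected Pearson chi-square 6.933 (p = 0.008),
and the marker separates chemo-resistant patients with AUC 0.70.

Every stage is callable on its own (`compute_qc()`, `wilcoxon_de()`,
`gsea()`, `coexpr_network()`, `rank_candidates()`, `km_logrank()`, ...),
takes/returns tibbles, and has `plot_*()` companions; `tidy()`/`glance()`
methods cover the report, network and survival objects. Readers and writers
for MTX/TSV counts, GMT, edge lists and clinical CSV are in `read_*` /
`write_*`.

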