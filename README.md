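# obulink

Linking biosynthetic domain diversity to taxonomy in amplicon surveys of
microbial communities.

## What this package is for

Degenerate-primer amplicon surveys of the ketosynthase (KS) domain of
polyketide synthases and the adenylation (AD) domain of nonribosomal
peptide synthetases capture a community's secondary-metabolite potential
without cultivation. Clustered at 95% identity, those amplicons form
**operational biosynthetic units (OBUs)** — the functional analogue of an
OTU. Most OBUs have no database match, so `obulink` attributes them to
taxa statistically instead: a biosynthetic gene cluster sits on the same
chromosome as the 16S rRNA gene, so an OBU's counts should co-occur
linearly with its producer's 16S counts across samples. For OBU *i* and
species *j* the package screens every pair with the no-intercept model

```
OBU_i = alpha_ij * species_j
```

(closed forms: `alpha_hat = sum(xy)/sum(x^2)`, t test on the slope,
p < 0.001 retained), after removing sparse features ("in only one sample
and with a total read size of < 10") and perfectly collinear species
(pairwise r² = 1). Retained links are aggregated per genus and compared
with taxonomic abundance — the headline question being whether rare taxa
can carry rich biosynthetic repertoires.

The package implements the full pipeline for users who analyse such
surveys, plus a synthetic community generator with planted ground truth so
every stage can be validated end to end:

* `run_obu_pipeline()` — trim (240/175 bp), join with a single-N spacer,
  greedy 97% within-sample clustering, pooled 95% clustering, singleton
  removal → OBU table (alignment kernel in C++).
* `chao1()`, `rarefaction_curve()`, `normalize_counts()`, `bray_curtis()`,
  `pcoa()`, `biplot_loadings()`, `permanova()`, `anova_tukey()` —
  formula-level diversity statistics.
* `clean_matrices()`, `dedup_collinear_species()`, `fit_link()`,
  `screen_links()`, `summarize_by_genus()`, `abundance_vs_potential()` —
  the function-to-taxon screen.
* `obu_recovery()`, `obu_recovery_by()`, `culturability()` —
  cultured-fraction (eDNA vs pDNA) accounting.
* `generator_config()`, `generate_community()`, `generate_obu_counts()`,
  `generate_domain_reads()` — the synthetic world; `demo_synthetic()` and
  `run_all()` — end-to-end orchestration.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated two-niche, three-replicate survey with planted low-abundance
producers (`Rscript analysis/01_simulate.R` … `05_recover.R`). The
linking step prints, per niche:

```
seawater: 96 links from 1770 tests; planted OBUs detected 20/20
  genus OBU counts: median 2, range 0-14; abundance-vs-OBU r2 = 0.0298
sediment: 46 links from 1800 tests; planted OBUs detected 20/20
  genus OBU counts: median 2, range 0-10; abundance-vs-OBU r2 = 0.1111
```

Reading: all 20 planted OBUs per niche are recovered by the p < 0.001
screen; per genus the number of linked OBUs is highly right-skewed (median
2, a few genera with many); and the regression of genus abundance on
linked-OBU count has r² near zero — taxonomic abundance does not predict
biosynthetic potential, because the producers were planted below 0.1%
relative abundance. The recovery step then plants 15% of OBUs on
simulated plates and reports:

```
  domain   source n_obus_edna n_obus_pdna n_shared pct_recovered
1 OBU_KS seawater          30           4        4      13.33333
2 OBU_KS sediment          30           4        4      13.33333
```

A single call runs everything on a fresh synthetic world:

```r
library(obulink)
res <- demo_synthetic(seed = 1, out_dir = "demo_out")
res$report
#      niche n_planted n_recovered producer_genera_in_top
# 1 seawater        16          16              0.7142857
# 2 sediment        16          16              1.0000000
```

`demo_out/` then contains the OBU table and centroid FASTA from read-level
clustering, richness/ordination/PERMANOVA tables, the link and genus
summaries, the recovery report, and a JSON provenance manifest; reruns
with the same seed are byte-identical.

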