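# iprdesign

Rational selection of payload insertion sites in phage genomes.

Engineered bacteriophages carrying reporter or effector payloads need the
payload placed where the phage's own transcriptional program will express it
— without disrupting any native gene. `iprdesign` implements a
promoter-guided design pipeline for annotated phage genomes:

1. **Intergenic search space.** Gene bodies are taken from a GenBank record;
   split loci (genes annotated in multiple parts with other genes nested
   between the parts, as with intron-encoded homing endonucleases) are
   merged into contiguous spans so no spurious "intergenic" gap opens inside
   them. The maximal gaps between gene bodies are extracted and extended
   50 bp into each flanking gene, because promoters frequently overlap
   coding-sequence ends.
2. **Promoter scoring.** Promoter predictions — a table from an external
   machine-learning predictor, or hits from the package's built-in σ70
   consensus PWM scanner (`TTGACA` … 15–21 bp spacer … `TATAAT`) — carry
   probability-like scores *s* ∈ [0, 1]. Predictions below the 0.5 run
   threshold are discarded.
3. **Intergenic Promoter Regions (IPRs).** Within each extended intergenic
   region, predictions are grouped by strand into IPRs and scored
   cumulatively with an exponential weighting that favors strong promoters:

   *IPR score* = Σᵢ exp(sᵢ)

   A single promoter with *s* = 0.921 therefore gives an IPR score of
   exp(0.921) = 2.51.
4. **Insertion-site selection.** IPRs are ranked by score; for each IPR the
   first downstream gene in the same orientation is found, and the insertion
   point is placed immediately after that gene's stop. With a gene
   temporal-class table (early/middle/late expression), the top site per
   class is returned.
5. **Donor design.** For each site a homologous-recombination donor is
   built: 200–400 bp homology arms flanking the insertion point, an RBS
   (`GAGGAGGTAAATATAT`) + payload cassette oriented to the gene's strand,
   and — when the gap to the next gene is under 20 bp — a duplication of the
   last `20 − d` bases of the preceding gene after the cassette, so the
   downstream gene's ribosome-binding context is preserved. The edit is
   applied in silico and verified: every native CDS must survive verbatim.

A seeded synthetic-genome generator (`simulate_genome()`) plants consensus
promoter clusters with controlled density and score into toy genomes, so the
whole pipeline is testable without network access or the external predictor.

## Worked example

```r
library(iprdesign)

sim <- simulate_genome(demo_sim_config(seed = 42))   # 20 kb, 12 genes,
sim                                                  # 3 planted clusters
#> <ipr_simulation> seed 42: 20000 bp, 12 genes, 12 planted promoter(s)

res <- run_pipeline(sim$genome, sim$predictions,
                    payload = nluc_seq,              # any CDS string/FASTA
                    classes = sim$classes,
                    outdir = "demo_out", payload_name = "nluc")
res$iprs
#> <ipr_set> 3 IPR(s)
#>  rank      ipr_id region_id strand span_start span_end n_members ipr_score
#>     1 ipr_002_fwd   igr_002      +       1419     1588         5 12.560589
#>     2 ipr_007_fwd   igr_007      +       6498     6736         4  9.476694
#>     3 ipr_012_fwd   igr_012      +      11532    11561         1  1.970088
res$sites
#>   site_id position strand driving_ipr selected_gene_id temporal_class
#> 1 site_01     2508      + ipr_002_fwd          gene_02          early
#> 2 site_02     7384      + ipr_007_fwd          gene_07         middle
#> 3 site_03    12873      + ipr_012_fwd          gene_12           late
res$donors[[1]]
#> <donor_construct> site_01 (+ strand) at position 2508
#>   left arm : 400 bp [2108,2508)
#>   insert   : 316 bp cassette 'nluc'
#>   right arm: 400 bp [2508,2908)
```

The three planted clusters (5 promoters at mean score 0.95, 4 at 0.8, 3 at
0.6) come out ranked by their cumulative weighted scores — the third
cluster's weaker promoters mostly fall below the 0.5 threshold, leaving one
member — and each drives one insertion site in its temporal class:
immediately after `gene_02` (early), `gene_07` (middle) and `gene_12`
(late). `run_pipeline()` also writes `intergenic.bed`, `iprs.gff3`,
`ipr_ranking.tsv`, `insertion_sites.tsv`, `donors.fasta`, one
`recombinant_<site>.gb` per site, two diagnostic plots and a `run.log`
echoing the full configuration.

The same stages are available from a shell:

```sh
Rscript inst/cli/iprdesign.R simulate --out fixtures --seed 42
Rscript inst/cli/iprdesign.R run --genome fixtures/genome.gb \
    --predictions fixtures/predictions.tsv --payload payload.fasta \
    --classes fixtures/classes.tsv --out demo_out
```

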