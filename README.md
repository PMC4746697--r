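# natphase

Discovery of natural antisense transcripts (NATs) and phase-distributed
nat-siRNAs from **de novo assembled transcriptomes** — no reference genome
required.

NATs are pairs of endogenous transcripts with long complementary regions that
anneal in vivo; their double-stranded regions are processed by Dicer-like
proteins into phased siRNA duplexes with 2-nt 3′ overhangs, like trans-acting
siRNA precursors. `natphase` is for small-RNA and transcriptome researchers
working on non-model organisms: it takes assembled transcripts (FASTA),
collapsed small-RNA libraries (`>{id}_x{count}` FASTA) and optional degradome
libraries, and produces a validated NAT list plus phased nat-siRNA clusters
with degradome processing evidence.

## Method at a glance

1. **Antisense search** — every transcript pair (A, B) is scanned for local
   alignments of A against revcomp(B) (seed-and-extend, affine-gap
   Smith–Waterman; +1/−2, gaps −5/−2, score ≥ 60). Regions are classified
   **HC** (complementary span > 50% of a transcript) and/or **100-nt**
   (consecutive complementary region ≥ 100 nt).
2. **Duplex validation** — each region is re-aligned as an inter-molecular
   duplex maximizing `pairs − λ·unpaired` (Watson–Crick + G·U; a mismatch is
   a 1+1 bubble). Retained only if the structure-predicted region overlaps
   the alignment-predicted region at ≥ 80% on both transcripts and no bubble
   exceeds 10% of the region. A single perfectly annealed region ⇒ *cis*-NAT
   candidate.
3. **Phasing** — inside perfectly annealed segments > 80 bp, perfectly
   mapped sense-strand sRNAs are binned into phase slots of length *n*
   (21/24 nt); the antisense partner of sense slot `[i, i+n−1]` occupies
   `[i−2, i+n−3]` (2-nt 3′ overhangs). A slot is evidenced by a 5′-end match
   on either strand; ≥ 4 consecutive evidenced slots form a phased cluster.
4. **Degradome evidence** — perfectly mapped degradome tags whose 5′ ends hit
   a phased siRNA 5′ end, or the nucleotide next to the 3′ end of the last
   phased siRNA of a strand, mark siRNAs/clusters as degradome-supported.

See `vignettes/nat-phasirna-discovery.Rmd` for the full model, parameter
semantics and design rationale.

## Worked example

All inputs below are generated by the package's deterministic fixture module,
so this runs anywhere:

```r
library(natphase)
fx  <- make_fixture(fixture_spec(seed = 3))   # 1 planted NAT + 5 decoys,
                                              # 8 phased 21-nt sRNAs, degradome
run <- run_pipeline(run_config(transcripts = fx$transcripts,
                               srna = fx$srna, degradome = fx$degradome,
                               quiet = TRUE))
run
#> natphase run
#>   n_transcripts            7
#>   n_complementary_pairs    1
#>   n_complementary_regions  1
#>   n_class_hc               1
#>   n_class_nt100            1
#>   n_retained_nats          1
#>   n_cis_candidates         1
#>   n_regions_searched       1
#>   n_clusters               1
#>   n_phased_sirnas          8
#>   n_supported_sirnas       1
#>   n_supported_clusters     1
```

The planted pair is recovered as a cis-NAT candidate (one perfect 120-bp
annealed region, natA 61–180 ↔ natB 41–160), carrying one 21-nt cluster of 4
phases / 8 sRNAs at register 2, with degradome tags confirming slot 1's 5′
end (position 63) and the cluster terminus (position 147 = last siRNA 3′ end
+ 1). The human-readable rendering (`render_report_text(run)`):

```
NAT pair natA | natB [both] (cis-NAT candidate)
  (1) annealed region: natA from 61th to 180th nucleotide; natB from 41th to 160th nucleotide (1 perfect segment(s), 0 bubble(s))
  (2) cluster natA|natB|61-180|n21|r2|p63: 8 nat-siRNAs assigned to 4 consecutive phases (21-nt register 2); libraries: leaf
  (3) degradome evidence: root_dg01 (root, pos 63, sense strand, slot 1, 500000.0 RPM); root_dg02 (root, pos 147, sense strand, slot terminus, 500000.0 RPM)
```

With `out_dir` set, `run_pipeline()` writes `summary.tsv`, `nat_pairs.tsv`,
`clusters.tsv`, `cluster_expression.tsv` (counts and RPM per sRNA and
library), `degradome_evidence.tsv`, `report.txt` and `config.json`.

## Command line

```sh
Rscript inst/cli/natphase-cli.R make-fixtures --seed 3 --out-dir demo
Rscript inst/cli/natphase-cli.R all \
  --transcripts demo/transcripts.fa \
  --srna leaf=demo/srna_leaf.fa --degradome root=demo/degradome_root.fa \
  --out-dir results_demo
```

Subcommands `predict-nats` (transcripts only), `find-phasirnas` / `all`, and
`make-fixtures`; every stage threshold is a flag.

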