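# haustorstage

Stage-marker discovery and reference-gene validation for staged expression
experiments, built around haustorium development in the parasitic plant
*Cuscuta campestris*.

Dodder haustoria develop through macroscopically distinct stages — non-infective
stem (**niS**), swelling (**SWE**), attaching (**ATT**) and penetrating
(**PEN**) — and can be induced host-free, giving a clean 4-stage × 3-replicate
RNA-seq design. `haustorstage` turns such a transcript × sample count matrix
into:

* **housekeeper (reference) genes** — expressed in all samples, mean
  log2(RPKM) ≥ 5, coefficient of variation and median absolute deviation in
  the lowest 10% of the expressed population, and no significant fold change
  (FDR ≤ 0.05, |log2FC| ≥ 1.5) in any pairwise stage contrast;
* **stage markers** — up-regulated in a stage versus *all* other stages, mean
  in-stage z-score ≥ 1, and gene significance GS ≥ 0.7 with p ≤ 0.05, where
  GS is the Pearson correlation of a transcript's expression with the binary
  stage indicator and p comes from `t = r·sqrt((n−2)/(1−r²))` on n−2 df;
* **a stage classifier** for new samples measured by RT-qPCR: relative
  quantities `RQ = E^(Cqmin−Cq)` normalized to the geometric mean of the
  validated references, z-scored per gene, each sample called as the stage
  whose marker set has the highest mean z-score.

Differential expression uses the exact conditional negative-binomial test with
a common qCML dispersion and TMM scaling factors; reference-gene validation
implements **geNorm** (stepwise-exclusion M values and pairwise variations
V(n/n+1)), **NormFinder** (model-based intra/inter-group stability values) and
**BestKeeper** (correlation with the per-sample index) from their published
models, integrated by the geometric mean of the three competition ranks. A
negative-binomial generator with planted housekeepers and markers provides
ground truth for end-to-end validation. See the methods vignette
(`vignettes/haustorstage-methods.Rmd`) for the models, parameter defaults and
their rationale.

## Worked example

Simulate the 12-sample design with planted truth, run the discovery chain,
validate references and re-stage the samples from simulated qPCR data:

```r
library(haustorstage)

cfg <- simulationConfig(seed = 1)       # 2000 transcripts, 4 stages x 3 reps
sim <- simulateCounts(cfg)
sim$counts
#> StageCounts: 2000 transcripts x 12 samples
#>   stages: ATT(3) niS(3) PEN(3) SWE(3)

fc <- filterExpressed(sim$counts)
de <- allPairwiseContrasts(fc)          # 6 exact-test contrasts, common phi
gs <- geneSignificance(fc)
hk <- selectHousekeepers(fc, de)
mk <- selectMarkers(fc, de, gs, relax_stage = "ATT")
head(hk, 3)
#>    transcript_id mean_log2rpkm     se     CV   MAD
#> 10       Tx00012         10.08 0.0421 0.0145 0.175
#> 1        Tx00001          9.76 0.0637 0.0226 0.167
#> 18       Tx00020         10.08 0.0708 0.0244 0.209
```

The top housekeepers are planted ones (`Tx00001`–`Tx00020`), flat across
stages and highly expressed; `CV` and `MAD` are the variability of their
log2(RPKM) rows. Markers come out with near-perfect stage correlation:

```r
head(mk[order(-mk$GS), c("transcript_id", "stage", "zscore", "GS", "p.GS")], 3)
#>     transcript_id stage zscore    GS     p.GS
#> 94        Tx00029   SWE   1.64 0.991 5.73e-10
#> 361       Tx00039   PEN   1.63 0.983 1.13e-08
#> 307       Tx01357   ATT   1.63 0.983 1.14e-08
```

Reference validation on simulated Cq data ranks five housekeeper candidates
by all three stability algorithms and integrates the ranks:

```r
refs  <- head(hk$transcript_id, 5)
panel <- lapply(split(mk, mk$stage),
                function(d) head(d$transcript_id[order(-d$GS)], 3))
cqt  <- simulateCq(log2p(toRPKM(fc))[unique(c(refs, unlist(panel))), ], cfg)
stab <- rankStability(cqt, groups = as.character(stageOf(fc)),
                      candidates = refs)
stab
#> StabilityRanking over 5 candidates
#>  candidate         M        SV         r rank_genorm rank_normfinder ...   GM
#>    Tx00001 0.2377780 0.2095253 0.4840520           1               2 ... 1.59
#>    Tx00012 0.2377780 0.1898628 0.2471865           1               1 ... 1.59
#>  ...
#> pairwise variation: V2/3=0.103 V3/4=0.084 V4/5=0.085
```

The geNorm final pair shares rank 1 with identical M, V(2/3) ≈ 0.1 (< 0.15)
says two references suffice, and `GM` is the geometric mean of the three
ranks. Staging the samples from the normalized marker quantities recovers
every planted label:

```r
nrq   <- normalizeToReferences(relativeAbundance(cqt),
                               head(stabilityTable(stab)$candidate, 2))
calls <- classifyStages(nrq, panel)
table(call = calls$call,
      truth = as.character(stageOf(fc))[match(calls$sample_id, colnames(fc))])
#>      truth
#> call  ATT niS PEN SWE
#>   niS   0   3   0   0
#>   SWE   0   0   0   3
#>   ATT   3   0   0   0
#>   PEN   0   0   3   0
```

`runPipeline(pipelineConfig(out_dir = "run"))` executes the same chain end to
end, writing one TSV per stage plus a YAML manifest of the thresholds used.

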