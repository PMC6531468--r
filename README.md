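# selexarray

Multidomain RNA-binding proteins recognize RNA not through one long motif
but through an *array* of short elements — each domain binding a degenerate
tetramer, with affinity emerging from element identity, order and spacing.
`selexarray` implements the computational pipeline for deriving such a
multi-element recognition model from an in vitro selection (SELEX-seq)
experiment and testing it against in vivo CLIP data. It is written for
RNA-biochemistry and regulatory-genomics groups who run bind-n-seq-style
selections and want the full analysis — preprocessing, enrichment
statistics, spacing grammar, transcript scanning, binding-index
correlation — as tested, reusable functions.

## What it computes

**Enrichment z-scores.** For each k-mer m (k = 4, 5, 6), containment counts
(tags containing m at least once) are converted to frequencies
f(m) = count/total and standardized over the full 4^k universe:

    z_raw(m) = (f(m) − mean f) / sd f          (population sd)
    z_corr(m) = z_raw,sample(m) − z_raw,control(m)

with the matched negative-control selection subtracted per motif and round.

**Pair-spacing analysis.** The same machinery applied to ordered tetramer
pairs at gaps 0–25 nt (gap = nucleotides strictly between the motifs, the
N_x notation), 65,536 × 26 cells standardized jointly; pairs ranked by mean
corrected z over gaps, and the top 500 partitioned into motif-class groups
(CA-rich/CA-rich, CA-rich × GGC-core in both orders, GGC/GGC) whose
per-gap profiles form the spacing heat maps.

**Motif-array grammar.** Transcript regions are scanned for
`(GGC) – N30–200 – (GGC)` anchor pairs enclosing two CA elements with
≥ 10 nt anchor margins and ≥ 6 nt mutual gap, plus one external CA element
6–200 nt outside an anchor; qualifying anchor pairs are greedily reduced to
a non-overlapping set.

**Binding index.** B = CLIP tag count / expression per region; regions
grouped by array count (0, 1, 2/3, ≥4) and compared with Welch's
two-sample t test.

A synthetic-data module (selection simulator with planted motif/pair
affinities, the designed 101-mer validation series, and a synthetic
regulome with planted arrays, lognormal expression and Poisson tags)
generates every input with known ground truth.

## Worked example

Simulate a selection with a planted hexamer affinity and recover it:

```r
library(selexarray)

sim  <- simulate_selex_rounds(selex_sim_config(
          pool_size = 50000,
          planted_motifs = data.frame(motif = "CACACA", gain = 3),
          seed = 17))
ctrl <- simulate_selex_rounds(selex_sim_config(pool_size = 50000, seed = 1017))

zs <- compute_z_scores(
  count_kmer_containment(sim$R4, 6, sample = "planted", round = "R4"),
  count_kmer_containment(ctrl$R4, 6, sample = "control", round = "R4"))
rank_top_motifs(zs, n = 3)
#>   rank  motif z_corrected highlight
#> 1    1 CACACA    49.62977      TRUE
#> 2    2 ACACAC    19.06075      TRUE
#> 3    3 GCACAC    14.15750      TRUE
```

The planted hexamer ranks first of 4096 with corrected z ≈ 50; the runners-up
are its overlapping neighbours, which hitchhike on the same selected tags.
Scanning the designed 101-mer series with the array grammar:

```r
fx <- make_fixture_101mers()
vapply(fx, function(s) nrow(scan_motif_arrays(s)), integer(1))
#>          WT      CA->UG     GGC->UG       allUG    GGC<->CA GGC<->CA_UG
#>           1           0           0           0           0           0
#>    (CA)4<->
#>           0
```

Only the wild-type layout satisfies all three criteria. End to end on a
synthetic regulome, the B index rises with planted array count:

```r
reg <- generate_regulome(regulome_config(n_regions = 2000, seed = 42))
ann <- annotate_sequences(reg$sequences)
b   <- compute_b_index(reg$regions, reg$tags, reg$expression,
                       array_counts = ann$summary)
group_and_compare(b)$group_means
#>         0         1       2/3       >=4
#> 0.5039678 1.4738883 2.9474740 4.8801781
```

matching the planted expectation E[B] = λ0 + λ1·k with λ0 = 0.5, λ1 = 1.

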