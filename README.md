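# binpbs — probability of being signal for binned ChIP-seq

Histone ChIP-seq analysis usually goes through peak callers, which
struggle with two recurring problems: broad repressive marks (H3K27me3
and friends) spread low enrichment over megabases and evade narrow-peak
detection, and peak sets from different samples are hard to compare
because positions shift and normalisation differs. `binpbs` takes the
low-resolution route instead: it divides the genome into non-overlapping
5 kB bins, counts reads per bin, corrects the counts for mappability and
copy number, estimates a genome-wide gamma background from the low-count
half of the data, and assigns every bin a **probability of being signal
(PBS)** between 0 and 1. PBS values are universally normalised, so tracks
from different samples, marks, or tissues can be compared bin-by-bin —
differential enrichment is literally subtraction.

## The model

Bin counts are a two-component mixture: a fraction λ of bins draw from a
gamma background f\*(x; α, β), the rest carry signal of unspecified
shape. Counts at or below the sample median θ are taken as
background-dominated, and (α, β, λ) minimise a modified Cramér–von Mises
criterion

    ω² = ∫_{-∞}^{θ} [F(x) − λ F*(x; α, β)]² dF*(x; α, β)

between the empirical CDF F and the λ-scaled gamma CDF. Each bin with
count x then gets

    PBS(x) = (f(x) − λ f*(x; α, β)) / f(x)   if f(x) > λ f*(x),  else 0

— the fraction of bins at that count level the background cannot
explain (1 minus a local FDR). A residual-area metric
q = ∫ (λ f\* − f)₊ dx over the top half of the data scores the fit;
q < 0.05 is a good fit. CNVs are detected with Hartigan's dip test on 20
genome-order subsets of an input control and corrected via a
normal-mixture ploidy estimate; mappability correction divides counts by
per-bin uniqueness scores (bins < 0.5 are dropped).

## Worked example

Simulate a punctate 8× mark over 10% of a 100,000-bin genome, fit the
background, and score every bin:

```r
library(binpbs)

spec <- simulation_spec(n_bins = 100000, lam = 0.9, signal_fold = 8,
                        signal_shape = 8, seed = 42)
sim <- simulate_counts(spec)

emp <- empirical_distribution(sim$track)
fit <- fit_background(sim$track, emp = emp)
print(fit)
#> GammaBackgroundFit: alpha=3.008 beta=0.1011 lambda=0.8904 theta=29.05
#>   omega2=1.26e-07 q=0.005098 (good fit)

pbs <- compute_pbs(sim$track, emp, fit, bins = sim$bins)
summarize_categories(pbs, edges = c(0.1, 0.9))
#>   category  bins fraction
#>    [0,0.1) 85679   0.8568
#>  [0.1,0.9)  4894   0.0489
#>    [0.9,1]  9427   0.0943

mean(pbs$values[sim$labels] > 0.9, na.rm = TRUE)
#> [1] 0.94
```

The fit recovers the generating background (α = 3, β = 0.1, λ = 0.9) and
q is far below the 0.05 good-fit bound. The PBS histogram is bimodal —
86% of bins score below 0.1 (background), 9.4% above 0.9 — and 94% of
the truly enriched bins land above PBS 0.9, matching the generating
mixture's own posterior. A broad-mark simulation
(`simulate_broad_mark()`, 2× over 30% of bins) instead concentrates its
enriched bins at intermediate PBS — the expected signature of repressive
domains.

For real data the same pipeline runs end-to-end from files:

```r
cfg <- run_config(counts = "sample.bedGraph", chrom_sizes = "hg38.chrom.sizes",
                  blacklist = "hg38-blacklist.bed", mappability = "umap100.bedGraph",
                  input_counts = "input.bedGraph", out_dir = "out/")
res <- run_pipeline(cfg)   # writes rescaled.bedGraph, fit.tsv, pbs.bedGraph, log
```

or from the shell via the thin wrapper `inst/exec/binpbs`
(`binpbs pbs --chrom-sizes ... --counts ... --out out/`; subcommands
`simulate`, `diff`, `summarize`, `overlap`, `matrix`). Thresholded
annotations (e.g. PBS > 0.9 domains for heritability partitioning) come
from `write_bin_track(..., format = "bed_threshold")`.

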