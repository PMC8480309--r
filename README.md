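# translag

Multi-omics analysis of the lag between translation and protein
abundance. Germinating seeds mobilise stored mRNAs onto polysomes well
before the encoded proteins change in abundance; `translag` quantifies
that delay from matched time courses of **total mRNA**, **polysomal mRNA
(translatome)** and **protein** over a germination series (0/dry, 6, 26,
48, 72 hours after imbibition, three biological replicates), and ships a
synthetic generator with planted ground truth so the entire pipeline can
be exercised and scored without the original microarray/LC-MS data.

It is written for seed biologists and computational biologists working
with translatome–proteome couplings, in tidyverse style: every stage
takes a data frame and returns a tibble, so analyses compose with the
pipe.

## The statistics at the core

* **Moderated differential expression per consecutive contrast.** Per
  gene a one-way group-means fit over detected time points; variances
  shrunk by empirical Bayes, *s̃²* = (*d₀s₀²* + *d·s²*)/(*d₀* + *d*)
  with (*d₀*, *s₀²*) estimated by moment-matching log *s²* (trigamma
  inversion); moderated *t* = log₂FC / √(*s̃²*(1/nᵢ + 1/nⱼ)) on
  *d₀* + *d* df; BH-FDR per contrast; calls at |log₂FC| > 1, adj. *p* < 0.05.
* **Time-lagged per-gene Spearman correlation** between layers: layer
  *a* at *tᵢ* paired with layer *b* at *tᵢ₊ₗₐ𝓰*, replicate-matched.
* **Delay classification.** A gene whose first protein change comes
  1–3 contrasts after its first polysomal change, in the same direction,
  is a Delayed-response Up-/Down-regulated Gene (DUG/DDG); the delayed
  fraction is (#DUG + #DDG) / proteome size.
* **Sequence machinery.** Exact PWM scanning (tail probabilities of the
  integerised log-odds score by convolution, enumeration-verified),
  one-tailed Fisher/hypergeometric enrichment with custom backgrounds,
  and a deterministic exhaustive k-mer ranking as a de novo discovery
  stand-in.

## Worked example

```r
library(translag)

run <- run_pipeline(pipeline_config(sim = sim_config(seed = 42)))
run$delayed_fraction
#> # A tibble: 1 × 4
#>   n_dug n_ddg proteome_size delayed_fraction
#>   <int> <int>         <int>            <dbl>
#> 1   181    44          1863            0.121

run$metrics     # recovery against the generator's planted truth
#> # A tibble: 1 × 5
#>   n_called n_true_observable sensitivity   fdp modal_shift_match
#>      <int>             <int>       <dbl> <dbl>             <dbl>
#> 1      225               267       0.843     0                 1

head(run$kmers, 3)   # the planted 5'UTR motif tops the k-mer ranking
#> # A tibble: 3 × 8
#>   kmer        k n_target n_background expected_rate odds_ratio  p_value    p_adj
#>   <chr>   <int>    <int>        <int>         <dbl>      <dbl>    <dbl>    <dbl>
#> 1 TCTTCT…     8       67          144       0.00359       6.84 4.24e-24 1.69e-19
#> 2 CTTCTTC     7       67          155       0.0109        6.31 1.21e-22 2.41e-18
#> 3 TCTTCTT     7       68          166       0.0176        5.99 6.00e-22 7.97e-18
```

Reading the output: of 2,000 simulated genes, 1,863 pass the proteome
detection filter; 181 DUGs and 44 DDGs are recovered (12% of this
detected proteome — the generator plants 20% delayed genes, some of
whose lags run past the last time point). Sensitivity 0.84 at zero false
discovery against the planted truth, and every recovered shift equals
its planted lag. The top-ranked k-mer is the planted TCTTCTTC (67/100
target genes vs 144/900 background, adj. *p* ≈ 2e-19). Individual stages
are available as plain functions (`fit_contrasts() |> ebayes_shrink()
|> call_de()`, `classify_delay()`, `per_gene_layer_correlation()`,
`pwm_scan()`, `go_enrichment()`, ...) and results plot with
`plot_de_counts()`, `plot_lag_correlation()`, `plot_shifted_profiles()`
and `autoplot()`.

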