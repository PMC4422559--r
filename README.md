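# hubmotif

Metabolites are among the first cellular components to respond to an
environmental change, which makes every responding metabolite *correlated*
with the ensuing transcriptional program — and makes its causal position
the real question. `hubmotif` classifies each measured metabolite into one
of four causal network motifs relative to a nutrient-signaling hub such as
yeast TORC1, using dynamic metabolite and transcript measurements from
three perturbations: a nutrient upshift, a nutrient downshift, and a
drug-induced hub bypass (rapamycin):

| motif | meaning |
|---|---|
| `downstream` | the hub drives the metabolite (post-translational enzyme control) |
| `upstream`   | the metabolite is an input signal to the hub |
| `parallel`   | the metabolite drives transcription independently of the hub |
| `unrelated`  | metabolite and transcriptome changes are not related |

## Method in brief

For every metabolite *m* and condition, two features in [0, 1] are
computed:

* **DD (dynamic dependence)** — for every transcript, the sampled distance
  correlation (Székely) between the metabolite trajectory (minutes 0–10,
  1-min grid) and an 11-sample window of the transcript's spline-estimated
  time derivative, delayed by d = 0…10 min (a signal must precede its
  effects); the maximum over delays ranks transcripts, the top 10% form
  the metabolite's significant gene set (SSG), and DD is the mean over the
  SSG.
* **RG (representation of hub genes)** — the fraction of the SSG documented
  as targets of the hub-controlled transcription factors (default: the 11
  TORC1-controlled TFs).

Feature values are converted to likelihoods via mid-distribution empirical
CDFs of a *random-metabolite* null ensemble (constant + noise at the
dataset's CV), compared against per-motif prototypes (MAX: L = F̂(x); R:
L = 1 − 2·max(0, F̂(x) − 0.5)), multiplied over (condition, feature) terms,
and normalized with uniform priors into posteriors (Bayes factors =
likelihood ratios). This is repeated for 48 method variants
(2 interpolations × 4 noise CVs × 3 replicate pairings × 2 likelihood
modes); the final call is the motif supported with posterior > 0.5 by more
than half of the variants, else `none`.

The package also quantifies assignment robustness under perturbations of
the hub-TF prior (exhaustive removals of 1–3 TFs; random additions), and
fits the six-parameter impulse model
f(t) = (1/h₁)·[h₀+(h₁−h₀)σ(β(t−t₁))]·[h₂+(h₁−h₂)σ(−β(t−t₂))]
to transcript time courses to extract onset times t₁/₂ (time to half of the
maximum expression change).

## Worked example

A synthetic three-condition experiment with planted ground truth (200
genes, 6 metabolites — one upstream, one downstream, one parallel, three
unrelated), analysed with the full 48-variant pipeline:

```r
library(hubmotif)

sim <- generate_experiment(synthetic_config(seed = 1))
ma  <- assign_motifs(sim$experiment, n_random = 100, seed = 1)
ma
#> <motif_assignment> 6 metabolites, 48 method variants
#> # A tibble: 6 x 2
#>   metabolite      call
#>   <chr>           <chr>
#> 1 met_downstream  downstream
#> 2 met_parallel    parallel
#> 3 met_unrelated_1 none
#> 4 met_unrelated_2 none
#> 5 met_unrelated_3 none
#> 6 met_upstream    upstream
```

All three planted motifs are recovered and the unrelated metabolites get
no motif. The assignment frequencies behind the calls (fraction of the 48
variants supporting each motif with posterior > 0.5):

```r
tidy(ma) |> tidyr::pivot_wider(names_from = motif, values_from = frequency)
#>   metabolite      call       downstream parallel unrelated upstream
#> 1 met_downstream  downstream      1       0          0       0
#> 2 met_parallel    parallel        0       0.75       0       0.104
#> 3 met_unrelated_1 none            0.25    0.104      0.271   0.0625
#> 4 met_unrelated_2 none            0.208   0.0417     0.333   0.125
#> 5 met_unrelated_3 none            0.146   0.104      0.292   0.125
#> 6 met_upstream    upstream        0.167   0.104      0       0.562
```

`met_downstream` is unanimous (every variant supports `downstream`);
`met_upstream` wins a 56% majority — upstream calls rest entirely on the
bypass condition and are the least stable class (see the vignette).
`autoplot(ma)` draws this table as a heat map;
`hub_tf_robustness(ma)` reruns the calls under perturbed TF priors.

Fitting the impulse model to a transcript profile:

```r
times <- c(0, 1, 3, 5, 7, 11, 15, 19, 24)
fit <- fit_impulse(times, impulse_value(
  list(h0 = 1, h1 = 3, h2 = 2.2, t1 = 4, t2 = 14, beta = 1.2), times))
glance(fit)
#>        sse t_half flag      n
#> 1 2.14e-25   4.01 ok        9
```

A thin command-line wrapper (`inst/cli/hubmotif`) exposes the
`simulate` / `infer` / `robustness` / `onset` pipeline over YAML run
configurations; see `?read_run_config`.

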