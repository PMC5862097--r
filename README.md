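# laminarmeg

Can MEG tell which cortical lamina a signal came from? The deep
(white-matter boundary) and superficial (pial) cortical surfaces are only
2-4 mm apart, but with precise anatomical models they are distinct
generative hypotheses for the measured sensor data. `laminarmeg` is an R
toolkit for testing laminar discrimination by simulation: it builds linked
two-layer synthetic cortices, simulates trial-structured patch sources at
controlled per-trial SNR, inverts the sensor data by empirical-Bayes
restricted maximum likelihood under four prior schemes, and decides - per
simulated source - which surface generated the data.

It is aimed at methods researchers in MEG/EEG source modelling who want a
self-contained, fully seeded laboratory for laminar inference, with the
statistics used to evaluate classifiers included.

## The model in brief

Sensor data are modelled as `Y = L J + E`, with `L` the lead field of a
candidate cortical surface (current dipoles normal to the surface in a
spherical conductor, fT/nAm) and `E` Gaussian noise. Data are reduced to
orthonormal spatial (lead-field) modes and 4 temporal modes, and the
covariance of the evoked (trial-averaged) response is fitted by ReML:

    Sigma = exp(l_0) I + sum_k exp(l_k) Q_k

where the source components `Q_k` encode the scheme - IID (minimum norm),
COH (locally coherent), EBB (beamformer-estimated local variance), or MSP
(a library of rank-one patch components). The log hyperparameters carry
Gaussian hyperpriors and the reported free energy `F` bounds the log model
evidence, so `dF = F_pial - F_white` approximates a log Bayes factor
between the two laminar hypotheses (`|dF| > 3` is about 20:1 evidence).
Decisions can also be made by held-out-sensor cross-validation or by a
paired t-statistic over trials on a functionally defined ROI of the
combined two-surface source space. Exact binomial, exact McNemar, Spearman
and Meng correlated-correlation tests quantify classifier accuracy and
bias.

## A worked example

```r
library(laminarmeg)

cfg <- laminar_config(n_sources_per_surface = 5, n_trials = 100,
                      snr_grid_db = -20, include_noise_only = FALSE)
sweep <- run_snr_sweep(cfg, seed = 1)
glance(sweep)
#> # A tibble: 4 x 10
#>   snr_db scheme analysis        n accuracy pial_bias significant_fraction
#>    <dbl> <chr>  <chr>       <int>    <dbl>     <dbl>                <dbl>
#> 1    -20 EBB    roi            10      100        50                  100
#> 2    -20 EBB    whole_brain    10       90        40                  100
#> 3    -20 MSP    roi            10      100        50                  100
#> 4    -20 MSP    whole_brain    10      100        50                  100
```

Ten patch sources (five per surface, 20 Hz, 10 nAm, patch FWHM 5 mm) are
simulated on a folded synthetic cortex at -20 dB per-trial SNR. Both
sparse schemes recover the generating surface for every source under the
ROI paired t-test; MSP also classifies all ten perfectly in the
whole-brain free-energy comparison, while EBB whole-brain misassigns one
deep source (accuracy 90 %, a slight deep-ward bias at this reduced trial
count). Every decision clears its significance threshold. `tidy(sweep)` returns the
per-simulation table (delta F, ROI t, labels), `autoplot(sweep)` plots
accuracy against SNR, and `plot_decision_metrics(sweep)` shows the
per-source metrics by true surface.

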