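# stimclean

Removal of periodic stimulation artifacts from gapped, possibly
sub-Nyquist-sampled neural recordings.

Deep brain stimulation (DBS) devices contaminate local field potential
recordings with a high-amplitude periodic artifact. Removing it by
harmonic regression requires knowing the artifact's fundamental frequency
far more precisely than the device setting provides — a relative
frequency error of 0.001 % already inflates the reconstruction error to
the 10 % range — and implanted devices add two complications: low
sampling rates that alias the stimulation frequency into the
physiological band, and wireless dropouts that split the record into
segments separated by gaps of unknown length, leaving the artifact's
phase unknown in every segment after the first.

`stimclean` is for researchers analyzing stimulation-on electrophysiology
(e.g. for closed-loop biomarker discovery) who need the underlying signal
back. It jointly estimates the artifact's fundamental frequency
$\omega$, per-segment phase shifts $\delta_i$ (in cycles, $\delta_0 = 0$),
and harmonic amplitudes, then subtracts the reconstructed artifact.

## Method

The artifact is modelled as a truncated Fourier series with $K$ harmonics,

$$a(t \mid \omega, \delta, \alpha, \beta) = \alpha_0 + \sum_{k=1}^{K}
  \alpha_k \cos\big(2\pi k(\omega t + \delta)\big) +
  \beta_k \sin\big(2\pi k(\omega t + \delta)\big),$$

and fitted by variable projection: for fixed $(\omega, \delta_1, \dots,
\delta_n)$ the amplitudes have a closed-form least-squares solution, and
the residual sum of squares defines the envelope objective
$g(\omega, \delta_1, \dots, \delta_n)$, minimized by a safeguarded Newton
descent with analytic gradient (envelope theorem) and Hessian (implicit
differentiation). The descent is initialized by multi-start modified
Newton ascent on an alignment energy
$E = |\sum_i \int S_i(t)\, e^{-2\pi i (\omega t + \delta_i)}\,dt|^2$
(trapezoid-rule quadrature), which phase-aligns all segments with a
single complex exponential. The relative RMSE metric is
$100 \sqrt{\sum(f - \hat f)^2 / \sum f^2}$.

## Worked example

The hardest shipped scenario: a 5-harmonic artifact at 150.6117 Hz
sampled at 250 Hz (fundamental aliased to 99.3883 Hz), 10 segments of
250 samples separated by random-length gaps, over a simulated neural
signal plus noise, with the artifact only 1.4× the signal RMS.

```r
library(stimclean)

sim <- simulate_example3(seed = 42)
sim$observed
#> <segmented_recording: 10 segment(s), 2500 samples, fs = 250 Hz>

res <- run_pipeline(
  sim$observed,
  init_config(m0 = 150.6, delta_omega = 5, num_init = 25, seed = 7),
  removal_config(K_hat = 5),
  truth = sim$truth_signal, true_params = sim$true_params
)

dplyr::select(glance(res), omega_hz, alias_hz, freq_rel_error_pct,
              relative_rmse_pct, mean_phase_error_cycles)
#> # A tibble: 1 × 5
#>   omega_hz alias_hz freq_rel_error_pct relative_rmse_pct mean_phase_error_cycles
#>      <dbl>    <dbl>              <dbl>             <dbl>                   <dbl>
#> 1     151.     99.4            0.00219              7.40                 0.00307
```

Reading the numbers: the pipeline recovered the aliased working frequency
(99.4 Hz digitally, i.e. 150.6 Hz nominal) with a relative error of
2.2 × 10⁻³ %, recovered the underlying signal with 7.4 % relative RMSE,
and recovered all nine unknown segment phases to ~0.003 cycles on average
(phases are identifiable only modulo 1). `res$recovered` is the cleaned
recording; `tidy(res)` lists the fitted per-harmonic amplitudes; the
fundamental's band power drops by ~30 dB:

```r
res$spectra$drop
#> # A tibble: 5 × 2
#>   frequency drop_db
#>       <dbl>   <dbl>
#> 1     99.4    30.0
#> 2     51.2    23.0
#> ...
```

On artifact-only records at 1000 Hz (no gaps), the same chain recovers
the frequency to machine precision, far beyond the DFT grid limit
(compare `figure_dft_comparison()`), and the residual after subtraction
is numerically zero.

Real data enter through `read_segments("segments.csv", fs)` — a CSV with
columns `segment_id,sample_index,value` — and a thin command-line
launcher (`inst/scripts/stimclean-cli.R`) exposes `simulate`, `init`,
`remove` and `metrics` subcommands.

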