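# imkfit

Dose-rate effects in radiation biology, modelled end to end: `imkfit`
implements the integrated microdosimetric-kinetic (IMK) model of DNA
double-strand-break (DSB) kinetics and clonogenic cell survival, for normal
human cells (lens epithelial cells and WI-38 fibroblasts are shipped as
reference parameter sets) exposed acutely, in fraction trains, or
continuously at dose rates spanning 1.82 down to 0.00081 Gy/min. It is
aimed at radiation biologists and modellers who want to fit the model to
γ-H2AX focus-count and colony-formation data, predict how residual damage
and survival depend on dose rate, and test those predictions statistically.

## The model

Reparable potentially lethal lesions (PLLs) are created at $k_N$ per
nucleus per Gy and removed at total rate $a+c$ (repair $c$, plus conversion
to lethal lesions at first-order rate $a$); PLL pairs convert at
second-order rate $b$. Under a dose-rate history $\dot D(s)$,

$$X(t) = k_N \int_0^t \dot D(s)\,e^{-(a+c)(t-s)}ds, \qquad
\frac{dW}{dt} = aX + bX^2 + \gamma b k_N^2 G(t),$$

with $G$ the intra-track pair-survival convolution (kernel
$e^{-2(a+c)(t-s)}$) and $\gamma = y_D/(\rho\pi r_d^2)$ the microdosimetric
single-event dose factor. Observable foci per nucleus are
$\delta_N(t) = X(t)+W(t)$; survival is

$$-\ln S = (\alpha_0 + \gamma\beta_0)D + F\beta_0 D^2, \qquad
F = \frac{2}{(a{+}c)^2T^2}\left[(a{+}c)T + e^{-(a{+}c)T} - 1\right],$$

the Lea–Catcheside protraction factor $F$ linking the survival curve to
delivery time $T$. The coefficient relations
$\alpha_0 = ak_N/(a{+}c)$, $\beta_0 = bk_N^2/2(a{+}c)$ connect the survival
fit back to the microscopic rates.

Parameters are estimated in stages: an exponential repair fit
($k_N$, $c$) on acute focus kinetics, a Metropolis MCMC fit of
($\alpha_0,\beta_0,a{+}c$) on the survival curve with the repair rate as
prior information, and inversion to ($a$, $b$) with delta-method errors.
See the vignette (`vignettes/imk-dose-rate-modelling.Rmd`) for the
assumptions, the σ (likelihood-width) policy, and numerical details.

## Worked example

Calibrate on synthetic acute-exposure data generated at the shipped human
lens epithelial cell (HLEC) parameters, then predict the dose-rate
dependence of survival:

```r
library(imkfit)

p <- imk_cell_lines("HLEC")
s <- acute_schedule(1, 1.82)                     # 1 Gy at 1.82 Gy/min
foci <- gen_foci(p, s, lapply(c(0.5, 1, 2.5, 6, 24, 48), timepoint),
                 n_cells = 100, lambda0 = 0.5, seed = 101)
surv <- gen_survival(p, dose_rate = 1.82, cv = 0.1, seed = 101)

fit <- imk_fit(foci, surv, background = 0.5, seed = 101,
               cell_line = "HLEC (simulated)")
fit
#> IMK model fit (HLEC (simulated))
#>   repair fit:   k_N = 41.55 per Gy, c = 0.3081 per h (R^2 = 0.9994)
#>   survival fit: alpha0 = 0.5633 per Gy, beta0 = 0.02109 per Gy^2, a+c = 0.3089 per h (R^2 = 0.9824)
#>   derived:      a = 0.004187 per h, b = 7.546e-06 per h
```

The repair fit recovers the generating DSB yield (40.6 per Gy) and removal
rate (0.309 h⁻¹) within its uncertainties; the survival posterior recovers
α₀ = 0.559 Gy⁻¹ and β₀ = 0.0175 Gy⁻² likewise, and the derived microscopic
rates land near the generating 4.27×10⁻³ and 6.58×10⁻⁶ h⁻¹.

```r
predict_doserate_survival(fit$params, c(1.82, 0.1, 0.033, 0.00081), doses = 2)
#>   dose_rate_Gy_min dose_Gy         F neg_log_s        sf
#> 1          1.82000       2 0.9981170  1.251136 0.2861795
#> 2          0.10000       2 0.9665469  1.248473 0.2869428
#> 3          0.03300       2 0.9036349  1.243165 0.2884698
#> 4          0.00081       2 0.1449702  1.179159 0.3075372
```

Between 1.82 and 0.033 Gy/min the 2 Gy surviving fraction moves by less
than 0.003 — the protraction factor barely drops below 1 because delivery
is still short against the ~3 h repair timescale — while at 0.00081 Gy/min
(a 41 h delivery) F falls to 0.14 and survival rises visibly. Focus-side
predictions across the five study regimens come from
`predict_doserate_foci(fit$params, doserate_scenarios(1))`, and
`compare_foci()` tabulates observed/predicted ratios with standard errors.

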