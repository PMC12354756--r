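# whiskr

Seasonal diet reconstruction of a mesocarnivore from serial whisker
stable isotopes.

Whiskers grow at a near-constant rate, so a whisker cut into fixed-length
segments is a dated archive of assimilated diet: each segment's
δ13C/δ15N pair reflects what the animal ate over a ~two-week window.
`whiskr` turns a table of segmented whisker isotope values, a table of
diet end-members ("sources"), and scat occurrence records into a full
seasonal diet analysis:

* **Concentration-dependent Bayesian mixing model.** For diet
  proportions `p = softmax(θ)` and elemental concentrations `q_kj`, the
  consumer mean on isotope `j` is
  `μ_j(p) = Σ_k p_k q_kj (μ_kj + Δ_kj) / Σ_k p_k q_kj`, with source and
  trophic-discrimination (TDF) variance propagated through the same
  weights plus a residual σ_j. Priors are normal on the softmax (centred
  log-ratio) scale and can be elicited from scat frequencies of
  occurrence. Fits are sampled by componentwise adaptive Metropolis
  (population-level with individual random effects, or one fit per
  whisker segment), with rank-normalized split-R̂ and
  autocorrelation-based ESS gates.
* **Isotopic niche (δ-space).** Seasonal ANOVA, standard ellipse areas
  (`SEA = π√det(S)`, small-sample `SEAc`), Bayesian ellipses, and the
  ellipse-overlap statistic `O_δ = O / ((B_W + B_S) − O)`.
* **Dietary niche (p-space).** Posterior-distribution overlap,
  probabilistic niche-region overlap across individuals, specialization
  `ε` and similarity `s` indices with quadrant classification and 2-D
  strategy kernels, Pianka's overlap with bootstrap, SIMPER
  contributions on Bray–Curtis dissimilarity, and a permutation MANOVA
  season test.
* **Seasonality.** Day-of-year stacking of segment windows, running
  two-week averages, Colwell's constancy/contingency/predictability
  (C, M, P = C + M and M/(C+M)), autocorrelation, Morlet wavelet power
  with white-noise surrogate significance, and a local-level +
  annual-harmonic state-space smoother fit by Kalman maximum likelihood.
* **Synthetic study generator.** Emulates the target system — four
  isotopically distinct diet groups, 16 individuals with 5–6 segments
  each (~88 segments), 442 scats, and seasonally phase-shifted diets
  (wolf carrion peaking in winter, human foods keyed to a park
  open/close calendar) — so the entire pipeline is testable without any
  field data.

## A worked example

```r
library(whiskr)

cfg <- default_config()
cfg$iterations <- 20000L; cfg$burn_in <- 10000L; cfg$thin <- 5L

study <- simulate_study(cfg, seed = 1)
consumers <- assign_window_season(study$consumers, cfg)

prior <- elicit_priors_from_scats(
  study$scats[study$scats$season == "winter", ],
  cfg$source_groups, eps0 = 0.01
)
post <- fit_population(consumers, study$sources, prior,
                       season = "winter", cfg, seed = 1)
summary(post)
```

```
         group       mean         sd       q2.5        q50      q97.5
1   small_prey 0.16311811 0.03390600 0.10359586 0.16130460 0.23505715
2 wolf_carrion 0.63042103 0.03043354 0.56758067 0.63138145 0.68733407
3  human_foods 0.16990980 0.01651974 0.13716937 0.16987129 0.20308574
4      berries 0.03655106 0.01264253 0.01716535 0.03492177 0.06693164
```

The fitted winter diet is dominated by wolf carrion (posterior mean
0.63, 95% CrI 0.57–0.69), with small prey and human foods each around
0.16 and berries nearly absent — recovering the generator's true winter
diet of (0.20, 0.62, 0.15, 0.03). The isotopic niche follows from the
same table:

```r
e_w <- standard_ellipse(consumers[consumers$season == "winter",
                                  c("d13C", "d15N")])
e_s <- standard_ellipse(consumers[consumers$season == "summer",
                                  c("d13C", "d15N")])
ellipse_overlap(e_s, e_w)$O_delta
#> [1] 0.1581877
```

i.e. the summer and winter 95% isotope ellipses share only ~16% of
their union: the population shifts its isotopic niche between seasons.

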