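# matesim

An individual-based simulation of good-genes inter-sexual selection under
environmental disruption of male mating signals, with a guppy-like life
history (overlapping generations, gestation, density-dependent juvenile
mortality). It is aimed at evolutionary ecologists who want quantitative,
multi-generational predictions for systems — such as guppies exposed to
endocrine-disrupting chemicals — where pollutants degrade the honesty of a
sexually selected signal.

## The model

Each individual carries two diploid traits with alleles on [0, 1], one
allele per parent, traits expressed as the allele mean:

- **Viability** *V*: survival advantage ("good genes");
- **Preference** *P*: a female threshold — she mates only with mature males
  whose signal is at least *P*, choosing uniformly among them; with no
  acceptable male she forgoes mating that step (the wallflower cost).

Males advertise viability through a **signal** fixed at birth:

    S = V (1 − D)

where *D* ∈ [0, 1] is the environmental disruption. At *D* = 0 the signal is
honest (*S* = *V*); as *D* grows the disparity between males of different
viability shrinks, vanishing at *D* = 1.

Each time step (one day), four sub-models run in order: environmental
disruption update, ageing and death, reproduction, mating. Juveniles
(age < 60) survive each step with

    p_juv = max(0, 1 − J / K)

with *J* the juvenile count and *K* = 2000 the carrying capacity; adults
survive with

    p_adult = 1 − clamp(age² / Senescence − VE · V, 0, 1)

(*Senescence* = 100 000, *VE* = 0.3). Pregnant females deliver
Poisson(6) litters after a 27-step gestation; transmitted alleles mutate to
a fresh Uniform(0, 1) draw with probability 0.05 (viability) and 0.001 or
0.01 (preference).

A run starts from 75 + 75 founders, evolves disruption-free for 20 000
steps (time-point A), experiences disruption *D* for a scheduled duration
(ending at time-point B), then recovers for 30 000 steps (time-points C1,
C2). The reported observable is the mean paternally inherited allele of
each trait over all living individuals.

## Worked example

```r
library(matesim)
p <- sim_params(disruption = 0.4, disruption_duration = 2000)
run_single(p, seed = 2)
#> <sim_run> seed 2, EXTINCT at t = 20393
#>   label     t   n n_males n_females n_juveniles mean_pref_pat mean_pref_mat
#> 1     A 20000 127      63        64          82        0.9118        0.8797
#>   mean_viab_pat mean_viab_mat mean_signal_males
#> 1        0.9428        0.8679            0.9125

run_single(p, seed = 3)$records[, c("label", "t", "n", "mean_pref_pat",
                                    "mean_viab_pat", "mean_signal_males")]
#>   label     t   n mean_pref_pat mean_viab_pat mean_signal_males
#> 1     A 20000 132     0.5575658     0.8372969         0.8072830
#> 2     B 22000 116     0.5407138     0.9667957         0.5684606
#> 3    C1 32000  91     0.5440552     0.8859824         0.9049529
#> 4    C2 52000 144     0.5440552     0.8749657         0.8733086
```

The two seeds show the two characteristic fates. In the first, females had
evolved a stringent preference (0.91) by the end of burn-in; disruption
shifted every male signal below that threshold, females stopped mating, and
the population went extinct 422 steps into the disruption window. In the
second, a moderate preference (0.56) survived the window: mean male signal
dropped from 0.81 to 0.57 while disruption was active, preference eroded
slightly, and signal honesty (and population size) recovered after the
window closed.

Sweeps, calibration and summaries:

```r
spec <- sweep_spec(disruption_levels = c(0.1, 0.4, 0.7),
                   durations = c(500, 2000, 5000), replicates = 20)
tab <- run_sweep(spec)
extinction_summary(tab, "disruption")
calibration_correlation(sim_params(), n_runs = 50, seed_base = 1)
```

A thin command-line front end over the same functions ships at
`inst/cli/matesim.R` (`run`, `sweep`, `calibrate`, `summarize`).

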