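# synclock

Stochastic simulation and analysis of circadian oscillators in syncytial
(multinucleate) cells.

Filamentous fungi such as *Neurospora crassa* keep circadian time with
astonishingly few clock mRNAs — single-digit copy numbers per nucleus at
peak transcription — while hundreds of nuclei share one cytoplasm. This
package is for modelers of cellular oscillators and of nuclear coordination
in syncytia who want to ask: can a transcription–translation clock run
reliably in that regime, how does protein sharing between nuclei shape it,
and how is the labor of transcription divided among nuclei?

## The model

A cell is a line of `N` nuclear compartments (lengths `l_i`). Per
compartment, nuclear mRNA `mn`, cytoplasmic mRNA `mc`, cytoplasmic protein
`pc` and nuclear protein `pn` evolve by six reactions — transcription under
Hill self-repression, export, mRNA decay, translation, nuclear import, and
protein decay:

    transcription rate = alpha * ( K / (K + pn / V_n) )^r

mRNAs never leave their compartment; cytoplasmic proteins equilibrate
instantly: whenever `p_tot` changes, every compartment gets
`floor(p_tot / N)` molecules and the remainder is scattered one-each over
random distinct compartments (length-weighted apportionment for unequal
compartments). Trajectories are simulated exactly (Gillespie SSA, compiled
core, deterministic per seed). The deterministic counterpart has a Hopf
bifurcation at `alpha_crit = 4 * 5^5 * nu^2 * K * V_n / beta ≈ 2039 /h` at
the default parameter set — and the central phenomenon is that the
stochastic model keeps oscillating orders of magnitude *below* that
threshold.

Rhythm regularity is rated by the spectral quality factor `q`: the fraction
of trial-averaged nuclear-protein spectral power within ±2 h of the
dominant period. Division-of-labor statistics count per-nucleus
transcription events over trough-to-trough circadian periods;
a synchronization experiment compares peak-time dispersion between
protein-sharing and isolated nuclei.

## Worked example

```r
library(synclock)

m <- clock_model(alpha = 18, N = 2)   # two-nucleus cell, minimal rate
summary(m)
#> Syncytial circadian clock model
#>   compartments: N = 2 (uniform)
#>   alpha = 18 /h, beta = 10 /h, K = 200 /pL, r = 5
#>   gamma_m = 0.2856, gamma_p = 0.2856, delta_m = 0.2856, delta_p = 0.2856 /h
#>   V_n = 0.1 pL, V_c = 2 pL
#>   deterministic oscillation threshold: alpha_crit = 2039.2 /h (damped regime)
#>   per-compartment fixed point (counts): mn = 0.80, mc = 0.80, pc = 27.93, pn = 27.93

quality_pipeline(m, n_trials = 25, seed = 1)
#> Quality factor q = 0.187 (tau = 2 h); peak 0.0341 cycles/h (T* = 29.4 h), band [0.0319, 0.0365]

division_of_labor(m, t_end = 10000, seed = 7)
#> Division-of-labor tally: 400 periods, 2 compartments
#>   periods with >2-fold transcription skew: 31.0%
#>   mean transcript fraction in compartment 2: 0.500

consistency_experiment(n_trials = 25, seed = 1)
#> Peak-time consistency, 25 trials per scenario, init (mn=2, mc=1, pc=16, pn=16)
#>   coupled     sigma (h): 5.70, 6.26, 8.00, 7.60, 9.16; mean day 23.4 h; excluded 0
#>   independent sigma (h): 4.99, 7.63, 12.22, 15.55, 15.86; mean day 24.8 h; excluded 0
```

Reading the output: the cell sits far below the deterministic oscillation
threshold (the ODE damps to a fixed point with under one mRNA per nucleus),
yet the stochastic trajectories oscillate with a ~29 h dominant period and
concentrate ~19% of their spectral power within 2 h of it. Even with
identical compartments, one nucleus out-transcribes the other more than
two-fold in ~31% of circadian periods — labor divides spontaneously while
the average share stays at one half. And protein sharing acts as an
internal entrainment signal: by day five, peak timing drifts almost twice
as much across isolated nuclei as across coupled ones.

The sweep drivers `run_table1()` (quality versus transcription rate),
`run_compartment_sweep()` (quality and peak frequency versus `N`) and
`run_size_ratio_sweep()` (division of labor and whole-cell quality versus
compartment-size asymmetry) script the full experiments; see the vignette
in `vignettes/` for the model's assumptions and every numerical convention.

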