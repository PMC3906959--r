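# ifnlattice

Agent-based stochastic simulation of noise propagation through extracellular
cytokine signaling in a virus-infected dendritic-cell population.

## The scientific problem

When dendritic cells (DCs) are infected by a virus at moderate multiplicity
of infection (MOI), only a random ~40% of cells are infected, and within
those, type-I interferon (IFN-β) induction is itself stochastic: the IFNB1
enhanceosome assembles by sequential cooperative binding of transcription
factors, so cells start secreting hours apart. The secreted cytokine
diffuses, binds the interferon receptor (IFNAR) on infected *and* uninfected
cells, and drives induction of interferon-stimulated genes such as *DDX58*
(encoding the viral sensor RIG-I). During the transient — roughly the first
ten hours post-infection — the spatial randomness of the cytokine sources
combines with their temporal sporadicity to make the *DDX58* copy-number
distribution across the population enormously broad (Fano factor
`Var/Mean` ≫ 1), even though the pre-infection steady state is Poisson
(Fano ≈ 1). Later, diffusion homogenizes the extracellular field and
paracrine signaling quenches the variability.

`ifnlattice` is a multi-scale simulator of this mechanism:

- **Lattice**: a 40 × 40 grid of 30 μm boxes (≤ 1 cell per box), 210 cells
  placed uniformly at random, infected as a Poisson zero-class
  (`P(infected) = 1 − e^(−MOI)`).
- **Intracellular kinetics** (exact Gillespie SSA per cell): 4-step
  enhanceosome assembly with RIG-I–dependent forward rates, activation to a
  transcribing state (bursting kinetics), IFN-β transcription upregulated by
  bound IFNAR (IRF-3 → IRF-7 exchange, a Hill function of `B`),
  translation-coupled secretion, receptor binding/unbinding restricted to
  the cell's own box, a two-state *DDX58* gene with switch-on rate
  `k_on(B) = k_off · (B/475)²` (half-maximal induction at 475 of 1000 bound
  receptors), and RIG-I translation closing the feedback loop.
- **Extracellular diffusion**: per-box binomial/multinomial random-walk
  sweeps (hop probability 0.5 per step), synchronized with the SSA by
  operator splitting every `τ = p·L²/(4D) = 11.25 s`.

The compiled core (Rcpp) runs a full 15-hour, 210-cell baseline
(~10⁸ reaction events) in ~20 s.

## Worked example

```r
library(ifnlattice)
cfg <- sim_config(seed = 1)   # baseline: 210 cells, MOI 0.5, 15 h
cfg
#> <ifn_config> baseline
#>   lattice 40 x 40 boxes of 30 um, 210 cells, MOI 0.5 (bernoulli)
#>   D = 10 um^2/s, hop 0.5 -> dt = 11.25 s; 15 h, sampled every 300 s
#>   1000 IFNAR/cell, threshold 0.475 (B* = 475); seed 1

sim <- run_simulation(cfg)
sim
#> <ifn_sim> baseline: 210 cells (87 infected), 15 h, 181 samples, 1.3e+08 SSA events

subset(sim$series, time_h %in% c(4, 6, 7, 9, 11),
       c(time_h, fano_dx, frac_expressing, mean_bound,
         frac_boxes_low, frac_boxes_high))
#>  time_h fano_dx frac_expressing mean_bound frac_boxes_low frac_boxes_high
#>       4   1.048           0.057      5.752          1.000           0.000
#>       6   1.521           0.092     35.895          0.995           0.000
#>       7  26.844           0.138     76.424          0.890           0.005
#>       9 195.313           0.230    450.857          0.014           0.271
#>      11  71.375           0.483    914.938          0.000           1.000
```

Reading the table: at 4–6 h the population is still near its Poisson basal
state (`fano_dx ≈ 1`) and >99% of cell-occupied boxes hold fewer than 133
free cytokines (`frac_boxes_low`). Between 7 and 9 h bound receptors sweep
through the *DDX58* threshold and the Fano factor explodes (peak ≈ 197 at
8.8 h in this realization); by 11 h about half of the infected cells contain
IFN-β mRNA, every occupied box holds more than 1200 free cytokines
(`frac_boxes_high = 1`, spatial homogenization), and the Fano factor is
declining through ≈ 100. Replicate-averaged trajectories (e.g.
`run_scenario(scenario_spec("baseline"))`) smooth the realization noise.

Named figure-level experiments (pretreatment control, density / MOI /
threshold sweeps, simultaneous secretion, 1050-cell size check) run through
`run_scenario()`, one-parameter sensitivity studies through
`sensitivity_sweep()`, and everything is scriptable via the CLI wrapper
(`inst/cli/ifnlattice simulate|scenario|sweep|report`).

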