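# rodletkin

Single-fibril kinetics and lattice simulation of hydrophobin rodlet assembly.

Class I hydrophobins are small amphiphilic fungal proteins that self-assemble
into amyloid-like fibrils ("rodlets") which pack into dense, aligned films on
cell surfaces. High-speed AFM shows that a rodlet end alternates between a
*pause* state and a *growth* state: dwell times, step (growth) times and step
sizes are all exponentially distributed, and elongation accelerates when
rodlets bundle laterally ("surface-catalyzed elongation"). `rodletkin`
packages the computational side of that analysis for people working on
single-fibril kinetics:

* a **synthetic-data generator** for two-state end trajectories (exponential
  dwell/step renewal process sampled at the 12.75 s AFM frame interval, with
  Gaussian position noise), logistic precursor-height traces, and
  thioflavin-T (ThT) curves;
* **trajectory kinetics**: dwell/step segmentation, exponential fits
  (`N = A e^{-t/tau}`; MLE and histogram least squares), apparent elongation
  rates, per-step rates, the growth–pause equilibrium constant
  `K_d = tau_dwell / tau_step`, sigmoid plateau fits, the Brunner–Munzel
  rank test and a paired sign-flip permutation test for fast vs. slow ends;
* a **lattice Monte Carlo simulator** (Rcpp) of nucleation, elongation and
  lateral bundling on a 100 x 100 lattice with states {-1, 0, +1}, attempt
  gates P = 0.1 / 0.005, Boltzmann orientation choice and Metropolis
  acceptance at k_BT = 0.1, plus the orientational angle pair correlation
  function `G2(r) = <cos 2(theta_i - theta_j)>` and a simplified
  tip-elongation experiment;
* the **dock–lock bulk model** `dM/dt = 2 k+ P0 m / (1 + m/K_M)` with mass
  conservation `m = m_total - M`: adaptive Runge–Kutta integration,
  interface-on/off and seeding scenarios, and nonlinear least-squares
  fitting with bootstrap confidence intervals;
* TSV/JSON **file formats and a CLI** (`generate`, `analyze-traj`,
  `simulate-lattice`, `g2`, `fit-tht`, `tip-experiment`) with reproducibility
  manifests.

## Worked example

```r
library(rodletkin)

# growth-pause equilibrium constants from mean dwell/step times (s)
round(equilibrium_constant(43.6, 20.6), 2)  # bundled rodlets -> 2.12
round(equilibrium_constant(67.1, 31.2), 2)  # single rodlets  -> 2.15

# synthetic stop-and-go trajectory -> segmentation -> exponential fits
tr <- gen_end_trajectory(trajectory_params(tau_dwell = 61, tau_step = 29.7,
                                           mean_step_size = 26.5, seed = 1))
ev <- detect_phases(tr)
ev
#> <kinetic_events> 38 phases (dwell: 19, step: 19), frame 12.75 s
apparent_elongation_rate(ev)        # 15.55 nm/min for this seed
steps <- ev$phases[ev$phases$kind == "step" & !ev$phases$censored, ]
fit_exponential(steps$delta)
#> <exponential_fit> tau = 25.1 (n = 18, mle), 95% CI [16.6, 42.35]

# lattice Monte Carlo: lateral interactions order the film
sim <- run_simulation(lattice_config(eps_lateral = -0.5, seed = 1))
sim
#> <lattice_sim> 100x100, 10000/10000 cells filled after 488568 steps, ...
mean(angle_pair_correlation(sim, max_r = 10)$G2)   # 0.17 at eps_lateral -0.5
ct <- count_elongation_events(sim)
ct$n_surface_catalyzed > ct$n_independent          # TRUE
```

The trajectory fit returns tau close to the generating mean (25.1 vs. 26.5 nm
here with only 18 steps); the acceptance suite checks recovery at n = 200
trajectories. The G2 average drops to about 0.09 when `eps_lateral = 0`,
the simulated signature of lateral interactions driving domain alignment.

## CLI

```sh
Rscript -e 'quit(status = rodletkin::run_cli())' generate \
    --preset bundled --n 10 --seed 7 --out out/gen
Rscript -e 'quit(status = rodletkin::run_cli())' analyze-traj \
    --input out/gen/trajectories.tsv --group-by context --out out/ana
```

Every subcommand writes a `manifest.json` (full configuration + seed +
package version) alongside its outputs.

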