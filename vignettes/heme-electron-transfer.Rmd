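---
title: "Heme-to-heme electron transfer: pathway model, linear-response estimators and cavity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heme-to-heme electron transfer: pathway model, linear-response estimators and cavity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemeET)
```

hemeET analyses transmembrane heme-to-heme electron transfer (ET) after the
molecular dynamics has been run: it consumes trajectory snapshots
(multi-model PDB) and vertical energy-gap time series, and produces tunneling
pathways, ET thermodynamic parameters, coupling statistics and
dioxygen-cavity occupancies. This vignette explains the models the package
implements, the tunable parameters, what the synthetic-data generators do and
do not emulate, and the numerical choices behind the implementation.

## The tunneling pathway model

Long-range electron tunneling through a protein is attenuated by the
intervening medium. In the semi-empirical pathway picture the coupling
between donor and acceptor is

$$H_{if} = H_{if}^{\mathrm{contact}} \, \varepsilon_{tot}, \qquad
\varepsilon_{tot} = \prod_{N_c}\varepsilon_c \times
\prod_{N_{hb}}\varepsilon_{hb} \times \prod_{N_{ts}}\varepsilon_{ts},$$

where the product runs over the covalent bonds, hydrogen bonds and
through-space jumps composing the pathway, with per-step decays

$$\varepsilon_c = 0.6,\qquad
\varepsilon_{hb} = 0.36\,e^{-\beta_S (R_H - 2.8)},\qquad
\varepsilon_{ts} = 0.6\,e^{-\beta_S (R_S - 1.4)}.$$

$R_H$ is the hydrogen-bond length taken as the inter-heavy-atom distance and
$R_S$ the atom-atom jump distance, both in &Aring;ngstr&ouml;m. The decay
constant $\beta_S$ defaults to 1.1&nbsp;&Aring;$^{-1}$, the value
recalibrated against quantum chemistry; the original 1990s calibration
(1.7&nbsp;&Aring;$^{-1}$) remains available through `pathway_params()`.
Covalent bonds inside a porphyrin macrocycle are fully conductive
($\varepsilon = 1$), which makes the result independent of which macrocycle
atom is nominated as donor or acceptor.

Finding the pathway that maximizes $\varepsilon_{tot}$ is a shortest-path
problem under the additive weights $w = -\ln\varepsilon \ge 0$, solved
exactly by Dijkstra's algorithm with a virtual source wired to every donor
atom and a virtual sink wired to every acceptor atom. `best_pathway()`
implements this on the graph built by `build_tunneling_graph()`;
`pathway_ensemble()` repeats it over every trajectory snapshot and
`decompose_pathway()` reports the step counts $(N_c, N_{hb}, N_{ts})$ and the
mediating residue ("route") carrying each path.

### Pathway parameters

| parameter | unit | default | role |
|---|---|---|---|
| `epsilon_c` | — | 0.6 | per-covalent-bond decay |
| `hb_prefactor`, `hb_offset` | —, &Aring; | 0.36, 2.8 | hydrogen-bond decay law |
| `ts_prefactor`, `ts_offset` | —, &Aring; | 0.6, 1.4 | through-space decay law |
| `beta_s` | &Aring;$^{-1}$ | 1.1 | exponential distance decay |
| `ts_max_distance` | &Aring; | 6.0 | graph-construction cutoff |
| `contact_coupling` | eV | 0.177829 | $H_{if}^{\mathrm{contact}}$ |

The 6&nbsp;&Aring; through-space cutoff only bounds graph size: jumps longer
than that carry decays below $4\times10^{-3}$ and never survive the best-path
competition, so results are insensitive to the cutoff. The contact coupling
corresponds to an attempt frequency of about $4.3\times10^{13}$ Hz through
$H = h\nu$ (`contact_coupling_from_frequency()`).

## Marcus / linear-response estimation

The reaction free energy and reorganization energy of ET are estimated from
the vertical energy gap $\Delta E = E_f - E_i$ (final minus initial diabatic
state, a sign convention fixed package-wide), sampled along trajectories in
each redox state:

$$\Delta A^0 = \tfrac12\left(\langle\Delta E\rangle_i +
\langle\Delta E\rangle_f\right), \qquad
\lambda^{St} = \tfrac12\left(\langle\Delta E\rangle_i -
\langle\Delta E\rangle_f\right), \qquad
\lambda^{var}_x = \frac{\mathrm{var}(\Delta E_x)}{2 k_B T}.$$

Under the linear response approximation (LRA) the gap is Gaussian with equal
variance in both states and the three reorganization estimates coincide. The
ergodicity factor
$\chi_G = (\lambda^{var}_i + \lambda^{var}_f)/(2\lambda^{St})$ measures
departures: values near 1 indicate ergodic, LRA-consistent sampling, while
slow hidden degrees of freedom (e.g. a bimodal gap distribution) push
$\chi_G$ above 1.

`lra_fit()` is the central estimator and returns a classed fit with `print`,
`summary`, `coef`, `plot` and `simulate` methods (`simulate()` draws new
synthetic gap series at the fitted parameters). `block_analysis()` applies
it to independent trajectory segments after discarding an equilibration
window (default 20&nbsp;ns) and reports segment means with an uncertainty of
twice the standard error over segments — the convention used for error bars
here. `decompose_gap()` splits $\Delta A^0$ and $\lambda^{St}$ over
user-supplied component columns (transmembrane domain, membrane, water,
counter-ions, cofactors, ...), which is exact by linearity of the two
estimators.

Two smaller pieces complete the thermodynamics: `inner_sphere_lambda()`
evaluates the four-point (two-geometry, two-redox-state) formula for the
cofactor reorganization energy from user-supplied electronic-structure
energies, and `total_reorganization()` adds inner- and outer-sphere parts.
Numerical conventions: $k_B = 8.617333\times10^{-5}$ eV/K, default
temperature 310 K (the simulation temperature), population variances
(divisor $n$) for bit-reproducibility, energies in eV, lengths in &Aring;,
times in ps everywhere.

Energy-gap bimodality is reported descriptively (histograms, running
averages, $\chi_G$); the package deliberately performs no automatic mode
assignment because no clear-cut structural switch accompanies the observed
regime changes. No rate constants are computed, and no polarizable-force-field
induction correction is applied beyond what the user chooses to do with the
returned reorganization energies (non-polarizable force fields overestimate
them by roughly 30%).

## Coupling coherence statistics

Over an ensemble of snapshots the decay factors fluctuate. With population
moments $\langle\varepsilon\rangle$ and $\sigma^2$, the coherence ratio

$$R_{coh} = \frac{\langle\varepsilon\rangle^2}
{\langle\varepsilon\rangle^2 + \sigma^2}$$

distinguishes coupling governed by its average ($R_{coh}\to1$) from coupling
governed by fluctuations ($R_{coh}\to0.5$). `ensemble_stats()` computes it
from the (mean, variance) pair through the identity
$\langle\varepsilon^2\rangle = \langle\varepsilon\rangle^2 + \sigma^2$,
which is then exact as computed — printed tables that round the moments
independently show small drift against this identity, so the identity form
is authoritative here. The same function reports per-route occupancies and
moments, and `coupling_from_decay()` converts decays to absolute couplings.

## The dioxygen cavity

Near the terminal heme a cavity lined by an arginine and two histidines can
host the dioxygen molecule that accepts the final electron. Its position is
tracked as the distance between the O$_2$ center and the center of the
cavity-lining group (`com_distance_series()`); the geometric (unweighted)
center is the default because the reference analysis does not state mass
weighting, and a mass-weighted option is provided. The distance distribution
is bimodal — an inserted site near 2.5&nbsp;&Aring; and an edge site near
4.3&nbsp;&Aring; — and `site_occupancy()` thresholds at their midpoint
(3.4&nbsp;&Aring;, configurable) to obtain site fractions, dwell times and
transition counts. `classify_o2_pathways()` labels heme-to-O$_2$ pathways
"short" (a direct through-space jump from the macrocycle onto O$_2$) or
"long" (an intermediate passage through a cavity residue before the jump);
short pathways carry order-of-magnitude larger decays, which is the
mechanistic lever coupling cavity occupancy to tunneling efficiency.

## Synthetic data: what it does and does not emulate

Every stage is testable without the original trajectories through
generators whose ground truth is known analytically:

* `generate_lra_gaps()` draws gaps from the exact LRA sampling picture —
  state means $\Delta A \pm \lambda$, variance $2\lambda k_B T$ — with
  optional AR(1) time correlation and component splits. Estimator recovery
  on these series closes the loop on the estimator implementations.
* `generate_bimodal_gaps()` superimposes a slow symmetric telegraph of the
  initial-state mean between regimes $\pm$`mode_offset`/2. The mixture
  variance exceeds the within-regime variance by $(\mathrm{offset}/2)^2$, so
  $\chi_G$ rises above 1 by a known amount; an offset of 0.42 eV places
  $\chi_G$ near 1.4, the middle of the non-ergodic range observed for this
  system.
* `generate_two_site_distance()` is a two-state Markov jump process with
  Gaussian jitter (widths 0.2 &Aring;) about modes at 2.5 and 4.3 &Aring;,
  switching on the few-nanosecond timescale. Default rates depend on the
  redox state — near-site occupancy 0.70 in the final (reduced terminal
  heme) state and 0.30 in the initial state — reproducing the qualitative
  occupancy reversal between redox states; the exact fractions are a
  generator choice, as no reference values are printed for them.
* `make_toy_structure()` emits small geometries with real PDB atom/residue
  naming whose best pathway follows in closed form, and
  `brute_force_best_path()` enumerates all simple paths on graphs of up to
  12 nodes as an oracle for the Dijkstra search.

The generators reproduce the *statistics* of the real observables, not the
physics that produces them: there is no force field, no membrane, no
solvent, and no correlation between the gap series and the structures.
Passing tests therefore demonstrate that the estimators and searches are
correct on data satisfying their assumptions — they do not validate the LRA
or the pathway model for any particular protein.

## Numerical choices and edge cases

* **Tie-breaking.** Among equal-decay pathways (common, because conductive
  edges cost nothing) the lexicographically smallest atom-index sequence is
  returned, a shorter optimal path preceding its extensions; two log-costs
  within $10^{-9}$ (relative) are treated as tied. The brute-force oracle
  applies the same rule, so engine/oracle agreement is exact.
* **Decay caps.** $\varepsilon_{hb}$ and $\varepsilon_{ts}$ are capped at
  $\varepsilon_c$ below their offset distances, so no single step ever beats
  a covalent bond; uncapped values above 0.6 at very short distances would
  be unphysical in this model.
* **Conductive edges** require a perceived covalent bond between two atoms
  of the same conductive set (the macrocycle is covalently connected, so
  within-set communication at $\varepsilon = 1$ is unaffected).
* **Bond perception** is geometric: covalent radii sums plus 0.4 &Aring;,
  user-overridable; hydrogens bond only to their nearest heavy atom.
  Hydrogen bonds use a 3.5 &Aring; heavy-atom cutoff with a 120&deg;
  donor–H–acceptor angle criterion that is active only when hydrogens are
  present, keeping the criterion reproducible on heavy-atom-only snapshots.
* **Degenerate inputs.** Disconnected donor/acceptor pairs raise an explicit
  "no pathway" error and are counted (never silently dropped) by
  `pathway_ensemble()`; empty selections, non-monotonic time axes and
  component columns that do not sum to the total gap are all refused at
  construction.
* **Problem sizes.** The shipped tests and the acceptance script use
  $10^5$ gap samples per state (20 seeds for the bias checks), 200 random
  graphs for oracle equivalence, 400 snapshot frames for route occupancies
  and $2\times10^4$ distance samples — sizes at which the Monte Carlo error
  of every checked quantity is far below its tolerance while the whole
  suite runs in minutes.

## Known limitations

The pathway model is semi-empirical: it returns the single best pathway per
snapshot and a classical coherence ratio, with no multi-path quantum
interference. Only multi-model PDB input is supported (trajectory formats
are converted upstream); no protonation assignment, topology-file parsing or
solvent handling is attempted, and water molecules participate in pathways
only if the user includes them in the pruned region. ET rates are out of
scope — the outputs are the thermodynamic parameters and couplings a rate
theory would consume.
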