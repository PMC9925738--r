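---
title: "Density-corrected composite energies and DC-DFT-principled dispersion fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-corrected composite energies and DC-DFT-principled dispersion fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dc4)
```

## The model

Density-corrected DFT (DC-DFT) separates the error of a self-consistent
Kohn–Sham calculation into a *functional-driven* part (the approximation
itself) and a *density-driven* part (the error in the self-consistent
density). When the density-driven part is substantial, evaluating the
functional non-self-consistently on Hartree–Fock orbitals — HF-DFT — removes
most of it. This package assembles the composite energy

$$E_\text{total} = E_\text{DFA}[n^\text{HF}] + E_\text{disp}(s_6, s_8, s_9, a_1, a_2),$$

where the dispersion term is a charge- and coordination-dependent pairwise
model with Becke–Johnson damping,

$$E_2 = -\sum_{A<B}\; s_6\,\frac{C_6^{AB}}{R_{AB}^6 + f^6}
  + s_8\,\frac{C_8^{AB}}{R_{AB}^8 + f^8},\qquad
  f = a_1\sqrt{C_8^{AB}/C_6^{AB}} + a_2,$$

with $C_8 = 3\,C_6\sqrt{Q_A Q_B}$ and an optional Axilrod–Teller–Muto
three-body term scaled by $s_9$. The $C_6^{AB}$ are Casimir–Polder
integrals of atomic dynamic polarizabilities interpolated to each atom's
fractional coordination number and scaled by its electronegativity-
equilibration (EEQ) partial charge.

The central methodological rule is how the dispersion parameters are
*trained*: only on density-insensitive (DI), spin-clean reactions, by
minimizing the mean absolute error (MAE), with water-dimer interaction
energies held out as validation. Density-sensitive (DS) reactions are
excluded because their energetic errors are dominated by density-driven
error — parameters fitted on them absorb an error the dispersion model was
never meant to describe, which ruins water energetics. The package also
implements the cautionary "naive" mode (all reactions, WTMAD-2 cost) so the
two protocols can be compared on equal footing.

## Density sensitivity

The sensitivity of a reaction is

$$\tilde S = \left|\Delta E_\text{DFA}[n^\text{HF}] -
\Delta E_\text{DFA}[n^\text{proxy}]\right|,$$

the change in the reaction energy when the functional is evaluated on two
different proxy densities. We use the HF density versus an LDA-quality
density, the standard operational pair in the DC-DFT literature; the proxy
is pluggable (`proxy_functional` argument) because published applications
differ in this detail. Classification uses a cutoff of 2 kcal/mol, the
standard choice; the boundary value itself is classified DS — the
conservative convention for training-set exclusion, where a borderline
reaction is better left out. Sensitivity is a *reaction-level* quantity:
the same clusters can be strongly DS for binding energies yet nearly DI for
relative isomer energies, so per-species screening would misclassify.

A spin screen accompanies the classification: a reaction is excluded when
any open-shell species' HF $\langle S^2\rangle$ deviates from the exact
$S(S+1)$ by more than 10% (relative, configurable), since spin-contaminated
HF densities are not reliable correction densities.

## Engines

All electronic-structure energies flow through one contract,
`evaluate_energy(engine, molecule, method_spec)`, with `method_spec`
carrying the density source (`"SC"` or `"HF"`), functional, basis and grid
level. Three implementations ship:

* an **analytic toy engine**: tabulated atomic energies plus Morse-type
  pair wells (geometric-mean depths, additive radii, width 1.8/Å), with a
  per-molecule density-error knob $\delta$ (Hartree). Self-consistent
  evaluation adds $\delta$, HF-density evaluation adds $0.1\,\delta$ (HF
  densities retain a small residual of the density-driven error), and the
  LDA proxy adds $-\delta$, so $\tilde S = 1.1\,|\Delta_r\delta|$ exactly.
  Every downstream algorithm can therefore be checked against closed-form
  values.
* a **cached-energy store** (JSON lines), keyed by a documented canonical
  hash of elements, coordinates rounded to $10^{-6}$ Å, charge,
  multiplicity and method fields. This is how energies from a real
  quantum-chemistry backend are consumed: run them elsewhere, store them,
  and the whole pipeline — sensitivities, fits, benchmarks — replays from
  the cache. A cache miss is an explicit error unless a fallback engine is
  configured.
* the contract slot for a **real backend adapter**. HF-DFT is defined
  non-self-consistently: one HF SCF, then a single functional evaluation on
  the converged HF density, no post-HF orbital relaxation. Numerical
  settings (basis, grid) are configuration keys, not constants; a
  quadruple-zeta basis with a dense grid is the recommended default.

## Reference tables

The dispersion model needs per-element data. The tables shipped for H, C,
N and O are this package's own compact parameterization, assembled from
published physical constants rather than copied from any existing
dispersion code:

* covalent radii (Pyykkö single-bond values) scaled by the customary 4/3
  inside the error-function coordination count
  $\mathrm{CN}_i = \sum_j \tfrac12\left(1 + \mathrm{erf}(-7.5\,(R_{ij}/R_{\mathrm{cov}} - 1))\right)$;
* EEQ electronegativities, hardnesses and Gaussian charge widths chosen to
  give the familiar ordering (O most negative, H positive; water
  O ≈ −0.33 e) with a coordination correction
  $\chi_i(\mathrm{CN}) = \chi_i - \kappa_i\sqrt{\mathrm{CN}_i}$. The
  constrained minimization is solved as a bordered symmetric linear system;
  condition numbers beyond $10^{12}$ raise an error naming the geometry;
* reference polarizabilities per coordination state with a one-oscillator
  (Drude/London) frequency dependence whose effective frequency reproduces
  the published free-atom $C_6$ through the London relation
  $C_6 = \tfrac34\alpha_0^2\omega_0$; charge dependence enters through a
  saturating exponential scaling that grows for anionic and shrinks for
  cationic atoms;
* $\sqrt{Q}$ factors from the standard
  $Q = \tfrac12\sqrt{Z}\,\langle r^4\rangle/\langle r^2\rangle$ multipole
  ratios.

The Casimir–Polder integral uses a fixed 32-node Gauss–Legendre grid mapped
to $[0,\infty)$, stored in the tables so every $C_6$ in a session shares
it; the quadrature reproduces the analytic London value to better than
$10^{-6}$ relative. The table format is plain R data, documented so more
elements can be added. Because the tables are not those of any published
dispersion parameterization, energies are *model-consistent* within this
package (and with any engine through the cache) but not numerically
interchangeable with other dispersion implementations.

## Fitting

`fit_dc4()` minimizes MAE (or WTMAD-2) over the free parameters — by
default $\{s_8, a_1, a_2\}$ with $s_6$ fixed at 1, the standard choice for
functionals with correct asymptotics, and no three-body term — inside the
box $s_8\in[0,3]$, $a_1\in[0,1]$, $a_2\in[0,8]$ Bohr. Because the base
energies and the pair data ($R$, $C_6$, $C_8$) are parameter-independent,
they are computed once per species and every objective evaluation is a
vectorized damped pair sum, which makes refits essentially free.

The optimizer is a seeded multi-start bounded local search: box-constrained
quasi-Newton (L-BFGS-B) from the box centre plus uniformly drawn starts,
followed by a derivative-free Nelder–Mead polish (Brent in one dimension),
since an L1 objective is only piecewise smooth. Starts tied within
$10^{-9}$ are resolved by the lexicographically smallest parameter vector,
so results are reproducible bit-for-bit given the seed. The validation set
is evaluated exactly once, after optimization; the fit object records the
objective call count and the validation call count so this separation is
checkable, and the report carries an exclusion ledger (tag + reason,
DS or spin) that partitions the input set.

## Synthetic study conditions

`generate_toy_dataset()` builds association reactions — water dimers over
O–O distances 2.7–5.5 Å, alternating with mixed closed-shell diatomic
pairs (H₂, N₂, CO) at 3.2–6.0 Å — whose reference energies are the toy
base energy plus an *exact* dispersion tail computed with known
parameters, recorded in the provenance. This makes parameter recovery a
well-posed oracle: a correct fitter must return the generating values.

Three generator knobs define the harder study conditions:

* **Density sensitivity** concentrates on the water-cluster reactions
  (assigned to them first), mirroring the empirical situation where
  density-driven errors concentrate in water-cluster binding energies. The
  default knob $\delta = 0.02$ Eh gives $\tilde S \approx 14$ kcal/mol —
  far past the 2 kcal/mol cutoff, within the range water-cluster
  sensitivities reach — and leaves a ≈ 1.3 kcal/mol residual bias on the
  HF density.
* **Reference noise** of 0.05 kcal/mol models the irreducible functional
  error. It matters for the naive-fit comparison: with a noiseless,
  exactly realizable clean subset, an L1 objective is robust enough to
  ignore a minority of biased reactions entirely, and the contrast between
  training protocols collapses to zero. Real fits are compromises; the
  noise restores that.
* **DS fraction** 0.4 for the protocol-contrast experiments, so the biased
  reactions form the majority of the water dataset, as they do in the
  benchmark sets that motivated the DI-exclusion rule.

Under these conditions the DI-filtered MAE fit recovers the generating
parameters and holds the validation (clean water-dimer) MAE at the noise
floor, while the naive all-reaction WTMAD-2 fit visibly skews the
parameters and degrades validation MAE by factors of ~2–10 depending on
the seed — the mechanism behind the poor water performance of
dispersion corrections fitted without DC-DFT principles.

What the generator does *not* emulate: MD-ensemble dimer geometries (only
the O–O distance scan structure of such data), optimized cluster
geometries (ring placements with random monomer orientations stand in for
hexamer topologies), basis-set effects, and any correlation between noise
and system size. Passing tests therefore demonstrate algorithmic
correctness and the training-protocol mechanism on a controlled model, not
quantitative transferability to real water benchmarks — for that, plug a
real engine (or its cached energies) into the same pipeline.

## Many-body expansion

`mbe_decompose()` uses the standard inclusion–exclusion definition
$\varepsilon(S) = E(S) - \sum_{T\subsetneq S}\varepsilon(T)$ over fragment
subsets at frozen in-cluster monomer geometries (no relaxation — the usual
convention, stated here because it is often left implicit), with
$\varepsilon_K = \sum_{|S|=K}\varepsilon(S)$. Enumeration is exhaustive
with memoized subset energies. Internally the recursion runs on
monomer-subtracted subset energies, which leaves every $\varepsilon_K$
($K\ge2$) unchanged in exact arithmetic but avoids the catastrophic
cancellation of total energies of order $10^2$ Eh; the sum identity
$\sum_K \varepsilon_K = E_\text{int}$ then holds to $10^{-10}$ kcal/mol
on hexamers. Counterpoise treatment of subcluster energies is deliberately
out of scope for the toy engine and configuration-gated in spirit for real
engines (no counterpoise by default).

## Benchmark metrics

`water_metric()` pools the per-reaction errors of the five water-based
dataset tags (hexamer isomers, larger-cluster isomers, cluster binding,
water–small-molecule interactions, water dimers) and takes one MAE over
the pooled list — pooling, not averaging of dataset MAEs, is the defining
choice. `wtmad2()` implements
$\mathrm{WTMAD\text{-}2} = \sum_i N_i\,(56.84/\overline{|\Delta E|}_i)\,\mathrm{MAD}_i \,/\, \sum_i N_i$,
the weighting defined for the GMTKN55 collection. Failed reactions are
excluded from every metric with a mandatory count in the report — silent
dropping is forbidden by construction.

## Numerical choices and degenerate inputs

* Units: Å in all I/O, Bohr internally; Hartree internally, kcal/mol in
  all reports (1 Å = 1.8897259886 Bohr, 1 Eh = 627.509474 kcal/mol).
* Molecules are validated on construction: element coverage, coordinate
  shape, charge/multiplicity parity, and a 0.3 Å minimum separation.
* All generators are pure functions of (arguments, seed), driven by an
  isolated Mersenne–Twister stream that never touches the global RNG
  state. `perturb_cluster()` resamples clashing draws up to a bounded
  retry count, then errors.
* No distance cutoffs in the dispersion sums — systems here are small
  and exactness is worth more than speed; the three-body term is off by
  default and $s_9$ is conventionally 1 when enabled.
* Problem sizes used by the test-suite and the acceptance script (toy
  sets of 10–60 reactions, clusters up to 10 monomers, 20-seed noise
  sweeps) were chosen to make every check a few seconds to a few minutes
  on one core while keeping the statistical properties interpretable.

## Known limitations

* Reference tables cover H, C, N, O only; other elements error out
  loudly.
* The default dispersion parameters are placeholders of typical magnitude,
  not a fitted set for any particular functional: deriving parameters is
  what `fit_dc4()` is for, and fitted values should be shipped with their
  provenance (`write_d4_params()` stores it).
* No analytic gradients, no periodic systems, no D3-style variants.
* The toy engine's density-error model is linear by design; it can show
  that the machinery behaves correctly, not how large density-driven
  errors are in any real system.
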