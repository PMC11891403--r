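---
title: "Substrate competition between acyl-ACP and acyl-CoA at the acyltransferases: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrate competition between acyl-ACP and acyl-CoA at the acyltransferases: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the model addresses

When *E. coli* is fed long-chain fatty acids, the acyl-CoA thioesters made
from them by FadD enter the phospholipid synthesis pathway through the
acyltransferases PlsB (sn-1 of glycerol-3-phosphate) and PlsC (sn-2 of
lysophosphatidic acid), the same enzymes that consume the acyl-ACP products
of de-novo fatty acid synthesis. Within about a minute of feeding, long-chain
acyl-ACP accumulate and malonyl-ACP falls by roughly half — far too fast for
transcription. `acylsim` implements the kinetic explanation: acyl-CoA
competes with acyl-ACP for the acyltransferase active sites, the unconsumed
long-chain acyl-ACP pool grows, and that pool feedback-inhibits the first
committed step of fatty acid synthesis (acetyl-CoA carboxylase, ACC). The
demand side of phospholipid synthesis thereby keeps control of synthesis flux
no matter how much exogenous fatty acid is available.

## Model structure

The fatty-acid pathway is reduced to initiation and elongation:

* **ACC-FabD** (lumped): holo-ACP + acetyl-CoA → malonyl-ACP, two-substrate
  irreversible Michaelis–Menten with a noncompetitive inhibition factor
  $1/(1+(\mathrm{LC}/K_i)^n)$, where LC is the summed concentration of *free*
  C16:0, C16:1, C18:0 and C18:1 acyl-ACP (enzyme-bound thioesters excluded —
  these are the species that accumulate in the experiments).
* **FabH**: malonyl-ACP + acetyl-CoA → C4:0-ACP (chain start).
* **Elongation** ("FabB/FabF" combined): Cn-ACP + malonyl-ACP →
  C(n+2)-ACP + holo-ACP, one generic reaction per step with a per-product
  preference weight in (0, 1] encoding chain-length specificity; weights are
  ~1 up to C16 and very small for the C16→C18 steps, which is what terminates
  chains at 16–18 carbons.
* **Branch at C10:0-ACP**: two parallel reactions consume the common C10:0
  substrate — continued saturated elongation, and a single-substrate
  isomerization into C10:1-ACP committing flux to the unsaturated branch
  (the in-vivo FabA/FabB pair, phenomenologically).
* **Acyltransferases**: for each substrate in
  {C16:0, C16:1, C18:1} × {ACP, CoA}, explicit binding
  ($k_{on}[E][S]$), unbinding ($k_{off}[ES]$) and catalysis
  ($k_{cat}[ES] \cdot \mathrm{acceptor\ saturation}$) steps. Substrate
  preference (PlsB disfavors C16:1, PlsC disfavors C16:0) is implemented
  purely by reduced $k_{on}$. Catalysis by PlsB carries a phospholipid
  feedback factor $1/(1+(\mathrm{PL}/K_{PL})^{h})$ so total lipid flux is
  homeostatic. PlsC partitions its flux over the LPA acceptor species
  competitively (each LPA weighted by its concentration over a shared
  Michaelis term).
* **Lipids**: LPA (by sn-1 chain), PA and PL (by ordered sn-1/sn-2 chain
  pair); PA → PL is first order; LPA, PA and PL are diluted at
  $\mu = \ln 2 / 2500\,\mathrm{s^{-1}}$ (a ~42 min doubling), which gives the
  pre-feeding network a genuine steady state.

Acetyl-CoA, G3P and the three acyl-CoA species are clamped boundary species.
ACP, PlsB and PlsC moieties are conserved exactly by construction (the
conservation vectors lie in the left null space of the stoichiometry matrix),
and the test suite verifies drift below $10^{-6}$ relative along
trajectories.

Two modeling choices deserve emphasis:

* **C18:0-ACP turnover.** C18:0-ACP is not an acyltransferase substrate, so
  in the bare network it would be a dead-end sink and no steady state could
  exist. A slow first-order hydrolysis (0.01 s⁻¹) returns its ACP,
  representing thioesterase-like turnover and consumption by other lipid
  pathways. C18:0-ACP still rises after palmitate feeding, as observed.
* **Feeding as a clamp.** The 0.8 mM external fatty-acid reservoir is large
  compared with consumption, so feeding is modeled as a stepwise clamp of the
  corresponding intracellular acyl-CoA (default step at $t = 8000$ s), not a
  depleting bolus. Default post-step clamp values (20, 8 and 12 µM for
  C16:0-, C16:1- and C18:1-CoA) are calibration choices: intracellular
  acyl-CoA concentrations under feeding are not reported.

## Units, parameters and calibration

All concentrations are µM, time is in seconds. The full default parameter
set is documented in `?fa_default_params`. Enzyme totals are 1 µM each for
PlsB and PlsC and 200 µM total ACP, matching the intracellular scale where
ACP is one of the most abundant proteins and the acyltransferases are scarce.

The parameters were calibrated — once, against the experimental anchors, in
the order below — and then frozen:

1. the pre-feeding steady state has a PlsB acyl-ACP substrate-pool C16:0
   fraction $[\mathrm{C16{:}0\ ACP}]/([\mathrm{C16{:}0\ ACP}]+[\mathrm{C18{:}1\ ACP}])
   \approx 0.8$, with C18:0-ACP and C18:1-ACP minor pools;
2. palmitate feeding roughly doubles C16:0-ACP and roughly halves
   malonyl-ACP in the immediate (60–300 s) window;
3. unsaturated feeding raises C18:1-ACP about five-fold and roughly halves
   malonyl-ACP;
4. cis-vaccenate raises both the saturated and the unsaturated long-chain
   pools.

Two calibration findings became structural defaults:

* **Hill coefficient 2 for the ACC feedback.** With $n = 1$ the inhibition
  factor after feeding is bounded below by
  $\mathrm{LC}_{pre}/\mathrm{LC}_{post}$; since the free long-chain pool
  rises less than two-fold under palmitate (unsaturated pools partly fall),
  no choice of $K_i$ or $V_{max}$ can halve malonyl-ACP. A mildly
  cooperative term ($n = 2$, $K_i = 1.1$ µM) reproduces the observed drop.
  Acyl-ACP inhibition of ACC in vitro is consistent with tight, effectively
  ultrasensitive inhibition, so this is not biochemically exotic.
* **A nearly substrate-saturated C16:1 → C18:1 elongation step** (its own
  Michaelis constant 0.15 µM against 5 µM elsewhere). This buffers
  malonyl-ACP demand against swings of the C16:1 pool, so that when the ACC
  feedback is removed the malonyl-ACP response to feeding nearly vanishes —
  the property that isolates the feedback as *the* mechanism. It also keeps
  the loop stable: with elongation fully malonyl-saturated everywhere the
  delayed negative feedback develops a limit cycle, and with km_malonyl well
  above the malonyl level the branch ratio drifts; km_malonyl = 0.5 µM with
  malonyl ≈ 1.1 µM damps the loop while preserving responsiveness.

## Feedback knockout

`remove_acc_feedback(model, state)` removes the long-chain inhibition
($K_i \to \infty$) while rescaling ACC's $V_{max}$ by the inhibition factor
prevailing at the given state, so the baseline steady state is preserved
exactly. This is the standard control-analysis knockout at an operating
point. A naive $K_i \to \infty$ without rescaling instead moves the system
into a regime where holo-ACP is nearly exhausted and every response is
dominated by ACP-pool redistribution — a different model, not an isolation
of the feedback. With the operating-point knockout, the malonyl-ACP
fold change under all three feedings stays within 2% of 1.

## Numerics

Stiff integration uses `deSolve::lsoda` with rtol $10^{-9}$ and atol
$10^{-13}$; halving both changes trajectories by under $10^{-6}$ relative
(measured ≈ $2\times10^{-8}$). Rates are evaluated on the nonnegative part
of the state, which leaves the conservation laws untouched; solver output
never dips below $-10^{-9}$ µM. The steady state is found by long
integration in doubling chunks with the residual criterion
$\max_i |\dot x_i|/(|x_i|+10^{-6}) < 10^{-8}$ over non-clamped species
(root-finding is avoided because the conserved moieties make the Jacobian
singular). Feeding runs restart the integrator exactly at the step time.
The default reporting grid is 200 s before the step, 10 s for the first
10 min after it and 60 s thereafter out to one hour — fine enough to resolve
the ~1 min response the experiments show.

## The synthetic LCMS generator

`simulate_lcms_counts()` emulates the structure, not the physics, of the
targeted LCMS measurements: per-analyte count series at sampled times, a
shared internal-normalizer channel per injection (the nonacylated-ACP
peptide; its abundance tracks conserved total ACP and is therefore flat),
two biological replicates, at least three pre-feeding baseline samples, and
multiplicative lognormal noise (default CV 0.15, mean-corrected so expected
counts are proportional to concentration). The default CV is a modeling
choice — replicate scatter is not quantified in the source data.
`simulate_protein_response()` is a saturating-exponential stand-in for the
slow transcriptional induction of FabB (95% of the rise at ~2 h); no
mechanistic transcription model is attempted. What passes on these data
therefore shows that the *analysis pipeline* is correct and that fold
changes of the simulated magnitude survive realistic replicate noise — it
says nothing about chromatographic artifacts, ionization suppression or
isotope-standard behavior in real data.

Analysis conventions follow the experimental ones: counts are divided by the
normalizer, then by the mean of the pre-treatment samples (pooled across
replicates by default; per-replicate baselines behind a flag, since the
source convention is not stated); the PlsB pool fraction counts acyl-ACP
only (acyl-CoA inclusion behind a flag); Welch's t-test (unequal variances,
two-tailed) is used for condition comparisons, and p-values are reported raw.

## Problem sizes

The shipped analyses and tests run the full 55-species model: one
steady-state search (≈ 6×10⁴ s of model time), four feeding experiments
(1 h post-step window each), three knockout runs, and synthetic datasets of
2 replicates × 13 time points. These sizes reproduce the reported
magnitudes; nothing in the method depends on them.

## Known limitations

* No hydroxy-/enoyl-ACP intermediates or FabI step, so responses of those
  flux-sensitive pools (and triclosan or mupirocin perturbations) are out of
  scope; no β-oxidation chain shortening of C18:1-CoA; PG/PE headgroup
  chemistry is lumped into one phospholipid sink.
* Transcriptional adaptation (FabA/FabB via FadR/FabR) is represented only
  by the phenomenological induction curve in the synthetic-data module; the
  kinetic model describes the first post-translational hour.
* Whether the PlsB feedback is inhibition by phospholipid level or a flux
  controller is not settled; level inhibition plus growth dilution is used
  here because it yields the same fixed flux at steady state with one fewer
  mechanism. The alternative changes nothing qualitative in the feeding
  window (the PL pool moves by ~10% in an hour).

```{r example}
library(acylsim)
model <- build_model()
ss <- find_steady_state(model)
plsb_substrate_fraction(ss)
traj <- run_feeding_experiment(model, "palmitate", steady_state = ss)
fold_change_at(traj, "C16:0_ACP")    # ~2
fold_change_at(traj, "malonyl_ACP")  # ~0.5
```
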