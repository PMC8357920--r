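---
title: "Charge- and spin-conditioned neural potentials with spin-charge equilibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge- and spin-conditioned neural potentials with spin-charge equilibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neqnet)
```

## The problem

Neural interatomic potentials map a molecular geometry to a total energy by
summing learned atomic contributions over local, symmetry-invariant
descriptors.  Classic models of this family are parametrized for a single
electronic state: they cannot distinguish a cation from an anion of the same
conformer, because the descriptors depend on geometry only.  `neqnet`
implements a family of models that take the total molecular charge and spin
multiplicity as *inputs* and return, besides the energy, per-atom
spin-resolved partial charges that sum to the requested molecular spin
charges *by construction*.  From three such predictions at a fixed geometry
(cation, neutral, anion) the package derives vertical ionization potentials
and electron affinities and the standard conceptual-DFT reactivity
descriptors, plus per-atom site features for modelling electrophilic
aromatic substitution (EAS) regioselectivity.

## Model

**Featurization.**  Each atom's environment is encoded by two-body radial
symmetry functions (a Gaussian expansion of interatomic distances) and
three-body angular functions (a joint Gaussian expansion of the mean
distance to a neighbour pair and a sharpened cosine expansion of the
subtended angle), all damped by a cosine cutoff
$f_c(R) = \tfrac12(\cos(\pi R/R_c)+1)$:

$$ g^{(r)}_{ij,s} = e^{-\eta_r (R_{ij}-R_s)^2} f_c(R_{ij}), \qquad
   g^{(a)}_{ijk,s,t} = 2^{1-\zeta}\,(1+\cos(\theta_{ijk}-\theta_t))^{\zeta}\,
   e^{-\eta_a\left(\frac{R_{ij}+R_{ik}}{2}-R_s\right)^2}
   f_c(R_{ij})\,f_c(R_{ik}). $$

Instead of routing these sums through one-hot species channels, the raw
functions are contracted with learnable per-element *atomic feature vectors*
(AFVs): the radial block of atom $i$ is $\sum_j g^{(r)}_{ij} \otimes A_j$ and
the angular block uses the symmetric pair reduction $A_j + A_k$.  With
one-hot AFVs this reduces exactly to the per-species construction, which is
how the featurizer is validated (a brute-force per-species loop is kept as
an independent oracle in the test suite).

**Iterative passes.**  One pass maps the concatenation of the environment
embedding and the atom's own AFV through a shared interaction MLP to a joint
latent atom-in-molecule (AIM) vector, from which small heads predict the
atomic energy $E_i$, raw spin charges $\tilde q^s_i$, and positive weights
$f^s_i$.  The weights and charges of a pass are folded back into the AFVs by
a learned affine update, and the next pass re-featurizes with the updated
AFVs.  All blocks share weights across passes; three passes are the
default.  The first pass runs with the element AFVs (no charge information),
so only later passes can be conditioned on the requested state.

**Spin-charge equilibration (NSE).**  The raw charges of each spin channel
$s \in \{\alpha, \beta\}$ are renormalized against the requested molecular
spin charge $Q^s$:

$$ q^s_i = \tilde q^s_i + \frac{f^s_i}{\sum_j f^s_j}
   \left( Q^s - \sum_j \tilde q^s_j \right), $$

which conserves $\sum_i q^s_i = Q^s$ for *any* network weights -- an
architectural guarantee, not a training outcome.  The weights $f$ have the
meaning of atomic Fukui functions, $\partial q_i/\partial Q = f_i/\sum f$;
they are kept strictly positive by a softplus transform (plus a floor of
$10^{-4}$) because the formula divides by their sum.  Channels are
equilibrated independently.  The spin-state convention is
$Q^\alpha = (Q - (M-1))/2$, $Q^\beta = (Q + (M-1))/2$ with $M$ the
multiplicity: the $\alpha$ channel carries the excess unpaired electrons and
therefore the more negative channel charge.  Any consistent convention
works; this one is fixed throughout the package, including the surrogate
generator.

**Variants.**  Four architectures are exposed for comparison: `ani`
(one-hot AFVs, per-element energy heads, single pass, no charges), `aimnet`
(single-state, learnable AFVs and passes), `aimnet_mt` (multitask heads for
the fixed state set cation/neutral/anion from a shared trunk; charge sums
are *not* constrained), and `aimnet_nse` (the charge-conditioned model with
the equilibration unit).

## Conceptual-DFT descriptors

With three forward passes at fixed geometry the package computes vertical
$\mathrm{IP} = E_{\mathrm{cat}} - E_{\mathrm{neu}}$ and
$\mathrm{EA} = E_{\mathrm{neu}} - E_{\mathrm{an}}$, and from them
$\mu = -(\mathrm{IP}+\mathrm{EA})/2$, $\chi = -\mu$,
$\eta = (\mathrm{IP}-\mathrm{EA})/2$, $\omega = \mu^2/2\eta$; condensed
Fukui functions $f^-_a = q_a^{\mathrm{cat}} - q_a^{\mathrm{neu}}$,
$f^+_a = q_a^{\mathrm{neu}} - q_a^{\mathrm{an}}$,
$f^0_a = (f^-_a + f^+_a)/2$; and philicity indexes
$\omega^x_a = \omega f^x_a$.  Two sign conventions deserve a note: hardness
is implemented as $+(\mathrm{IP}-\mathrm{EA})/2$ (positive whenever
IP > EA, which makes $\omega$ positive), and the radical Fukui function as
the *difference* $(q^{\mathrm{cat}}_a - q^{\mathrm{an}}_a)/2$.  Printed
variants with the opposite hardness sign, or with a sum instead of the
difference, circulate in the literature; they break positivity and the
$\sum_a f_a = 1$ normalization, so the package deliberately uses the
standard finite-difference forms.  When the inputs are NSE-conserved
charges the normalizations $\sum_a f^x_a = 1$ and
$\sum_a \omega^x_a = \omega$ hold to $10^{-8}$ regardless of training
state; both are tested.

Ion radicals of closed-shell parents are treated as doublets.  The EAS site
descriptor of a query atom concatenates $\omega$, $\omega^-_a$, and the
atom's AIM vector from the forward pass of the molecule's cation-radical
form (length `d_aim + 2`); training the downstream classifier is out of
scope.

## The physics surrogate

Real training data for such models comes from large-scale quantum
chemistry.  At desk scale the package substitutes a deterministic
electronegativity-equalization (QEq-style) energy model: per spin channel,
charges minimize

$$ \sum_i (\chi_{Z_i} \pm s_{Z_i}) q_i + \tfrac12 \sum_i \eta_{Z_i} q_i^2
 + \tfrac12 \sum_{i \ne j} J(R_{ij}) q_i q_j
 \quad \text{s.t.} \quad \sum_i q_i = Q^s, $$

solved exactly via the KKT linear system.  $J(R) = k_e/(R^3+\gamma^3)^{1/3}$
is a shielded Coulomb kernel; the shielding
$\gamma_{ij} = 4k_e/(\eta_i+\eta_j)$ caps its on-site limit at
$(\eta_i+\eta_j)/4$, which keeps the quadratic form positive definite for
arbitrary geometries (with radius-based shielding the matrix can go
indefinite and the constrained solution becomes unphysical).  The
per-element spin shift $s_Z$ enters the two channels with opposite signs for
open-shell states only, giving ion radicals a nontrivial spin-density
pattern.  The total energy adds per-element self-energies, harmonic bond
springs and a short-range exponential repulsion.

Because the per-channel problems are quadratic in the constraint, the
surrogate's left and right charge derivatives coincide: its condensed
$f^-_a$ and $f^+_a$ are equal by construction.  That makes the surrogate a
clean recovery target but means tests on it cannot discriminate asymmetric
Fukui behaviour -- a known limitation relative to real electronic-structure
labels, along with the absence of bond breaking, conformational barriers
and any anharmonicity beyond the repulsion term.

The generator builds random tree-bonded molecules over {H, C, N, O} by
default (valences C:4, N:3, O:2, H:1, hydrogens fill open valence, electron
counts forced even so neutral parents are singlets), perturbs each
equilibrium-like geometry with 0.05--0.15 Å Gaussian coordinate noise as its
molecular-dynamics stand-in, and labels every conformer in the neighbouring
charge states of its parent (−1, 0, +1 for neutral parents), ions as
doublets.  The geometric energy constants are deliberately thermal-scale:
with 0.1 Å-class displacements, the default spring constant of 3 eV/Å²
keeps per-bond strain at a few $k_BT$, which is what "near-equilibrium
sampling" means physically; stiff real-bond springs under displacements of
this size would produce conformers tens of eV above the minimum.  Label
noise defaults are σ_E = 0.01 eV on energies and σ_q = 0.005 e per
atom-channel; the charge noise is drawn zero-sum per channel so that even
noisy labels conserve the channel charges exactly, like charges derived
from a wavefunction population analysis would.

## Training protocol

Minibatches are composed of molecules with the same atom count, so no
padding is ever needed; batch composition is formed once per run (seeded)
and only the batch order is reshuffled across epochs, which lets the
geometry-dependent contraction operators be computed once per conformer.
The objective is a weighted multi-target MSE over passes,
$L = \sum_t w_t [w_E\,\mathrm{MSE}(E^t) + w_q\,\mathrm{MSE}(q^t)]$ with
defaults $w_E = 1$ (per molecule, eV²) and $w_q = 100$ (per atom-channel,
e²; charges are roughly two orders of magnitude smaller in scale).  For the
NSE variant only the last two passes enter the loss, since the first pass
is not charge-conditioned; for the other variants all passes contribute,
which regularizes the earlier iterations.  Optimization is Adam with a
reduce-on-plateau schedule (factor 0.5, patience 10 epochs, floor
$10^{-5}$) and global L2 gradient-norm clipping (default threshold 5),
which removes the occasional large-minibatch spikes that otherwise undo
several epochs of progress.  Per-element self-energies are fitted by linear regression on
the training composition before optimization and added back at inference,
so the network learns size-intensive residuals.  A fixed per-feature RMS
scaling of the embedding, estimated once at the initial AFVs, conditions
the optimization; it is a constant diagonal layer stored in the checkpoint.
Validation molecules are held out by molecule identity, so all charge
states and conformers of a molecule fall on the same side of the split;
k-fold utilities and ensemble averaging (arithmetic mean of member
energies and charges, which preserves conservation) support the usual
cross-validated ensemble workflow.

Numerical choices worth knowing: the activation is SiLU
($x\,\sigma(x)$ -- smooth and non-saturating, with its sigmoid factor
cached so the backward pass needs no extra transcendentals); weights are
initialized from scaled normal distributions with zero biases, seeded from
the config; gradients of every block, including the equilibration unit and
the cross-pass AFV update chain, are analytic and verified against central
finite differences in the test suite; a non-finite loss aborts training
with a diagnostic rather than continuing silently.

## Problem sizes used by the checks

The recovery experiment in the test suite trains on 2,000 generated
molecules (≤ 8 heavy atoms, three charge states each, one conformer per
molecule — 6,000 labelled samples) with a d_afv = 16, d_aim = 64, t = 3
model, and evaluates held-out charge and energy RMSE, IP/EA accuracy
against the surrogate oracle, the pass-3 vs pass-1 error trend, and the
ensemble (Jensen) property with a 3-member ensemble; `scripts/acceptance.R`
runs a 900-molecule version of the same pipeline end to end.  These sizes
are the package's chosen desk-scale study conditions.  What passing them
shows is parameter recovery against a smooth, conservative, deterministic
oracle; it does not certify accuracy on real quantum-chemical data, where
labels are noisier, interactions longer-ranged and chemistry far more
diverse.

## Known limitations

At the desk-scale data sizes above, held-out charges and the vertical
IP/EA (energy *differences* at fixed geometry) converge well before
held-out absolute energies do: long-schedule convergence probes plateau
with the absolute-energy error several times larger than the
charge-implied scale, dominated by a generalization gap on the geometric
energy terms rather than by the state dependence.  Absolute energies are
the quantity to treat most cautiously from a model trained at this scale.

No forces or gradients with respect to coordinates are exposed (no MD); no
periodic boundary conditions; no explicit long-range electrostatics beyond
what equilibration carries implicitly; the multitask variant's charge sums
are only approximately integral, by design; SMILES handling, 3D embedding
and conformer optimization are out of scope.
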