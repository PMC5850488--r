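---
title: "Modeling joint sequence and dihedral-angle evolution in homologous protein pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling joint sequence and dihedral-angle evolution in homologous protein pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torusevol)
```

## The model

`torusevol` is a generative probabilistic model of local protein sequence
and structure evolution for a pair of homologous proteins $p_a$ and $p_b$
separated by an evolutionary time $t_{ab}$. Each aligned site $i$ carries
up to three observation pairs: amino acids $(A_a^i, A_b^i)$, backbone
dihedral angles $X^i = (\phi^i, \psi^i)$ on the torus
$\mathbb{T}^2 = [-\pi, \pi)^2$, and a three-class secondary-structure
label (helix H, sheet S, coil C). A hidden Markov chain over the
alignment couples neighboring sites; each hidden state specifies a
distribution over a pair of *site-classes*, and each site-class bundles
the parameters of three conditionally independent, time-reversible
processes:

* **Amino acids** evolve by a reversible CTMC $Q_r = \Lambda_r S \Pi_r$,
  with a global symmetric exchangeability matrix $S$ (190 free
  parameters), site-class equilibrium frequencies $\Pi_r$ (19 free
  parameters each) and a site-class rate multiplier $\Lambda_r$.
* **Secondary structure** evolves by a reversible 3-state CTMC
  $R_r = V\,\Omega_r$ with a global exchangeability $V$ and site-class
  equilibria $\Omega_r$.
* **Dihedral angles** evolve by a wrapped-normal (WN) diffusion on
  $\mathbb{T}^2$, the torus analogue of the Ornstein-Uhlenbeck process,
  with drift matrix
  $A = \begin{pmatrix}\alpha_1 & \alpha_3\sigma_1/\sigma_2\\
  \alpha_3\sigma_2/\sigma_1 & \alpha_2\end{pmatrix}$ and infinitesimal
  covariance $\Sigma = \mathrm{diag}(\sigma_1^2, \sigma_2^2)$, subject
  to $\alpha_1\alpha_2 > \alpha_3^2$ so that the stationary law is a
  wrapped bivariate normal with covariance $\tfrac12 A^{-1}\Sigma$.

The likelihood of a site observation pair factorizes over the three
observation types given the hidden state, the site-class pair and
$t_{ab}$. This factorization is what makes missing data cheap: a factor
is dropped when a field is unobserved on both sides and replaced by a
single-sided stationary density when observed on one side only.

### The WN diffusion and its pseudo transition density

The exact transition density of the WN diffusion is intractable; the
package uses the standard winding-weighted approximation: a mixture over
winding numbers $m \in \mathbb{Z}^2$ of wrapped Gaussians with means
$\mu_t^m = \mu + e^{-tA}(\theta_1 - \mu + 2\pi m)$ and common covariance
$\Gamma_t = \int_0^t e^{-sA}\Sigma e^{-sA^\top}ds$, with weights
proportional to the stationary Gaussian density of the corresponding
winding copy at $\theta_1$. The approximation is exact in the three
regimes that matter: $t \to 0$ (Dirac collapse), $t \to \infty$
(stationary law) and high concentration, and it satisfies the
time-reversibility identity with respect to the stationary law exactly
(machine precision in the implementation; the test suite checks
$10^{-8}$). Its known deficiency is in the far tails at intermediate
times, which is why the Euler-Maruyama cross-check in the test suite
compares only cells carrying at least $10^{-3}$ probability mass.

Numerical choices: $\Gamma_t$ is computed in closed form as
$\Gamma_\infty - e^{-tA}\Gamma_\infty e^{-tA^\top}$ with
$\Gamma_\infty = \tfrac12 A^{-1}\Sigma$; the $2\times 2$ matrix
exponential uses the exact trace-determinant closed form (a general Padé
routine was measured at only $\sim 3\times10^{-8}$ accuracy here, which
is not good enough for the reversibility identity). The infinite winding
sums are truncated to $k \in \{-K..K\}^2$; the default $K = 1$ (nine
windings) is accurate to well below likelihood-relevant precision for
angular scales typical of backbone dihedrals, and $K = 2$ is used in the
quadrature-based unit tests. $K$ is exposed on every density and on the
model container.

### Site-classes, jump events and their kernel

Each hidden state holds two site-classes with equilibrium $(\pi_1,
\pi_2)$ and a jump rate $\gamma > 0$. At a site, both proteins either
share one site-class (*constant evolution*: all three factors use their
time-$t$ transition kernels) or differ (*jump event*: both sides draw
independently from their own class's stationary laws, a likelihood that
no longer depends on $t$). Jumps couple sequence and structure
directionally: a class switch can simultaneously move the amino-acid
preferences and the dihedral basin.

The site-class pair kernel implemented is
$$p(r_a \mid r_b, t) = e^{-\gamma t}\,\mathbb{1}[r_a = r_b] +
\pi_{r_a}\,(1 - e^{-\gamma t}),$$
the two-state reversible jump chain. It normalizes over $r_a$, satisfies
detailed balance (hence the two discordant-pair probabilities coincide
for all $t$, for any $(\pi_1, \pi_2)$), and yields $(\pi_1, 0, 0,
\pi_2)$ at $t = 0$ and independence as $t \to \infty$. The index placed
on $\pi$ matters: putting the *conditioning* class's equilibrium there
would neither normalize nor be reversible when $\pi_1 \neq \pi_2$, so
the kernel above is the coherent reading and the one whose discordant
curves superimpose exactly, as required.

Two site-classes per hidden state are supported; the likelihood code
enumerates the four class pairs explicitly and is tested against
brute-force four-term sums.

### The HMM, alignment, and TKF92

For a fixed alignment the likelihood is a standard forward recursion
over hidden states, $O(mh^2)$ for $m$ columns and $h$ states, in log
space with per-site rescaling. Insertion and deletion columns emit the
single-sided stationary mixture over the state's two site-classes.

When the alignment is unobserved it is marginalized under a TKF92
fragment insertion-deletion prior: a pair HMM with states M/D/I built
from the classic birth function $\beta(t)$, survival probability
$\alpha = e^{-\mu t}$ and fragment-extension probability $r$ (a
self-loop on each state); $r = 0$ recovers TKF91. The joint dynamic
program runs over (residue index in $p_a$, residue index in $p_b$,
pair-HMM state, hidden state), $O(|p_a||p_b|h^2)$. Hidden-state
transitions are applied between consecutive *emitted columns* regardless
of column type — the natural reading of "neighboring dependencies at
adjacent alignment sites" — rather than letting the hidden state persist
silently through indel runs; this keeps the DP exact and is the choice
the enumeration tests pin down. MAP alignments use joint Viterbi over
(column path, hidden state), which is deterministic; posterior samples
of alignments use stochastic backtrace of the summed DP. For $h > 1$
the joint Viterbi optimum can in principle differ from the
alignment-marginal optimum; the exact-argmax tests therefore use
$h = 1$ instances, and for $h > 1$ the MAP's posterior weight is
checked to dominate 1,000 posterior samples.

Default indel parameters tie $\lambda/\mu$ to the observed mean sequence
length via $E[\text{length}] = \frac{\lambda}{\mu - \lambda}
\cdot\frac{1}{1 - r}$ with $r = 0.5$; all three are exposed.

### Estimation

**Evolutionary time** is estimated by bounded one-dimensional
maximization of the (fixed-alignment or alignment-marginal)
log-likelihood on $\log t \in [\log 10^{-4}, \log 20]$, using any subset
of the observation tracks. Recovery tests simulate at $t = 0.3$ and
require the median estimate from 20 replicates of 300 sites to fall
within 15% for sequence-only and angle-only subsets alike.

**Model fitting** uses stochastic EM. Initialization is data-driven, as
is standard for mixture-flavored HMMs: the pooled dihedral observations
are clustered by k-means on their (cos, sin) circle embedding into 2h
centers, and the centers are paired into per-state (class 1, class 2)
seeds using the cross-cluster flux of strongly discordant sites — sites
whose two sides fall in different clusters more than 1 radian apart are
candidate jump events, and the cluster pairs they connect most often
become the hidden states' class pairs. This seeds both the basins and
the jump structure, which a few stochastic-EM iterations then refine;
with random initialization the fits frequently stall in local optima
that misassign basins to classes (in particular, modes in which one
state splits a basin pair across two states, which plain stochastic EM
escapes only over many iterations). Centers closer than 0.9 rad in the
chord metric are merged first — halves of one over-split basin sit well
below that scale, distinct Ramachandran basins above it. The E-step
samples hidden paths by forward-filter backward-sampling and site-class
pairs from their per-site posteriors; these sampled assignments drive
the emission-parameter updates. The chain-structure parameters are
Rao-Blackwellised: the hidden transition matrix uses exact
forward-backward expected transition counts, and each state's class
equilibrium and jump rate use the exact posterior expected class-pair
counts (grouped by evolutionary time; the jump rate is then a 1-D MLE
over those counts), which converges markedly faster than hard sampled
counts. The remaining M-step updates are closed-form counts (+0.5
smoothing) for the amino-acid/secondary-structure equilibria;
Nelder-Mead on an unconstrained reparameterization (log rates,
$\tanh^{-1}$ of the normalized coupling) for the per-class diffusion
parameters, with a mild ridge penalty for stability; and 1-D likelihood
maximization for the amino-acid scale. The global exchangeability matrices can be
updated by symmetrized expected-count reweighting (off by default: at
desk scale the counts are thin and a flat $S$ is an adequate
initializer; the flag is `update_exchangeability`). The initial
distribution of the hidden chain is its stationary distribution, not a
free parameter. Fits run a configurable number of random restarts and
keep the best final objective; the whole fit is bitwise reproducible
under its seed. The tracked objective is the observed-data forward
log-likelihood, which is monotone in expectation only — the test suite
asserts improvement over the run, not per-iteration monotonicity.

**Model selection** uses BIC $= -2\log L + p\log n$ with $p$ from the
deterministic free-parameter counter (190 amino-acid exchangeabilities,
3 secondary-structure exchangeabilities, 28 per site-class, 1 class
equilibrium and 1 jump rate per state, $h(h-1)$ transition entries) and
$n$ the number of aligned site observation pairs.

### Evolutionary-motif detection

Jump-event motifs are called by a two-stage posterior criterion: the
joint posterior $p(H_i = k, r_a \neq r_b \mid A_a, A_b, X_a, X_b)$ must
exceed 0.90 for a *single* hidden state $k$ (not summed over states),
and the same joint posterior for the same $k$ must exceed 0.50 when one
angle track is dropped — under *either* single-structure condition (the
inclusive reading of the criterion). Thresholds are strict inequalities.
The second stage can only shrink the first-stage set.

## The synthetic-data generator

`example_model()` builds the generator used throughout the tests and
fixtures: hidden states sitting in canonical Ramachandran basins
(right-handed $\alpha$-helix $(-1.05, -0.79)$, $\beta$-sheet
$(-2.36, 2.36)$, polyproline-II coil $(-1.31, 2.71)$, left-handed helix
$(1.05, 0.79)$), with matching secondary-structure equilibria
(e.g. 0.90 helix mass in the helix state), amino-acid preferences of the
expected flavor (A/E/L in helices, V/I/Y in sheets, P/S/T in coil, G/N
in the left-handed basin), per-coordinate stationary spreads of
0.35–0.45 rad, a class equilibrium of $(0.7, 0.3)$, a jump rate of 2 and
a self-transition probability of 0.85 (secondary-structure run lengths
of order 7 sites). Simulated evolutionary times are drawn from a grid
spanning 0.05–1.2, reflecting that most homologous pairs in curated
structural databases sit at small divergence. `generate_fixtures()`
writes such datasets to disk (track TSVs, FASTA, gapped-FASTA true
alignments, the true model as JSON, a manifest), with single-sided
columns sprinkled in at a small per-boundary rate to exercise indel
handling.

What the generator deliberately does *not* emulate: experimental noise
in measured dihedral angles, within-protein global dependencies (radius
of gyration, packing), non-identifiable secondary-structure assignment
ambiguity, and compositional heterogeneity across protein families.
Tests passing on this generator therefore demonstrate correctness of the
inference machinery under the model's own assumptions, not performance
claims about real structures.

## Problem sizes used by the heavier checks

The parameter-recovery experiment refits a 3-state generator on 200
simulated pairs of 150 sites (times on the grid $\{0.1, 0.2, 0.3,
0.5\}$, treated as known during the refit, as when training from a
curated pair database with trusted divergence estimates) and requires
every generating diffusion mean to be matched within 0.15 rad and every
amino-acid equilibrium within 0.05 total variation. BIC selection runs
10 replicate datasets of 30 pairs x 60 sites over $h \in \{1, 2, 3, 4,
6\}$ and requires the generating $h = 3$ to win at least 8 of 10. The
time-estimation mirror uses 30 pairs of 200 sites across $t \in [0.05,
1]$; the divergence-curve mirror imputes angles on a seven-point time
grid; the prediction-error ordering uses 20 pairs of 30 residues under
combinations (nothing / both sequences / both sequences + homologous
angles) with alignment marginalization.

## Degenerate inputs and edge behavior

At $t = 0$ the dihedral transition kernel is a Dirac delta: samplers
return the starting point exactly, the pair density is $+\infty$ on the
diagonal and $-\infty$ off it, and discrete kernels reduce to the
identity. Posterior motif detection at $t = 0$ returns the empty set
directly, since the jump prior carries no mass there. Half-observed
angle pairs (one of $\phi, \psi$ missing) are rejected at construction —
the diffusion is irreducibly bivariate. Non-homologous columns must
carry data on exactly one side. The half-open interval convention maps
$\pi$ to $-\pi$ everywhere.

## Known limitations

* Two proteins only; no phylogenies, and hidden states do not evolve
  along branches — jump events are the deliberate abstraction of that
  ideal.
* The pseudo transition density underestimates far-tail mass at
  intermediate times; the jump mechanism absorbs most, not all, of the
  resulting misfit for large conformational changes.
* The StEM M-step's exchangeability update is a moment heuristic, not a
  full MLE; at desk scale it is disabled by default.
* MAP alignment is a joint Viterbi over hidden states and columns, not
  the marginal-posterior argmax (see above).
* Secondary structure is consumed as 3-class labels; the package maps
  8-class labels down but does not compute assignments from geometry.
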