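---
title: "Alignment scores as probability models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment scores as probability models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phmmscore)
```

## The model

Classical pairwise alignment assigns a score $S_{xy}$ to aligning reference
letter $x$ with query letter $y$, and affine gap scores: a gap of length $k$
costs $a + b(k-1)$, with separate $(a_D, b_D)$ for deletions and
$(a_I, b_I)$ for insertions.  The same comparison can be phrased
generatively with a pair hidden Markov model (PHMM): flanking states emit
unaligned letters with probabilities $\phi$ (reference) and $\psi$ (query),
a core emits aligned pairs with probability $\pi_{xy}$, and transition
probabilities ($\omega_D, \omega_I$ for the flanks; $\gamma$, $\alpha$,
$\beta$ for continuing the core, opening and extending gaps) govern the
lengths.  The bridge between the two views is a temperature $t$:

$$\Pr(\text{alignment}) \propto \exp(\text{score}/t).$$

Writing $S'_{xy} = e^{S_{xy}/t}$, $a' = e^{a/t}$, $b' = e^{b/t}$, every
PHMM that reproduces a given scoring scheme shares the same *primed
invariants*:

$$c' = \frac{\gamma}{\omega_D \omega_I} = \sum_{xy}\phi_x\psi_y S'_{xy},
\qquad a'_D = \frac{\alpha_D(1-\beta_D)}{\omega_D}, \qquad
b'_D = \frac{\beta_D}{\omega_D},$$

and symmetrically for insertions.  The remaining freedom — the choice of
$\omega_D, \omega_I$ — changes the model but not a single alignment score:
`realize_phmm()` materializes any member of the family and
`scores_from_pair_probs()` maps it back, reproducing the original scheme to
$10^{-9}$ (this round trip is tested property-style on random schemes).

An alignment score is a log probability ratio against the *null alignment*
(all letters unaligned, probability $\mu_G$ from `null_probability()`), so
every probabilistic quantity in the package is a ratio relative to that
null.

## Special temperatures

Two conditions single out temperatures with no prior bias on alignment
length:

* **Uniform length probability (gapless):** $c(t) = 1$.  Under homogeneous
  letter probabilities ($\phi_x = \sum_y \pi_{xy}$, solved as a linear
  system by `solve_homogeneous()`), $c(t)$ falls from very large values at
  low $t$, dips below 1, and returns to 1 from below as
  $t \to \infty$ — so at most one finite root exists.
  `find_uniform_length_temperature()` brackets it on a log-spaced scan of
  512 points over $[10^{-3}, 10^{6}] \times \max|S|$ (scaled with the score
  magnitude) and bisects to a relative tolerance of $10^{-12}$.  The solve
  is carried out after factoring out $e^{\max(S)/t}$, so low temperatures do
  not overflow; the sign of $\log c$ is used instead of $c$ itself.
* **Balanced length probability (affine):**
  $C' = c' + a'_D/(1-b'_D) + a'_I/(1-b'_I) = 1$.  Unlike the gapless case
  this does not pin down $t$: `find_balanced_temperatures()` scans the same
  kind of grid and refines every sign change, returning zero, one
  (tangency), or two roots.  For the Simple matrix with gap scores
  $-6/-1$ there are exactly two; with $-3/-1$, or for HoxD70 with
  $-430/-30$, none — strong mismatch and gap costs are what make balance
  attainable.  A scheme with $C' > 1$ can always be repaired by subtracting
  the constant `balance_shift()` from the matrix, provided the gap terms
  alone stay below 1.

When $C' < 1$ the omegas may approach 1 (bias toward shorter alignments);
when $C' > 1$ they hit the feasibility boundary
$\gamma + \alpha_D + \alpha_I = 1$.  With symmetric gaps that boundary is
the smallest root in $(0,1)$ of the cubic
$b'c'\omega^3 - c'\omega^2 - (2a'+b')\omega + 1 = 0$
(`max_omega_symmetric()`, solved by `polyroot()` with complex parts below
$10^{-10}$ discarded; roots at or beyond $1/b'$ are rejected because the
gap-extension series must converge).  In the large-$t$ limit
$a' = b' = c' = 1$ the root is $\omega = 0.311$, at which
$\alpha = \omega/(1-\omega) = 0.452$.  `sweep_max_omega()` traces the bound
over temperature (256 grid points, golden-section refinement around the
best grid point).

## Optimal alignment

Two maximum-score local DP variants are provided.  Variant I keeps three
tables and forbids a deletion directly after an insertion (the two orders
tie, so one suffices); variant II folds $\max(X, Y, Z, 0)$ into a single
table.  They give identical scores whenever $a \le b$ per gap side; when a
first gap costs *less* than an extension, variant II may split a long gap
into several and score higher — that situation is flagged with a warning
rather than an error, since it is a modeling choice, not a defect.  Both
kernels are compiled (Rcpp), as is the global aligner used to exercise the
score transformations of `transform_scheme()`.

Traceback is deterministic by convention: aligned pairs are preferred over
deletions, deletions over insertions, insertions over a local restart, and
among equal-scoring endpoints the smallest $(i, j)$ wins.  The underlying
recurrences do not dictate any of this; the convention exists so that
golden tests are stable.

## Summing over alignments

`forward_modelA()` is the sum-product counterpart of variant II: maxima
become sums, scores become primed factors, and every cell's $W'$ carries a
$+1$ for a fresh local start.  Its total $\sum_{ij} W'_{ij}$ sums over
*distinguishable state paths*, which includes the $(m+1)(n+1)$ flank-split
variants of the null alignment and, within a gap run of length $k$, all
$2^{k-1}$ ways of extending versus re-opening.  `forward_modelB()` is the
counterpart of variant I: alignments begin and end with an aligned pair,
gaps never re-open, and exactly one path corresponds to one alignment, so
its total is $1 + \sum_{ij} X'_{ij}$ and never exceeds model A's.  The
exact recurrences for model B's Forward are this package's own
reconstruction from variant I (documented here because no printed reference
form was available); it is validated against its own path enumerator only,
never against model A.

`enumerate_paths()` is the independent oracle: a depth-first enumeration of
every distinguishable path on tiny instances.  By default the $2^{k-1}$
open/extend labelings of a gap run are summed in closed form,
$a'(a'+b')^{k-1}$; a fully naive mode keeps every labeling as an explicit
branch, and the two modes are cross-checked against each other before the
collapsed mode is used against the Forward kernels (200 seeded instances
with $m, n \le 4$).

Posterior aligned-pair probabilities come from an adjoint (backward) pass
over the same recurrences: the summed ratio of paths through pair $(i,j)$
is $X'_{ij}\,\bar W_{ij}$, and dividing by the total gives
$P[i,j]$, validated cell-for-cell against the enumerator.
`column_reliability()` reads an alignment against that table, scoring gap
columns by the posterior probability that the letter is *not* aligned.

**Numerical scaling.**  Primed factors like $e^{91/30}$ overflow quickly,
so each DP row is stored divided by a running scale: whenever a row's
maximum exceeds $2^{256}$ the row is renormalized and the scale's log
grows.  Totals are combined across rows by log-sum-exp, and the returned
`log_total` is exact even when the plain ratio overflows a double.  The
$2^{256}$ threshold leaves $\sim\!10^{230}$ of headroom above the scale for
within-row growth; a non-finite intermediate still raises an explicit
overflow error rather than returning garbage.  Null-path contributions
whose scaled value underflows (possible once the scale's log exceeds
$\sim\!745$) are dropped; they are then smaller than the total by hundreds
of orders of magnitude.

As a consistency check across the two views, scaling all primed factors to
the 50th power (temperature $t/50$) collapses both the hybrid score and
$t\,\log$ of the Forward total onto the variant-II optimal score, to well
under 0.01 on an identity fixture.

## Hybrid scores and Gumbel calibration

The hybrid score replaces the Forward total's final summation by a
maximization: $\max_{ij} t \ln W'_{ij}$.  For balanced parameters, hybrid
scores of random sequences are expected to follow a Gumbel distribution
with scale $\lambda = 1/t$.  `check_lambda()` tests this claim
empirically: it finds the balanced temperatures, simulates independent
letter sequences (`simulate_pair()`, one RNG substream per replicate so
results do not depend on evaluation order), computes hybrid scores, and
fits a Gumbel by maximum likelihood.

The fit (`fit_gumbel()`) solves the standard profile equation for the
scale by Newton iteration (the profile derivative $1 + \mathrm{Var}_w(x)/\beta^2$
is strictly positive, so the iteration is monotone and safe), initialized
at the moment estimate $\hat\beta = s\sqrt{6}/\pi$, to relative tolerance
$10^{-10}$; weights are computed with min-subtraction for stability, and
the standard error comes from the observed information.  On $2\times10^4$
synthetic Gumbel draws the fit recovers $\lambda \in \{0.25, 1, 4\}$ within
2%.

**Simulation sizes and what they show.**  No reference simulation sizes
exist for this calibration, so the defaults are a desk-scale choice:
$m = n = 100$ and 1000 replicates, giving a scale standard error of about
2.5%.  At the *lower* balanced temperature of Simple:6:1
($t \approx 0.918$) this setting already reproduces
$\hat\lambda t \approx 1.04$.  At the *upper* balanced temperature
($t \approx 1.70$) sequences of length 100 are far from the asymptotic
regime: $\hat\lambda t$ starts around 1.6 and decreases steadily with
sequence length (the test suite verifies the decreasing trend over lengths
100–400; separate runs at length 2000 reach $\approx 1.06$).  The
$\lambda = 1/t$ law is an asymptotic statement, and length 100 is simply
not asymptotic for weakly-coupled parameters — a known limitation of the
default configuration, deliberately not papered over by changing the
defaults.

The simulated sequences are i.i.d. letters: no repeats, no composition
bias, no indel structure beyond what the model itself generates.  Passing
calibration therefore says nothing about biological sequences with tandem
repeats or skewed composition; it tests the mathematical claim under the
model's own null.

## Other numerical and design choices

* Homogeneous solves that produce any letter probability below
  $-10^{-12}$ are rejected as inconsistent; values within $[-10^{-12}, 0]$
  are clamped to 0 (float noise at a boundary).
* Balance classification treats $|C' - 1| \le 10^{-9}$ as balanced; the
  classification is otherwise a strict sign comparison.
* The gap convention throughout is $a + b(k-1)$; the command-line interface
  accepts positive open/extend costs and converts them as $a = -\text{open}$,
  $b = -\text{extend}$.
* Asymmetric gap limits are not given a dedicated solver: the symmetric
  cubic covers the cases of interest, and the general feasibility check
  lives inside `realize_phmm()`.
* The maximum-possible-$\gamma$ curve over temperature is *not* exposed:
  evaluating $\gamma = c'\omega^2$ at the cubic root does not reproduce a
  defensible limiting value in the large-$t$ limit, and the optimization
  that would define "maximum possible $\gamma$" is ambiguous.  Only the
  $\omega$, $\alpha$ and $\beta$ limit curves, which are internally
  consistent with the feasibility identity, are computed.

## Limitations

* Only one similar segment is modeled; sequences with multiple similar
  regions (e.g. repeated domains) violate the model and are out of scope.
* No E-values are reported for Forward or hybrid scores, and no
  importance-sampling machinery for Gumbel location estimation is included.
* The DP kernels are the plain quadratic algorithms — no banding, seeding,
  or linear-space variants.
* Parameter estimation from data (Baum–Welch) is deliberately absent: the
  package maps given scores to models and back, it does not fit models to
  alignments.
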