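# phmmscore

Pairwise alignment is usually driven by *ad hoc* scores — a substitution
matrix plus affine gap costs — while probabilistic alignment uses pair
hidden Markov models (PHMMs).  The two are not rival frameworks: **any
scoring scheme corresponds, at every temperature t, to a whole family of
PHMMs that produce exactly the same optimal alignments**, via

    prob(alignment) ∝ exp(alignment score / t).

`phmmscore` implements this correspondence for people who work with
alignment scoring schemes (genome aligner parameters, substitution matrices
such as HoxD70) and want the probabilistic machinery that comes with a
model: alignment-column reliabilities, integrated (Forward) similarity
measures, mapping probabilities, and principled score statistics.

What the package computes:

* **Score → model and back.**  With letter probabilities φ, ψ and
  temperature t, the aligned-pair probabilities are
  π_xy = φ_x ψ_y exp(S_xy/t)/c with c = Σ φ_x ψ_y exp(S_xy/t)
  (`pair_probs_from_scores()`), and each feasible choice of the flank
  probabilities ω_D, ω_I yields a concrete PHMM (`realize_phmm()`).  The
  inverse map `scores_from_pair_probs()` recovers S, a, b exactly:
  S_xy = t ln(π_xy/(φ_x ψ_y) · γ/(ω_D ω_I)), b_D = t ln(β_D/ω_D), …
* **Special temperatures.**  `find_uniform_length_temperature()` solves
  c(t) = 1 under homogeneous letter probabilities (no length bias for
  gapless alignment); `find_balanced_temperatures()` solves the affine-gap
  generalization C′ = c′ + a′_D/(1−b′_D) + a′_I/(1−b′_I) = 1, which can
  hold at zero, one, or two temperatures.  `balance_shift()` repairs an
  unbalanced matrix by a constant shift.
* **Parameter limits.**  `max_omega_symmetric()` solves the feasibility
  cubic b′c′ω³ − c′ω² − (2a′+b′)ω + 1 = 0 bounding ω;
  `sweep_max_omega()` maximizes that bound over temperature.
* **Alignment engines.**  Compiled maximum-score local alignment (two
  classical DP variants plus deterministic traceback), a global aligner,
  Forward algorithms for two local PHMM topologies, posterior
  aligned-pair probabilities, per-column reliabilities, MAF output with a
  reliability line, hybrid alignment scores, and Gumbel calibration of
  hybrid-score statistics (`check_lambda()`).

## Worked example

HoxD70 with gap costs 430/30 — a standard genome-alignment setting:

```r
library(phmmscore)

S <- builtin_matrix("HoxD70")
t <- find_uniform_length_temperature(S)
t
#> [1] 96.1735
sol <- solve_homogeneous(S, t)
round(sol$phi, 3)
#>     A     C     G     T
#> 0.266 0.234 0.234 0.266
```

At t = 96.17 the matrix's own letter probabilities come out AT-rich-ish and
the gapless length bias vanishes.  Adding the gap scores, is the *gapped*
model still unbiased?

```r
sch <- score_scheme(S, a_D = -430, b_D = -30, a_I = -430, b_I = -30, t = t)
pr <- primed_params(sch, sol$phi, sol$psi)
classify_balance(pr)
#> Length-probability balance: C' = 1.085344 -> longer_bias
```

No: C′ > 1, a bias toward longer alignments (and in fact no temperature
balances this scheme).  One concrete PHMM from the family, with both flank
probabilities at 0.9:

```r
params <- realize_phmm(pr, sol$phi, sol$psi, omega_D = 0.9, omega_I = 0.9,
                       topology = "A")
round(unlist(params[c("gamma", "alpha_D", "beta_D")]), 4)
#>   gamma alpha_D  beta_D
#>  0.8100  0.0302  0.6588
```

Align two diverged sequences and ask how reliable each column is:

```r
fx <- make_fixture("diverged", 40, divergence = 0.15, seed = 4)
aln <- traceback_alignment(align_local(fx$R, fx$Q, sch, "II"))
aln
#> Local alignment score 3271  R[0,39) x Q[0,39)
#> TGGGGTGCACGTCCCCTATGGGGATTAACTGTAGACATT
#> TGGGGCGCACGTCCCCTATGGAGATTCACTGTAGACATT
P <- posterior_match_probs(fx$R, fx$Q, pr)
rel <- column_reliability(aln, P)
round(range(rel), 3)
#> [1] 0.604 1.000
cat(write_posterior_maf(aln, rel, "ref", "qry", 40, 40), sep = "\n")
#> a score=3271
#> s ref      0     39 +     40 TGGGGTGCACGTCCCCTATGGGGATTAACTGTAGACATT
#> s qry      0     39 +     40 TGGGGCGCACGTCCCCTATGGAGATTCACTGTAGACATT
#> p                            6899999+++++++++++++++++++++++++++99986
```

Interior columns are near-certain ('+' is ≥ 0.995); columns near the ends
and around mismatches drop toward 0.6 — exactly the parts of an alignment
one should not over-interpret.  The Forward total integrates over all
alignments:

```r
forward_modelA(fx$R, fx$Q, pr)
#> Forward total (topology A): log ratio = 35.22583
```

A command-line front end covering these operations (subcommands
`temperature`, `convert`, `balance`, `limits`, `align`, `forward`,
`posterior`, `mapprob`, `calibrate`) is installed at
`system.file("cli", "phmmscore", package = "phmmscore")`.

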