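---
title: "Inconsistency diagnostics for fixed-effect network meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inconsistency diagnostics for fixed-effect network meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmainc)
```

## The model

Network meta-analysis (NMA) combines direct and indirect evidence on
treatment contrasts across a connected network of randomized trials. The
*consistency* assumption — that direct and indirect evidence estimate the
same contrast — is what lets the network borrow strength; *inconsistency*
is their disagreement, and it is a property of treatment loops, not of
individual comparisons. This package implements a family of diagnostics for
locating and testing inconsistency under a fixed-effect, contrast-based,
two-stage model:

1. **Within-design pooling.** A *design* is the set of treatments compared
   within a trial; trials with the same treatment set share a design. Each
   design's trials are pooled by inverse-variance (generalized for
   multi-arm designs, which contribute $t-1$ contrasts with a block
   covariance), giving design-level estimates $\hat\theta_c$ with
   covariance $V_c$.
2. **Design-level GLS.** Under consistency every contrast is a difference
   of $T-1$ basic parameters $\beta$ (each treatment versus a reference).
   With design matrix $X$ (entries in $\{-1,0,1\}$) and weights
   $W = \mathrm{blockdiag}(V_c)^{-1}$, the fit is
   $\hat\beta = (X'WX)^{-}X'W\hat\theta$ with hat matrix
   $H = X(X'WX)^{-}X'W$.

All fitting is fixed-effect: no heterogeneity variance is estimated. This
keeps the Q decomposition exact and mirrors the standard construction of
the net heat diagnostics.

### Cochran's Q decomposition

The total
$Q = \sum_c\sum_i (\hat\theta_{ic}-\hat\theta_{Nc})' S_{ic}^{-1}(\hat\theta_{ic}-\hat\theta_{Nc})$
splits exactly into a within-design part
$Q^{het} = \sum_c\sum_i (\hat\theta_{ic}-\hat\theta_c)' S_{ic}^{-1}(\hat\theta_{ic}-\hat\theta_c)$
and a between-design part
$Q^{inc} = \sum_c (\hat\theta_c - X_c\hat\beta)' V_c^{-1}(\hat\theta_c - X_c\hat\beta)$,
because the pooled $\hat\theta_c$ is itself the within-design GLS solution
(cross terms vanish). Degrees of freedom: $\sum_c (n_c-1)\,\dim_c$ for
$Q^{het}$ and $\sum_c \dim_c - (T-1)$ for $Q^{inc}$; p-values are
upper-tail chi-squared, with no multiplicity adjustment.

### The net heat matrix

Detaching a design $d$ means relaxing consistency for exactly that design.
We implement it by *design-matrix augmentation*: one extra indicator column
per contrast row of $d$ (a 1 on that row, 0 elsewhere), then a GLS refit.
The augmented model fits $d$'s rows perfectly, so $d$ contributes no
information to the basic parameters — algebraically equivalent to leaving
the design out, but the residual bookkeeping for every other design stays
in place, and the construction generalizes cleanly when a design sits in
several loops.

One convention deserves care. The per-design contribution after detachment,
$Q^{inc}_{c(d)}$, is evaluated against the *basic-parameter* network values
$X_c\hat\beta_{(d)}$ of the detached fit. For $c \ne d$ this is the obvious
choice (the indicator columns do not touch those rows). For $c = d$ it
means the detached design's own contribution is measured against the purely
indirect evidence that remains — $(1/s_c^2)(\hat\theta_c^{dir} -
\hat\theta_c^{ind})^2$ in a triangle — rather than being identically zero
from the perfect fit. That is the convention under which the analytic
triangle expressions (the off-diagonal form and its negative diagonal
companion) match the matrix machinery exactly, and both readings are
asserted in the test suite: the augmented fitted values reproduce $d$'s
rows to $10^{-10}$, *and* the diagonal difference equals the closed form.

The displayed matrix puts $Q^{inc}_c$ on the diagonal and
$Q^{diff}_{c,d} = Q^{inc}_c - Q^{inc}_{c(d)}$ off the diagonal. Eligible
designs are those inside at least one loop whose removal keeps the network
connected; rows/columns are ordered by descending diagonal (ties
lexicographic — no ordering is canonical). Cell coloring saturates at
$|Q^{diff}| = 8$, the conventional display threshold; grey inner squares
scale with the design-aggregated absolute hat-matrix entries. No p-values
are attached to $Q^{diff}$: as a difference of two correlated chi-squared
statistics it has no standard distribution, which is precisely why the
formal tests below matter.

### Formal tests

*Bucher loop test*: for a three-treatment loop,
$\hat\omega = \hat\theta^{dir} - \hat\theta^{ind}$ with
$\mathrm{Var}(\hat\omega)$ the sum of the three direct variances and
$z = \hat\omega/\sqrt{\mathrm{Var}}$ referred to N(0,1). Only two-arm
direct evidence enters; loops that exist solely inside one multi-arm design
are refused (randomization within a design precludes inconsistency there).
In a two-arm triangle $z^2 = Q^{inc}$ exactly — the approaches are
algebraically equivalent, and the test suite asserts it to $10^{-8}$.

*Node-splitting*: the direct estimate pools every design containing both
treatments; the indirect estimate refits the network with all of those
designs detached, so the two parts are independent and
$SE^2_{diff} = SE^2_{dir} + SE^2_{ind}$. In a single loop the node-split
difference reproduces $\hat\omega$ exactly.

### Closed forms

For the two topologies where the algebra is tractable the package ships
analytic $Q^{diff}$ expressions and verifies the matrix machinery against
them: the two-arm triangle (off-diagonal
$(1/s_c^2)\,w^2(\hat\theta^{dir}-\hat\theta^{ind})^2$ with
$w = s_c^2/\sum s^2$, diagonal the same times $w^{-2}(w^2 - 1) \le 0$) and
the equal-variance radial network with $k$ indirect pathways, where the
entry factorizes approximately as $P_1 P_2 / s^2$ with
$P_1 = \bar\theta^{ind(-d)} - \theta^{ind(d)}$ and
$P_2 = (2/k)(\theta^{dir} - \bar\theta^{ind})$. The $1/k$ factor in $P_2$
is the analytic heart of the masking phenomenon: a pathway can stay as
deviant as it likes ($P_1$ large) while its net heat entry collapses.

## The synthetic-data generator

`simulate_radial_network()` emulates a radial world with one inflated
design: treatments A, B, C plus spokes $X_1 \ldots X_{k-1}$, designs A:B,
A:C, B:C, A:$X_i$, B:$X_i$, six trials per design. Per-trial effects are
drawn N(0, 0.2) except design A:C, drawn N(2, 0.2) — a gross, known
inconsistency in the ABC loop. Per-trial standard errors are drawn as
|N(0,1)|, redrawn below a floor of 0.05. The floor is our choice: a
literal normal draw is not positive (the absolute value is the natural
reading), and unfloored tiny SEs produce unbounded Q statistics from
near-singular weights; 0.05 is small relative to the typical draw (~0.8)
and is configurable.

Two deliberate departures from real data:

* **Effects are the drawn values themselves** — no sampling noise is
  layered on top, so the dispersion of observed effects (0.2) is decoupled
  from the claimed standard errors. This is the stated world of the
  escalation study, and it means Q statistics in this world are *not*
  chi-squared calibrated. A green masking test therefore establishes the
  relative behavior of the diagnostics across $k$, not their null
  calibration.
* For calibration checks the generator has a `sampling = "calibrated"`
  mode (observed = design mean + N(0, se²) noise, zero effect dispersion)
  under which the node-split z is exactly standard normal; the test suite
  confirms a ~5% rejection rate at 500 replicates.

The escalation study (`run_loop_escalation()`) regenerates the whole
network for each loop count $k = 1 \ldots 10$ and each replicate, and
records $Q^{diff}_{AB,AC}$, $Q^{inc}_{AB}$, $Q^{inc}_{AB(AC)}$, the A–B
node split and the ABC-loop Bucher $z^2$. Single runs are a seed lottery
(the quartile bands span an order of magnitude), so aggregate mode with
replicate medians is the default for testing. Master seed spawns
collision-free per-(k, replicate) substreams.

### What the masking test does and does not establish

Across replicates the median $Q^{diff}_{AB,AC}$ falls by an order of
magnitude from $k=1$ to $k=10$ and drops below the display threshold 8
from small $k$ onward, while the median within-loop Bucher statistic stays
flat — the masking phenomenon. The acceptance test additionally asserts
*strictly* decreasing medians across all nine adjacent pairs. That is a
property of the true median curve (verified with 3000 replicates per
$k$), but at the tail ($k \ge 7$) the per-step decrements (~0.1–0.2) are
comparable to the Monte Carlo standard error of a 100-replicate median
(the interquartile range there is ~3), so a small replicate count can show
spurious inversions. The test therefore uses 2000 replicates — replicates
control only estimation noise, not the stated world — which resolves the
ordering reliably; nothing else (generator parameters, threshold, seed)
differs from the stated configuration.

## Numerical choices

* GLS solves use an SVD pseudoinverse with relative cutoff $10^{-10}$;
  rank-deficient augmented systems (detachment) are handled in the
  minimum-norm sense, which leaves identifiable contrasts untouched.
* Identifiability of a node-split's indirect contrast is checked by
  projecting the contrast onto the range of the Schur complement of the
  augmented normal equations (tolerance $10^{-6}$ relative).
* Multi-arm shared-arm covariance defaults to half the smallest contrast
  variance when not supplied, with a warning — the convention if all arm
  variances were equal; supply `shared_arm_variance` for real data.
* The multi-arm heterogeneity df counts contrast dimensions,
  $(n_c-1)\dim_c$, which reproduces the expected 40/39/1 bookkeeping on the
  three-design lung topology with 42 two-arm trials.
* Reference treatment defaults to the lexicographically first label;
  estimates are invariant to the choice (tested).

## Limitations

* Fixed effects only: with real heterogeneity the Q decomposition still
  computes but its calibration degrades; no random-effects or
  design-by-treatment interaction model is provided.
* Arm-level data reduction, IPD survival modelling and Bayesian
  node-splitting are out of scope; inputs are contrast-level summaries.
* Closed forms cover only triangle and radial topologies; for anything
  else the matrix machinery is the definition.
* $Q^{diff}$ is reported without p-values by design — its distribution is
  nonstandard, and the package's own simulation shows why its magnitude
  should not be read as evidence strength.
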