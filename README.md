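# parsec

Parameter-sensitivity clustering for model-based design of experiments on
ODE kinetic models, with an ABC-FAR (fixed-acceptance-rate approximate
Bayesian) parameter estimator for automated design ranking.

## Who this is for

Systems biologists (and other dynamical-model builders) who must decide
*when* — and which variables — to measure in a costly time-course
experiment so that the data pin down the model parameters. The package
answers: given an ODE model, a feasible time grid, measurable variables,
and a sample-size budget, which measurement combinations are most
informative, and how much better are they than a random schedule?

## The method

For every feasible measurement candidate $M_i$ (variable set + time
point), a vector of first-order eFAST sensitivity indices
$\Psi(M_i, \Theta_j) = [\psi(M_i, \Theta_j, \theta_1), \ldots,
\psi(M_i, \Theta_j, \theta_p)]^T$ is computed at parameter vectors
$\Theta_j$ sampled (LHS) from the stated parameter uncertainty, and
concatenated into a PARSEC-PSI vector. Candidates are clustered on the
Euclidean distance between these vectors (k-means or fuzzy c-means,
minimising intra-cluster distance); a design takes one candidate per
cluster, so its measurements cover distinct sensitivity profiles instead
of duplicating one.

Designs are scored by simulating the data they would produce and running
ABC-FAR: iteratively sample $N$ parameter combinations from
noise-augmented marginals
($m^k = \tfrac{0.25}{k+1}U + (1-\tfrac{0.25}{k+1})p^{(k-1)}$, Latin
hypercube per parameter), rank them by
$\chi^2 = \sum (R_D - R_P)^2/\sigma_D^2$, keep the best
$M = \mathrm{round}(\mathrm{FAR}\times N)$, and update the marginals;
a history-dependent update keeps the best-ever combinations in the pool.
Design quality is the estimation error
$\sqrt{\sum_j \sum_m (\theta_j - \hat\theta^m_j)^2}$ (log10 scale) of the
final selection against the generating truth. A dummy parameter fitted
alongside the real ones flags sampling artifacts and calibrates the
significance of pairwise identifiability diagnostics.

Fixtures included: Lotka-Volterra (2 states / 4 parameters), a three-gene
repressilator (3 / 6), and a six-species viral life-cycle model (6 / 11,
7 free). All synthetic data is generated in code; a minimal SBML Level-3
importer handles external models.

## Worked example

Design six simultaneous measurements of repressilator proteins B and C on
the 3-hourly grid up to 72 h, and compare PARSEC(k) designs (`PD`)
against random (`RD`) and anti-PARSEC (`WD`, all candidates from one
cluster) ensembles at the reduced evaluation profile:

```r
library(parsec)
model      <- repressilator_model()
candidates <- enumerate_candidates(seq(3, 72, by = 3), c("B", "C"))
psi        <- compute_parsec_psi(model, candidates, seed = 1)

pd <- design_ensemble(psi, candidates, 20, 6, "parsec_k",    seed = 101)
rd <- design_ensemble(psi, candidates, 20, 6, "random",      seed = 102)
wd <- design_ensemble(psi, candidates, 20, 6, "anti_parsec", seed = 103)
cmp <- compare_ensembles(list(PD = pd, RD = rd, WD = wd), model,
                         far = 0.01, n = 2000, iterations = 4, seed = 7,
                         horizon = 72)
writeLines(format_comparison(cmp))
timepoint_entropy(pd, 72)
```

```
| generator | designs | mean error | pooled mean | accuracy ratio |
|---|---|---|---|---|
| PD | 20 | 1.856 | 1.856 | 1 |
| RD | 20 | 2.94 | 2.94 | 1.58 |
| WD | 20 | 4.591 | 4.591 | 2.47 |
[1] 3.48
```

Read: sensitivity-clustered designs estimate the six parameters with a
mean log10 error of 1.86 — 1.58× better than random schedules, 2.5×
better than redundant single-cluster designs — while their pooled
time-point distribution stays near-uniform (3.48 bits vs the 3.58-bit
uniform bound), i.e. the advantage comes from *combinations* of time
points, not from favouring particular times. A single `run_pipeline()`
call (YAML config) runs candidates → PSI → clustering → ensembles →
evaluation end-to-end with a hash manifest; `inst/cli/parsec` exposes the
same stages as subcommands.

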