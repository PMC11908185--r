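# resmix

Bayesian analysis of ligand–protein binding residence times from
molecular-dynamics contact data.

## What it does, and for whom

Long coarse-grained MD simulations of membrane proteins (GPCRs and
friends) yield, per residue, thousands of binding events between the
protein and a lipid such as cholesterol. The distribution of event
durations at one residue mixes several kinetic processes — sub-ns
"flicker" contacts across the distance cutoff, intermediate
rearrangements, and rare long-lived bound poses. The question a
simulator actually asks is: *how many kinetic processes does this
residue support, and how slow is the slowest one?*

`resmix` answers it with a Bayesian nonparametric mixture model. The
residence times $t = (t_1,\dots,t_\Omega)$ are modelled as draws from a
hyperexponential distribution

$$p(t \mid \pi, \lambda) = \sum_{k=1}^{K} \pi_k\, \lambda_k\,
e^{-\lambda_k t},$$

with a symmetric Dirichlet prior $\gamma_k = 1/K$ on the weights (the
finite approximation of a Dirichlet process: $K$ is an upper bound, not
a choice of model), Gamma priors on the rates, and a latent per-event
indicator. A Gibbs sampler draws from the joint posterior; postprocessing
filters negligible weights ($\pi_k < 10/\Omega$), undoes MCMC label
switching by clustering the samples in $(\log\lambda, \log\pi)$ space,
removes diffuse noise clusters, and reports MAP rates and residence
times $\tau = 1/\lambda$ with 95% credible intervals. Because every
event keeps its posterior cluster membership, binding events — and hence
trajectory frames — can be *kinetically mapped*: segments are labelled
by timescale, and per-cluster probability-weighted 3D densities of the
bound ligand show where each kinetic process lives (OpenDX output).

## Worked example

Simulate 5000 events from a known three-component mixture
($\pi = (0.9, 0.09, 0.01)$, $\lambda = (5, 0.5, 0.05)\,\mathrm{ns}^{-1}$)
and fit with a deliberately generous component bound:

```r
library(resmix)
d <- synthetic_dataset(n = 5000, weights = c(0.9, 0.09, 0.01),
                       rates = c(5, 0.5, 0.05), seed = 3)
fit <- resmix(d$durations, K = 10, n_iter = 11000, burn_in = 1000,
              thin = 10, seed = 2)
summary(fit)
```

```
Bayesian residence-time mixture fit
Call:  resmix(t = d$durations, K = 10, n_iter = 11000, burn_in = 1000,      thin = 10, seed = 2)

Events: 5000  Kept posterior samples: 1000  Component bound K: 10

Kinetic clusters (MAP estimates, 95% credible intervals):
 cluster  weight rate_ns rate_lo rate_hi tau_ns tau_lo tau_hi multimodal noise
       1 0.90400  4.8200  4.6600   5.030  0.204  0.199  0.214       TRUE FALSE
       2 0.08590  0.4810  0.3540   0.709  2.100  1.410  2.820      FALSE FALSE
       3 0.00288  0.3860  0.1540   1.240  2.100  0.804  6.510      FALSE  TRUE
       4 0.01050  0.0385  0.0253   0.103 21.800  9.750 39.500      FALSE FALSE

Slowest process: tau = 21.8 ns (95% CI 9.75 - 39.5 ns)
```

Reading the table: the sampler was offered ten components but the data
support three. Clusters are ordered fastest to slowest; the three signal
clusters recover the generating weights (0.904, 0.086, 0.011 vs. true
0.9, 0.09, 0.01) and rates (4.82, 0.48, 0.039 vs. true 5, 0.5, 0.05 —
each true mid/slow rate inside its interval at this modest sample size).
Cluster 3 is a diffuse cluster that no event is ever confidently
assigned to; it is flagged as noise and excluded from reporting. The
residue's reported residence time is that of the slowest signal cluster,
here $\tau \approx 22$ ns (true: 20 ns) with an honest interval.

Downstream:

```r
plot(fit, "survival")              # empirical S(t) + fitted components
p  <- predict(fit, "membership")   # per-event cluster probabilities
cl <- predict(fit, "cluster")      # hard assignment, ties -> slower
r  <- residuals(fit)               # Cox-Snell residuals ~ Exp(1) if OK
```

Per-residue pipelines (`pipeline_run()`), residence-time fingerprints
(`fingerprint()`, `fingerprint_diff()`), contact-event extraction from
distance series (`extract_events()`), kinetic mapping
(`assign_frames()`, `weighted_density()`, `write_dx()`), and a thin CLI
(`inst/scripts/resmix-cli.R`) wrap the same machinery. The methods
vignette (`vignettes/residence-time-inference.Rmd`) documents the model,
the postprocessing, and every numerical choice.

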