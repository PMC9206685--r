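# emosource

Decoding emotional state from multichannel EEG by working in **source
space**: invert the scalp recording into a sparse set of cortical sources,
encode the sources' joint activity as a correlation-weighted graph, and
classify the graph with a dynamic graph convolutional network (DGCNN)
whose adjacency matrix is learned during training.

The package is aimed at researchers in EEG decoding and Bayesian source
imaging who want a fully self-contained, testable implementation of this
chain: every stage can be exercised on synthetic data generated by the
package itself, with ground truth retained for scoring.

## The model

**Forward model.** A sensor snapshot obeys

    y = H x + e,        e ~ N(0, sigma^2 I),

with `y` the N electrode potentials, `H` the N x M lead field (N < M:
under-determined), and `x` the M dipole amplitudes, assumed sparse.

**Sparse Bayesian inversion.** Each amplitude carries a Bernoulli-Laplace
(spike-and-slab) prior

    f(x_i | omega, lambda) = (1 - omega) delta(x_i)
                             + omega/(2 lambda) exp(-|x_i|/lambda),

with a Jeffreys prior on `sigma^2`. A Gibbs sampler draws each `x_i` from
its three-component conditional (spike + two truncated Gaussians, weights
computed in the log domain), then `sigma^2`, `lambda`, `omega` from their
conjugate conditionals. Chains are initialized from the sLORETA
standardized minimum-norm solution. Posterior inclusion probabilities give
the active support; restricted least squares recovers the time courses.

**Graph + classifier.** Sources passing the 50%-of-max power rule become
nodes; edges are absolute Pearson correlations thresholded at `beta`. The
DGCNN filters node signals with Chebyshev polynomials of the rescaled graph
Laplacian, `z = sum_k theta_k T_k(L~) x`, and updates its adjacency by the
relaxation `W* <- (1 - rho) W* + rho dLoss/dW*` (descent sign by default),
re-symmetrized and clamped nonnegative after every step.

## Worked example

Sparse recovery on a 32-sensor / 200-source problem with three active
dipoles at 20 dB SNR:

```r
library(emosource)

lf <- build_lead_field(32, 200, seed = 7)
set.seed(123)
x <- numeric(200); x[c(20, 80, 140)] <- c(3, -2.5, 2)
clean <- as.numeric(lf$H %*% x)
y <- clean + rnorm(32, sd = sqrt(mean(clean^2) / 10^2))   # 20 dB

post <- summarize_posterior(run_gibbs(y, lf, gibbs_config(seed = 1)))
post$support                     # 20 80 140   <- exact support recovery
round(post$x_mean[post$support], 2)  # 2.96 -2.55 1.97
signif(post$sigma2_mean, 4)      # 0.004269 (true noise variance 0.004412)
```

The three active sources are found exactly, their amplitudes are recovered
to within a few percent, and the posterior mean of the noise variance is
within 4% of the truth.

End to end on a compact synthetic experiment (4 subjects x 6 trials,
16 sensors, 60 sources, 2 s epochs):

```r
rep <- run_pipeline(pipeline_config(seed = 2,
  dataset = list(n_subjects = 4, trials_per_subject = 6, n_sensors = 16,
                 n_sources = 60, epoch_s = 2,
                 active_sets = list(positive = c(10L, 30L),
                                    negative = c(20L, 50L))),
  gibbs = list(n_iter = 400, burn_in = 150, inclusion_threshold = 0.5,
               n_snapshots = 3),
  train = list(rho = 1e-3, lr = 3e-3, epochs = 60, batch_size = 8,
               adjacency_updates = TRUE, weight_decay = 1e-2,
               augment_shift = TRUE)))
rep
#> <run_report>
#>   mode: subject_dependent
#>   train accuracy: 0.875
#>   test accuracy: 0.938
#>   merged support: 10, 20, 30, 50
```

The merged support is exactly the union of the two classes' true active
sets, and 93.8% of held-out trials are classified correctly. The default
configuration (`pipeline_config()` as is: 10 subjects x 10 trials,
32 sensors, 200 sources, 15 dB) reaches test accuracy 1.00 in both the
subject-dependent and subject-independent protocols at seed 1.

A command-line wrapper lives at `inst/cli/emosource`
(`simulate | localize | build-graph | run-all`), configured by a YAML file
mirroring `pipeline_config()`.

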