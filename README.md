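# sbtip — Schrödinger-bridge transition paths and tipping indicators

Stochastic systems with two meta-stable invariant sets — a resting state and
an oscillatory attractor in a neuron model, a healthy and a diseased cohort
in an embedding of imaging data — transition between them along an ensemble
of paths, not a single trajectory. `sbtip` computes the *most probable
evolution of the whole density* between two prescribed marginals, the
Schrödinger bridge, and derives from it a time-resolved early-warning
statistic for tipping between the two states. It is aimed at researchers in
computational neuroscience and stochastic dynamics who have samples of two
distributions (or a mechanistic model whose invariant sets supply them) and
want transition-path densities plus a quantitative signal of *when* the flow
reorganizes.

## The method

Given marginals ρ₀, ρ₁ and a reference diffusion
dX = f(t,X)dt + σ_t dW, the bridge is the path measure P* minimizing
KL(P ∥ reference) subject to X₀ ~ ρ₀, X₁ ~ ρ₁ — equivalently,
entropy-regularized optimal transport. Its optimality conditions form a
forward–backward SDE pair

- forward: dX = [f + σ_t² ∇ln φ_t] dt + σ_t dW, X₀ ~ ρ₀
- backward: dX = [f − σ_t² ∇ln φ̂_t] dt + σ_t dW, X₁ ~ ρ₁ (reversed time)

whose score fields Z ≈ σ_t∇ln φ_t, Ẑ ≈ σ_t∇ln φ̂_t the package trains by
likelihood alternation: each stage freezes one field, caches trajectories
from the frozen policy, and fits the other field by full-batch Adam on the
discretized likelihood

L = Σ_k Δt·E[ ½‖Z+Ẑ‖² + ∇·(σ_k Ẑ − f) ] − E ln p₁(X₁).

On the solved bridge, the velocity v = f + σ_t²∇ln φ_t transports the
marginal flow, and the early-warning indicator is its running mean kinetic
energy

I(t) = (1/t) ∫₀ᵗ E‖v(s, X_s)‖² ds,

whose total over [0,1] is bounded below by the squared 2-Wasserstein
distance W₂²(ρ₀, ρ₁) (Benamou–Brenier). A tipping step is a qualitative jump
in the increments of I, detected against a numeric threshold or by a robust
z-score (`detect_tipping`).

Supporting machinery: a Morris–Lecar neuron simulator with invariant-set
extraction (both printed parameter regimes), semi-discrete optimal transport
via the discrete Brenier potential for *non-convex* (disconnected) targets,
closed-form 1-D Gaussian-bridge and Bures–Wasserstein oracles, and seeded
synthetic generators. See `vignettes/sbtip-methods.Rmd` for the full account.

## Worked example

Bridge two 1-D Gaussians, N(−2, 0.1) → N(2, 0.1), under noise g = 0.5:

```r
library(sbtip)
pair <- make_gaussian_pair(list(n = 2000, seed = 42))
fit <- alternating_train(pair$rho0, pair$rho1,
                         schedule = noise_schedule("constant", 0.5),
                         T = 1, N = 50, seed = 1)
fwd <- propagate_forward(fit$model, pair$rho0, n_paths = 2000, seed = 2)
bwd <- propagate_backward(fit$model, pair$rho1, n_paths = 2000, seed = 3)
mean(fwd$states[, 51, 1])                            # forward terminal mean
mean(bwd$states[, 1, 1])                             # backward initial mean
marginal_consistency(fwd, bwd, times = 0.5)$l1       # fwd/bwd mid-bridge L1
ind <- action_indicator(fit$model, fwd)
attr(ind, "total_action")                            # total kinetic action
detect_tipping(ind, "auto")
```

Output from this exact run:

```
forward terminal mean:  2.008
backward initial mean: -1.923
mid-bridge L1 discrepancy: 0.183
total kinetic action: 17.62  (squared Wasserstein lower bound: 16)
largest indicator increment at step 22 (z = 2.97)
```

Reading: the trained bridge reaches both boundary marginals (means ±2
recovered within 0.1); forward and backward densities agree mid-bridge
(L1 = 0.18 on a common grid — the convergence diagnostic); the total action
17.6 sits above its transport lower bound W₂² = 16, as it must; and the
largest indicator increment is unremarkable (z ≈ 3), i.e. a smooth
unimodal-to-unimodal bridge raises no tipping alarm. Contrast this with the
two-cluster experiment in the vignette, where the indicator's z-score
exceeds 5 when the density splits.

A thin command-line interface wraps the same functions:

```sh
inst/cli/sbtip make-synthetic --kind nonconvex --n 5000 --seed 7 --out-prefix synth
inst/cli/sbtip train-bridge --rho0 synth_rho0.csv --rho1 synth_rho1.csv --g 0.5 --out model.ckpt
inst/cli/sbtip indicator --model model.ckpt --rho0 synth_rho0.csv --C auto --out indicator.csv
```

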