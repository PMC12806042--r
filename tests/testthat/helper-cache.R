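# Trained bridge models are expensive; fits are memoized here so that the
# unit tests and the acceptance suite share them within one test run.

.sbtip_fit_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.sbtip_fit_cache[[key]])) .sbtip_fit_cache[[key]] <- builder()
  .sbtip_fit_cache[[key]]
}

# Gaussian-pair bridge: rho0 = N(-2, 0.1), rho1 = N(2, 0.1) (variances), the
# standard smoke-test conditions.
gauss_pair_fit <- function(seed, g, stages = 8, iters = 200, N = 50) {
  cache_get(sprintf("gauss_%d_%g_%d_%d_%d", seed, g, stages, iters, N), function() {
    pair <- make_gaussian_pair(list(n = 2000, seed = 1000 + seed))
    fit <- alternating_train(pair$rho0, pair$rho1,
                             schedule = noise_schedule("constant", g),
                             T = 1, N = N,
                             config = sb_train_config(stages = stages, iters = iters),
                             seed = seed)
    fw <- propagate_forward(fit$model, pair$rho0, 2000, seed = 20 + seed)
    bw <- propagate_backward(fit$model, pair$rho1, 2000, seed = 40 + seed)
    list(pair = pair, fit = fit, model = fit$model, fwd = fw, bwd = bw)
  })
}

# Two-cluster non-convex task: connected source blob, disconnected target,
# bridged under the decaying (time-adaptive stand-in) noise schedule.
split_task_fit <- function(seed, stages = 8, iters = 200, N = 50) {
  cache_get(sprintf("split_%d_%d_%d_%d", seed, stages, iters, N), function() {
    dat <- make_nonconvex_target(list(n = 2000, seed = 2000 + seed))
    fit <- alternating_train(dat$rho0, dat$rho1,
                             schedule = noise_schedule("cosine", g = 1, g_end = 0.1),
                             T = 1, N = N,
                             config = sb_train_config(stages = stages, iters = iters),
                             seed = seed)
    fw <- propagate_forward(fit$model, dat$rho0, 2000, seed = 60 + seed)
    list(dat = dat, fit = fit, model = fit$model, fwd = fw)
  })
}
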