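# Likelihood training of the forward-backward SDE system by stage-wise
# alternation: each stage freezes one score field, simulates and caches a
# batch of trajectories under the frozen policy, and trains the other field
# on the cached states.
#
# Stage objectives are obtained from the discretized likelihood loss (see
# likelihood_loss) by dropping the terms that are constant within a stage:
#   backward stage (train Zhat on forward-sampled states):
#     sum_k dt E[ 1/2 ||Zhat||^2 + <Z, Zhat> + sig_k div Zhat ]
#   forward stage (train Z on backward-sampled states):
#     sum_k dt E[ 1/2 ||Z||^2 + <Zhat, Z> + sig_k div Z ]
# The boundary marginals are enforced by construction: forward caches start
# from rho0 samples, backward caches from rho1 samples (the iterative
# proportional fitting structure).  The terminal log-likelihood (or the
# quadratic cluster attachment) is constant under trajectory caching and so
# contributes to the reported loss, not to stage gradients.

#' Training configuration for [alternating_train()]
#'
#' @param stages Number of alternating half-stages (stage 1 trains the
#'   backward field on forward trajectories, stage 2 the forward field on
#'   backward trajectories, and so on). 0 returns the initialized model.
#' @param iters Adam iterations per stage (full-batch gradients on the cached
#'   trajectory states).
#' @param batch_paths Trajectories cached per stage.
#' @param lr Adam learning rate.
#' @param hidden Hidden width of the score networks.
#' @param init_scale Initialization scale of the score networks (small values
#'   start training from the reference process).
#' @param anneal_factor Noise-annealing start multiplier (>= 1). Early stages
#'   simulate and weight their objectives at `anneal_factor` times the target
#'   noise, decaying geometrically to 1 over the first 60 percent of the
#'   stages; this keeps the forward and backward trajectory tubes overlapping
#'   while the fields are still rough, which is what makes low-noise bridges
#'   trainable. 1 disables annealing. The returned model always carries the
#'   target schedule.
#' @return A list of class `sb_train_config`.
#' @export
sb_train_config <- function(stages = 8, iters = 200, batch_paths = 192,
                            lr = 2e-2, hidden = 48, init_scale = 0.05,
                            anneal_factor = 4) {
  structure(list(stages = stages, iters = iters, batch_paths = batch_paths,
                 lr = lr, hidden = hidden, init_scale = init_scale,
                 anneal_factor = anneal_factor),
            class = "sb_train_config")
}

# Per-stage noise multipliers: geometric decay from anneal_factor to 1 over
# the first 60% of the stages, then 1.  Early stages run at inflated noise so
# the forward and backward trajectory tubes overlap and each score field is
# trained where the opposite policy will visit; late stages run at the target
# noise, which is what the returned model carries.
anneal_multipliers <- function(stages, factor) {
  if (stages < 1) return(numeric(0))
  if (is.null(factor) || factor <= 1) return(rep(1, stages))
  n_dec <- max(1L, ceiling(0.6 * stages))
  mult <- rep(1, stages)
  mult[seq_len(n_dec)] <- factor^(rev(seq_len(n_dec) - 1) / max(n_dec - 1, 1))
  mult
}

#' Solve a Schrodinger bridge between two empirical marginals
#'
#' Likelihood training of the forward-backward SDE system by alternating
#' stages (see the package vignette for the scheme and its derivation).
#'
#' @param rho0_samples,rho1_samples Matrices (or vectors) of samples from the
#'   initial and terminal marginals.
#' @param drift A [drift_spec] for the reference process (default zero).
#' @param schedule A [noise_schedule].
#' @param T Physical horizon.
#' @param N Time steps.
#' @param config An [sb_train_config].
#' @param terminal_mode `"none"`, `"density"` or `"cluster"`; recorded on the
#'   model and used when reporting the full likelihood loss. In `"cluster"`
#'   mode `cluster_targets` carries the per-source-cell target atoms of the
#'   semi-discrete transport map.
#' @param cluster_targets Optional matrix of target atoms (cluster mode).
#' @param seed Master seed; fans out to initialization and per-stage
#'   simulation streams.
#' @return `list(model = bridge_model, report = data.frame(stage, iteration,
#'   loss), final_loss = ...)`. The loss column records the stage objective.
#' @export
alternating_train <- function(rho0_samples, rho1_samples, drift = NULL,
                              schedule = noise_schedule("constant", 1),
                              T = 1, N = 50, config = sb_train_config(),
                              terminal_mode = c("none", "density", "cluster"),
                              cluster_targets = NULL, seed = NULL) {
  terminal_mode <- match.arg(terminal_mode)
  X0 <- as_sample_matrix(rho0_samples, "rho0_samples")
  X1 <- as_sample_matrix(rho1_samples, "rho1_samples")
  if (ncol(X0) != ncol(X1)) stop("marginal dimensions differ")
  d <- ncol(X0)
  sub_seed <- function(i) {
    if (is.null(seed)) NULL else (as.numeric(seed) * 1000003 + i) %% 2147483647
  }
  # parameterize the networks in drift units: gain = 1 / mean effective noise
  sig_bar <- mean(schedule$sigma(seq(0, 1, length.out = N + 1L) * T) * sqrt(T))
  gain <- 1 / max(sig_bar, 1e-6)
  m <- bridge_model(drift = drift, schedule = schedule,
                    z_fwd = score_mlp(d, config$hidden, config$init_scale,
                                      gain = gain, seed = sub_seed(1)),
                    z_bwd = score_mlp(d, config$hidden, config$init_scale,
                                      gain = gain, seed = sub_seed(2)),
                    T = T, N = N, d = d)
  m$terminal_mode <- terminal_mode
  m$cluster_targets <- cluster_targets
  report <- vector("list", max(config$stages, 0))
  opt_f <- adam_init(m$z_fwd)
  opt_b <- adam_init(m$z_bwd)
  g <- model_grid(m)
  mults <- anneal_multipliers(config$stages, config$anneal_factor)
  for (stage in seq_len(config$stages)) {
    train_bwd <- stage %% 2L == 1L
    # stage model: same fields, noise inflated by the annealing multiplier.
    # The field gains are rescaled to 1/(sigma_bar * multiplier) so that the
    # network weights keep representing the same transport drift u = sigma * Z
    # across stages; without this the drift correction would jump whenever the
    # stage noise changes.
    ms <- m
    if (mults[stage] != 1) {
      base_sigma <- m$schedule$sigma
      ms$schedule <- structure(
        list(kind = m$schedule$kind, g = m$schedule$g * mults[stage],
             g_end = m$schedule$g_end * mults[stage], T = m$schedule$T,
             sigma = local({ f <- mults[stage]; function(t) f * base_sigma(t) })),
        class = "noise_schedule")
    }
    ms$z_fwd$gain <- gain / mults[stage]
    ms$z_bwd$gain <- gain / mults[stage]
    m$z_fwd$gain <- gain / mults[stage]
    m$z_bwd$gain <- gain / mults[stage]
    ens <- if (train_bwd)
      propagate_forward(ms, X0, config$batch_paths, sub_seed(100 + stage))
    else
      propagate_backward(ms, X1, config$batch_paths, sub_seed(100 + stage))
    cache <- flatten_left_states(ens, ms)
    frozen <- if (train_bwd) m$z_fwd else m$z_bwd
    Cmat <- sf_eval(frozen, cache$t_int, cache$X)
    w <- rep(g$dt / config$batch_paths, nrow(cache$X))
    omega <- w * cache$sig
    field <- if (train_bwd) m$z_bwd else m$z_fwd
    opt <- if (train_bwd) opt_b else opt_f
    losses <- numeric(config$iters)
    for (it in seq_len(config$iters)) {
      fwd <- mlp_forward(field, cache$t_int, cache$X)
      gr <- mlp_objective_grad(field, fwd$U, fwd$A, fwd$Z, Cmat, w, omega)
      if (!is.finite(gr$value))
        stop("divergent loss at stage ", stage, ", iteration ", it)
      st <- adam_step(field, gr, opt, lr = config$lr)
      field <- st$field; opt <- st$state
      losses[it] <- gr$value
    }
    if (train_bwd) { m$z_bwd <- field; opt_b <- opt }
    else { m$z_fwd <- field; opt_f <- opt }
    report[[stage]] <- data.frame(stage = stage,
                                  iteration = seq_len(config$iters),
                                  loss = losses)
  }
  report <- if (length(report)) do.call(rbind, report)
            else data.frame(stage = integer(0), iteration = integer(0),
                            loss = numeric(0))
  list(model = m, report = report,
       final_loss = if (nrow(report)) report$loss[nrow(report)] else NA_real_)
}

# Flatten an ensemble into evaluation rows at the left grid points
# k = 0..N-1: states, internal times and effective sigmas.
flatten_left_states <- function(ens, m) {
  g <- model_grid(m)
  n <- dim(ens$states)[1]
  Xs <- vector("list", m$N)
  for (k in seq_len(m$N)) Xs[[k]] <- slice_states(ens, k)
  list(X = do.call(rbind, Xs),
       t_int = rep(g$s[seq_len(m$N)], each = n),
       sig = rep(g$sig[seq_len(m$N)], each = n))
}
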