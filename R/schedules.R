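# Noise schedules sigma(t) and base drift specifications for bridge models.

#' Noise schedule
#'
#' A nonnegative scalar noise intensity as a function of physical time on
#' `[0, T]`. `"constant"` returns `g` everywhere; `"linear"` interpolates from
#' `g` at t = 0 to `g_end` at t = T; `"cosine"` follows a half-cosine ramp
#' between the same endpoints (smooth start and finish), a simple stand-in for
#' time-adaptive intensities.
#'
#' @param kind One of `"constant"`, `"linear"`, `"cosine"`.
#' @param g Noise intensity at t = 0 (and everywhere, for `"constant"`).
#' @param g_end Intensity at t = T for the time-varying kinds.
#' @param T Physical horizon the schedule is defined on.
#' @return An object of class `noise_schedule` with a vectorized `$sigma(t)`.
#' @export
noise_schedule <- function(kind = c("constant", "linear", "cosine"),
                           g = 1, g_end = g, T = 1) {
  kind <- match.arg(kind)
  stopifnot(g >= 0, g_end >= 0, T > 0)
  sigma <- switch(kind,
    constant = function(t) rep_len(g, length(t)),
    linear = function(t) {
      s <- pmin(pmax(t / T, 0), 1)
      g + (g_end - g) * s
    },
    cosine = function(t) {
      s <- pmin(pmax(t / T, 0), 1)
      g + (g_end - g) * (1 - cos(pi * s)) / 2
    })
  structure(list(kind = kind, g = g, g_end = g_end, T = T, sigma = sigma),
            class = "noise_schedule")
}

#' Base drift specification
#'
#' Wraps the reference-process drift `f(t, x)` of the bridge. `drift_spec()`
#' with no argument gives the zero field (plain Brownian reference);
#' [ml_drift_spec()] wraps the Morris-Lecar field.
#'
#' @param fn `NULL` for the zero field, or `function(t, X)` mapping physical
#'   time and an n x d state matrix to an n x d drift matrix.
#' @param name Label used in printing.
#' @return An object of class `drift_spec`.
#' @export
drift_spec <- function(fn = NULL, name = if (is.null(fn)) "zero" else "custom") {
  if (is.null(fn)) {
    fn <- function(t, X) matrix(0, nrow(X), ncol(X))
    name <- "zero"
  }
  stopifnot(is.function(fn))
  structure(list(fn = fn, name = name), class = "drift_spec")
}

#' @rdname drift_spec
#' @param p An [ml_params] object.
#' @export
ml_drift_spec <- function(p) {
  validate_ml_params(p)
  drift_spec(function(t, X) ml_drift(X, p), name = paste0("morris_lecar_", p$regime_label))
}
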