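# Internal helpers shared across modules.

# Wrap angles into (-pi, pi].
wrap_pi <- function(x) {
  y <- ((x + pi) %% (2 * pi)) - pi
  y[y == -pi] <- pi
  y
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Minimum-jerk progression profile on s in [0, 1] (clamped outside).
min_jerk <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  10 * s^3 - 15 * s^4 + 6 * s^5
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_jc <- function(...) stop(sprintf(...), call. = FALSE)
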