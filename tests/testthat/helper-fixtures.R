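# Shared fixtures: a default hydrodynamic context and a small helper to
# build noiseless straight-line tracks.

default_ctx <- hydro_context()

straight_track <- function(speed_um_s, duration = 300, dt = 10,
                           direction = c(-1, 0), x0 = 300, y0 = 300,
                           id = 1) {
  times <- seq(0, duration, by = dt)
  tibble::tibble(
    track_id = id,
    frame = seq_along(times) - 1,
    time = times,
    x = x0 + direction[1] * speed_um_s * times,
    y = y0 + direction[2] * speed_um_s * times
  )
}

# Noiseless creep series generated directly from the model (bypasses the
# trajectory layer) for fit-recovery tests.
model_creep_series <- function(G0, G1, mu0p, mu1p, F_A = 1.56e-9,
                               dt = 0.5, duration = 30,
                               ctx = default_ctx, noise_sd = 0) {
  t <- seq(0, duration, by = dt)
  J <- c(0, kv4_compliance(t[-1], G0, G1, mu0p, mu1p))
  scale <- F_A / (6 * pi * ctx$particle$radius * ctx$correction)
  X <- J * scale
  if (noise_sd > 0) X <- X + rnorm(length(X), 0, noise_sd)
  structure(
    tibble::tibble(time = t, displacement = X,
                   compliance = 6 * pi * ctx$particle$radius *
                     ctx$correction * X / F_A),
    class = c("creep_series", class(tibble::tibble())),
    F_A = F_A, ctx = ctx
  )
}
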