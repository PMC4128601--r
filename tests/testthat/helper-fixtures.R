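# shared fixtures, built lazily and cached for the whole test run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (is.null(.fixtures[[name]])) {
    .fixtures[[name]] <- switch(name,
      proto = make_adjacent_protocol(16),
      mesh6 = build_mesh(density = 6),          # ~200 elements, oracle scale
      mesh8 = build_mesh(density = 8),          # ~500 elements, phantom scale
      J6 = conductivity_jacobian(fixture("mesh6"), 1, fixture("proto")),
      J6n = conductivity_jacobian(fixture("mesh6"), 1, fixture("proto"),
                                  normalized = TRUE),
      R6 = noser_prior(fixture("J6n")),
      model_A0 = build_reconstructor("A0", fixture("mesh6"), fixture("proto")),
      model_F2 = build_reconstructor("F2", fixture("mesh6"), fixture("proto")),
      model_I2 = build_reconstructor("I2", fixture("mesh6"), fixture("proto")),
      quiet_recording = simulate_recording(
        fixture("mesh8"), fixture("proto"),
        phantom_config(noise_sd = 0, gain_sd = 0), "Z21a", seed = 3),
      stop("unknown fixture ", name))
  }
  .fixtures[[name]]
}

# relative max reciprocity violation of a channel-voltage vector
reciprocity_violation <- function(v, protocol) {
  r <- attr(protocol, "reciprocal")
  max(abs(v - v[r])) / max(abs(v))
}

# target contrast: elements within 0.1 of a point at radius 0.5
point_target <- function(mesh, angle = 0) {
  ctr <- 0.5 * mesh$radius * c(cos(angle), sin(angle))
  d <- sqrt((mesh$centroids[, 1] - ctr[1])^2 + (mesh$centroids[, 2] - ctr[2])^2)
  x <- as.numeric(d <= 0.1 * mesh$radius)
  if (!any(x > 0)) x[which.min(d)] <- 1
  x
}
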