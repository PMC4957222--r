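# Circular statistics used only to validate the simulator.

circ_mean <- function(phi) atan2(mean(sin(phi)), mean(cos(phi)))

circ_dist <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# Rayleigh test of circular uniformity; returns the p-value.
rayleigh_p <- function(phi) {
  n <- length(phi)
  R <- sqrt(mean(cos(phi))^2 + mean(sin(phi))^2)
  Z <- n * R^2
  exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n))
}

# Circular-linear correlation (Mardia): correlation of x with (cos phi, sin phi).
circ_lin_cor <- function(phi, x) {
  rcx <- cor(x, cos(phi)); rsx <- cor(x, sin(phi)); rcs <- cor(cos(phi), sin(phi))
  sqrt((rcx^2 + rsx^2 - 2 * rcx * rsx * rcs) / (1 - rcs^2))
}
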