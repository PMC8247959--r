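# Independent oracles used against the package's analytic machinery.

# closed-form consecutive-reaction (Bateman) solutions for the chain
# A --k1--> B --k2--> C starting from pure A, k1 != k2
bateman_intermediate <- function(t, k1, k2) {
  k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
}
bateman_product <- function(t, k1, k2) {
  1 - (k2 * exp(-k1 * t) - k1 * exp(-k2 * t)) / (k2 - k1)
}

# brute-force numerical integration of the reaction network ODEs, as an
# oracle for the matrix-exponential propagator
ode_propagate <- function(net, initial, times) {
  A <- phratefit:::network_matrix(net)
  rhs <- function(t, y, parms) list(as.numeric(A %*% y))
  out <- deSolve::lsoda(y = initial, times = times, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-14)
  unname(as.matrix(out[, -1]))
}

random_network <- function() {
  k <- stats::runif(6, 0, 1e-5)
  kinetic_network(k_iso_45 = k[1], k_iso_54 = k[2], k_cl_4 = k[3],
                  k_cl_5 = k[4], k_h_cAMP = k[5], k_h_AMP = k[6])
}

# closed-form weighted least-squares line through the normal equations
wls_line <- function(x, y, w) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  c(intercept = beta[1], slope = beta[2])
}
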