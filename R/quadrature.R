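# Gauss-Hermite rule rescaled for expectations over a standard normal:
# E[f(Z)] ~ sum(w * f(x)).  Weights are renormalised to sum exactly to 1
# so that constants integrate without quadrature round-off.
gh_rule <- function(order) {
  if (order < 2L) stop("quadrature order must be at least 2", call. = FALSE)
  r <- pracma::gaussHermite(as.integer(order))
  list(x = sqrt(2) * r$x, w = r$w / sum(r$w))
}
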