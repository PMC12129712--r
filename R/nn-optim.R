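# Adam optimiser over nested parameter lists.

adam_init <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

# Elementwise walk of two same-shaped nested lists.
walk2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- walk2(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- walk2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- walk2(state$v, grads,
                   function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- walk2(state$m, state$v,
               function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- walk2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
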