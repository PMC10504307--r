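# Low-level building blocks for the two adversarial networks: thin R wrappers
# around the compiled conv/pool/upsample kernels, activation functions with
# their derivatives, and an Adam optimizer over named parameter lists.

conv_fw <- function(x, w, b, k = 3L) .conv2d_forward(x, w, b, k)
conv_bw <- function(x, w, dy, k = 3L) .conv2d_backward(x, w, dy, k)

relu_fw <- function(x) pmax(x, 0)
relu_bw <- function(pre, dy) dy * (pre > 0)
lrelu_fw <- function(x, a = 0.2) {
  pos <- x > 0
  x * (pos + a * !pos)
}
lrelu_bw <- function(pre, dy, a = 0.2) {
  pos <- pre > 0
  dy * (pos + a * !pos)
}
tanh_bw <- function(y, dy) dy * (1 - y^2)
sigmoid_fw <- function(x) 1 / (1 + exp(-x))

# He-normal conv init: weight matrix (k*k*cin) x cout
init_conv <- function(k, cin, cout, gain = 2) {
  fan_in <- k * k * cin
  list(w = matrix(rnorm(fan_in * cout, 0, sqrt(gain / fan_in)), fan_in, cout),
       b = numeric(cout))
}

n_params <- function(params) {
  sum(vapply(params, function(p) length(p$w) + length(p$b), numeric(1)))
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) list(w = p$w * 0, b = p$b * 0)),
       v = lapply(params, function(p) list(w = p$w * 0, b = p$b * 0)))
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (slot in c("w", "b")) {
      g <- grads[[nm]][[slot]]
      if (is.null(g)) next
      state$m[[nm]][[slot]] <- beta1 * state$m[[nm]][[slot]] + (1 - beta1) * g
      state$v[[nm]][[slot]] <- beta2 * state$v[[nm]][[slot]] + (1 - beta2) * g^2
      params[[nm]][[slot]] <- params[[nm]][[slot]] -
        lr * (state$m[[nm]][[slot]] / bc1) /
        (sqrt(state$v[[nm]][[slot]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]]$w <- a[[nm]]$w + b[[nm]]$w
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}
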