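# Shared fixtures: tiny tensors, random small RBMs and views, and the
# enumeration utilities used as independent oracles.

# A tiny deterministic tensor: 5 drugs x 4 diseases.
tinyTensor <- function() {
  a <- array(0L, c(5, 4, 3))
  a[1, 2, 1] <- 1L            # drug 1 indicated for disease 2
  a[1, 3, 2] <- a[1, 3, 3] <- 1L  # SE + CI at disease 3
  a[2, 1, 2] <- 1L
  a[3, 2, 1] <- a[3, 4, 3] <- 1L
  a[4, 4, 2] <- 1L
  AssociationTensor(a)
}

randomModel <- function(nv, m, scale = 0.7) {
  RBMModel(W = array(rnorm(nv * m * 3, sd = scale), c(nv, m, 3)),
           a = matrix(rnorm(nv * 3, sd = scale), nv, 3),
           b = rnorm(m, sd = scale),
           D = matrix(rnorm(nv * m, sd = scale), nv, m))
}

zeroModel <- function(nv, m) {
  RBMModel(W = array(0, c(nv, m, 3)), a = matrix(0, nv, 3),
           b = numeric(m), D = matrix(0, nv, m))
}

# A random valid view: every observed disease carries at least one bit.
randomView <- function(nv, obs) {
  v <- matrix(0, nv, 3)
  for (i in obs) {
    bits <- rbinom(3, 1, 0.5)
    if (sum(bits) == 0) bits[sample.int(3, 1)] <- 1
    v[i, ] <- bits
  }
  methods::new("DrugView", entity = 1L, observed = as.integer(obs), v = v,
               r = as.numeric(seq_len(nv) %in% obs))
}

# Same view with a different visible configuration (enumeration only;
# bypasses the at-least-one-bit data invariant on purpose).
viewWithV <- function(view, v) {
  slot(view, "v", check = FALSE) <- v
  view
}

# Independent oracle: log p(v | r) by enumerating every joint (v, h)
# configuration of the energy model. O(2^(3|O|) * 2^m); tiny cases only.
enumLogLik <- function(model, view) {
  nv <- nVisible(model); m <- nHidden(model)
  Wf <- matrix(aperm(model@W, c(1, 3, 2)), nv * 3, m)
  obs <- view@observed
  vc <- as.matrix(expand.grid(rep(list(0:1), 3 * length(obs))))
  hc <- as.matrix(expand.grid(rep(list(0:1), m)))
  condPre <- drop(crossprod(model@D, view@r))
  allNegE <- NULL
  target <- NA
  for (i in seq_len(nrow(vc))) {
    v <- matrix(0, nv, 3)
    v[obs, ] <- matrix(vc[i, ], length(obs), 3)
    vf <- as.vector(v)
    hidPre <- drop(crossprod(Wf, vf)) + model@b + condPre
    negE <- vapply(seq_len(nrow(hc)), function(j)
      sum(as.vector(model@a) * vf) + sum(hidPre * hc[j, ]), 0)
    allNegE <- rbind(allNegE, negE)
    if (all(v == view@v)) target <- i
  }
  lse <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
  lse(allNegE[target, ]) - lse(as.vector(allNegE))
}
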