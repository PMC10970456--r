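# panel builders used across the suite

# X, Y: dimension x unit matrices
make_panel <- function(X, Y, inst = NULL, state = "S") {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- ncol(X)
  if (is.null(inst)) inst <- sprintf("U%02d", seq_len(n))
  d <- data.frame(institution = inst, state = state, t(X), t(Y))
  ind <- sprintf("in%d", seq_len(nrow(X)))
  outd <- sprintf("out%d", seq_len(nrow(Y)))
  names(d)[-(1:2)] <- c(ind, outd)
  dea_panel(d, inputs = ind, outputs = outd)
}

random_panel <- function(n, m, s, lo = 1, hi = 100) {
  make_panel(matrix(runif(m * n, lo, hi), m, n),
             matrix(runif(s * n, lo, hi), s, n))
}

toy_panel <- function() {
  make_panel(matrix(c(1, 2), 1), matrix(c(2, 2), 1))
}
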