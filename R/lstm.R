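# Coupled-gate peephole LSTM.
#
# The cell has no separate forget gate: the forget coefficient is
# (1 - i_t). Both gates carry peephole connections (W_ci on the previous
# cell state, W_co on the current one):
#
#   i_t = sigma(W_xi x_t + W_hi h_{t-1} + W_ci c_{t-1} + b_i)
#   c_t = (1 - i_t) (.) c_{t-1} + i_t (.) tanh(W_xc x_t + W_hc h_{t-1} + b_c)
#   o_t = sigma(W_xo x_t + W_ho h_{t-1} + W_co c_t + b_o)
#   h_t = o_t (.) tanh(c_t)
#
# Backpropagation through this exact cell is derived by hand below and
# verified against central finite differences in the test suite.

#' Initialize coupled-gate LSTM cell parameters
#'
#' Weight matrices are Glorot-uniform, biases zero.
#'
#' @param input_size dimension of x_t.
#' @param hidden_size dimension of h_t and c_t.
#' @param seed integer seed.
#' @return an object of class `lstm_cell`: a named list of matrices
#'   `W_xi, W_hi, W_ci, b_i, W_xc, W_hc, b_c, W_xo, W_ho, W_co, b_o`.
#' @export
new_lstm_cell <- function(input_size, hidden_size, seed = 1L) {
  D <- input_size; H <- hidden_size
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
  }
  with_seed(seed, {
    cell <- list(
      W_xi = glorot(H, D), W_hi = glorot(H, H), W_ci = glorot(H, H),
      b_i = numeric(H),
      W_xc = glorot(H, D), W_hc = glorot(H, H), b_c = numeric(H),
      W_xo = glorot(H, D), W_ho = glorot(H, H), W_co = glorot(H, H),
      b_o = numeric(H)
    )
  })
  structure(cell, class = "lstm_cell")
}

zero_like_cell <- function(cell) {
  out <- lapply(cell, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
  class(out) <- "lstm_cell"
  out
}

#' One step of the coupled-gate peephole LSTM
#'
#' Computes the cell recurrences above exactly: input gate with peephole on
#' `c_prev`, coupled forget coefficient `(1 - i_t)`, output gate with
#' peephole on the freshly computed `c_t`.
#'
#' @param x_t input vector (length D).
#' @param h_prev,c_prev previous hidden and cell state (length H).
#' @param cell an [new_lstm_cell()] parameter list.
#' @return list with `h` and `c` (each length H).
#' @export
lstm_step <- function(x_t, h_prev, c_prev, cell) {
  H <- length(cell$b_i)
  if (length(x_t) != ncol(cell$W_xi) || length(h_prev) != H ||
        length(c_prev) != H) {
    stop("lstm_step: shape mismatch between inputs and cell parameters")
  }
  i <- sigmoid(as.numeric(cell$W_xi %*% x_t) + as.numeric(cell$W_hi %*% h_prev) +
                 as.numeric(cell$W_ci %*% c_prev) + cell$b_i)
  g <- tanh(as.numeric(cell$W_xc %*% x_t) + as.numeric(cell$W_hc %*% h_prev) +
              cell$b_c)
  c_t <- (1 - i) * c_prev + i * g
  o <- sigmoid(as.numeric(cell$W_xo %*% x_t) + as.numeric(cell$W_ho %*% h_prev) +
                 as.numeric(cell$W_co %*% c_t) + cell$b_o)
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t)
}

# Forward pass over a whole sentence with caches for backprop.
# X is n x D; initial h, c are zero. Returns H_out (n x H) plus caches.
lstm_forward <- function(X, cell) {
  n <- nrow(X); H <- length(cell$b_i)
  Xi <- X %*% t(cell$W_xi)   # n x H precomputed input contributions
  Xc <- X %*% t(cell$W_xc)
  Xo <- X %*% t(cell$W_xo)
  I <- matrix(0, n, H); G <- matrix(0, n, H); O <- matrix(0, n, H)
  Cs <- matrix(0, n + 1L, H)   # row t holds c_{t-1}
  Hs <- matrix(0, n + 1L, H)   # row t holds h_{t-1}
  TanhC <- matrix(0, n, H)
  h <- numeric(H); c <- numeric(H)
  for (t in seq_len(n)) {
    i <- sigmoid(Xi[t, ] + as.numeric(cell$W_hi %*% h) +
                   as.numeric(cell$W_ci %*% c) + cell$b_i)
    g <- tanh(Xc[t, ] + as.numeric(cell$W_hc %*% h) + cell$b_c)
    c_new <- (1 - i) * c + i * g
    o <- sigmoid(Xo[t, ] + as.numeric(cell$W_ho %*% h) +
                   as.numeric(cell$W_co %*% c_new) + cell$b_o)
    tc <- tanh(c_new)
    h <- o * tc
    I[t, ] <- i; G[t, ] <- g; O[t, ] <- o; TanhC[t, ] <- tc
    Cs[t + 1L, ] <- c_new; Hs[t + 1L, ] <- h
    c <- c_new
  }
  list(H_out = Hs[-1L, , drop = FALSE],
       cache = list(X = X, I = I, G = G, O = O, Cs = Cs, Hs = Hs,
                    TanhC = TanhC))
}

# Backward pass. dH_out is n x H (dLoss/dh_t). Returns parameter
# gradients (same structure as the cell) and dX (n x D).
lstm_backward <- function(cell, cache, dH_out) {
  X <- cache$X; I <- cache$I; G <- cache$G; O <- cache$O
  Cs <- cache$Cs; Hs <- cache$Hs; TanhC <- cache$TanhC
  n <- nrow(X); H <- ncol(I)
  g_cell <- zero_like_cell(cell)
  dX <- matrix(0, n, ncol(X))
  dh_next <- numeric(H); dc_next <- numeric(H)
  for (t in seq(n, 1L)) {
    x_t <- X[t, ]
    i <- I[t, ]; g <- G[t, ]; o <- O[t, ]; tc <- TanhC[t, ]
    c_prev <- Cs[t, ]; c_t <- Cs[t + 1L, ]; h_prev <- Hs[t, ]
    dh <- dH_out[t, ] + dh_next
    do_ <- dh * tc
    da_o <- do_ * o * (1 - o)
    dc <- dh * o * (1 - tc^2) + dc_next +
      as.numeric(crossprod(cell$W_co, da_o))
    di <- dc * (g - c_prev)
    dg <- dc * i
    dc_prev <- dc * (1 - i)
    da_i <- di * i * (1 - i)
    dc_prev <- dc_prev + as.numeric(crossprod(cell$W_ci, da_i))
    da_g <- dg * (1 - g^2)
    g_cell$W_xi <- g_cell$W_xi + tcrossprod(da_i, x_t)
    g_cell$W_hi <- g_cell$W_hi + tcrossprod(da_i, h_prev)
    g_cell$W_ci <- g_cell$W_ci + tcrossprod(da_i, c_prev)
    g_cell$b_i <- g_cell$b_i + da_i
    g_cell$W_xc <- g_cell$W_xc + tcrossprod(da_g, x_t)
    g_cell$W_hc <- g_cell$W_hc + tcrossprod(da_g, h_prev)
    g_cell$b_c <- g_cell$b_c + da_g
    g_cell$W_xo <- g_cell$W_xo + tcrossprod(da_o, x_t)
    g_cell$W_ho <- g_cell$W_ho + tcrossprod(da_o, h_prev)
    g_cell$W_co <- g_cell$W_co + tcrossprod(da_o, c_t)
    g_cell$b_o <- g_cell$b_o + da_o
    dX[t, ] <- as.numeric(crossprod(cell$W_xi, da_i)) +
      as.numeric(crossprod(cell$W_xc, da_g)) +
      as.numeric(crossprod(cell$W_xo, da_o))
    dh_next <- as.numeric(crossprod(cell$W_hi, da_i)) +
      as.numeric(crossprod(cell$W_hc, da_g)) +
      as.numeric(crossprod(cell$W_ho, da_o))
    dc_next <- dc_prev
  }
  list(grads = g_cell, dX = dX)
}

#' Bidirectional LSTM encoding of an embedded sentence
#'
#' Runs `forward_cell` left-to-right and `backward_cell` right-to-left
#' (independent parameters, zero initial states) and concatenates the
#' two hidden states per position.
#'
#' @param X n x D matrix of embedded tokens, n >= 1.
#' @param forward_cell,backward_cell [new_lstm_cell()] parameter lists.
#' @return n x 2H matrix `[h_fwd ; h_bwd]`.
#' @export
bilstm_encode <- function(X, forward_cell, backward_cell) {
  if (!is.matrix(X) || nrow(X) < 1) stop("empty sentence")
  fw <- lstm_forward(X, forward_cell)
  bw <- lstm_forward(X[rev(seq_len(nrow(X))), , drop = FALSE], backward_cell)
  cbind(fw$H_out, bw$H_out[rev(seq_len(nrow(X))), , drop = FALSE])
}
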