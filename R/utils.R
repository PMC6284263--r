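#' Numerically stable log-sum-exp
#'
#' @param x numeric vector.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Logistic function
#' @param x numeric.
#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# Seed handling: every stochastic entry point takes an integer seed and
# restores the caller's RNG state on exit, so library calls never perturb
# user-level reproducibility.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Flatten a nested list of numeric arrays into one vector, and write a
# flat vector back into the same structure. Used by the finite-difference
# gradient checks and by global-norm gradient clipping.
flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

unflatten_params <- function(template, x) {
  out <- template
  pos <- 1L
  assign_rec <- function(node) {
    if (is.list(node)) {
      for (i in seq_along(node)) node[[i]] <- assign_rec(node[[i]])
      node
    } else {
      n <- length(node)
      v <- x[pos:(pos + n - 1L)]
      pos <<- pos + n
      if (is.matrix(node)) {
        matrix(v, nrow = nrow(node), ncol = ncol(node))
      } else {
        v
      }
    }
  }
  assign_rec(out)
}

global_norm <- function(p) sqrt(sum(flatten_params(p)^2))

scale_params <- function(p, s) {
  if (is.list(p)) lapply(p, scale_params, s = s) else p * s
}

add_params <- function(a, b, s = 1) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- add_params(a[[i]], b[[i]], s)
    a
  } else {
    a + s * b
  }
}
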