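# Shared constants and small helpers.

# 20 canonical amino acids + gap; the gap is deliberately last so that it can
# serve as the reference state removed during mean-field inversion.
aa_alphabet <- function(q = 21L) {
  ab <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
  if (q < 1L || q > 21L) stop("alphabet size must be between 1 and 21")
  ab[seq_len(q)]
}

# column block of the flattened (site, state) indexing for site i
.state_block <- function(i, q) ((i - 1L) * q + 1L):(i * q)

# run an expression with a locally set RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# one-hot encoding of an alignment character matrix as a sparse M x (L*q)
# indicator matrix, ordered site-major (site 1 states, site 2 states, ...)
one_hot <- function(seqs, alphabet) {
  q <- length(alphabet)
  M <- nrow(seqs)
  L <- ncol(seqs)
  state <- match(seqs, alphabet)
  if (anyNA(state)) stop("alignment contains symbols outside the alphabet")
  col <- rep((seq_len(L) - 1L) * q, each = M) + state
  Matrix::sparseMatrix(i = rep(seq_len(M), L), j = col, x = 1,
                       dims = c(M, L * q))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
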