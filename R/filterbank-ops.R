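# Decimated periodic filtering, implemented as cached banded matrices so that
# a whole image column block is transformed with one BLAS call.

.twinwave_cache <- new.env(parent = emptyenv())

.mat_key <- function(tag, N, f, phase) {
  paste(tag, N, phase, length(f), format(sum(f * seq_along(f)), digits = 17),
        format(sum(f * f), digits = 17), sep = "|")
}

# analysis operator: (N/2) x N matrix A with
#   (A x)[k] = sum_n f[n] x[(2k + phase - n) mod N]
.dec_mat <- function(N, f, phase) {
  key <- .mat_key("dec", N, f, phase)
  M <- .twinwave_cache[[key]]
  if (!is.null(M)) return(M)
  K <- N %/% 2L
  M <- matrix(0, K, N)
  for (n in seq_along(f) - 1L) {
    idx <- ((seq.int(0L, N - 2L, 2L) + phase - n) %% N) + 1L
    M[cbind(seq_len(K), idx)] <- M[cbind(seq_len(K), idx)] + f[n + 1L]
  }
  .twinwave_cache[[key]] <- M
  M
}

# synthesis operator: N x (N/2) matrix S with the overall filter-bank delay d
# already compensated:
#   (S y)[t] = sum_n f[n] u[(t + d - n) mod N],  u[2k + phase] = y[k]
.syn_mat <- function(N, f, phase, d) {
  key <- .mat_key(paste0("syn", d), N, f, phase)
  M <- .twinwave_cache[[key]]
  if (!is.null(M)) return(M)
  K <- N %/% 2L
  M <- matrix(0, N, K)
  up_pos <- (seq.int(0L, N - 2L, 2L) + phase) %% N      # position of y[k]
  for (n in seq_along(f) - 1L) {
    rows <- ((up_pos + n - d) %% N) + 1L
    M[cbind(rows, seq_len(K))] <- M[cbind(rows, seq_len(K))] + f[n + 1L]
  }
  .twinwave_cache[[key]] <- M
  M
}

# One separable 2-D analysis step for a single (row-tree, col-tree) pair.
# `fc` filters run along dim 1 (matrix rows), `fr` along dim 2 (columns).
.fwt_step <- function(X, fr, fc) {
  A0c <- .dec_mat(nrow(X), fc$h0, fc$phase)
  A1c <- .dec_mat(nrow(X), fc$h1, fc$phase)
  A0r <- .dec_mat(ncol(X), fr$h0, fr$phase)
  A1r <- .dec_mat(ncol(X), fr$h1, fr$phase)
  lo <- A0c %*% X
  hi <- A1c %*% X
  list(LL = lo %*% t(A0r), LH = hi %*% t(A0r),
       HL = lo %*% t(A1r), HH = hi %*% t(A1r))
}

.iwt_step <- function(sb, fr, fc) {
  N1 <- 2L * nrow(sb$LL)
  N2 <- 2L * ncol(sb$LL)
  S0c <- .syn_mat(N1, fc$g0, fc$phase, fc$d)
  S1c <- .syn_mat(N1, fc$g1, fc$phase, fc$d)
  S0r <- .syn_mat(N2, fr$g0, fr$phase, fr$d)
  S1r <- .syn_mat(N2, fr$g1, fr$phase, fr$d)
  lo <- sb$LL %*% t(S0r) + sb$HL %*% t(S1r)
  hi <- sb$LH %*% t(S0r) + sb$HH %*% t(S1r)
  S0c %*% lo + S1c %*% hi
}
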