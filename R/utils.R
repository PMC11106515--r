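# Summed-area table with a zero padding row/column: S[r+1, c+1] = sum of
# X[1:r, 1:c]. sat_rect() then returns rectangle sums for vectors of
# (row1, row2, col1, col2), all 1-based inclusive.
sat <- function(X) {
  S <- matrix(0, nrow(X) + 1L, ncol(X) + 1L)
  S[-1L, -1L] <- t(apply(apply(X, 2L, cumsum), 1L, cumsum))
  S
}

sat_rect <- function(S, r1, r2, c1, c2) {
  S[cbind(r2 + 1L, c2 + 1L)] - S[cbind(r1, c2 + 1L)] -
    S[cbind(r2 + 1L, c1)] + S[cbind(r1, c1)]
}
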