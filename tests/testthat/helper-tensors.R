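# shared fixture builders for the tensor tests

random_beta_tensor <- function(seed, sd = 100, frequency = 0) {
  set.seed(seed)
  beta_tensor(array(rnorm(27, sd = sd), c(3, 3, 3)), frequency = frequency)
}

single_component_tensor <- function(value = 1, i = 3, j = 3, k = 3) {
  b <- array(0, c(3, 3, 3))
  b[i, j, k] <- value
  beta_tensor(b, symmetrize = TRUE)
}

# independent exact oracle for <beta'_ZZZ^2>: the sixth moment of a uniform
# unit vector is the symmetrized triple-delta sum over the 15 perfect
# matchings of six index slots, divided by 105:
#   E[z_a z_b z_c z_d z_e z_f] = (1/105) * sum_matchings delta..delta
# Contracting beta_abc beta_def against it is a finite sum, independent of
# the closed-form coefficient bookkeeping under test.
zzz2_pairing_oracle <- function(t) {
  b <- t$components
  idx <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
  # pairings of slots (a,b,c,d,e,f); slots 1:3 from the first beta, 4:6 second
  matchings <- list(
    c(1,2, 3,4, 5,6), c(1,2, 3,5, 4,6), c(1,2, 3,6, 4,5),
    c(1,3, 2,4, 5,6), c(1,3, 2,5, 4,6), c(1,3, 2,6, 4,5),
    c(1,4, 2,3, 5,6), c(1,4, 2,5, 3,6), c(1,4, 2,6, 3,5),
    c(1,5, 2,3, 4,6), c(1,5, 2,4, 3,6), c(1,5, 2,6, 3,4),
    c(1,6, 2,3, 4,5), c(1,6, 2,4, 3,5), c(1,6, 2,5, 3,4))
  total <- 0
  for (u in seq_len(27)) for (v in seq_len(27)) {
    slots <- c(unlist(idx[u, ]), unlist(idx[v, ]))
    bb <- b[idx$a[u], idx$b[u], idx$c[u]] * b[idx$a[v], idx$b[v], idx$c[v]]
    if (bb == 0) next
    m_sum <- 0
    for (m in matchings) {
      if (slots[m[1]] == slots[m[2]] && slots[m[3]] == slots[m[4]] &&
          slots[m[5]] == slots[m[6]]) m_sum <- m_sum + 1
    }
    total <- total + bb * m_sum
  }
  total / 105
}
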