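# shared helpers: tiny constructors and brute-force oracles

make_spec <- function(name, efficacy, role = "prevention", af = 1, inc_e = 0,
                      inc_af = 1) {
  intervention_spec(name, role, efficacy = efficacy, affected_fraction = af,
                    incidence_efficacy = inc_e,
                    incidence_affected_fraction = inc_af)
}

random_specs <- function(n, role = NULL) {
  lapply(seq_len(n), function(i) {
    make_spec(sprintf("rnd_%02d", i),
              efficacy = runif(1),
              role = role %||% sample(c("prevention", "treatment"), 1),
              af = runif(1))
  })
}

`%||%` <- function(a, b) if (is.null(b) && FALSE) a else if (is.null(a)) b else a

# all permutations of 1..n, brute force (n <= 5 in tests)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# independent oracle for the residual: explicit product formula, written
# without reference to the cascade implementation
residual_oracle <- function(deaths, effs, afs, dcs) {
  deaths * prod(1 - effs * afs * dcs)
}
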