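# Independent brute-force oracles.  Everything here is written with scalar
# loops and per-individual enumeration, deliberately avoiding the package's
# vectorised code paths, so agreement is informative.

# rarity score of cell (species row i, community col k), computed from first
# principles on a bare count matrix
oracle_z <- function(n, map, i, k, component) {
  hab <- map$habitat[match(colnames(n)[k], map$community)]
  cols_in_hab <- which(map$habitat[match(colnames(n), map$community)] == hab)
  p_i <- sum(n[i, ]) / sum(n)
  p_i_jk <- n[i, k] / sum(n[, k])
  switch(component,
         gamma = -log(p_i),
         alpha = -log(p_i_jk),
         beta = -log(p_i) + log(p_i_jk))
}

# Shannon component by enumerating individuals: each of the n_... individuals
# contributes z / n_...
oracle_shannon <- function(ct, component) {
  n <- ct$counts
  total <- sum(n)
  acc <- 0
  for (i in seq_len(nrow(n))) {
    for (k in seq_len(ncol(n))) {
      if (n[i, k] > 0) {
        z <- oracle_z(n, ct$map, i, k, component)
        for (ind in seq_len(n[i, k])) acc <- acc + z / total
      }
    }
  }
  acc
}

# full-sum evaluation of the five-term partition, no factored shortcuts:
# explicit loops over species x community with scalar guards for every
# zero-mass conditioning event.  z_source = "pooled" only (the default).
oracle_partition <- function(prev_ct, fut_ct, component) {
  N <- prev_ct$counts
  Fm <- fut_ct$counts
  map <- prev_ct$map
  hab_of_col <- map$habitat[match(colnames(N), map$community)]

  M <- Fm * (N == 0)
  R <- Fm - M
  phi <- sum(M) / sum(Fm)

  # scalar probability lookups on an arbitrary count matrix
  p_i_fun <- function(n, i) sum(n[i, ]) / sum(n)
  p_j_i_fun <- function(n, i, j) {
    tot <- sum(n[i, ])
    if (tot == 0) return(NA_real_)
    sum(n[i, hab_of_col == j]) / tot
  }
  p_k_ij_fun <- function(n, i, k) {
    j <- hab_of_col[k]
    nij <- sum(n[i, hab_of_col == j])
    if (nij == 0) return(NA_real_)
    n[i, k] / nij
  }

  H_prev <- oracle_shannon(prev_ct, component)
  H_fut <- oracle_shannon(fut_ct, component)
  dH <- H_fut - H_prev

  t1 <- t2 <- t3 <- t4 <- 0
  if (sum(R) > 0) {
    for (i in seq_len(nrow(N))) {
      for (k in seq_len(ncol(N))) {
        j <- hab_of_col[k]
        a <- p_i_fun(N, i); a2 <- p_i_fun(R, i)
        if (N[i, k] > 0) {
          b <- p_j_i_fun(N, i, j); cc <- p_k_ij_fun(N, i, k)
          z <- oracle_z(N, map, i, k, component)
          b2 <- p_j_i_fun(R, i, j); if (is.na(b2)) b2 <- 0
          c2 <- p_k_ij_fun(R, i, k); if (is.na(c2)) c2 <- 0
          t1 <- t1 + (a2 - a) * b * cc * z
          t2 <- t2 + a2 * (b2 - b) * cc * z
          t3 <- t3 + a2 * b2 * (c2 - cc) * z
        }
        if (R[i, k] > 0) {
          zf <- oracle_z(Fm, map, i, k, component)  # pooled future scores
          z <- oracle_z(N, map, i, k, component)
          t4 <- t4 + (R[i, k] / sum(R)) * (zf - z)
        }
      }
    }
  }

  immigration <- 0
  if (phi > 0) {
    h_imm <- 0
    for (i in seq_len(nrow(N))) {
      for (k in seq_len(ncol(N))) {
        if (M[i, k] > 0) {
          h_imm <- h_imm + (M[i, k] / sum(M)) * oracle_z(Fm, map, i, k, component)
        }
      }
    }
    immigration <- phi * (h_imm - H_prev)
  }

  w <- 1 - phi
  list(species = w * t1, habitat = w * t2, community = w * t3,
       transmission = w * t4, immigration = immigration, total = dH)
}
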