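# Fixture builders shared across the suite.  Everything is generated in
# code; no binary fixtures.

# count_table from a vector/matrix with compact arguments
make_ct <- function(x, species, communities, habitats, time = "1") {
  m <- matrix(x, nrow = length(species), ncol = length(communities),
              dimnames = list(species, communities))
  count_table(m, community_map(communities, habitats), time = time)
}

# single-community table from named counts
one_comm <- function(counts, time = "1") {
  make_ct(counts, species = names(counts), communities = "c1",
          habitats = "h1", time = time)
}

# random metacommunity census pair sharing one universe; sprinkles zeros so
# immigration, extinction and empty conditioning events all occur
random_pair <- function(S = 4, J = 2, K = 2, lambda = 8, p_zero = 0.3) {
  Cn <- J * K
  species <- paste0("s", seq_len(S))
  communities <- paste0("h", rep(seq_len(J), each = K), "_c", rep(seq_len(K), J))
  habitats <- rep(paste0("h", seq_len(J)), each = K)
  draw <- function() {
    m <- matrix(rpois(S * Cn, lambda) * (runif(S * Cn) > p_zero), S, Cn,
                dimnames = list(species, communities))
    m
  }
  prev <- draw()
  fut <- draw()
  # both censuses must be non-empty
  if (sum(prev) == 0) prev[1L, 1L] <- 1
  if (sum(fut) == 0) fut[1L, 1L] <- 1
  map <- community_map(communities, habitats)
  list(previous = count_table(prev, map, "1"), future = count_table(fut, map, "2"))
}
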