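#' Per-individual rarity contributions to a diversity component
#'
#' Every individual contributes a rarity score z to each diversity
#' component.  For gamma diversity the score measures rarity across the
#' whole metacommunity, `z_gamma = -log(p_i..)`; for alpha diversity it
#' measures rarity within the individual's own community,
#' `z_alpha = -log(p_i|jk)`; and the beta score is the difference,
#' `z_beta = z_gamma - z_alpha`.  Scores are undefined (`NA`) on cells with
#' zero support; such cells always receive zero weight downstream.
#'
#' @param probs a `probability_set` from [compute_probabilities()].
#' @param component one of `"gamma"`, `"alpha"`, `"beta"`.
#' @return A `contribution_tensor`: list with the species x community score
#'   matrix `z` (in nats) and the `component` label.
#' @examples
#' map <- community_map("c1", "h1")
#' ct <- count_table(matrix(c(2, 2), 2, 1, dimnames = list(c("A", "B"), "c1")), map)
#' rarity_contributions(compute_probabilities(ct), "gamma")$z  # log 2 everywhere
#' @export
rarity_contributions <- function(probs, component = c("gamma", "alpha", "beta")) {
  component <- match.arg(component)
  z <- z_matrix(probs, component)
  structure(list(component = component, z = z), class = "contribution_tensor")
}

# bare score matrix, NA off-support; vectorised helper for the hot path
z_matrix <- function(probs, component) {
  switch(component,
    gamma = {
      zg <- -log(probs$p_i)
      zg[probs$p_i == 0] <- NA_real_
      matrix(zg, nrow = length(zg), ncol = ncol(probs$p_ijk),
             dimnames = dimnames(probs$p_ijk))
    },
    alpha = {
      za <- -log(probs$p_i_given_jk)
      za[is.na(probs$p_i_given_jk) | probs$p_i_given_jk == 0] <- NA_real_
      za
    },
    beta = z_matrix(probs, "gamma") - z_matrix(probs, "alpha")
  )
}

# sum of w * z over cells with positive weight, with the 0 * log 0 = 0
# convention: zero-weight cells contribute 0 even where z is undefined
weighted_z_sum <- function(w, z) {
  on <- !is.na(w) & w > 0
  if (any(on & is.na(z))) {
    stop("undefined rarity score carries positive weight", call. = FALSE)
  }
  sum(w[on] * z[on])
}

#' Shannon diversity components and their Hill numbers
#'
#' Each component is the abundance-weighted average of the per-individual
#' rarity contributions, `H_o = sum_ijk p_ijk * z_ijko` (with 0 log 0 = 0).
#' Gamma is the entropy of the pooled species relative abundances, alpha the
#' abundance-weighted mean within-community entropy, and beta their
#' difference -- the mutual information between species identity and
#' location, so `H_gamma = H_alpha + H_beta` and `H_beta >= 0`.  The Hill
#' number `exp(H)` is the number of equally abundant species that would give
#' the same entropy.
#'
#' @param counts a [count_table()] with at least one individual.
#' @param component character vector drawn from `"gamma"`, `"alpha"`,
#'   `"beta"`; default all three.
#' @param base logarithm base for the reported entropy (natural log, i.e.
#'   nats, by default).  Hill numbers do not depend on the base.
#' @return A data frame with columns `component`, `entropy`, `hill`.
#' @examples
#' map <- community_map("c1", "h1")
#' ct <- count_table(matrix(c(10, 10), 2, 1, dimnames = list(c("A", "B"), "c1")), map)
#' shannon(ct)  # gamma entropy log 2 = 0.69, hill number 2
#' @export
shannon <- function(counts, component = c("gamma", "alpha", "beta"),
                    base = exp(1)) {
  component <- match.arg(component, several.ok = TRUE)
  probs <- compute_probabilities(counts)
  entropy_nats <- vapply(component, function(comp) {
    weighted_z_sum(probs$p_ijk, z_matrix(probs, comp))
  }, numeric(1L))
  data.frame(component = component,
             entropy = entropy_nats / log(base),
             hill = exp(entropy_nats),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Convert an entropy change to a multiplicative Hill-scale factor
#'
#' `exp(dH)` re-expresses an additive change in Shannon entropy as a
#' multiplicative change in the effective number of uniformly distributed
#' species.  Because `exp(a + b) = exp(a) exp(b)`, the five additive
#' partition terms become five factors whose product is the total factor.
#'
#' @param entropy_change numeric change(s) in entropy.
#' @param base base in which `entropy_change` is expressed (nats by
#'   default).
#' @return Multiplicative factor(s) on the effective-species scale.
#' @examples
#' hill_transform(log(2))  # a gain of log 2 nats doubles the effective richness
#' @export
hill_transform <- function(entropy_change, base = exp(1)) {
  base^entropy_change
}
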