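#' Joint, marginal, and conditional relative abundances
#'
#' From a census count table, computes the probability that a randomly drawn
#' individual belongs to species i, habitat j, community k:
#' `p_ijk = n_ijk / n_...`, together with the species marginal
#' `p_i.. = n_i.. / n_...`, the within-community relative abundance
#' `p_i_given_jk = n_ijk / n_.jk`, the habitat share within a species
#' `p_j_given_i = n_ij. / n_i..`, and the community share within a
#' species-habitat combination `p_k_given_ij = n_ijk / n_ij.`.  The joint
#' probability factorises as
#' `p_ijk = p_i.. * p_j_given_i * p_k_given_ij` cell by cell.
#'
#' Conditional probabilities whose conditioning event has zero mass (an
#' empty community, a species absent from a habitat) are undefined and are
#' returned as `NA`; they always carry zero weight in downstream sums and
#' are never evaluated as 0/0.
#'
#' @param counts a [count_table()] with at least one individual.
#' @return A `probability_set`: list with matrices `p_ijk` (species x
#'   community), `p_i_given_jk` (species x community, `NA` columns for empty
#'   communities), `p_k_given_ij` (species x community, `NA` where the
#'   species is absent from the community's habitat), `p_j_given_i`
#'   (species x habitat), the vector `p_i` (species marginal), and
#'   `n_total`.
#' @examples
#' map <- community_map("c1", "h1")
#' ct <- count_table(matrix(c(2, 2), 2, 1, dimnames = list(c("A", "B"), "c1")), map)
#' compute_probabilities(ct)$p_i
#' @export
compute_probabilities <- function(counts) {
  if (!inherits(counts, "count_table")) {
    stop("`counts` must be a count_table", call. = FALSE)
  }
  if (counts$total <= 0) {
    stop("empty metacommunity: total count is zero", call. = FALSE)
  }
  probability_set(counts$counts, counts$map)
}

# internal constructor working on a bare species x community matrix; used on
# resident / immigrant / pooled count matrices in the partition hot path
probability_set <- function(n, map) {
  n_total <- sum(n)
  hab <- habitat_of(map)[colnames(n)]
  habitats <- unique(map$habitat)

  p_ijk <- n / n_total
  n_i <- rowSums(n)
  p_i <- n_i / n_total

  # within-community relative abundance; NA for empty communities
  n_jk <- colSums(n)
  p_i_given_jk <- sweep(n, 2L, n_jk, "/")
  p_i_given_jk[, n_jk == 0] <- NA_real_

  # species x habitat totals n_ij.
  n_ij <- t(rowsum(t(n), group = hab, reorder = FALSE))
  n_ij <- n_ij[, habitats, drop = FALSE]
  p_j_given_i <- n_ij / n_i
  p_j_given_i[n_i == 0, ] <- NA_real_

  # community share within species x habitat; NA where n_ij. = 0
  n_ij_expanded <- n_ij[, hab, drop = FALSE]
  colnames(n_ij_expanded) <- colnames(n)
  p_k_given_ij <- n / n_ij_expanded
  p_k_given_ij[n_ij_expanded == 0] <- NA_real_

  structure(list(p_ijk = p_ijk, p_i = p_i, p_i_given_jk = p_i_given_jk,
                 p_j_given_i = p_j_given_i, p_k_given_ij = p_k_given_ij,
                 n_total = n_total, map = map, habitat = hab),
            class = "probability_set")
}

#' @export
print.probability_set <- function(x, ...) {
  cat("probability_set: ", length(x$p_i), " species x ", ncol(x$p_ijk),
      " communities, n = ", format(x$n_total, big.mark = ","), "\n", sep = "")
  invisible(x)
}
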