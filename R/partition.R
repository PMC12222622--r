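#' Split a future census into immigrants and residents
#'
#' Applies the operational classification rule: any individual belonging to
#' a species that was unobserved in a given community at the previous census
#' is an immigrant to the region; all other individuals are residents.
#' Status is assigned at the (species, community) level, so descendants of
#' earlier immigrants count as residents once their species has been
#' recorded in the community.  Emigrants and extinctions need no bookkeeping
#' of their own: only individuals present in the future census are tracked.
#'
#' @param previous,future [count_table()]s sharing species, communities and
#'   the community map.
#' @return An `immigrant_split`: list with `immigrant` and `resident` count
#'   tables (summing cellwise to `future`) and `phi`, the immigrant fraction
#'   of the future census.
#' @examples
#' map <- community_map("c1", "h1")
#' prev <- count_table(matrix(c(10, 10, 0), 3, 1,
#'                            dimnames = list(c("A", "B", "C"), "c1")), map, "1")
#' fut <- count_table(matrix(c(10, 10, 20), 3, 1,
#'                           dimnames = list(c("A", "B", "C"), "c1")), map, "2")
#' classify_immigrants(prev, fut)$phi  # 0.5
#' @export
classify_immigrants <- function(previous, future) {
  check_same_universe(previous, future)
  if (future$total <= 0) {
    stop("future census is empty: immigrant fraction undefined", call. = FALSE)
  }
  imm <- future$counts * (previous$counts == 0)
  res <- future$counts - imm
  structure(list(
    immigrant = count_table(imm, future$map, future$time),
    resident = count_table(res, future$map, future$time),
    phi = sum(imm) / future$total
  ), class = "immigrant_split")
}

#' @export
print.immigrant_split <- function(x, ...) {
  cat("immigrant_split: phi = ", format(x$phi), " (",
      x$immigrant$total, " immigrants / ", x$immigrant$total + x$resident$total,
      " individuals)\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Internal engine.  Works on bare count matrices for speed (the bootstrap
# calls this tens of thousands of times).  All entropies in nats.
#
# The resident change H'_d - H is decomposed over the factorisation
# p_ijk = p_i.. * p_{j|i.} * p_{k|ij} (and the score z) with the staggered
# discrete product rule
#   D(a b c z) = Da.b.c.z + a'.Db.c.z + a'.b'.Dc.z + a'.b'.c'.Dz
# in the fixed order (species, habitat, community, z), which telescopes
# exactly.  Terms are returned pre-multiplied by (1 - phi) so that
#   species + habitat + community + transmission + immigration = dH.
#
# z_source = "pooled": future scores z' come from the pooled future census
# (immigrants + residents), which makes the immigrant/resident split of dH
# an exact identity.  z_source = "resident": z' conditioned on residents
# only; the immigration term is then the exact residual dH - resident terms.
# ---------------------------------------------------------------------------
partition_engine <- function(N, Fm, map, components, z_source = "pooled") {
  if (sum(N) <= 0) stop("empty metacommunity: total count is zero", call. = FALSE)
  if (sum(Fm) <= 0) stop("future census is empty", call. = FALSE)

  M <- Fm * (N == 0)              # immigrants: species new to the community
  R <- Fm - M
  phi <- sum(M) / sum(Fm)
  res_total <- sum(R)

  P <- probability_set(N, map)
  Pf <- probability_set(Fm, map)
  Pr <- if (res_total > 0) probability_set(R, map) else NULL
  Zsrc <- if (z_source == "pooled") Pf else Pr

  S <- nrow(N)
  C <- ncol(N)
  hab <- P$habitat
  mask <- N > 0

  # previous-census factors; all defined on mask
  aM <- matrix(P$p_i, S, C)
  BM <- P$p_j_given_i[, hab, drop = FALSE]
  CM <- P$p_k_given_ij

  if (res_total > 0) {
    a2M <- matrix(Pr$p_i, S, C)
    B2M <- Pr$p_j_given_i[, hab, drop = FALSE]
    B2M[is.na(B2M)] <- 0          # species absent from residents: zero weight
    C2M <- Pr$p_k_given_ij
    C2M[is.na(C2M)] <- 0          # species-habitat empty among residents
    rmask <- R > 0
  }
  qsum <- if (phi > 0) M / sum(M) else NULL
  mmask <- M > 0

  out <- vector("list", length(components))
  names(out) <- components
  for (comp in components) {
    Z <- z_matrix(P, comp)
    H <- weighted_z_sum(P$p_ijk, Z)
    H_fut <- weighted_z_sum(Pf$p_ijk, z_matrix(Pf, comp))
    dH <- H_fut - H

    if (res_total > 0) {
      Zp <- z_matrix(Zsrc, comp)
      t1 <- sum(((a2M - aM) * BM * CM * Z)[mask])
      t2 <- sum((a2M * (B2M - BM) * CM * Z)[mask])
      t3 <- sum((a2M * B2M * (C2M - CM) * Z)[mask])
      t4 <- sum((Pr$p_ijk * (Zp - Z))[rmask])
      w <- 1 - phi
      terms <- c(species = w * t1, habitat = w * t2,
                 community = w * t3, transmission = w * t4)
    } else {
      # phi = 1: no residents, resident terms defined as 0
      terms <- c(species = 0, habitat = 0, community = 0, transmission = 0)
    }

    immigration <- if (phi == 0) {
      0
    } else if (z_source == "pooled") {
      Zp_pooled <- z_matrix(Pf, comp)
      H_imm <- sum((qsum * Zp_pooled)[mmask])
      phi * (H_imm - H)
    } else {
      dH - sum(terms)             # exact residual under resident-only z'
    }

    out[[comp]] <- list(terms = terms, immigration = immigration,
                        total = dH, phi = phi, H_prev = H, H_fut = H_fut,
                        resident_total = sum(terms),
                        no_residents = res_total == 0)
  }
  out
}

#' Immigrant and resident contributions to a diversity change
#'
#' Splits the total change `dH = H' - H` into an immigration part
#' `phi * (H'_I - H)` and a resident part `(1 - phi) * (H'_d - H)`, where
#' `H'_I` and `H'_d` average future rarity scores over the immigrant-only
#' and resident-only abundance distributions.  With the default pooled
#' future scores the two parts sum to `dH` exactly.
#'
#' @param previous,future [count_table()]s sharing one universe.
#' @param split the [classify_immigrants()] result for this census pair.
#' @param component one of `"gamma"`, `"alpha"`, `"beta"`.
#' @param z_source `"pooled"` (default): future scores from the full future
#'   census; `"resident"`: scores conditioned on residents only, with the
#'   immigration part defined as the exact residual.
#' @return Named numeric vector with elements `immigration` and `resident`
#'   (nats).  When there are no residents (`phi = 1`) the resident part is 0
#'   and carries attribute `no_residents = TRUE`.
#' @export
split_change <- function(previous, future, split = classify_immigrants(previous, future),
                         component = c("gamma", "alpha", "beta"),
                         z_source = c("pooled", "resident")) {
  component <- match.arg(component)
  z_source <- match.arg(z_source)
  check_split(future, split)
  eng <- partition_engine(previous$counts, future$counts, previous$map,
                          component, z_source)[[component]]
  out <- c(immigration = eng$immigration, resident = eng$resident_total)
  if (eng$no_residents) attr(out, "no_residents") <- TRUE
  out
}

check_split <- function(future, split) {
  if (!inherits(split, "immigrant_split")) {
    stop("`split` must come from classify_immigrants()", call. = FALSE)
  }
  if (!isTRUE(all.equal(split$immigrant$counts + split$resident$counts,
                        future$counts, tolerance = 0))) {
    stop("split is inconsistent with the future census", call. = FALSE)
  }
  invisible(TRUE)
}

#' Decompose the resident diversity change across scales
#'
#' Applies the staggered discrete product rule to the resident change
#' `H'_d - H` over the factorisation `p_ijk = p_i.. p_{j|i.} p_{k|ij}` and
#' the rarity score z, yielding species-scale selection (change in species
#' marginals), habitat-scale selection (change in habitat shares within
#' species), community-scale selection (change in community shares within
#' species and habitat), and transmission (change in the scores themselves).
#' Terms come pre-multiplied by `(1 - phi)` so they sum with the immigration
#' term to the total change.
#'
#' @inheritParams split_change
#' @return Named numeric vector `species`, `habitat`, `community`,
#'   `transmission` (nats, already scaled by `1 - phi`).
#' @export
decompose_resident_change <- function(previous, split,
                                      component = c("gamma", "alpha", "beta"),
                                      z_source = c("pooled", "resident")) {
  component <- match.arg(component)
  z_source <- match.arg(z_source)
  future_counts <- split$immigrant$counts + split$resident$counts
  if (any(split$resident$counts > 0 & previous$counts == 0)) {
    stop("resident cell with no previous occupancy: classifier violated",
         call. = FALSE)
  }
  partition_engine(previous$counts, future_counts, previous$map,
                   component, z_source)[[component]]$terms
}

#' Five-term partition of a census-to-census diversity change
#'
#' Composes [classify_immigrants()], [split_change()] and
#' [decompose_resident_change()]: the change in each Shannon diversity
#' component between two censuses is split exactly into species-scale
#' selection, habitat-scale selection, community-scale selection,
#' transmission, and immigration.  Each additive term (nats) is also
#' reported as a multiplicative Hill-scale factor `exp(term)`; the factors
#' multiply to `exp(total)`.  Gamma diversity ignores where individuals of
#' a species live, so its habitat and community selection terms vanish.
#'
#' @param previous,future [count_table()]s sharing one universe.
#' @param component character vector drawn from `"gamma"`, `"alpha"`,
#'   `"beta"`; default all three.
#' @param z_source see [split_change()].
#' @param base logarithm base for the reported entropy terms (nats by
#'   default); Hill factors are base-independent.
#' @return A `partition_result` data frame, one row per component, with
#'   columns `from`, `to`, `component`, `species_selection`,
#'   `habitat_selection`, `community_selection`, `transmission`,
#'   `immigration`, `total`, `phi`, and `hill_*` twins of every term.
#' @examples
#' map <- community_map("c1", "h1")
#' prev <- count_table(matrix(c(10, 10), 2, 1, dimnames = list(c("A", "B"), "c1")), map, "1")
#' fut <- count_table(matrix(c(30, 10), 2, 1, dimnames = list(c("A", "B"), "c1")), map, "2")
#' partition_change(prev, fut, component = "gamma")
#' @export
partition_change <- function(previous, future,
                             component = c("gamma", "alpha", "beta"),
                             z_source = c("pooled", "resident"),
                             base = exp(1)) {
  component <- match.arg(component, several.ok = TRUE)
  z_source <- match.arg(z_source)
  check_same_universe(previous, future)
  eng <- partition_engine(previous$counts, future$counts, previous$map,
                          component, z_source)
  partition_result(eng, previous$time, future$time, base)
}

# assemble the tidy result data frame from engine output
partition_result <- function(eng, from, to, base = exp(1)) {
  lb <- log(base)
  rows <- lapply(names(eng), function(comp) {
    e <- eng[[comp]]
    tm <- e$terms
    data.frame(
      from = from, to = to, component = comp,
      species_selection = tm[["species"]] / lb,
      habitat_selection = tm[["habitat"]] / lb,
      community_selection = tm[["community"]] / lb,
      transmission = tm[["transmission"]] / lb,
      immigration = e$immigration / lb,
      total = e$total / lb,
      phi = e$phi,
      hill_species_selection = exp(tm[["species"]]),
      hill_habitat_selection = exp(tm[["habitat"]]),
      hill_community_selection = exp(tm[["community"]]),
      hill_transmission = exp(tm[["transmission"]]),
      hill_immigration = exp(e$immigration),
      hill_total = exp(e$total),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("partition_result", "data.frame")
  out
}

#' Partition every consecutive census pair of a series
#'
#' One five-term partition per consecutive census pair per diversity
#' component.  Interval totals telescope: summed over intervals they equal
#' `H(last) - H(first)` for each component.
#'
#' @param x a [metacommunity()] or a list of two or more [count_table()]s in
#'   temporal order.
#' @inheritParams partition_change
#' @return A `partition_result` data frame with one row per interval per
#'   component.
#' @export
partition_series <- function(x, component = c("gamma", "alpha", "beta"),
                             z_source = c("pooled", "resident"),
                             base = exp(1)) {
  component <- match.arg(component, several.ok = TRUE)
  z_source <- match.arg(z_source)
  tables <- if (inherits(x, "metacommunity")) x$tables else x
  if (length(tables) < 2L) {
    stop("a series needs at least two censuses", call. = FALSE)
  }
  x <- metacommunity(tables)  # validates shared universe and ordering
  res <- lapply(seq_len(length(x$tables) - 1L), function(i) {
    partition_change(x$tables[[i]], x$tables[[i + 1L]],
                     component = component, z_source = z_source, base = base)
  })
  out <- do.call(rbind, res)
  class(out) <- c("partition_result", "data.frame")
  out
}

#' @export
print.partition_result <- function(x, digits = 4, ...) {
  cat("Partition of diversity change (entropy units; hill_* columns are exp of each term)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
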