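#' Simulate a future census under the Poisson drift null
#'
#' Holds the present counts fixed and draws each future cell independently
#' from a Poisson distribution whose mean is the observed present count of
#' that cell.  Cells empty in the present stay empty (Poisson with mean 0),
#' so the null cannot generate immigration; drift alone moves the counts.
#'
#' @param present a [count_table()].
#' @param seed optional integer seed; if supplied the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return A [count_table()] for the simulated future census.
#' @export
simulate_null_future <- function(present, seed = NULL) {
  if (!inherits(present, "count_table")) {
    stop("`present` must be a count_table", call. = FALSE)
  }
  sim <- draw_poisson_counts(present$counts, seed)
  count_table(sim, present$map, time = paste0(present$time, "+sim"))
}

# Poisson draw over a count matrix, optionally under a private seed.
# Shared by the bootstrap null and the simulator's stochastic mode, so the
# two are the same distribution by construction when fitness is 1.
draw_poisson_counts <- function(lambda, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed))
  }
  out <- matrix(stats::rpois(length(lambda), lambda = lambda),
                nrow = nrow(lambda), dimnames = dimnames(lambda))
  storage.mode(out) <- "double"
  out
}

#' Parametric bootstrap confidence intervals for all partition terms
#'
#' Repeats the full partitioning pipeline on futures simulated under the
#' Poisson drift null ([simulate_null_future()]) and reports empirical
#' quantile intervals for each of the five terms and the total, per
#' component.  The immigrant classifier is re-applied within each replicate;
#' under this null it is degenerate (no cell empty in the present can become
#' occupied), so the immigration term is identically zero -- documented
#' behaviour, kept so the bootstrap exercises the same code path as real
#' data.
#'
#' Replicate r draws from its own substream (a seed derived from the master
#' seed), so results do not depend on execution order.
#'
#' @param present a [count_table()] with at least one individual.
#' @param n_reps number of replicates (the reference procedure uses 1000).
#' @param level coverage of the empirical interval (default 0.95).
#' @param seed master integer seed.
#' @param component character vector drawn from `"gamma"`, `"alpha"`,
#'   `"beta"`.
#' @return A `bootstrap_result` data frame with columns `component`, `term`,
#'   `lower`, `upper` (nats) and attributes `n_reps`, `level`, `seed`,
#'   `replicates` (the n_reps x term matrix per component, for diagnostics).
#' @export
bootstrap_partition <- function(present, n_reps = 1000, level = 0.95,
                                seed = 1L,
                                component = c("gamma", "alpha", "beta")) {
  component <- match.arg(component, several.ok = TRUE)
  if (!inherits(present, "count_table")) {
    stop("`present` must be a count_table", call. = FALSE)
  }
  if (present$total <= 0) {
    stop("degenerate present census: total count is zero", call. = FALSE)
  }
  if (n_reps < 2) stop("`n_reps` must be at least 2", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)

  rep_seeds <- substream_seeds(seed, n_reps)
  term_names <- c("species_selection", "habitat_selection",
                  "community_selection", "transmission", "immigration",
                  "total")
  draws <- lapply(seq_len(n_reps), function(r) {
    fut <- draw_poisson_counts(present$counts, rep_seeds[r])
    if (sum(fut) == 0) return(NULL)  # practically impossible for real data
    eng <- partition_engine(present$counts, fut, present$map, component)
    vapply(component, function(comp) {
      e <- eng[[comp]]
      c(e$terms[["species"]], e$terms[["habitat"]], e$terms[["community"]],
        e$terms[["transmission"]], e$immigration, e$total)
    }, numeric(6L))
  })
  keep <- !vapply(draws, is.null, TRUE)
  if (!all(keep)) {
    warning(sum(!keep), " replicate(s) produced an empty future and were dropped")
    draws <- draws[keep]
  }

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  reps <- list()
  rows <- list()
  for (ci in seq_along(component)) {
    comp <- component[ci]
    m <- t(vapply(draws, function(d) d[, ci], numeric(6L)))
    colnames(m) <- term_names
    reps[[comp]] <- m
    qs <- apply(m, 2L, stats::quantile, probs = probs, type = 7, names = FALSE)
    rows[[comp]] <- data.frame(component = comp, term = term_names,
                               lower = qs[1L, ], upper = qs[2L, ],
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_reps = length(draws), level = level, seed = seed,
            replicates = reps,
            class = c("bootstrap_result", "data.frame"))
}

# per-replicate seeds derived deterministically from the master seed,
# without disturbing the caller's RNG state
substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

#' @export
print.bootstrap_result <- function(x, digits = 4, ...) {
  cat("Bootstrap intervals (", attr(x, "n_reps"), " replicates, level ",
      attr(x, "level"), ", seed ", attr(x, "seed"), ")\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
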