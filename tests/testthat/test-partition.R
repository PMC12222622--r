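TOL_PART <- 1e-10

terms5 <- c("species_selection", "habitat_selection", "community_selection",
            "transmission", "immigration")

test_that("immigrant classification follows the previous-occupancy rule", {
  prev <- one_comm(c(A = 10, B = 10, C = 0), time = "1")
  fut <- one_comm(c(A = 12, B = 8, C = 20), time = "2")
  split <- classify_immigrants(prev, fut)
  # species present at both censuses: residents
  expect_equal(unname(split$resident$counts[c("A", "B"), "c1"]), c(12, 8))
  expect_equal(unname(split$immigrant$counts[c("A", "B"), "c1"]), c(0, 0))
  # species previously unobserved: all 20 are immigrants
  expect_equal(unname(split$immigrant$counts["C", "c1"]), 20)
  expect_equal(split$phi, 0.5)
  # split reconstructs the future table cellwise
  expect_equal(split$immigrant$counts + split$resident$counts, fut$counts)

  # mismatched universes are rejected
  other <- one_comm(c(A = 1, B = 1), time = "2")
  expect_error(classify_immigrants(prev, other), "species set")
})

test_that("split_change reproduces the worked immigrant-arrival case", {
  prev <- one_comm(c(A = 10, B = 10, C = 0), time = "1")

  # no immigrants: immigration exactly 0, residents carry all of dH
  fut0 <- one_comm(c(A = 30, B = 10, C = 0), time = "2")
  s0 <- split_change(prev, fut0, component = "gamma")
  dH0 <- shannon(fut0, "gamma")$entropy - shannon(prev, "gamma")$entropy
  expect_identical(unname(s0[["immigration"]]), 0)
  expect_equal(unname(s0[["resident"]]), dH0, tolerance = TOL_PART)

  # residents steady at (10, 10), immigrant C arrives with 20: the
  # immigrants are exactly as rare as the baseline, so their term is 0 and
  # the residents carry dH = log(4) - log(2) - (log(2) - log(2)) = 0.3466
  futC <- one_comm(c(A = 10, B = 10, C = 20), time = "2")
  sC <- split_change(prev, futC, component = "gamma")
  expect_equal(unname(sC[["immigration"]]), 0, tolerance = TOL_PART)
  expect_equal(unname(sC[["resident"]]), 0.3466, tolerance = 1e-4)
  expect_equal(sum(sC), log(2) / 2, tolerance = TOL_PART)  # dH

  # stationary census: both parts zero
  sI <- split_change(prev, prev, split = classify_immigrants(prev, prev),
                     component = "gamma")
  expect_equal(unname(sI), c(0, 0), tolerance = TOL_PART)
})

test_that("resident decomposition matches hand-evaluated staggered terms", {
  prev <- one_comm(c(A = 10, B = 10), time = "1")
  fut <- one_comm(c(A = 30, B = 10), time = "2")
  split <- classify_immigrants(prev, fut)
  d <- decompose_resident_change(prev, split, component = "gamma")
  H_fut <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  dH <- H_fut - log(2)  # -0.1308
  # both species start equally rare: species selection cancels exactly
  expect_equal(unname(d[["species"]]), 0, tolerance = TOL_PART)
  expect_equal(unname(d[["habitat"]]), 0, tolerance = TOL_PART)
  expect_equal(unname(d[["community"]]), 0, tolerance = TOL_PART)
  expect_equal(unname(d[["transmission"]]), dH, tolerance = TOL_PART)
  expect_equal(round(dH, 4), -0.1308)

  # previous = future: all four terms vanish
  d0 <- decompose_resident_change(prev, classify_immigrants(prev, prev),
                                  component = "alpha")
  expect_equal(unname(d0), c(0, 0, 0, 0), tolerance = TOL_PART)
})

test_that("partition_change composes the pieces with exact bookkeeping", {
  prev <- one_comm(c(A = 10, B = 10, C = 0), time = "1")

  # stationary metacommunity: everything 0, Hill factors 1
  p0 <- partition_change(prev, prev)
  expect_true(all(abs(as.matrix(p0[, c(terms5, "total")])) < TOL_PART))
  expect_true(all(abs(as.matrix(p0[, paste0("hill_", c(terms5, "total"))]) - 1) < TOL_PART))

  # the (10,10) -> (30,10) case: transmission carries the whole change
  fut <- one_comm(c(A = 30, B = 10, C = 0), time = "2")
  pg <- partition_change(prev, fut, component = "gamma")
  expect_equal(round(pg$total, 4), -0.1308)
  expect_equal(pg$transmission, pg$total, tolerance = TOL_PART)
  expect_equal(pg$species_selection, 0, tolerance = TOL_PART)

  # immigrant arrival: immigration 0, selection 0, transmission 0.3466
  futC <- one_comm(c(A = 10, B = 10, C = 20), time = "2")
  pc <- partition_change(prev, futC, component = "gamma")
  expect_equal(pc$immigration, 0, tolerance = TOL_PART)
  expect_equal(pc$species_selection, 0, tolerance = TOL_PART)
  expect_equal(round(pc$transmission, 4), 0.3466)

  # Hill factors multiply to exp(total)
  hf <- as.numeric(pc[, paste0("hill_", terms5)])
  expect_equal(prod(hf), exp(pc$total), tolerance = TOL_PART)
})

test_that("five terms sum to dH, beta = gamma - alpha, gamma is scale-blind", {
  set.seed(404)
  for (rep in 1:150) {
    pair <- random_pair(S = sample(2:6, 1), J = sample(1:3, 1),
                        K = sample(1:3, 1))
    for (zs in c("pooled", "resident")) {
      pr <- partition_change(pair$previous, pair$future, z_source = zs)
      sums <- rowSums(as.matrix(pr[, terms5]))
      expect_lt(max(abs(sums - pr$total)), TOL_PART)
      g <- pr[pr$component == "gamma", ]
      a <- pr[pr$component == "alpha", ]
      b <- pr[pr$component == "beta", ]
      for (col in c(terms5, "total")) {
        expect_equal(b[[col]], g[[col]] - a[[col]], tolerance = TOL_PART)
      }
      expect_lt(abs(g$habitat_selection), TOL_PART)
      expect_lt(abs(g$community_selection), TOL_PART)
    }
  }
})

test_that("every term matches the brute-force full-sum oracle", {
  set.seed(505)
  for (rep in 1:40) {
    pair <- random_pair(S = sample(2:3, 1), J = sample(1:2, 1),
                        K = sample(1:2, 1), lambda = 6)
    for (comp in c("gamma", "alpha", "beta")) {
      got <- partition_change(pair$previous, pair$future, component = comp)
      want <- oracle_partition(pair$previous, pair$future, comp)
      expect_equal(got$species_selection, want$species, tolerance = TOL_PART)
      expect_equal(got$habitat_selection, want$habitat, tolerance = TOL_PART)
      expect_equal(got$community_selection, want$community, tolerance = TOL_PART)
      expect_equal(got$transmission, want$transmission, tolerance = TOL_PART)
      expect_equal(got$immigration, want$immigration, tolerance = TOL_PART)
      expect_equal(got$total, want$total, tolerance = TOL_PART)
    }
  }
})

test_that("extinctions flow through the terms without special handling", {
  # species B disappears entirely; everything stays finite and additive
  prev <- make_ct(c(10, 5, 8, 3), species = c("A", "B"),
                  communities = c("c1", "c2"), habitats = c("h1", "h2"))
  fut <- make_ct(c(12, 0, 6, 0), species = c("A", "B"),
                 communities = c("c1", "c2"), habitats = c("h1", "h2"),
                 time = "2")
  pr <- partition_change(prev, fut)
  expect_true(all(is.finite(as.matrix(pr[, c(terms5, "total")]))))
  expect_lt(max(abs(rowSums(as.matrix(pr[, terms5])) - pr$total)), TOL_PART)
})

test_that("a fully-immigrant future puts the whole change on immigration", {
  prev <- one_comm(c(A = 10, B = 10, C = 0, D = 0), time = "1")
  fut <- one_comm(c(A = 0, B = 0, C = 15, D = 5), time = "2")
  pr <- partition_change(prev, fut, component = "gamma")
  expect_equal(pr$phi, 1)
  dH <- shannon(fut, "gamma")$entropy - shannon(prev, "gamma")$entropy
  expect_equal(pr$immigration, dH, tolerance = TOL_PART)
  expect_equal(pr$species_selection + pr$habitat_selection +
                 pr$community_selection + pr$transmission, 0)
})

test_that("partition_series telescopes and counts intervals", {
  set.seed(606)
  # 8-census random series sharing one universe
  base <- random_pair(S = 5, J = 2, K = 2)
  tables <- list(base$previous)
  for (t in 2:8) {
    nxt <- draw <- matrix(rpois(length(base$previous$counts), 6) *
                            (runif(length(base$previous$counts)) > 0.25),
                          nrow(base$previous$counts),
                          dimnames = dimnames(base$previous$counts))
    if (sum(nxt) == 0) nxt[1, 1] <- 1
    tables[[t]] <- count_table(nxt, base$previous$map, time = as.character(t))
  }
  pr <- partition_series(tables)
  expect_equal(nrow(pr), 7 * 3)  # 7 intervals x 3 components
  for (comp in c("gamma", "alpha", "beta")) {
    sub <- pr[pr$component == comp, ]
    H_first <- shannon(tables[[1]], comp)$entropy
    H_last <- shannon(tables[[8]], comp)$entropy
    expect_equal(sum(sub$total), H_last - H_first, tolerance = TOL_PART)
  }

  # constant series: every value 0
  const <- lapply(1:3, function(t) count_table(base$previous$counts,
                                               base$previous$map,
                                               as.character(t)))
  prc <- partition_series(const)
  expect_true(all(abs(as.matrix(prc[, c(terms5, "total")])) < TOL_PART))

  expect_error(partition_series(tables[1]), "at least two")
})
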