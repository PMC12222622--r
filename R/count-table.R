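#' Community-to-habitat nesting map
#'
#' Records which habitat each community belongs to.  Communities are nested
#' in habitats: every community maps to exactly one habitat, and community
#' labels are globally unique (not merely unique within a habitat).  The map
#' is shared by every census of a dataset.
#'
#' @param community character vector of community labels.
#' @param habitat character vector of habitat labels, parallel to
#'   `community`.
#' @return A `community_map`: a data frame with columns `community` and
#'   `habitat`, one row per community.
#' @examples
#' community_map(c("m1", "m2", "m3", "m4"), c("grass", "grass", "shrub", "shrub"))
#' @export
community_map <- function(community, habitat) {
  community <- as.character(community)
  habitat <- as.character(habitat)
  if (length(community) != length(habitat)) {
    stop("`community` and `habitat` must have the same length", call. = FALSE)
  }
  if (length(community) == 0L) {
    stop("a community map needs at least one community", call. = FALSE)
  }
  if (anyDuplicated(community)) {
    dup <- community[duplicated(community)][1L]
    stop("community labels must be globally unique; duplicated: '", dup, "'",
         call. = FALSE)
  }
  map <- data.frame(community = community, habitat = habitat,
                    stringsAsFactors = FALSE)
  class(map) <- c("community_map", "data.frame")
  map
}

# habitat label for each community, named by community
habitat_of <- function(map) {
  stats::setNames(map$habitat, map$community)
}

same_map <- function(a, b) {
  identical(a$community, b$community) && identical(a$habitat, b$habitat)
}

#' Census count table
#'
#' Absolute abundances n_ijk of each species in each community at one census,
#' stored as a species x community matrix; the habitat index j is implied by
#' the community-to-habitat map.  All counts are nonnegative integers.
#'
#' @param counts numeric matrix of nonnegative integers, species in rows
#'   (rownames = species labels), communities in columns (colnames matching
#'   `map$community`).
#' @param map a [community_map()] covering every column of `counts`.
#' @param time census label (coerced to character); censuses of a series
#'   should sort into their temporal order unless an explicit order is kept.
#' @return A `count_table`: list with elements `counts` (integer-valued
#'   matrix), `map`, `time`, and `total` (n_...).
#' @examples
#' map <- community_map("c1", "h1")
#' count_table(matrix(c(10, 10), 2, 1, dimnames = list(c("A", "B"), "c1")),
#'             map, time = "1")
#' @export
count_table <- function(counts, map, time = "1") {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs species rownames and community colnames",
         call. = FALSE)
  }
  if (!inherits(map, "community_map")) {
    stop("`map` must be a community_map", call. = FALSE)
  }
  missing_comm <- setdiff(colnames(counts), map$community)
  if (length(missing_comm)) {
    stop("community absent from the community map: '", missing_comm[1L], "'",
         call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  # keep columns in map order so tables of a series align
  counts <- counts[, map$community, drop = FALSE]
  structure(list(counts = counts, map = map, time = as.character(time),
                 total = sum(counts)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table: census '", x$time, "', ", nrow(x$counts), " species x ",
      ncol(x$counts), " communities in ", length(unique(x$map$habitat)),
      " habitats, ", format(x$total, big.mark = ","), " individuals\n",
      sep = "")
  invisible(x)
}

# shared-universe check for a pair of censuses
check_same_universe <- function(previous, future) {
  if (!identical(rownames(previous$counts), rownames(future$counts))) {
    stop("censuses do not share the same species set", call. = FALSE)
  }
  if (!identical(colnames(previous$counts), colnames(future$counts)) ||
      !same_map(previous$map, future$map)) {
    stop("censuses do not share the same communities / community map",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Bundle an ordered series of censuses
#'
#' @param tables list of [count_table()]s in temporal order, sharing one
#'   species set and community map.
#' @return A `metacommunity`: list with elements `tables` (named by census
#'   time) and `map`.
#' @export
metacommunity <- function(tables) {
  if (!length(tables) || !all(vapply(tables, inherits, TRUE, "count_table"))) {
    stop("`tables` must be a non-empty list of count_table objects",
         call. = FALSE)
  }
  if (length(tables) > 1L) {
    for (i in seq_along(tables)[-1L]) check_same_universe(tables[[1L]], tables[[i]])
  }
  times <- vapply(tables, `[[`, "", "time")
  if (anyDuplicated(times)) stop("duplicated census times", call. = FALSE)
  names(tables) <- times
  structure(list(tables = tables, map = tables[[1L]]$map),
            class = "metacommunity")
}

#' @export
print.metacommunity <- function(x, ...) {
  cat("metacommunity series: ", length(x$tables), " censuses (",
      paste(names(x$tables), collapse = ", "), "), ",
      nrow(x$tables[[1L]]$counts), " species, ", nrow(x$map),
      " communities in ", length(unique(x$map$habitat)), " habitats\n",
      sep = "")
  invisible(x)
}
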