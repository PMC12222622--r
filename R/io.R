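#' Read a long-format census series
#'
#' The canonical exchange format is a tidy long table with header columns
#' `time`, `species`, `habitat`, `community`, `count` (UTF-8, one row per
#' (time, species, community)).  Rows with zero counts may be omitted:
#' missing combinations are filled with 0 on read, so an explicit and a
#' zero-free file reconstruct the same tables.  The community-to-habitat
#' map must be consistent across the whole file.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"`.
#' @param time_order optional character vector giving the census order; by
#'   default the sorted unique time labels (numerically when all labels are
#'   numeric, otherwise lexically).
#' @return A [metacommunity()].
#' @export
read_counts <- function(path, format = c("csv", "tsv"), time_order = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("time", "species", "habitat", "community", "count")
  if (!all(need %in% names(df))) {
    stop("header must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  count_num <- suppressWarnings(as.numeric(df$count))
  bad <- is.na(count_num) | count_num < 0 | count_num != round(count_num)
  if (any(bad)) {
    stop("negative or non-integer count in row ", which(bad)[1L], ": '",
         df$count[which(bad)[1L]], "'", call. = FALSE)
  }
  df$count <- count_num

  key <- paste(df$time, df$species, df$community, sep = "\r")
  if (anyDuplicated(key)) {
    first <- which(duplicated(key))[1L]
    stop("duplicate (time, species, community) row: time='", df$time[first],
         "', species='", df$species[first], "', community='",
         df$community[first], "'", call. = FALSE)
  }

  comm_hab <- unique(df[, c("community", "habitat")])
  if (anyDuplicated(comm_hab$community)) {
    offender <- comm_hab$community[duplicated(comm_hab$community)][1L]
    stop("community '", offender, "' is listed under two habitats",
         call. = FALSE)
  }
  comm_hab <- comm_hab[order(comm_hab$habitat, comm_hab$community), ]
  map <- community_map(comm_hab$community, comm_hab$habitat)

  species <- sort(unique(df$species))
  times <- unique(df$time)
  if (is.null(time_order)) {
    times <- if (!anyNA(suppressWarnings(as.numeric(times)))) {
      times[order(as.numeric(times))]
    } else sort(times)
  } else {
    if (!setequal(time_order, times)) {
      stop("`time_order` does not match the time labels in the file",
           call. = FALSE)
    }
    times <- time_order
  }

  tables <- lapply(times, function(tm) {
    sub <- df[df$time == tm, , drop = FALSE]
    m <- matrix(0, length(species), nrow(map),
                dimnames = list(species, map$community))
    m[cbind(match(sub$species, species), match(sub$community, map$community))] <-
      sub$count
    count_table(m, map, time = tm)
  })
  metacommunity(tables)
}

#' Write a census series in the canonical long format
#'
#' @param x a [metacommunity()] or list of [count_table()]s.
#' @param path output file path.
#' @param format `"csv"` or `"tsv"`.
#' @param include_zeros write zero-count rows too (default omits them; the
#'   reader restores them).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("csv", "tsv"),
                         include_zeros = FALSE) {
  format <- match.arg(format)
  if (inherits(x, "count_table")) x <- list(x)
  x <- if (inherits(x, "metacommunity")) x else metacommunity(x)
  hab <- habitat_of(x$map)
  rows <- lapply(x$tables, function(ct) {
    df <- data.frame(
      time = ct$time,
      species = rep(rownames(ct$counts), times = ncol(ct$counts)),
      habitat = rep(hab[colnames(ct$counts)], each = nrow(ct$counts)),
      community = rep(colnames(ct$counts), each = nrow(ct$counts)),
      count = as.vector(ct$counts),
      stringsAsFactors = FALSE
    )
    if (!include_zeros) df <- df[df$count > 0, , drop = FALSE]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
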