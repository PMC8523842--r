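#' Pareto dominance between two objective vectors
#'
#' All objectives are maximized. `a` dominates `b` when `a` is at least as
#' good in every objective and strictly better in at least one (strict Pareto
#' dominance).
#'
#' @param a,b Numeric objective vectors of equal length (all maximized).
#' @return `TRUE` iff `a` dominates `b`.
#' @examples
#' dominates(c(0.8, 10), c(0.7, 9))   # TRUE
#' dominates(c(0.8, 10), c(0.8, 10))  # FALSE: identity is not strict
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) {
    stop("objective vectors differ in dimension (", length(a), " vs ",
         length(b), ")")
  }
  all(a >= b) && any(a > b)
}

#' Non-dominated subset of a set of objective vectors
#'
#' Returns a logical vector marking the rows of `points` that are not
#' dominated by any other row. Duplicated rows in objective space are all
#' retained: distinct channel subsets with equal scores are distinct
#' solutions.
#'
#' @param points Numeric matrix, one row per solution, one column per
#'   objective (all maximized).
#' @return Logical vector of length `nrow(points)`.
#' @export
non_dominated <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(logical(0))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    # vectorized: rows that weakly beat row i everywhere
    ge <- points >= rep(points[i, ], each = n)
    gt <- points > rep(points[i, ], each = n)
    dom_i <- rowSums(ge) == ncol(points) & rowSums(gt) > 0L
    if (any(dom_i)) keep[i] <- FALSE
  }
  keep
}

#' Crowding distance over a front
#'
#' Per-objective boundary members receive infinite distance; interior members
#' receive the sum over objectives of (gap between sorted neighbours) /
#' (objective range). An objective with zero range contributes 0. Fronts of
#' size <= 2 are all infinite.
#'
#' @param front Numeric matrix, one row per member.
#' @return Numeric vector of distances, aligned with the rows of `front`.
#' @export
crowding_distance <- function(front) {
  front <- as.matrix(front)
  n <- nrow(front)
  if (n == 0L) return(numeric(0))
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (j in seq_len(ncol(front))) {
    ord <- order(front[, j])
    rng <- front[ord[n], j] - front[ord[1L], j]
    d[ord[c(1L, n)]] <- Inf
    if (rng > 0) {
      gaps <- (front[ord[3:n], j] - front[ord[1:(n - 2L)], j]) / rng
      d[ord[2:(n - 1L)]] <- d[ord[2:(n - 1L)]] + gaps
    }
  }
  d
}

#' Create an empty capped Pareto archive
#'
#' The archive holds mutually non-dominated individuals under a fixed
#' objective view; when an update would exceed `cap`, members with the lowest
#' crowding distance are removed one at a time (distance recomputed after each
#' removal), ties broken in favour of the earliest-inserted member.
#'
#' @param cap Maximum number of members (default 100).
#' @param objective_names Character names of the objective view, e.g.
#'   `c("MAR", "NC")`.
#' @return An object of class `pareto_archive`.
#' @export
pareto_archive <- function(cap = 100L, objective_names = c("acc", "NC")) {
  stopifnot(cap >= 1L)
  structure(
    list(members = list(), cap = as.integer(cap),
         objective_names = objective_names, next_id = 1L),
    class = "pareto_archive"
  )
}

archive_objectives <- function(archive) {
  if (length(archive$members) == 0L) {
    return(matrix(numeric(0), ncol = length(archive$objective_names)))
  }
  do.call(rbind, lapply(archive$members, function(m) m$objectives))
}

#' Update a Pareto archive with candidate individuals
#'
#' Merges candidates into the archive, keeps the non-dominated subset of the
#' union, and truncates to the cap by iterated lowest-crowding removal.
#' Each candidate is a list with at least `mask` (0/1 integer vector) and
#' `objectives` (numeric vector matching the archive's objective view);
#' a `task` element is carried through when present.
#'
#' @param archive A [pareto_archive()].
#' @param candidates List of individuals.
#' @return The updated archive.
#' @export
archive_update <- function(archive, candidates) {
  stopifnot(inherits(archive, "pareto_archive"))
  if (length(candidates) == 0L) return(archive)
  dim_want <- length(archive$objective_names)
  for (cand in candidates) {
    if (is.null(cand$objectives) || length(cand$objectives) != dim_want) {
      stop("candidate objectives missing or of wrong dimension for archive")
    }
    cand$insert_id <- archive$next_id
    archive$next_id <- archive$next_id + 1L
    archive$members <- c(archive$members, list(cand))
  }
  obj <- archive_objectives(archive)
  keep <- non_dominated(obj)
  archive$members <- archive$members[keep]
  # truncate by crowding distance, recomputed after each removal;
  # among minimal-distance members the latest-inserted is removed first,
  # so the earliest insertion survives
  while (length(archive$members) > archive$cap) {
    obj <- archive_objectives(archive)
    d <- crowding_distance(obj)
    worst <- which(d == min(d))
    if (length(worst) > 1L) {
      ids <- vapply(archive$members[worst], function(m) m$insert_id, integer(1))
      worst <- worst[which.max(ids)]
    }
    archive$members <- archive$members[-worst]
  }
  archive
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat("Pareto archive <", paste(x$objective_names, collapse = ", "), "> ",
      length(x$members), "/", x$cap, " members\n", sep = "")
  invisible(x)
}

#' Archive members as a data.frame
#'
#' @param x A `pareto_archive`.
#' @param channel_names Optional montage names used to render selected
#'   channels; defaults to `ch1..chK`.
#' @param ... Unused.
#' @return data.frame with one row per member: selected channel names, the
#'   mask as a bit string, and one column per objective.
#' @export
as.data.frame.pareto_archive <- function(x, channel_names = NULL, ...) {
  if (length(x$members) == 0L) {
    out <- data.frame(channels = character(0), mask = character(0))
    for (nm in x$objective_names) out[[nm]] <- numeric(0)
    return(out)
  }
  obj <- archive_objectives(x)
  colnames(obj) <- x$objective_names
  masks <- lapply(x$members, function(m) m$mask)
  k <- length(masks[[1L]])
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(k))
  chans <- vapply(masks, function(m) {
    paste(channel_names[m == 1L], collapse = ";")
  }, character(1))
  bits <- vapply(masks, function(m) paste(m, collapse = ""), character(1))
  data.frame(channels = chans, mask = bits, obj,
             row.names = NULL, check.names = FALSE)
}

#' Write an archive as CSV plus a JSON manifest
#'
#' @param archive A `pareto_archive`.
#' @param stem Output path without extension; writes `<stem>.csv` and
#'   `<stem>.json`.
#' @param channel_names Montage names for the channel column.
#' @param extra Named list merged into the manifest (seed, generation, ...).
#' @return Invisibly, the CSV path.
#' @export
write_archive <- function(archive, stem, channel_names = NULL, extra = list()) {
  df <- as.data.frame(archive, channel_names = channel_names)
  csv <- paste0(stem, ".csv")
  data.table::fwrite(df, csv)
  manifest <- c(list(cap = archive$cap,
                     objective_view = archive$objective_names,
                     n_members = length(archive$members)),
                extra)
  jsonlite::write_json(manifest, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv)
}
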