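#' Evolutionary run configuration
#'
#' Defaults follow the standard setup for this channel-selection problem:
#' population 100, crossover probability 0.8, mutation probability 0.2,
#' a budget of 10000 objective evaluations per run, archives capped at 100,
#' and the 15-channel montage split into a motor/central block (channels
#' 1-11) and an occipital block (channels 12-15).
#'
#' @param pop_size Population size N (even).
#' @param pc Crossover probability for mixed-task parent pairs; same-task
#'   pairs always recombine.
#' @param pm Mutation trigger probability for mixed-task pairs that did not
#'   recombine.
#' @param bit_flip_rate Per-bit flip probability inside the mutation
#'   operator; default `1 / n_channels`.
#' @param budget Total number of distinct objective evaluations allowed in a
#'   run (cache hits are free).
#' @param archive_cap Maximum size of each Pareto archive.
#' @param n_channels Number of channels K (mask length).
#' @param mi_block,ssvep_block Channel index ranges (1-based) analyzed for
#'   the MI and SSVEP tasks in stage two; must partition `1:n_channels`.
#' @param stage1_fraction Share of `budget` available to stage one.
#' @param max_generations Upper bound on stage-one generations. The stopping
#'   rule is budget exhaustion; this guard exists because a converged
#'   population produces only cache hits and would otherwise never spend the
#'   remaining budget.
#' @param stage2_passes Number of analysis + local-search passes in stage two.
#' @param cv_folds Stratified cross-validation folds for the MI objective.
#' @return A list of class `ea_config`.
#' @export
ea_config <- function(pop_size = 100L, pc = 0.8, pm = 0.2,
                      bit_flip_rate = NULL, budget = 10000L,
                      archive_cap = 100L, n_channels = 15L,
                      mi_block = 1:11, ssvep_block = 12:15,
                      stage1_fraction = 0.9, max_generations = 100L,
                      stage2_passes = 1L, cv_folds = 5L) {
  pop_size <- as.integer(pop_size)
  if (pop_size < 2L || pop_size %% 2L != 0L) {
    stop("pop_size must be an even integer >= 2")
  }
  if (pc < 0 || pc > 1 || pm < 0 || pm > 1) stop("pc and pm must lie in [0,1]")
  if (budget <= 0) stop("budget must be positive")
  n_channels <- as.integer(n_channels)
  if (is.null(bit_flip_rate)) bit_flip_rate <- 1 / n_channels
  if (bit_flip_rate < 0 || bit_flip_rate > 1) {
    stop("bit_flip_rate must lie in [0,1]")
  }
  blocks <- sort(c(mi_block, ssvep_block))
  if (!identical(as.integer(blocks), seq_len(n_channels))) {
    stop("mi_block and ssvep_block must partition 1:", n_channels)
  }
  structure(list(pop_size = pop_size, pc = pc, pm = pm,
                 bit_flip_rate = bit_flip_rate, budget = as.integer(budget),
                 archive_cap = as.integer(archive_cap),
                 n_channels = n_channels,
                 mi_block = as.integer(mi_block),
                 ssvep_block = as.integer(ssvep_block),
                 stage1_fraction = stage1_fraction,
                 max_generations = as.integer(max_generations),
                 stage2_passes = as.integer(stage2_passes),
                 cv_folds = as.integer(cv_folds)),
            class = "ea_config")
}

new_individual <- function(mask, task, objectives = NULL) {
  list(mask = as.integer(mask), task = as.integer(task),
       objectives = objectives)
}

#' Two-point crossover on binary channel masks
#'
#' Positional partial-mapped crossover degenerates to a two-point segment
#' exchange on binary strings: two cut points are drawn uniformly on the
#' `K + 1` position boundaries and the segment between them (positions
#' `cuts[1] + 1` through `cuts[2]`) is swapped between the parents. The
#' per-position multiset of bits is conserved across the pair.
#'
#' @param p1,p2 Equal-length 0/1 integer vectors.
#' @param cuts Optional sorted integer pair of boundary cut points in
#'   `0:K`; drawn uniformly when `NULL`. Equal cuts swap nothing.
#' @return List of two child masks.
#' @export
crossover_masks <- function(p1, p2, cuts = NULL) {
  k <- length(p1)
  if (length(p2) != k) stop("parent masks differ in length")
  if (is.null(cuts)) cuts <- sort(sample.int(k + 1L, 2L, replace = TRUE) - 1L)
  c1 <- p1; c2 <- p2
  if (cuts[2L] > cuts[1L]) {
    seg <- seq.int(cuts[1L] + 1L, cuts[2L])
    c1[seg] <- p2[seg]
    c2[seg] <- p1[seg]
  }
  list(c1, c2)
}

#' Flip-bit mutation
#'
#' Each bit is flipped independently with probability `rate`.
#'
#' @param mask 0/1 integer vector.
#' @param rate Per-bit flip probability in `[0, 1]`.
#' @return Mutated mask.
#' @export
flip_bit_mutation <- function(mask, rate) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0,1]")
  flip <- stats::runif(length(mask)) < rate
  out <- mask
  out[flip] <- 1L - out[flip]
  out
}

# non-domination rank and within-rank crowding distance, computed per task
# group on each individual's own 2-objective view; returns the population
# with $rank and $crowding attached
rank_and_crowd <- function(pop) {
  if (length(pop) == 0L) return(pop)
  tasks <- vapply(pop, function(ind) ind$task, integer(1))
  for (tk in unique(tasks)) {
    idx <- which(tasks == tk)
    obj <- do.call(rbind, lapply(pop[idx], function(ind) ind$objectives))
    remaining <- seq_along(idx)
    r <- 0L
    while (length(remaining) > 0L) {
      nd <- non_dominated(obj[remaining, , drop = FALSE])
      front <- remaining[nd]
      cd <- crowding_distance(obj[front, , drop = FALSE])
      for (q in seq_along(front)) {
        pop[[idx[front[q]]]]$rank <- r
        pop[[idx[front[q]]]]$crowding <- cd[q]
      }
      remaining <- remaining[!nd]
      r <- r + 1L
    }
  }
  pop
}

# TRUE when individual a beats b under (rank, crowding); NA on a full tie
crowded_better <- function(a, b) {
  if (a$rank != b$rank) return(a$rank < b$rank)
  if (a$crowding != b$crowding) return(a$crowding > b$crowding)
  NA
}

#' Binary tournament selection
#'
#' Draws `length(population)` binary tournaments with replacement. Each
#' tournament compares two individuals by non-domination rank within their
#' own task's 2-objective view, then by crowding distance, then by a coin
#' flip.
#'
#' @param population List of evaluated individuals.
#' @return Parent list of the same size.
#' @export
tournament_select <- function(population) {
  n <- length(population)
  if (n == 0L) return(list())
  if (any(vapply(population, function(ind) is.null(ind$objectives),
                 logical(1)))) {
    stop("tournament_select requires every individual to be evaluated")
  }
  pop <- rank_and_crowd(population)
  parents <- vector("list", n)
  for (i in seq_len(n)) {
    pick <- sample.int(n, 2L, replace = TRUE)
    a <- pop[[pick[1L]]]; b <- pop[[pick[2L]]]
    better <- crowded_better(a, b)
    if (is.na(better)) better <- stats::runif(1) < 0.5
    parents[[i]] <- if (better) a else b
  }
  parents
}

#' Generate offspring from a list of paired parents
#'
#' Parents are taken in consecutive pairs. Same-task pairs always recombine.
#' Mixed-task pairs recombine with probability `pc`; failing that, both
#' parents are mutated with probability `pm`; failing that, they are copied
#' unchanged. Every offspring inherits the task label of its positional
#' parent. An odd trailing parent is copied through unchanged.
#'
#' @param parents List of individuals with task labels.
#' @param config An [ea_config()].
#' @return List of unevaluated offspring.
#' @export
make_offspring <- function(parents, config) {
  n <- length(parents)
  offspring <- vector("list", n)
  i <- 1L
  while (i < n) {
    p1 <- parents[[i]]; p2 <- parents[[i + 1L]]
    if (p1$task == p2$task) {
      kids <- crossover_masks(p1$mask, p2$mask)
    } else {
      r1 <- stats::runif(1)
      if (r1 < config$pc) {
        kids <- crossover_masks(p1$mask, p2$mask)
      } else {
        r2 <- stats::runif(1)
        if (r2 < config$pm) {
          kids <- list(flip_bit_mutation(p1$mask, config$bit_flip_rate),
                       flip_bit_mutation(p2$mask, config$bit_flip_rate))
        } else {
          kids <- list(p1$mask, p2$mask)
        }
      }
    }
    offspring[[i]] <- new_individual(kids[[1L]], p1$task)
    offspring[[i + 1L]] <- new_individual(kids[[2L]], p2$task)
    i <- i + 2L
  }
  if (i == n) offspring[[n]] <- new_individual(parents[[n]]$mask,
                                               parents[[n]]$task)
  offspring
}
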