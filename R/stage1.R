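#' Initialize the multitasking population
#'
#' Masks are thresholded from uniform `[0, 1]` draws at 0.5; task labels are
#' drawn uniformly from {1, 2} (1 = MI, 2 = SSVEP). Objectives are left
#' unevaluated.
#'
#' @param config An [ea_config()].
#' @return List of `pop_size` individuals.
#' @export
initialize_population <- function(config) {
  lapply(seq_len(config$pop_size), function(i) {
    mask <- as.integer(stats::runif(config$n_channels) > 0.5)
    new_individual(mask, sample(c(1L, 2L), 1L))
  })
}

# evaluate each individual on its own task's (accuracy, NC) view; individuals
# that cannot be evaluated (budget exhausted) keep objectives = NULL
evaluate_individuals <- function(pop, backend, limit = Inf) {
  for (i in seq_along(pop)) {
    ind <- pop[[i]]
    if (!is.null(ind$objectives)) next
    acc <- if (ind$task == 1L) backend$mar(ind$mask, limit)
           else backend$sar(ind$mask, limit)
    if (!is.na(acc)) {
      pop[[i]]$objectives <- c(acc = acc, NC = nc_objective(ind$mask))
    }
  }
  pop
}

# NSGA-II-style survivor pick within one task group: fill whole fronts, then
# truncate the split front by crowding distance (earliest position wins ties)
select_within_group <- function(group, n_keep) {
  if (n_keep >= length(group)) return(group)
  obj <- do.call(rbind, lapply(group, function(ind) ind$objectives))
  chosen <- integer(0)
  remaining <- seq_along(group)
  while (length(chosen) < n_keep) {
    nd <- non_dominated(obj[remaining, , drop = FALSE])
    front <- remaining[nd]
    room <- n_keep - length(chosen)
    if (length(front) <= room) {
      chosen <- c(chosen, front)
    } else {
      cd <- crowding_distance(obj[front, , drop = FALSE])
      ord <- order(-cd, seq_along(front))
      chosen <- c(chosen, front[ord[seq_len(room)]])
    }
    remaining <- remaining[!nd]
  }
  group[sort(chosen)]
}

#' Environmental selection over a mixed-task pool
#'
#' Partitions the pool by task label and keeps, per label, an NSGA-II-style
#' selection (non-domination rank, then crowding distance) of a size
#' proportional to that label's share of the pool (rounded; total exactly
#' `pop_size`). Objective values of the two tasks are never compared
#' directly. If one label group is empty, all survivors come from the other
#' group with a warning.
#'
#' @param pool List of evaluated individuals (parents plus offspring).
#' @param config An [ea_config()].
#' @return Survivor list of length `config$pop_size` (or `length(pool)` if
#'   smaller).
#' @export
environmental_selection <- function(pool, config) {
  pool <- pool[!vapply(pool, function(ind) is.null(ind$objectives), logical(1))]
  n <- config$pop_size
  if (length(pool) <= n) return(pool)
  tasks <- vapply(pool, function(ind) ind$task, integer(1))
  g1 <- pool[tasks == 1L]; g2 <- pool[tasks == 2L]
  if (length(g1) == 0L || length(g2) == 0L) {
    warning("one task label has no individuals; multitasking degenerates ",
            "to single-task selection")
    return(select_within_group(c(g1, g2), n))
  }
  q1 <- round(n * length(g1) / length(pool))
  q1 <- min(max(q1, n - length(g2)), length(g1), n)
  q2 <- n - q1
  c(select_within_group(g1, q1), select_within_group(g2, q2))
}

#' Run stage one: the evolutionary-multitasking search
#'
#' One population, two task labels. Each generation applies tournament
#' selection, crossover/mutation with label inheritance, per-task objective
#' evaluation, proportional environmental selection, and per-task Pareto
#' archive updates. Terminates when the stage-one evaluation allotment is
#' exhausted or `max_generations` is reached.
#'
#' @param backend An [objective_backend()].
#' @param config An [ea_config()].
#' @param verbose Emit a per-generation progress line.
#' @param init_pop Optional starting population (e.g. with task labels forced
#'   to a single task, which reduces the search to a single-task
#'   two-objective one); defaults to [initialize_population()].
#' @return List with `ps_mi` and `ps_ssvep` (capped [pareto_archive()]s), the
#'   final `population`, number of `generations` run, and a per-generation
#'   `progress` data.frame.
#' @export
run_stage1 <- function(backend, config, verbose = FALSE, init_pop = NULL) {
  limit <- floor(config$budget * config$stage1_fraction)
  ledger <- backend$ledger
  ps_mi <- pareto_archive(config$archive_cap, c("MAR", "NC"))
  ps_ssvep <- pareto_archive(config$archive_cap, c("SAR", "NC"))

  pop <- if (is.null(init_pop)) initialize_population(config) else init_pop
  pop <- evaluate_individuals(pop, backend, limit)
  update_archives <- function(pop) {
    evald <- pop[!vapply(pop, function(i) is.null(i$objectives), logical(1))]
    tasks <- vapply(evald, function(i) i$task, integer(1))
    ps_mi <<- archive_update(ps_mi, evald[tasks == 1L])
    ps_ssvep <<- archive_update(ps_ssvep, evald[tasks == 2L])
  }
  update_archives(pop)

  progress <- list()
  log_gen <- function(gen) {
    best <- function(a) if (length(a$members)) {
      max(vapply(a$members, function(m) m$objectives[1L], numeric(1)))
    } else NA_real_
    row <- data.frame(generation = gen, evaluations = ledger$count,
                      ps_mi_size = length(ps_mi$members),
                      ps_ssvep_size = length(ps_ssvep$members),
                      best_mar = best(ps_mi), best_sar = best(ps_ssvep))
    progress[[length(progress) + 1L]] <<- row
    if (verbose) {
      message(sprintf(
        "gen %3d  evals %5d  |PS_MI| %3d  |PS_SSVEP| %3d  MAR* %.3f  SAR* %.3f",
        gen, ledger$count, row$ps_mi_size, row$ps_ssvep_size,
        row$best_mar, row$best_sar))
    }
  }
  log_gen(0L)

  gen <- 0L
  while (ledger$count < limit && gen < config$max_generations) {
    gen <- gen + 1L
    pop_evald <- pop[!vapply(pop, function(i) is.null(i$objectives), logical(1))]
    if (length(pop_evald) == 0L) break
    parents <- tournament_select(pop_evald)
    offspring <- make_offspring(parents, config)
    offspring <- evaluate_individuals(offspring, backend, limit)
    evald <- offspring[!vapply(offspring, function(i) is.null(i$objectives),
                               logical(1))]
    pop <- environmental_selection(c(pop_evald, evald), config)
    update_archives(pop)
    log_gen(gen)
  }
  list(ps_mi = ps_mi, ps_ssvep = ps_ssvep, population = pop,
       generations = gen, progress = do.call(rbind, progress))
}
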