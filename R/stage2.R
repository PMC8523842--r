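#' Single-bit toggle voting over one channel block
#'
#' For every channel `j` in `block` and every archive member, the member's
#' bit `j` is toggled and the task accuracy re-evaluated. A toggle that turns
#' the channel on and raises accuracy, or turns it off and lowers accuracy,
#' votes +1 for the channel; the opposite outcomes vote -1; unchanged
#' accuracy leaves the tally. The sign of the final tally assigns the channel
#' to the add (positive), delete (negative), or invalid (zero) group.
#'
#' @param archive A non-empty [pareto_archive()] whose members cache their
#'   own task accuracy as the first objective.
#' @param block Integer channel indices (1-based) to analyze.
#' @param accuracy_fn Function `mask -> accuracy` for the archive's task;
#'   may return `NA` when an evaluation budget is exhausted (vote 0).
#' @return List with integer vectors `add_group`, `delete_group`,
#'   `invalid_group` (a partition of `block`) and the per-channel `votes`.
#' @export
analyze_block <- function(archive, block, accuracy_fn) {
  block <- as.integer(block)
  if (length(archive$members) == 0L) {
    warning("empty archive: all channels in the block marked invalid")
    return(list(add_group = integer(0), delete_group = integer(0),
                invalid_group = block,
                votes = stats::setNames(integer(length(block)), block)))
  }
  votes <- stats::setNames(integer(length(block)), block)
  budget_hit <- FALSE
  for (bi in seq_along(block)) {
    j <- block[bi]
    flag <- 0L
    for (member in archive$members) {
      x <- member$mask
      acc <- member$objectives[1L]
      x1 <- x
      x1[j] <- 1L - x1[j]
      acc1 <- accuracy_fn(x1)
      if (is.na(acc1)) { budget_hit <- TRUE; next }
      if (x[j] == 0L) {            # toggled 0 -> 1
        if (acc1 > acc) flag <- flag + 1L
        else if (acc1 < acc) flag <- flag - 1L
      } else {                     # toggled 1 -> 0
        if (acc1 > acc) flag <- flag - 1L
        else if (acc1 < acc) flag <- flag + 1L
      }
    }
    votes[bi] <- flag
  }
  if (budget_hit) {
    warning("evaluation budget exhausted during decision-variable analysis; ",
            "unscored toggles contributed no votes")
  }
  list(add_group = block[votes > 0L], delete_group = block[votes < 0L],
       invalid_group = block[votes == 0L], votes = votes)
}

#' Decision-variable analysis over both archives
#'
#' The motor/central block (default channels 1-11) is analyzed over the MI
#' archive with MAR; the occipital block (default channels 12-15) over the
#' SSVEP archive with SAR. The union of the per-block partitions covers the
#' whole montage.
#'
#' @param ps_mi,ps_ssvep Stage-one [pareto_archive()]s.
#' @param backend An [objective_backend()].
#' @param config An [ea_config()] supplying the blocks.
#' @param limit Evaluation-count ceiling passed to the backend.
#' @return List of class `variable_groups`: `add_group`, `delete_group`,
#'   `invalid_group` over `1:K`, plus the per-block sub-partitions.
#' @export
decision_variable_analysis <- function(ps_mi, ps_ssvep, backend, config,
                                       limit = Inf) {
  mi_part <- analyze_block(ps_mi, config$mi_block,
                           function(mask) backend$mar(mask, limit))
  ss_part <- analyze_block(ps_ssvep, config$ssvep_block,
                           function(mask) backend$sar(mask, limit))
  structure(list(add_group = c(mi_part$add_group, ss_part$add_group),
                 delete_group = c(mi_part$delete_group, ss_part$delete_group),
                 invalid_group = c(mi_part$invalid_group, ss_part$invalid_group),
                 mi_block = mi_part, ssvep_block = ss_part),
            class = "variable_groups")
}

#' @export
print.variable_groups <- function(x, ...) {
  fmt <- function(v) paste0("{", paste(v, collapse = ", "), "}")
  cat("Decision-variable analysis\n")
  cat("  motor/central block:  add ", fmt(x$mi_block$add_group),
      "  delete ", fmt(x$mi_block$delete_group),
      "  invalid ", fmt(x$mi_block$invalid_group), "\n", sep = "")
  cat("  occipital block:      add ", fmt(x$ssvep_block$add_group),
      "  delete ", fmt(x$ssvep_block$delete_group),
      "  invalid ", fmt(x$ssvep_block$invalid_group), "\n", sep = "")
  invisible(x)
}

#' Guided local search over both archives
#'
#' Each MI-archive member receives one random channel index drawn from the
#' occipital block: if it is in the add group and currently off it is
#' switched on; if in the delete group and on, switched off; otherwise the
#' member is copied unchanged. SSVEP-archive members are treated
#' symmetrically with an index drawn from the motor/central block. One
#' candidate per member, so the candidate list has `n1 + n2` entries.
#'
#' @param ps_mi,ps_ssvep Stage-one [pareto_archive()]s.
#' @param groups A `variable_groups` from [decision_variable_analysis()].
#' @param config An [ea_config()] supplying the blocks.
#' @return List of unevaluated candidate individuals (masks only).
#' @export
local_search <- function(ps_mi, ps_ssvep, groups, config) {
  nudge <- function(member, block) {
    r <- block[sample.int(length(block), 1L)]
    x1 <- member$mask
    if (r %in% groups$add_group && x1[r] == 0L) x1[r] <- 1L
    else if (r %in% groups$delete_group && x1[r] == 1L) x1[r] <- 0L
    new_individual(x1, member$task)
  }
  c(lapply(ps_mi$members, nudge, block = config$ssvep_block),
    lapply(ps_ssvep$members, nudge, block = config$mi_block))
}

#' Assemble the final three-objective Pareto set
#'
#' Evaluates MAR, SAR, and NC for every archive member and local-search
#' candidate (both accuracies are now required for every solution; duplicate
#' masks are evaluated once), then keeps the non-dominated set under
#' three-objective maximization, capped at the archive cap.
#'
#' @param ps_mi,ps_ssvep Stage-one [pareto_archive()]s.
#' @param candidates Candidate list from [local_search()].
#' @param backend An [objective_backend()].
#' @param config An [ea_config()].
#' @param limit Evaluation ceiling; on exhaustion the set is assembled from
#'   the solutions that could be evaluated, with a warning.
#' @return A three-objective [pareto_archive()] with view (MAR, SAR, NC).
#' @export
assemble_final_ps <- function(ps_mi, ps_ssvep, candidates, backend, config,
                              limit = Inf) {
  pool <- c(ps_mi$members, ps_ssvep$members, candidates)
  keys <- vapply(pool, function(ind) paste(ind$mask, collapse = ""),
                 character(1))
  pool <- pool[!duplicated(keys)]
  final <- pareto_archive(config$archive_cap, c("MAR", "SAR", "NC"))
  evaluated <- list()
  dropped <- 0L
  for (ind in pool) {
    mar <- backend$mar(ind$mask, limit)
    sar <- backend$sar(ind$mask, limit)
    if (is.na(mar) || is.na(sar)) { dropped <- dropped + 1L; next }
    evaluated <- c(evaluated, list(new_individual(
      ind$mask, ind$task, c(MAR = mar, SAR = sar, NC = nc_objective(ind$mask)))))
  }
  if (dropped > 0L) {
    warning("evaluation budget exhausted: ", dropped, " solutions could not ",
            "be scored for the final Pareto set")
  }
  archive_update(final, evaluated)
}

#' Run stage two: analysis, local search, final assembly
#'
#' @param stage1 Output of [run_stage1()].
#' @param backend An [objective_backend()].
#' @param config An [ea_config()]; `stage2_passes` analysis + search passes
#'   are run (the archives feeding each pass are the stage-one archives).
#' @return List with the final three-objective archive (`final`), the last
#'   pass's `groups`, and the candidate count.
#' @export
run_stage2 <- function(stage1, backend, config) {
  limit <- config$budget
  groups <- NULL
  candidates <- list()
  for (pass in seq_len(config$stage2_passes)) {
    groups <- decision_variable_analysis(stage1$ps_mi, stage1$ps_ssvep,
                                         backend, config, limit)
    candidates <- c(candidates,
                    local_search(stage1$ps_mi, stage1$ps_ssvep, groups, config))
  }
  final <- assemble_final_ps(stage1$ps_mi, stage1$ps_ssvep, candidates,
                             backend, config, limit)
  list(final = final, groups = groups, n_candidates = length(candidates))
}
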