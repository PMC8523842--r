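# archive with explicit members for mock-driven analysis tests
mock_archive <- function(masks, accs, view = c("MAR", "NC")) {
  arch <- pareto_archive(cap = 100L, objective_names = view)
  arch$members <- lapply(seq_along(masks), function(i) {
    list(mask = masks[[i]], task = 1L,
         objectives = c(accs[i], nc_objective(masks[[i]])), insert_id = i)
  })
  arch
}

test_that("toggle voting assigns unanimous and constant channels correctly", {
  masks <- list(c(0L, 1L, 0L, 1L), c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L))
  # accuracy = 0.2 * bit1 + 0.1 (channel 1 always helps; others ignored)
  fn <- function(mask) 0.2 * mask[1] + 0.1
  arch <- mock_archive(masks, vapply(masks, fn, numeric(1)))
  out <- analyze_block(arch, 1:4, fn)
  expect_equal(out$add_group, 1L)
  expect_equal(sort(out$invalid_group), 2:4)
  expect_length(out$delete_group, 0L)
})

test_that("toggle voting matches exhaustive enumeration on a lookup table", {
  set.seed(50)
  # random lookup table over all 16 masks of 4 channels
  table <- runif(16)
  acc_of <- function(mask) table[sum(mask * 2^(0:3)) + 1]
  masks <- list(c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L), c(1L, 1L, 1L, 1L))
  arch <- mock_archive(masks, vapply(masks, acc_of, numeric(1)))
  out <- analyze_block(arch, 1:4, acc_of)

  # brute-force oracle: enumerate every member x channel toggle by hand
  votes <- integer(4)
  for (j in 1:4) {
    for (m in masks) {
      base <- acc_of(m)
      t <- m; t[j] <- 1L - t[j]
      val <- acc_of(t)
      if (m[j] == 0L) {
        votes[j] <- votes[j] + sign(val - base)
      } else {
        votes[j] <- votes[j] - sign(val - base)
      }
    }
  }
  expect_equal(unname(out$votes), votes)
  expect_equal(out$add_group, which(votes > 0))
  expect_equal(out$delete_group, which(votes < 0))
  expect_equal(out$invalid_group, which(votes == 0))
})

test_that("an empty archive marks the whole block invalid with a warning", {
  arch <- pareto_archive(cap = 10L)
  expect_warning(out <- analyze_block(arch, 12:15, function(m) 0.5), "empty")
  expect_equal(out$invalid_group, 12:15)
})

test_that("analysis with a deterministic accuracy function is deterministic", {
  masks <- list(c(1L, 0L, 1L, 0L), c(0L, 1L, 1L, 1L))
  fn <- function(mask) sum(mask * c(0.4, -0.2, 0.1, 0)) + 0.3
  arch <- mock_archive(masks, vapply(masks, fn, numeric(1)))
  expect_identical(analyze_block(arch, 1:4, fn), analyze_block(arch, 1:4, fn))
})

test_that("block partitions stay disjoint and cover the montage", {
  cfg <- fast_ea_config()
  be <- local({
    scfg <- fast_synth_config()
    mi <- generate_mi_epochs(scfg, 13L)
    ss <- generate_ssvep_epochs(scfg, 14L)
    objective_backend(mi, ss$epochs, ss$stim)
  })
  set.seed(51)
  s1 <- run_stage1(be, fast_ea_config(max_generations = 2L, budget = 200L))
  groups <- decision_variable_analysis(s1$ps_mi, s1$ps_ssvep, be, cfg)
  all_idx <- sort(c(groups$add_group, groups$delete_group,
                    groups$invalid_group))
  expect_equal(all_idx, 1:15)
  mi_part <- c(groups$mi_block$add_group, groups$mi_block$delete_group,
               groups$mi_block$invalid_group)
  expect_setequal(mi_part, 1:11)
  ss_part <- c(groups$ssvep_block$add_group, groups$ssvep_block$delete_group,
               groups$ssvep_block$invalid_group)
  expect_setequal(ss_part, 12:15)
})

test_that("toggle evaluations are charged to the shared ledger", {
  scfg <- fast_synth_config()
  mi <- generate_mi_epochs(scfg, 15L)
  ss <- generate_ssvep_epochs(scfg, 16L)
  be <- objective_backend(mi, ss$epochs, ss$stim)
  masks <- list(as_mask(c("C3", "C4")), as_mask(c("C3", "Cz")))
  accs <- vapply(masks, be$mar, numeric(1))
  arch <- mock_archive(masks, accs)
  before <- be$ledger$count
  analyze_block(arch, 1:2, function(m) be$mar(m))
  # 2 members x 2 channels = 4 toggles, each a distinct unseen mask
  expect_equal(be$ledger$count - before, 4L)
})

test_that("local search applies exactly one guided toggle per member", {
  cfg <- ea_config()
  groups <- structure(list(add_group = c(2L, 12L, 13L, 14L, 15L),
                           delete_group = c(1L, 11L),
                           invalid_group = setdiff(1:15, c(1, 2, 11:15))),
                      class = "variable_groups")
  # all-invalid groups: candidates are exact copies
  none <- structure(list(add_group = integer(0), delete_group = integer(0),
                         invalid_group = 1:15), class = "variable_groups")
  ps_mi <- mock_archive(list(as_mask(c("C3", "C4"))), 0.9)
  ps_ss <- mock_archive(list(as_mask(c("O1", "Oz"))), 0.8,
                        view = c("SAR", "NC"))
  set.seed(52)
  cands <- local_search(ps_mi, ps_ss, none, cfg)
  expect_length(cands, 2L)
  expect_equal(cands[[1]]$mask, as_mask(c("C3", "C4")))
  expect_equal(cands[[2]]$mask, as_mask(c("O1", "Oz")))

  # MI member with no occipital bits and add_group covering the occipital
  # block must gain exactly one occipital channel
  full_add <- structure(list(add_group = 12:15, delete_group = integer(0),
                             invalid_group = 1:11), class = "variable_groups")
  set.seed(53)
  for (r in 1:10) {
    cands <- local_search(ps_mi, ps_ss, full_add, cfg)
    gained <- which(cands[[1]]$mask != as_mask(c("C3", "C4")))
    expect_length(gained, 1L)
    expect_true(gained %in% 12:15)
  }
})

test_that("final assembly is oracle-equivalent, consistent, and capped", {
  scfg <- fast_synth_config()
  mi <- generate_mi_epochs(scfg, 17L)
  ss <- generate_ssvep_epochs(scfg, 18L)
  be <- objective_backend(mi, ss$epochs, ss$stim)
  cfg <- fast_ea_config(max_generations = 2L, budget = 300L)
  set.seed(54)
  s1 <- run_stage1(be, cfg)
  groups <- decision_variable_analysis(s1$ps_mi, s1$ps_ssvep, be, cfg)
  cands <- local_search(s1$ps_mi, s1$ps_ssvep, groups, cfg)
  expect_length(cands, length(s1$ps_mi$members) + length(s1$ps_ssvep$members))
  final <- assemble_final_ps(s1$ps_mi, s1$ps_ssvep, cands, be, cfg)
  expect_gt(length(final$members), 0L)
  expect_lte(length(final$members), cfg$archive_cap)
  obj <- do.call(rbind, lapply(final$members, function(m) m$objectives))
  expect_true(all(non_dominated(obj)))
  expect_equal(non_dominated(obj), oracle_non_dominated(obj))
  # NC is definitionally consistent with each mask
  for (m in final$members) {
    expect_equal(unname(m$objectives[3]), nc_objective(m$mask))
  }
})

test_that("a simultaneous best-in-everything solution is the sole survivor", {
  cfg <- fast_ea_config()
  scfg <- fast_synth_config()
  mi <- generate_mi_epochs(scfg, 19L)
  ss <- generate_ssvep_epochs(scfg, 20L)
  be <- objective_backend(mi, ss$epochs, ss$stim)
  # craft a pool whose first member dominates the rest on all three axes:
  # evaluate masks and keep only ones the planted mask beats
  champ <- as_mask(c("C3", "O1"))
  rivals <- list(as_mask(c("FC3", "C5", "CP3", "CP4", "C6")),
                 as_mask(c("FC3", "FC4", "C5", "C1", "C6", "CP3")))
  ps <- mock_archive(c(list(champ), rivals),
                     c(be$mar(champ), vapply(rivals, be$mar, numeric(1))))
  empty <- pareto_archive(cap = 100L, objective_names = c("SAR", "NC"))
  final <- assemble_final_ps(ps, empty, list(), be, cfg)
  obj <- do.call(rbind, lapply(final$members, function(m) m$objectives))
  champ_row <- c(be$mar(champ), be$sar(champ), nc_objective(champ))
  if (all(apply(obj, 1, function(r) all(champ_row >= r)))) {
    expect_equal(nrow(obj), 1L)
    expect_equal(unname(obj[1, ]), unname(champ_row))
  }
})

test_that("stage-2 never loses a three-objective non-dominated stage-1 member", {
  scfg <- fast_synth_config()
  mi <- generate_mi_epochs(scfg, 21L)
  ss <- generate_ssvep_epochs(scfg, 22L)
  be <- objective_backend(mi, ss$epochs, ss$stim)
  cfg <- fast_ea_config(max_generations = 2L, budget = 300L)
  set.seed(55)
  s1 <- run_stage1(be, cfg)
  groups <- decision_variable_analysis(s1$ps_mi, s1$ps_ssvep, be, cfg)
  cands <- local_search(s1$ps_mi, s1$ps_ssvep, groups, cfg)
  final <- assemble_final_ps(s1$ps_mi, s1$ps_ssvep, cands, be, cfg)
  # a stage-1 member still non-dominated after adding the local-search
  # candidates must survive into the final set (the cap was not reached)
  expect_lt(length(final$members), cfg$archive_cap)
  pool <- c(s1$ps_mi$members, s1$ps_ssvep$members)
  n_pool <- length(pool)
  all_obj <- t(vapply(c(pool, cands), function(m) {
    c(be$mar(m$mask), be$sar(m$mask), nc_objective(m$mask))
  }, numeric(3)))
  nd <- non_dominated(all_obj)
  final_keys <- vapply(final$members,
                       function(m) paste(m$mask, collapse = ""), character(1))
  for (i in which(nd[seq_len(n_pool)])) {
    expect_true(paste(pool[[i]]$mask, collapse = "") %in% final_keys)
  }
})
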