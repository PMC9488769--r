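test_that("dead-end detection respects reversibility", {
  m <- metabolic_model()
  m <- add_reaction(m, "R1", c(a = -1, b = 1), 0, 1000)      # produces b
  m <- add_reaction(m, "R2", c(b = -1, c = 1), -1000, 1000)  # reversible
  m <- add_reaction(m, "EX_a", c(a = -1), -10, 1000)
  dead <- find_dead_end_metabolites(m)
  # c: produced by reversible R2 and consumed by its reverse -> not dead
  expect_false("c" %in% dead$metabolite)
  expect_false("b" %in% dead$metabolite)
  m2 <- add_reaction(m, "R3", c(c = -1, d = 1), 0, 1000)
  dead2 <- find_dead_end_metabolites(m2)
  expect_true("d" %in% dead2$metabolite)  # produced, never consumed
})

test_that("candidate pool partitions by score and synthesizes exchanges", {
  g <- synth_network("gapped", size = 5, seed = 7)
  pool <- build_candidate_pool(g$db, g$scored, g$model)
  expect_true(all(g$known_optimal_gapfill %in%
                    pool$reaction_id[pool$kind == "low_conf_ec"]))
  expect_false(any(pool$reaction_id %in% names(g$model$reactions)))
  # highest EC score per reaction
  multi <- data.frame(protein_id = c("px", "py"),
                      ec = c("8.8.1.1", "8.8.1.1"), score = c(0.2, 0.4))
  pool2 <- build_candidate_pool(g$db, multi, g$model)
  expect_equal(pool2$s[pool2$reaction_id == "DEC01"], 0.4)
  # score above 0.5 -> not a candidate
  high <- data.frame(protein_id = "px", ec = "8.8.1.1", score = 0.6)
  pool3 <- build_candidate_pool(g$db, high, g$model)
  expect_false("DEC01" %in% pool3$reaction_id)
  # score at/below the floor -> treated as unscored
  floor <- data.frame(protein_id = "px", ec = "8.8.1.1", score = 1e-4)
  pool4 <- build_candidate_pool(g$db, floor, g$model)
  expect_equal(pool4$kind[pool4$reaction_id == "DEC01"], "no_conf")
})

test_that("penalties follow median scaling and its invariants", {
  cand <- data.frame(reaction_id = c("r1", "r2", "r3"),
                     kind = "low_conf_ec", s = c(0.1, 0.2, 0.4))
  pen <- compute_penalties(cand)
  expect_equal(pen$s_scaled, c(0.5, 1, 2))
  expect_equal(pen$penalty, c(2 / 3, 1 / 2, 1 / 3), tolerance = 1e-15)
  # median of scaled scores is exactly 1 for any nonempty scored set
  set.seed(12)
  for (n in c(1, 2, 5, 20, 101)) {
    s <- runif(n, 1e-4 + 1e-12, 0.5)
    cand2 <- data.frame(reaction_id = paste0("r", seq_len(n)),
                        kind = "low_conf_ec", s = s)
    pen2 <- compute_penalties(cand2)
    expect_equal(median(pen2$s_scaled), 1)
    # strict monotonicity: bigger score, smaller penalty
    o <- order(pen2$s)
    expect_true(all(diff(pen2$penalty[o]) < 0) || n == 1)
  }
  # unscored and dead-end penalties
  mixed <- data.frame(reaction_id = c("a", "b", "c"),
                      kind = c("low_conf_ec", "no_conf", "deadend_exchange"),
                      s = c(0.3, NA, NA))
  pm <- compute_penalties(mixed, default_penalty = 1, deadend_penalty = 10)
  expect_equal(pm$penalty, c(0.5, 1, 10))
})

test_that("gap-filling MILP finds the cheapest repair and verifies beta", {
  g <- synth_network("gapped", size = 5, seed = 7)
  pool <- compute_penalties(build_candidate_pool(g$db, g$scored, g$model))
  prob <- gapfill_problem(g$model, pool, g$db, beta = 0.1)
  res <- solve_gapfill_milp(prob)
  expect_setequal(res$selected, g$known_optimal_gapfill)
  expect_gte(res$biomass, 0.1)
  aug <- augment_model(g$model, res, prob)
  expect_gte(fba(aug)$objective, 0.1)
  expect_equal(aug$reactions[[res$selected[1]]]$provenance, "gapfill")
  # base model already feasible -> empty selection, zero penalty
  chain <- synth_network("chain", size = 4, seed = 1)
  pool0 <- compute_penalties(build_candidate_pool(chain$db, chain$scored,
                                                  chain$model))
  prob0 <- gapfill_problem(chain$model, pool0, chain$db, beta = 0.1)
  res0 <- solve_gapfill_milp(prob0)
  expect_equal(res0$selected, character(0))
  expect_equal(res0$objective, 0)
  expect_identical(augment_model(chain$model, res0, prob0)$reactions,
                   chain$model$reactions)
})

test_that("cheaper of two alternative single-reaction fixes is selected", {
  # EX -> a, biomass drains b; two candidate fixes a->b with penalties .4/.9
  m <- metabolic_model()
  m <- add_reaction(m, "EX_a", c(a = -1), -1, 1000)
  m <- add_reaction(m, "BIO", c(b = -1), 0, 1000)
  m <- set_objective(m, "BIO")
  cands <- list(
    FIXA = list(id = "FIXA", name = "FIXA", stoichiometry = c(a = -1, b = 1),
                lower = 0, upper = 1000, genes = character(),
                ecs = character(), provenance = "gapfill", penalty = NA),
    FIXB = list(id = "FIXB", name = "FIXB", stoichiometry = c(a = -1, b = 1),
                lower = 0, upper = 1000, genes = character(),
                ecs = character(), provenance = "gapfill", penalty = NA))
  cand_df <- data.frame(reaction_id = c("FIXA", "FIXB"), kind = "no_conf",
                        s = NA_real_, s_scaled = NA_real_,
                        penalty = c(0.4, 0.9))
  prob <- structure(list(model = m, candidates = cand_df,
                         candidate_reactions = cands, beta = 0.1),
                    class = "gapfill_problem")
  res <- solve_gapfill_milp(prob)
  expect_equal(res$selected, "FIXA")
  expect_equal(res$objective, 0.4)
})

test_that("infeasible gap-filling names unreachable objective precursors", {
  m <- metabolic_model()
  m <- add_reaction(m, "EX_a", c(a = -1), -1, 1000)
  m <- add_reaction(m, "BIO", c(z = -1), 0, 1000)
  m <- set_objective(m, "BIO")
  cand_df <- data.frame(reaction_id = character(), kind = character(),
                        s = numeric(), s_scaled = numeric(),
                        penalty = numeric())
  prob <- structure(list(model = m, candidates = cand_df,
                         candidate_reactions = list(), beta = 0.1),
                    class = "gapfill_problem")
  expect_error(solve_gapfill_milp(prob), "z")
})

test_that("raising the dead-end penalty never adds more dead-end exchanges", {
  for (seed in c(3, 5, 9)) {
    g <- synth_network("gapped", size = 4, seed = seed)
    pool <- build_candidate_pool(g$db, g$scored, g$model)
    n_ex <- function(dp) {
      pen <- compute_penalties(pool, deadend_penalty = dp)
      prob <- gapfill_problem(g$model, pen, g$db, beta = 0.1)
      res <- solve_gapfill_milp(prob)
      sum(grepl("^EX_", res$selected))
    }
    expect_lte(n_ex(10), n_ex(1))
  }
})
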