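test_that("FBA on unit chains equals the binding uptake bound", {
  net <- synth_network("chain", size = 4, seed = 1)
  expect_equal(fba(net$model)$objective, 1)
  # closing the uptake kills growth
  closed <- net$model
  closed$reactions$EX_m1$lower <- 0
  expect_equal(fba(closed)$objective, 0)
})

test_that("stoichiometric amplification doubles the optimum", {
  m <- metabolic_model()
  m <- add_reaction(m, "EX_a", c(a = -1), -1, 1000)
  m <- add_reaction(m, "AMP", c(a = -1, b = 2), 0, 1000)
  m <- add_reaction(m, "BIO", c(b = -1), 0, 1000)
  m <- set_objective(m, "BIO")
  expect_equal(fba(m)$objective, 2)
})

test_that("media override exchange bounds and must exist", {
  net <- synth_network("chain", size = 4, seed = 1)
  med <- media_definition(c(EX_m1 = 0.25))
  expect_equal(fba(net$model, media = med)$objective, 0.25)
  expect_error(fba(net$model, media = media_definition(c(EX_zz = 1))),
               "EX_zz")
})

test_that("knockout calls match reaction-deletion enumeration", {
  for (spec in c("chain", "parallel")) {
    net <- synth_network(spec, size = 4, seed = 1)
    calls <- single_gene_knockouts(net$model)
    genes <- sort(unique(unlist(lapply(net$model$reactions, `[[`, "genes"))))
    for (g in genes) {
      solo <- names(Filter(function(r) identical(r$genes, g),
                           net$model$reactions))
      # oracle: physically delete the reactions instead of zeroing bounds
      del <- net$model
      del$reactions[solo] <- NULL
      res <- fba(del)
      growth <- identical(res$status, "optimal") && res$objective >= 1e-4
      expect_equal(calls$call[calls$gene == g],
                   if (growth) "non-essential" else "essential")
    }
  }
})

test_that("genes only in multi-gene reactions are untestable", {
  m <- toy_model()
  m$reactions$CONV$genes <- c("g1", "g2")
  calls <- single_gene_knockouts(m)
  expect_equal(calls$call, rep("untestable", 2))
})

test_that("phenotype array swaps sources and applies the growth call", {
  # biomass reachable from m1 or from alternate source n1
  m <- metabolic_model()
  m <- add_reaction(m, "EX_m1", c(m1 = -1), -1, 1000)
  m <- add_reaction(m, "EX_n1", c(n1 = -1), 0, 1000)  # closed by default
  m <- add_reaction(m, "USE_M", c(m1 = -1, b = 1), 0, 1000)
  m <- add_reaction(m, "USE_N", c(n1 = -1, b = 1), 0, 1000)
  m <- add_reaction(m, "BIO", c(b = -1), 0, 1000)
  m <- set_objective(m, "BIO")
  swaps <- data.frame(element = c("C", "C"),
                      default_exchange = "EX_m1",
                      alternate_exchange = c("EX_n1", "EX_missing"))
  out <- phenotype_array(m, media_definition(c(EX_m1 = 1)), swaps)
  expect_equal(out$growth, c("positive", "untestable"))
  expect_equal(out$objective[1], 10)   # alternate bound 10 is binding
  # disconnected alternate -> negative
  m2 <- m
  m2$reactions$USE_N <- NULL
  out2 <- phenotype_array(m2, media_definition(c(EX_m1 = 1)), swaps[1, ])
  expect_equal(out2$growth, "negative")
})

test_that("growth call threshold is inclusive at 1e-4", {
  m <- metabolic_model()
  m <- add_reaction(m, "EX_m1", c(m1 = -1), 0, 1000)
  m <- add_reaction(m, "EX_n1", c(n1 = -1), 0, 1000)
  m <- add_reaction(m, "USE_N", c(n1 = -1, b = 1), 0, 1e-4)  # cap at 1e-4
  m <- add_reaction(m, "BIO", c(b = -1), 0, 1000)
  m <- set_objective(m, "BIO")
  swaps <- data.frame(element = "C", default_exchange = "EX_m1",
                      alternate_exchange = "EX_n1")
  out <- phenotype_array(m, media_definition(c(EX_m1 = 0)), swaps)
  expect_equal(out$objective, 1e-4)
  expect_equal(out$growth, "positive")
})

test_that("yields scale linearly in the substrate bound", {
  m <- metabolic_model()
  m <- add_reaction(m, "EX_glc", c(glc = -1), -1, 1000)
  m <- add_reaction(m, "GLYC", c(glc = -1, atp = 2), 0, 1000)
  m <- add_reaction(m, "ATPH", c(atp = -1), 0, 1000)
  m <- add_reaction(m, "BIO", c(atp = -1), 0, 1000)
  m <- set_objective(m, "BIO")
  y <- yield_analysis(m, "EX_glc", objective = "atp_hydrolysis",
                      atp_reaction_id = "ATPH")
  expect_equal(y$yield, 2)            # 1 glucose -> 2 ATP
  expect_equal(y$control, 0)
  expect_false(y$energy_cycle_sentinel)
  # homogeneity: 2.5x the uptake bound gives 2.5x the yield
  m25 <- m
  m25$reactions$EX_glc$lower <- -2.5
  expect_equal(fba(m25, objective_id = "ATPH")$objective, 5)
})

test_that("anaerobic yields close the oxygen exchange", {
  m <- metabolic_model()
  m <- add_reaction(m, "EX_glc", c(glc = -1), -1, 1000)
  m <- add_reaction(m, "EX_o2", c(o2 = -1), -10, 1000)
  m <- add_reaction(m, "RESP", c(glc = -1, o2 = -1, atp = 26), 0, 1000)
  m <- add_reaction(m, "FERM", c(glc = -1, atp = 3), 0, 1000)
  m <- add_reaction(m, "ATPH", c(atp = -1), 0, 1000)
  m <- add_reaction(m, "BIO", c(atp = -1), 0, 1000)
  m <- set_objective(m, "BIO")
  aero <- yield_analysis(m, "EX_glc", aerobic = TRUE,
                         objective = "atp_hydrolysis",
                         atp_reaction_id = "ATPH")
  anaero <- yield_analysis(m, "EX_glc", aerobic = FALSE,
                           objective = "atp_hydrolysis",
                           oxygen_exchange = "EX_o2",
                           atp_reaction_id = "ATPH")
  expect_equal(aero$yield, 26)
  expect_equal(anaero$yield, 3)
})

test_that("energy-cycle sentinel fires only on cycle fixtures", {
  cyc <- synth_network("energy_cycle", size = 3, seed = 1)
  y <- yield_analysis(cyc$model, "EX_m1", objective = "atp_hydrolysis",
                      atp_reaction_id = "ATPH")
  expect_true(y$energy_cycle_sentinel)
  expect_gt(y$control, 0)
  chain <- synth_network("chain", size = 3, seed = 1)
  y2 <- yield_analysis(chain$model, "EX_m1", objective = "biomass")
  expect_false(y2$energy_cycle_sentinel)
})

test_that("blocked-reaction diagnostic flags dead branches", {
  m <- toy_model()
  m <- add_reaction(m, "DEAD", c(a = -1, w = 1), 0, 1000)  # w has no sink
  br <- blocked_reactions(m)
  expect_true(br$blocked[br$reaction_id == "DEAD"])
  expect_false(br$blocked[br$reaction_id == "BIOMASS"])
})
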