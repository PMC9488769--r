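mk_table <- function(...) merge_prediction_tables(data.frame(...))

test_that("training sets follow the gold/predicted partition", {
  tab <- mk_table(protein_id = c("p1", "p2"), ec = "1.1.1.1",
                  tool = c("A", "B"), raw_score = 0.9,
                  confidence_level = "high")
  gold <- data.frame(protein_id = c("p1", "p3"), ec = "1.1.1.1")
  sets <- build_training_sets(tab, gold, "1.1.1.1")
  expect_equal(sets$positives, c("p1", "p3"))  # gold membership, not predictions
  expect_equal(sets$negatives, "p2")
  # no negatives -> degenerate error
  gold2 <- data.frame(protein_id = c("p1", "p2"), ec = "1.1.1.1")
  expect_error(build_training_sets(tab, gold2, "1.1.1.1"),
               class = "training_degenerate")
})

test_that("naive Bayes parameters match hand-counted smoothing", {
  feats <- matrix(c(rep(1, 4), 1, rep(0, 5)), ncol = 1)
  labels <- c(rep(1, 4), rep(0, 6))
  p <- fit_naive_bayes(feats, labels, alpha = 1)
  expect_equal(p$cond_pos[[1]], 5 / 6)
  expect_equal(p$cond_neg[[1]], 0.25)
  expect_equal(p$prior_pos, 5 / 12)
  expect_error(fit_naive_bayes(feats, labels, alpha = 0))
  expect_error(fit_naive_bayes(feats, rep(1, 10)))
})

test_that("posterior matches hand evaluation and normalizes", {
  par <- structure(list(ec = NULL, k = 2, prior_pos = 0.3,
                        cond_pos = c(0.9, 0.8), cond_neg = c(0.2, 0.1)),
                   class = "nb_params")
  expect_equal(nb_posterior(c(1, 0), par), 0.054 / 0.180, tolerance = 1e-12)
  expect_equal(nb_posterior(c(1, 1), par), 0.216 / (0.216 + 0.014),
               tolerance = 1e-12)
  # uninformative features collapse to the prior
  par2 <- par; par2$cond_neg <- par2$cond_pos
  for (f in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
    expect_equal(nb_posterior(f, par2), 0.3, tolerance = 1e-12)
  expect_error(nb_posterior(c(1, 0, 1), par), "k = 2")
})

test_that("posterior is monotone in features when tools are informative", {
  set.seed(7)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    cn <- runif(k, 0.01, 0.5)
    par <- structure(list(ec = NULL, k = k, prior_pos = runif(1, 0.05, 0.95),
                          cond_pos = cn + runif(k, 0.01, 0.49),
                          cond_neg = cn), class = "nb_params")
    f <- rbinom(k, 1, 0.5)
    base <- nb_posterior(f, par)
    for (i in which(f == 0)) {
      f2 <- f; f2[i] <- 1
      expect_gte(nb_posterior(f2, par), base)
    }
  }
})

test_that("alternative classifiers score in [0,1], deterministically", {
  set.seed(3)
  feats <- matrix(rbinom(120, 2, 0.5), ncol = 2,
                  dimnames = list(NULL, c("A", "B")))
  labels <- as.integer(feats[, 1] >= 1)   # separable in feature A
  for (method in c("logistic_regression", "random_forest")) {
    fit1 <- fit_alt_classifier(method, feats, labels, seed = 99)
    fit2 <- fit_alt_classifier(method, feats, labels, seed = 99)
    held <- matrix(c(0, 2, 1, 0), ncol = 2, byrow = TRUE,
                   dimnames = list(NULL, c("A", "B")))
    s1 <- fit1$score(held); s2 <- fit2$score(held)
    expect_equal(s1, s2)
    expect_true(all(s1 >= 0 & s1 <= 1))
    train_acc <- mean((fit1$score(feats) > 0.5) == labels)
    expect_equal(train_acc, 1.0)
  }
})

test_that("logistic scores rise with the number of high-confidence tools", {
  # balanced toy data where each tool is informative
  set.seed(21)
  f <- as.matrix(expand.grid(A = 0:1, B = 0:1))
  feats <- f[rep(1:4, times = 30), ]
  prob <- c(0.05, 0.5, 0.5, 0.95)[rep(1:4, times = 30)]
  labels <- rbinom(nrow(feats), 1, prob)
  fit <- fit_alt_classifier("logistic_regression", feats, labels, seed = 1)
  s <- fit$score(f)
  expect_true(s[4] >= s[2] && s[4] >= s[3])
  expect_true(s[2] >= s[1] && s[3] >= s[1])
})

test_that("majority rule counts only tools able to predict the EC", {
  ranges <- list(A = "1.1.1.1", B = "1.1.1.1", C = "1.1.1.1", D = "1.1.1.1",
                 E = c("1.1.1.1", "2.7.1.1"))
  pred3 <- list(A = "1.1.1.1", B = "1.1.1.1", C = "1.1.1.1")
  expect_equal(majority_rule_assign(pred3, ranges), "1.1.1.1")  # 3 of 5
  pred2 <- list(A = "1.1.1.1", B = "1.1.1.1")
  expect_equal(majority_rule_assign(pred2, ranges), character(0))  # 2 of 5
  predE <- list(E = "2.7.1.1")
  expect_equal(majority_rule_assign(predE, ranges), "2.7.1.1")  # 1 of 1
})

test_that("best-tool rule follows training F1, ties and fallback", {
  perf <- data.frame(ec = c("1.1.1.1", "1.1.1.1", "2.7.1.1", "2.7.1.1"),
                     tool = c("A", "B", "A", "B"),
                     f1 = c(0.9, 0.4, 0.7, 0.7))
  ranges <- list(A = c("1.1.1.1", "2.7.1.1", "3.5.1.2"),
                 B = c("1.1.1.1", "2.7.1.1", "3.5.1.2"))
  # only the worse tool predicts -> not assigned
  expect_equal(best_tool_assign(list(B = "1.1.1.1"), perf, ranges),
               character(0))
  # tie: any tied-best tool suffices
  expect_equal(best_tool_assign(list(A = "2.7.1.1"), perf, ranges),
               "2.7.1.1")
  # EC not in table -> majority fallback with warning
  expect_warning(
    out <- best_tool_assign(list(A = "3.5.1.2", B = "3.5.1.2"), perf, ranges),
    "fell back")
  expect_equal(out, "3.5.1.2")
})

test_that("high-confidence selection applies strict 0.5, auto rule and pass-through", {
  profs <- list(two_bin_profile("A", c("1.1.1.1", "2.7.1.1")),
                two_bin_profile("P", c("1.1.1.1", "2.7.1.1", "3.5.1.2")))
  tab <- mk_table(protein_id = c("p1", "p2", "p3"),
                  ec = c("1.1.1.1", "2.7.1.1", "3.5.1.2"),
                  tool = c("A", "A", "P"),
                  raw_score = c(0.9, 0.9, 0.9),
                  confidence_level = "high")
  model <- structure(list(
    method = "naive_bayes", per_ec_params = list("1.1.1.1" = NULL),
    auto_assign_ecs = "2.7.1.1", cooccurrence = list(),
    tool_ranges = list(A = c("1.1.1.1", "2.7.1.1"),
                       P = c("1.1.1.1", "2.7.1.1", "3.5.1.2")),
    profiles = profs, encoding = "binary_high_conf",
    passthrough_tool = "P"), class = "ensemble_model")
  scored <- data.frame(protein_id = c("p1", "p9", "p8"),
                       ec = "1.1.1.1",
                       score = c(0.51, 0.50, 0.49), source = "classifier")
  hc <- select_high_confidence(scored, model, tab)
  key <- paste(hc$protein_id, hc$ec)
  expect_true("p1 1.1.1.1" %in% key)            # 0.51 > 0.5
  expect_false("p9 1.1.1.1" %in% key)           # exactly 0.5 excluded
  expect_false("p8 1.1.1.1" %in% key)
  expect_true("p2 2.7.1.1" %in% key)            # auto rule
  expect_equal(hc$source[key == "p2 2.7.1.1"], "auto_rule")
  expect_true("p3 3.5.1.2" %in% key)            # pass-through outside range
  expect_equal(hc$source[key == "p3 3.5.1.2"], "passthrough")
  # idempotent and superset of triggered auto-rule predictions
  hc2 <- select_high_confidence(hc[hc$source == "classifier", ], model, tab)
  expect_setequal(paste(hc2$protein_id, hc2$ec), key)
})

test_that("multifunctional filter keeps top EC plus co-occurring, ties kept", {
  sc <- data.frame(ec = c("e1", "e2", "e3"), score = c(0.9, 0.6, 0.55))
  expect_equal(multifunctional_filter(sc, list(e1 = "e2")), c("e1", "e2"))
  expect_equal(multifunctional_filter(sc[1, , drop = FALSE]), "e1")
  tie <- data.frame(ec = c("e1", "e2", "e3"), score = c(0.9, 0.9, 0.2))
  expect_equal(multifunctional_filter(tie, list()), c("e1", "e2"))
})

test_that("auto-assign rule requires all able tools and zero false positives", {
  profs <- list(two_bin_profile("A", c("1.1.1.1", "2.7.1.1")),
                two_bin_profile("B", c("1.1.1.1", "2.7.1.1")))
  gold <- data.frame(protein_id = c("p1", "p2"),
                     ec = c("1.1.1.1", "2.7.1.1"))
  tab <- mk_table(
    protein_id = c("p1", "p1", "p2", "p3"),
    ec = c("1.1.1.1", "1.1.1.1", "2.7.1.1", "2.7.1.1"),
    tool = c("A", "B", "A", "B"),
    raw_score = 0.9, confidence_level = "high")
  # 1.1.1.1: both tools predict, no FPs -> auto.
  # 2.7.1.1: B predicts p3 which is an FP -> excluded.
  expect_equal(compute_auto_assign_ecs(tab, gold, profs), "1.1.1.1")
})
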