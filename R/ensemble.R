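#' Assemble positive and negative training sets for one EC
#'
#' Positives are the proteins carrying the EC in the gold standard; negatives
#' are proteins predicted to have that activity by at least one tool but
#' lacking it in the gold standard. The two sets are disjoint by construction.
#'
#' @param table a `prediction_table`.
#' @param gold data.frame with columns `protein_id`, `ec`.
#' @param ec the EC number under training.
#' @return list with character vectors `positives` and `negatives`.
#' @export
build_training_sets <- function(table, gold, ec) {
  positives <- sort(unique(gold$protein_id[gold$ec == ec]))
  df <- as.data.frame(table)
  predicted <- unique(df$protein_id[df$ec == ec])
  negatives <- sort(setdiff(predicted, positives))
  if (!length(positives) || !length(negatives)) {
    cond <- structure(
      class = c("training_degenerate", "error", "condition"),
      list(message = paste0("degenerate training set for EC ", ec,
                            ": ", length(positives), " positives, ",
                            length(negatives), " negatives"),
           call = sys.call()))
    stop(cond)
  }
  list(positives = positives, negatives = negatives)
}

#' Fit a per-EC Bernoulli naive Bayes classifier
#'
#' Each binary feature (was the EC predicted at high confidence by tool i?)
#' is modelled as a Bernoulli variable conditional on class membership.
#' Add-alpha (Laplace) smoothing keeps every estimated probability strictly
#' inside (0, 1):
#' prior = (n_pos + alpha) / (n + 2 alpha);
#' p(F_i = 1 | y = c) = (count + alpha) / (n_c + 2 alpha).
#'
#' @param features binary matrix (proteins x k tools) from
#'   [build_feature_matrix()] with `binary_high_conf` encoding.
#' @param labels 0/1 vector (1 = protein truly carries the EC).
#' @param alpha smoothing pseudo-count, must be > 0.
#' @param ec optional EC identifier stored with the parameters.
#' @return object of class `nb_params`: `k`, `prior_pos`, `cond_pos`,
#'   `cond_neg`.
#' @export
fit_naive_bayes <- function(features, labels, alpha = 1, ec = NULL) {
  stopifnot(alpha > 0)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("naive Bayes needs both positive and negative examples")
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels),
            all(features %in% c(0, 1)))
  pos <- features[labels == 1, , drop = FALSE]
  neg <- features[labels == 0, , drop = FALSE]
  n_pos <- nrow(pos); n_neg <- nrow(neg)
  params <- list(
    ec = ec, k = ncol(features),
    prior_pos = (n_pos + alpha) / (n_pos + n_neg + 2 * alpha),
    cond_pos = (colSums(pos) + alpha) / (n_pos + 2 * alpha),
    cond_neg = (colSums(neg) + alpha) / (n_neg + 2 * alpha))
  stopifnot(all(unlist(params[c("prior_pos", "cond_pos", "cond_neg")]) > 0),
            all(unlist(params[c("prior_pos", "cond_pos", "cond_neg")]) < 1))
  class(params) <- "nb_params"
  params
}

#' Posterior probability (likelihood score) of a Bernoulli naive Bayes model
#'
#' Computes p(y = 1 | F = f) = prior * prod_i p(F_i = f_i | y = 1) /
#' sum over both classes of the same product, the per-(protein, EC)
#' likelihood score of the ensemble.
#'
#' @param f binary feature vector of length k, or a matrix with k columns
#'   (one row per protein).
#' @param params an `nb_params` object.
#' @return numeric vector of posteriors in (0, 1).
#' @export
nb_posterior <- function(f, params) {
  f <- if (is.matrix(f)) f else matrix(f, nrow = 1)
  if (ncol(f) != params$k)
    stop("feature vector length ", ncol(f), " != k = ", params$k)
  lik <- function(cond) {
    # log-space product of Bernoulli terms per row
    exp(f %*% log(cond) + (1 - f) %*% log(1 - cond))
  }
  num <- params$prior_pos * lik(params$cond_pos)
  den <- num + (1 - params$prior_pos) * lik(params$cond_neg)
  as.numeric(num / den)
}

#' Fit an alternative per-EC classifier (logistic regression / random forest)
#'
#' Logistic regression trains on one-hot confidence-level features; random
#' forest on ordinal level features. Both return a scorer mapping feature
#' rows to [0, 1], deterministic given the seed.
#'
#' @param method `"logistic_regression"` or `"random_forest"`.
#' @param features numeric matrix in the encoding matching the method.
#' @param labels 0/1 vector.
#' @param seed integer seed for any stochastic fit.
#' @return object of class `alt_classifier` with a `$score(features)` closure.
#' @export
fit_alt_classifier <- function(method = c("logistic_regression", "random_forest"),
                               features, labels, seed = 42) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("classifier needs both positive and negative examples")
  features <- as.matrix(features)
  if (method == "logistic_regression") {
    dat <- as.data.frame(features)
    dat$.y <- labels
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = dat, family = stats::binomial()))
    score <- function(newf) {
      nd <- as.data.frame(as.matrix(newf))
      names(nd) <- colnames(features)
      as.numeric(suppressWarnings(
        stats::predict(fit, newdata = nd, type = "response")))
    }
  } else {
    dat <- as.data.frame(features)
    dat$.y <- factor(labels, levels = c(0, 1))
    fit <- ranger::ranger(.y ~ ., data = dat, probability = TRUE,
                          num.trees = 200, seed = seed,
                          respect.unordered.factors = TRUE)
    score <- function(newf) {
      nd <- as.data.frame(as.matrix(newf))
      names(nd) <- colnames(features)
      as.numeric(stats::predict(fit, data = nd)$predictions[, "1"])
    }
  }
  structure(list(method = method, fit = fit, score = score, seed = seed),
            class = "alt_classifier")
}

#' Assign ECs to a protein by majority vote
#'
#' An EC is assigned iff strictly more than half of the tools able to predict
#' it (per their predictive ranges) predicted it at high confidence.
#'
#' @param tool_predictions named list, tool -> character vector of
#'   high-confidence ECs predicted for the protein.
#' @param tool_ranges named list, tool -> predictive-range EC vector.
#' @return character vector of assigned ECs.
#' @export
majority_rule_assign <- function(tool_predictions, tool_ranges) {
  tool_predictions <- lapply(names(tool_predictions), function(t)
    intersect(tool_predictions[[t]], tool_ranges[[t]] %||% character()))
  names(tool_predictions) <- names(tool_ranges)[seq_along(tool_predictions)]
  all_ecs <- unique(unlist(tool_predictions))
  assigned <- vapply(all_ecs, function(ec) {
    able <- sum(vapply(tool_ranges, function(r) ec %in% r, logical(1)))
    votes <- sum(vapply(tool_predictions, function(p) ec %in% p, logical(1)))
    votes > able / 2
  }, logical(1))
  sort(all_ecs[assigned])
}

#' Assign ECs using the per-EC best-performing tool
#'
#' For each candidate EC, the tool(s) with the maximal training F1 for that EC
#' decide: the EC is assigned iff any tied-best tool predicted it at high
#' confidence. ECs absent from the performance table fall back to majority
#' rule with a warning.
#'
#' @param tool_predictions named list, tool -> high-confidence EC vector.
#' @param performance data.frame with columns `ec`, `tool`, `f1`.
#' @param tool_ranges named list for the majority fallback.
#' @return character vector of assigned ECs.
#' @export
best_tool_assign <- function(tool_predictions, performance, tool_ranges) {
  all_ecs <- unique(unlist(tool_predictions))
  out <- character()
  fallback <- character()
  for (ec in all_ecs) {
    perf <- performance[performance$ec == ec, , drop = FALSE]
    if (!nrow(perf)) { fallback <- c(fallback, ec); next }
    best <- perf$tool[perf$f1 >= max(perf$f1) - 1e-12]
    hit <- any(vapply(best, function(t)
      ec %in% (tool_predictions[[t]] %||% character()), logical(1)))
    if (hit) out <- c(out, ec)
  }
  if (length(fallback)) {
    warning("ECs absent from performance table fell back to majority rule: ",
            paste(fallback, collapse = ", "))
    sub <- lapply(tool_predictions, intersect, fallback)
    out <- c(out, majority_rule_assign(sub, tool_ranges))
  }
  sort(unique(out))
}

# ECs qualifying for the automatic assignment rule: every tool able to predict
# the EC predicted it at high confidence for at least one training protein,
# and no tool's high-confidence prediction of it was a false positive.
compute_auto_assign_ecs <- function(table, gold, profiles) {
  df <- as.data.frame(table)
  hc <- df[mapply(function(tool, lev) {
    p <- Filter(function(x) x$tool_name == tool, profiles)[[1]]
    lev == p$high_conf_bin
  }, df$tool, df$confidence_level), , drop = FALSE]
  gold_key <- paste(gold$protein_id, gold$ec)
  out <- character()
  for (ec in unique(hc$ec)) {
    able <- Filter(function(p) ec %in% p$predictive_range, profiles)
    if (!length(able)) next
    sub <- hc[hc$ec == ec, , drop = FALSE]
    predicted_by <- unique(sub$tool)
    if (!all(vapply(able, function(p) p$tool_name %in% predicted_by,
                    logical(1)))) next
    fp <- !(paste(sub$protein_id, sub$ec) %in% gold_key)
    if (!any(fp)) out <- c(out, ec)
  }
  sort(out)
}

#' Frequently co-occurring EC pairs from a gold standard
#'
#' Two ECs frequently co-occur when they are co-annotated on at least
#' `min_count` proteins and on at least `min_frac` of the proteins carrying
#' the first EC. Used by the optional multifunctional-protein filter.
#'
#' @param gold data.frame (`protein_id`, `ec`).
#' @param min_count minimum number of co-annotated proteins (default 10).
#' @param min_frac minimum fraction of the first EC's proteins (default 0.5).
#' @return named list, EC -> character vector of co-occurring ECs.
#' @export
build_cooccurrence <- function(gold, min_count = 10, min_frac = 0.5) {
  by_ec <- split(gold$protein_id, gold$ec)
  ecs <- names(by_ec)
  out <- list()
  for (a in ecs) {
    co <- character()
    for (b in setdiff(ecs, a)) {
      n <- length(intersect(by_ec[[a]], by_ec[[b]]))
      if (n >= min_count && n >= min_frac * length(by_ec[[a]])) co <- c(co, b)
    }
    if (length(co)) out[[a]] <- co
  }
  out
}

#' Train the full per-EC ensemble model
#'
#' Orchestrates training over all ECs with sufficient gold support
#' (`min_support`, default 10 sequences): builds per-EC training sets,
#' fits the chosen classifier per EC, derives the auto-assignment EC list
#' and the co-occurrence table, and records each tool's predictive range.
#' ECs whose training set is degenerate (no negatives, or no positives among
#' predicted proteins) get no classifier and are logged; they remain reachable
#' through the auto rule or the pass-through tool.
#'
#' @param table training `prediction_table`.
#' @param gold gold-standard data.frame (`protein_id`, `ec`).
#' @param profiles list of [tool_profile()]s.
#' @param method ensemble method.
#' @param passthrough_tool optional tool whose high-confidence predictions are
#'   accepted for ECs outside the trained range (broad-range profile tools).
#' @param min_support minimum gold sequences per trained EC.
#' @param alpha naive Bayes smoothing.
#' @param seed seed for stochastic fits.
#' @return object of class `ensemble_model`.
#' @export
train_ensemble <- function(table, gold, profiles,
                           method = c("naive_bayes", "logistic_regression",
                                      "random_forest", "majority_rule",
                                      "best_tool"),
                           passthrough_tool = NULL, min_support = 10,
                           alpha = 1, seed = 42) {
  method <- match.arg(method)
  support <- table(gold$ec)
  trainable <- names(support)[support >= min_support]
  encoding <- switch(method,
                     naive_bayes = "binary_high_conf",
                     logistic_regression = "one_hot_levels",
                     random_forest = "ordinal_levels",
                     "binary_high_conf")
  tool_ranges <- stats::setNames(lapply(profiles, `[[`, "predictive_range"),
                                 vapply(profiles, `[[`, "", "tool_name"))
  per_ec <- list()
  skipped <- character()
  if (method %in% c("naive_bayes", "logistic_regression", "random_forest")) {
    for (ec in trainable) {
      if (!any(vapply(profiles, function(p) ec %in% p$predictive_range,
                      logical(1)))) next
      sets <- tryCatch(build_training_sets(table, gold, ec),
                       training_degenerate = function(e) NULL)
      if (is.null(sets)) { skipped <- c(skipped, ec); next }
      prot <- c(sets$positives, sets$negatives)
      y <- c(rep(1L, length(sets$positives)), rep(0L, length(sets$negatives)))
      feats <- build_feature_matrix(table, ec, profiles, encoding,
                                    proteins = prot)
      per_ec[[ec]] <- if (method == "naive_bayes")
        fit_naive_bayes(feats, y, alpha = alpha, ec = ec)
      else fit_alt_classifier(method, feats, y, seed = seed)
    }
  }
  structure(list(
    method = method, per_ec_params = per_ec,
    auto_assign_ecs = compute_auto_assign_ecs(table, gold, profiles),
    cooccurrence = build_cooccurrence(gold),
    tool_ranges = tool_ranges, profiles = profiles, encoding = encoding,
    passthrough_tool = passthrough_tool, skipped_degenerate = skipped,
    seed = seed), class = "ensemble_model")
}

#' Score proteins with a trained ensemble model
#'
#' Produces a likelihood score per (protein, EC) for every trained EC. For the
#' voting methods (`majority_rule`, `best_tool`) scores are 0/1 assignments.
#'
#' @param model an `ensemble_model`.
#' @param table `prediction_table` of the proteins to score.
#' @param proteins optional subset of proteins.
#' @param performance optional per-(EC, tool) F1 table for `best_tool`.
#' @return data.frame `protein_id`, `ec`, `score`, `source`.
#' @export
score_proteins <- function(model, table, proteins = NULL, performance = NULL) {
  df <- as.data.frame(table)
  proteins <- proteins %||% sort(unique(df$protein_id))
  out <- list()
  if (model$method %in% c("naive_bayes", "logistic_regression",
                          "random_forest")) {
    for (ec in names(model$per_ec_params)) {
      # classifiers operate on predicted (protein, EC) pairs: the likelihood
      # score arbitrates among tool predictions, it does not conjure
      # annotations no tool made (training negatives are likewise drawn from
      # predicted proteins only)
      cand <- intersect(proteins, unique(df$protein_id[df$ec == ec]))
      if (!length(cand)) next
      feats <- build_feature_matrix(table, ec, model$profiles,
                                    model$encoding, proteins = cand)
      par <- model$per_ec_params[[ec]]
      s <- if (inherits(par, "nb_params")) nb_posterior(feats, par)
           else par$score(feats)
      out[[ec]] <- data.frame(protein_id = cand, ec = ec, score = s,
                              source = "classifier",
                              stringsAsFactors = FALSE)
    }
  } else {
    hc_sets <- high_conf_sets_by_protein(table, model$profiles)
    for (p in proteins) {
      sets <- hc_sets[[p]] %||% list()
      ecs <- if (model$method == "majority_rule")
        majority_rule_assign(sets, model$tool_ranges)
      else best_tool_assign(sets, performance %||%
                              data.frame(ec = character(), tool = character(),
                                         f1 = numeric()), model$tool_ranges)
      if (length(ecs))
        out[[p]] <- data.frame(protein_id = p, ec = ecs, score = 1,
                               source = "classifier", stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(protein_id = character(), ec = character(), score = numeric(),
               source = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# named list protein -> (named list tool -> high-confidence EC vector)
high_conf_sets_by_protein <- function(table, profiles) {
  df <- as.data.frame(table)
  hc_bin <- stats::setNames(vapply(profiles, `[[`, "", "high_conf_bin"),
                            vapply(profiles, `[[`, "", "tool_name"))
  df <- df[df$confidence_level == hc_bin[df$tool], , drop = FALSE]
  lapply(split(df, df$protein_id), function(sub)
    lapply(split(sub$ec, sub$tool), unique))
}

#' Select high-confidence annotations
#'
#' The high-confidence set is the union of: (i) classifier scores strictly
#' greater than `threshold` (default 0.5); (ii) auto-rule ECs predicted at
#' high confidence by any tool; (iii) the pass-through tool's high-confidence
#' predictions for ECs outside the trained classifier's range. Each selected
#' annotation carries its source tag. Idempotent.
#'
#' @param scored data.frame from [score_proteins()].
#' @param model an `ensemble_model`.
#' @param table the `prediction_table` (needed for the auto rule and
#'   pass-through).
#' @param threshold classifier score cutoff (strict inequality).
#' @return data.frame `protein_id`, `ec`, `score`, `source`.
#' @export
select_high_confidence <- function(scored, model, table, threshold = 0.5) {
  sel <- scored[scored$score > threshold, , drop = FALSE]
  sel$source <- "classifier"

  df <- as.data.frame(table)
  hc_bin <- stats::setNames(
    vapply(model$profiles, `[[`, "", "high_conf_bin"),
    vapply(model$profiles, `[[`, "", "tool_name"))
  hc <- df[df$confidence_level == hc_bin[df$tool], , drop = FALSE]

  auto <- hc[hc$ec %in% model$auto_assign_ecs, c("protein_id", "ec")]
  if (nrow(auto)) {
    auto <- unique(auto)
    auto$score <- NA_real_
    auto$source <- "auto_rule"
  }

  pt <- NULL
  if (!is.null(model$passthrough_tool)) {
    trained <- names(model$per_ec_params)
    pt <- hc[hc$tool == model$passthrough_tool & !(hc$ec %in% trained),
             c("protein_id", "ec"), drop = FALSE]
    if (nrow(pt)) {
      pt <- unique(pt)
      pt$score <- NA_real_
      pt$source <- "passthrough"
    }
  }

  out <- rbind(sel[, c("protein_id", "ec", "score", "source")],
               if (!is.null(auto) && nrow(auto)) auto,
               if (!is.null(pt) && nrow(pt)) pt)
  # precedence auto_rule > classifier > passthrough on duplicates
  pref <- c(auto_rule = 1L, classifier = 2L, passthrough = 3L)
  out <- out[order(out$protein_id, out$ec, pref[out$source]), , drop = FALSE]
  out <- out[!duplicated(paste(out$protein_id, out$ec)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter a multifunctional protein's ECs to the top-scoring set
#'
#' Retains the top-scoring EC(s) (ties all kept) plus any EC frequently
#' co-occurring with a retained top EC in the training data. Off by default in
#' the pipeline; evaluation considers all high-confidence ECs unless enabled.
#'
#' @param scored_ecs data.frame `ec`, `score` for a single protein.
#' @param cooccurrence named list from [build_cooccurrence()].
#' @return character vector of retained ECs.
#' @export
multifunctional_filter <- function(scored_ecs, cooccurrence = list()) {
  stopifnot(nrow(scored_ecs) >= 1)
  top <- scored_ecs$ec[scored_ecs$score >= max(scored_ecs$score) - 1e-12]
  keep <- unique(c(top, unlist(cooccurrence[top])))
  sort(intersect(scored_ecs$ec, keep))
}
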