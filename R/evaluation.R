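#' Per-EC confusion counts
#'
#' @param predictions data.frame (`protein_id`, `ec`) of predicted
#'   annotations.
#' @param gold data.frame (`protein_id`, `ec`) of true annotations.
#' @param ec_universe ECs over which counts are tallied; defaults to the
#'   union of predicted and gold ECs.
#' @return data.frame `ec`, `tp`, `fp`, `fn`.
#' @export
confusion_counts <- function(predictions, gold, ec_universe = NULL) {
  ec_universe <- ec_universe %||% sort(unique(c(predictions$ec, gold$ec)))
  do.call(rbind, lapply(ec_universe, function(ec) {
    p <- unique(predictions$protein_id[predictions$ec == ec])
    g <- unique(gold$protein_id[gold$ec == ec])
    data.frame(ec = ec, tp = length(intersect(p, g)),
               fp = length(setdiff(p, g)), fn = length(setdiff(g, p)),
               stringsAsFactors = FALSE)
  }))
}

#' Macro-averaged precision, recall and F1
#'
#' Per-EC precision and recall are averaged unweighted over EC classes, so
#' small classes count as much as large ones. ECs with no predictions have
#' undefined precision and are excluded from the precision mean (the exclusion
#' count is reported); ECs with no gold support are likewise excluded from the
#' recall mean. Macro F1 is the mean of per-class F1 = 2TP/(2TP+FP+FN)
#' (classes with any counts); the harmonic mean of macro precision and recall
#' is also reported for transparency.
#'
#' @inheritParams confusion_counts
#' @return list `macro_precision`, `macro_recall`, `macro_f1`,
#'   `macro_f1_harmonic`, `n_ec_precision_undefined`, `per_ec` (counts).
#' @export
macro_metrics <- function(predictions, gold, ec_universe = NULL) {
  if (!nrow(gold)) stop("empty gold standard")
  cc <- confusion_counts(predictions, gold, ec_universe)
  prec <- ifelse(cc$tp + cc$fp > 0, cc$tp / (cc$tp + cc$fp), NA_real_)
  rec <- ifelse(cc$tp + cc$fn > 0, cc$tp / (cc$tp + cc$fn), NA_real_)
  f1 <- ifelse(cc$tp + cc$fp + cc$fn > 0,
               2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn), NA_real_)
  mp <- mean(prec, na.rm = TRUE)
  mr <- mean(rec, na.rm = TRUE)
  list(macro_precision = mp, macro_recall = mr,
       macro_f1 = mean(f1, na.rm = TRUE),
       macro_f1_harmonic = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0,
       n_ec_precision_undefined = sum(is.na(prec)),
       per_ec = cbind(cc, precision = prec, recall = rec, f1 = f1))
}

#' Micro-averaged precision and recall
#'
#' Pools TP/FP/FN over all (protein, EC) pairs irrespective of class size.
#'
#' @inheritParams confusion_counts
#' @return list `precision` (NA when nothing is predicted), `recall`,
#'   `tp`, `fp`, `fn`.
#' @export
micro_metrics <- function(predictions, gold) {
  pk <- unique(paste(predictions$protein_id, predictions$ec))
  gk <- unique(paste(gold$protein_id, gold$ec))
  tp <- length(intersect(pk, gk))
  fp <- length(setdiff(pk, gk))
  fn <- length(setdiff(gk, pk))
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       tp = tp, fp = fp, fn = fn)
}

#' Specificity on a non-enzyme protein set
#'
#' Fraction of known non-enzymatic proteins receiving zero high-confidence EC
#' predictions.
#'
#' @param predictions data.frame (`protein_id`, `ec`).
#' @param non_enzyme_proteins character vector of non-enzyme protein ids.
#' @return numeric specificity in [0, 1].
#' @export
specificity_non_enzymes <- function(predictions, non_enzyme_proteins) {
  if (!length(non_enzyme_proteins)) stop("empty non-enzyme set")
  flagged <- unique(predictions$protein_id)
  mean(!(non_enzyme_proteins %in% flagged))
}

#' Stratified k-fold split preserving EC coverage
#'
#' Partitions proteins into k test folds so that every EC keeps at least one
#' training example in every fold. Multifunctional proteins appear in exactly
#' one fold; assignment is greedy, processing ECs from rarest to most common
#' and spreading each EC's unassigned proteins round-robin over the currently
#' least-loaded folds (coverage-preserving approximation of published
#' multifunctional-split protocols).
#'
#' @param gold data.frame (`protein_id`, `ec`).
#' @param k number of folds.
#' @param seed RNG seed; identical seeds give identical partitions.
#' @return list of k character vectors (test proteins per fold), with
#'   attribute `fold_of` (named fold index per protein).
#' @export
kfold_split <- function(gold, k = 5, seed = 42) {
  support <- table(gold$ec)
  if (any(support < k))
    stop("ECs with fewer than k proteins cannot keep coverage in every fold: ",
         paste(names(support)[support < k], collapse = ", "))
  with_seed(seed, {
    fold_of <- integer(0)
    per_ec_fold <- matrix(0L, nrow = length(support), ncol = k,
                          dimnames = list(names(support), NULL))
    for (ec in names(sort(support))) {
      prots <- unique(gold$protein_id[gold$ec == ec])
      # already-assigned multifunctional proteins contribute their fold
      done <- prots[prots %in% names(fold_of)]
      for (p in done) per_ec_fold[ec, fold_of[[p]]] <-
          per_ec_fold[ec, fold_of[[p]]] + 1L
      todo <- sample(setdiff(prots, done))
      for (p in todo) {
        f <- which.min(per_ec_fold[ec, ] + stats::runif(k, 0, 0.1))
        fold_of[[p]] <- f
        # update counts for every EC this protein carries
        for (e2 in gold$ec[gold$protein_id == p])
          per_ec_fold[e2, f] <- per_ec_fold[e2, f] + 1L
      }
    }
    # audit: every EC has >=1 training example in every fold
    for (ec in names(support)) {
      n_ec <- sum(per_ec_fold[ec, ])
      if (any(per_ec_fold[ec, ] == n_ec))
        stop("fold assignment failed to preserve training coverage for ", ec)
    }
    folds <- lapply(seq_len(k), function(f) sort(names(fold_of)[unlist(fold_of) == f]))
    attr(folds, "fold_of") <- fold_of
    folds
  })
}

#' Per-(EC, tool) F1 on a training prediction table
#'
#' Training-fold performance table consumed by the best-tool ensemble rule:
#' for each EC and tool, F1 of the tool's high-confidence predictions of that
#' EC against the gold standard.
#'
#' @param table `prediction_table` (training portion).
#' @param gold gold-standard data.frame.
#' @param profiles list of [tool_profile()]s.
#' @return data.frame `ec`, `tool`, `f1`.
#' @export
tool_performance_table <- function(table, gold, profiles) {
  df <- as.data.frame(table)
  out <- list()
  for (p in profiles) {
    sub <- df[df$tool == p$tool_name &
                df$confidence_level == p$high_conf_bin, , drop = FALSE]
    for (ec in intersect(unique(gold$ec), p$predictive_range)) {
      pred <- unique(sub$protein_id[sub$ec == ec])
      pos <- unique(gold$protein_id[gold$ec == ec])
      tp <- length(intersect(pred, pos))
      fp <- length(setdiff(pred, pos))
      fn <- length(setdiff(pos, pred))
      out[[length(out) + 1L]] <- data.frame(
        ec = ec, tool = p$tool_name,
        f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out) %||%
    data.frame(ec = character(), tool = character(), f1 = numeric())
}
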