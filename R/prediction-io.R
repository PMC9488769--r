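#' Describe an upstream EC-annotation tool
#'
#' A tool profile records how an upstream enzyme-annotation tool scores its
#' predictions: the kind of raw score it emits, how raw scores are discretized
#' into ordered confidence bins, which bin counts as "high-confidence", and the
#' tool's predictive range (the set of EC numbers it is able to emit at all).
#' Confidence binning is configuration, not code: different tools publish
#' different cutoffs.
#'
#' @param tool_name identifier of the tool.
#' @param score_kind one of `"probability"`, `"likelihood"`, `"bitscore_like"`,
#'   `"binary"`. Binary tools emit no raw score; every prediction they make is
#'   placed in their high-confidence bin.
#' @param bins data.frame with columns `label`, `lower`, `upper` describing
#'   ordered, disjoint half-open intervals `(lower, upper]` that partition the
#'   tool's score domain. Ignored (a single high bin is created) for binary
#'   tools.
#' @param high_conf_bin label of the bin treated as high-confidence.
#' @param predictive_range character vector of complete EC numbers the tool
#'   can emit.
#' @return object of class `tool_profile`.
#' @export
#' @examples
#' tool_profile("toolA", "probability",
#'              bins = data.frame(label = c("low", "high"),
#'                                lower = c(0, 0.5), upper = c(0.5, 1)),
#'              high_conf_bin = "high",
#'              predictive_range = c("1.1.1.1", "2.7.1.1"))
tool_profile <- function(tool_name, score_kind = c("probability", "likelihood",
                                                   "bitscore_like", "binary"),
                         bins = NULL, high_conf_bin = "high",
                         predictive_range = character()) {
  score_kind <- match.arg(score_kind)
  if (score_kind == "binary") {
    bins <- data.frame(label = high_conf_bin, lower = -Inf, upper = Inf,
                       stringsAsFactors = FALSE)
  }
  if (is.null(bins)) stop("bins required for non-binary tools")
  bins <- as.data.frame(bins)
  stopifnot(all(c("label", "lower", "upper") %in% names(bins)),
            nrow(bins) >= 1)
  o <- order(bins$lower)
  bins <- bins[o, , drop = FALSE]
  if (any(bins$lower >= bins$upper))
    stop("each confidence bin must satisfy lower < upper")
  if (nrow(bins) > 1 &&
      any(abs(bins$lower[-1] - bins$upper[-nrow(bins)]) > 1e-12))
    stop("confidence bins must be contiguous and disjoint")
  if (!high_conf_bin %in% bins$label)
    stop("high_conf_bin must be one of the bin labels")
  bad <- predictive_range[!is_complete_ec(predictive_range)]
  if (length(bad))
    stop("predictive_range contains incomplete EC numbers: ",
         paste(bad, collapse = ", "))
  structure(list(tool_name = tool_name, score_kind = score_kind, bins = bins,
                 high_conf_bin = high_conf_bin,
                 predictive_range = unique(predictive_range)),
            class = "tool_profile")
}

#' Map raw scores to confidence-bin labels
#'
#' Each raw score falls in exactly one of the profile's half-open bins
#' `(lower, upper]`; scores on the lowest bin's lower edge are included there.
#'
#' @param scores numeric raw scores.
#' @param profile a [tool_profile()].
#' @return character vector of bin labels; NA where the score lies outside
#'   the declared domain.
#' @export
confidence_level <- function(scores, profile) {
  bins <- profile$bins
  out <- rep(NA_character_, length(scores))
  for (i in seq_len(nrow(bins))) {
    lo <- bins$lower[i]; hi <- bins$upper[i]
    hit <- if (i == 1) scores >= lo & scores <= hi else scores > lo & scores <= hi
    out[hit & is.na(out)] <- bins$label[i]
  }
  out
}

new_prediction_table <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("protein_id", "ec", "tool", "raw_score", "confidence_level")
  stopifnot(all(need %in% names(records)))
  records <- records[, need]
  rownames(records) <- NULL
  structure(records, class = c("prediction_table", "data.frame"))
}

#' Combine prediction tables, collapsing duplicates
#'
#' At most one record per (protein, EC, tool) is kept; among duplicates the
#' record with the maximal raw score wins (idempotent merging), with a warning.
#'
#' @param ... prediction tables or compatible data.frames.
#' @return a `prediction_table`.
#' @export
merge_prediction_tables <- function(...) {
  recs <- do.call(rbind, lapply(list(...), as.data.frame))
  key <- paste(recs$protein_id, recs$ec, recs$tool, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (protein, ec, tool) rows collapsed keeping max raw_score")
    o <- order(key, -ifelse(is.na(recs$raw_score), -Inf, recs$raw_score))
    recs <- recs[o, ][!duplicated(key[o]), ]
  }
  new_prediction_table(recs[order(recs$protein_id, recs$ec, recs$tool), ])
}

#' Read one tool's EC predictions from TSV
#'
#' Expects a UTF-8 TSV with a header row and columns `protein_id`, `ec` and
#' (except for binary tools) `raw_score`. Rows whose EC number is incomplete
#' (fewer than four numeric fields) are dropped and counted. Each retained row
#' is assigned a confidence level from the profile's bins; binary tools'
#' predictions are all placed in the high-confidence bin.
#'
#' @param path TSV file path.
#' @param profile the [tool_profile()] of the emitting tool.
#' @return a `prediction_table` with attribute `summary`, a list with
#'   `n_dropped_partial` (incomplete-EC rows removed) and `n_records`.
#' @export
read_tool_predictions <- function(path, profile) {
  if (!file.exists(path)) stop("cannot read prediction file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("protein_id", "ec") %in% names(raw)))
    stop("prediction TSV must have columns protein_id and ec: ", path)
  complete <- is_complete_ec(raw$ec)
  n_dropped <- sum(!complete)
  raw <- raw[complete, , drop = FALSE]
  if (profile$score_kind == "binary" || !"raw_score" %in% names(raw)) {
    score <- rep(NA_real_, nrow(raw))
    level <- rep(profile$high_conf_bin, nrow(raw))
  } else {
    score <- as.numeric(raw$raw_score)
    level <- confidence_level(score, profile)
    if (anyNA(level)) {
      bad <- which(is.na(level))[1]
      stop(sprintf(
        "raw score %s outside declared domain of tool '%s' (row %d of %s)",
        format(score[bad]), profile$tool_name, bad, path))
    }
  }
  recs <- data.frame(protein_id = raw$protein_id, ec = raw$ec,
                     tool = profile$tool_name, raw_score = score,
                     confidence_level = level, stringsAsFactors = FALSE)
  tab <- merge_prediction_tables(recs)
  attr(tab, "summary") <- list(n_dropped_partial = n_dropped,
                               n_records = nrow(tab))
  tab
}

#' Write a prediction table to TSV
#'
#' Inverse of [read_tool_predictions()] modulo the tool column: all five
#' canonical columns are written so re-reading yields the identical record set.
#'
#' @param table a `prediction_table`.
#' @param path output path.
#' @export
write_prediction_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gold-standard protein-to-EC table
#'
#' TSV with header and columns `protein_id`, `ec`, one row per annotation.
#' Incomplete EC numbers are dropped with a message.
#'
#' @param path TSV path.
#' @return data.frame with columns `protein_id`, `ec`.
#' @export
read_gold_standard <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(all(c("protein_id", "ec") %in% names(g)))
  keep <- is_complete_ec(g$ec)
  if (any(!keep)) message(sum(!keep), " incomplete EC rows dropped from gold standard")
  unique(g[keep, c("protein_id", "ec")])
}

#' Build a per-EC feature matrix from tool predictions
#'
#' For one EC, rows are proteins and columns encode what each tool able to
#' predict that EC said about it. Three encodings are supported:
#' \describe{
#'   \item{binary_high_conf}{one column per predicting tool; 1 iff the tool
#'     predicted the EC in its high-confidence bin (the Bernoulli feature
#'     vector of the naive Bayes classifier, length k = number of tools able
#'     to predict the EC).}
#'   \item{one_hot_levels}{one 0/1 column per (tool, bin); at most one 1 per
#'     tool block (logistic-regression encoding).}
#'   \item{ordinal_levels}{one integer column per tool: 0 for no prediction,
#'     otherwise the 1-based index of the confidence bin (random-forest
#'     encoding).}
#' }
#' Proteins without any prediction of the EC by a tool get that tool's
#' all-zero / level-0 encoding.
#'
#' @param table a `prediction_table`.
#' @param ec a complete EC number.
#' @param profiles list of [tool_profile()]s.
#' @param encoding one of `"binary_high_conf"`, `"one_hot_levels"`,
#'   `"ordinal_levels"`.
#' @param proteins optional character vector of row proteins; defaults to all
#'   proteins in `table`.
#' @return numeric matrix with proteins as rownames.
#' @export
build_feature_matrix <- function(table, ec, profiles,
                                 encoding = c("binary_high_conf",
                                              "one_hot_levels",
                                              "ordinal_levels"),
                                 proteins = NULL) {
  encoding <- match.arg(encoding)
  able <- Filter(function(p) ec %in% p$predictive_range, profiles)
  if (!length(able))
    stop("EC ", ec, " is outside every tool's predictive range")
  proteins <- proteins %||% sort(unique(table$protein_id))
  df <- as.data.frame(table)
  df <- df[df$ec == ec & df$protein_id %in% proteins, , drop = FALSE]

  cols <- list()
  for (p in able) {
    sub <- df[df$tool == p$tool_name, , drop = FALSE]
    lev <- sub$confidence_level[match(proteins, sub$protein_id)]
    if (encoding == "binary_high_conf") {
      v <- as.numeric(!is.na(lev) & lev == p$high_conf_bin)
      cols[[p$tool_name]] <- v
    } else if (encoding == "ordinal_levels") {
      v <- match(lev, p$bins$label)
      v[is.na(v)] <- 0L
      cols[[p$tool_name]] <- as.numeric(v)
    } else {
      for (b in p$bins$label) {
        cols[[paste(p$tool_name, b, sep = ".")]] <-
          as.numeric(!is.na(lev) & lev == b)
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- proteins
  m
}
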