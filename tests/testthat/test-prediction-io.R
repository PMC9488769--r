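test_that("scores are binned into confidence levels and partial ECs dropped", {
  prof <- two_bin_profile("toolA", c("1.1.1.1", "2.7.1.1"))
  path <- write_pred_tsv(data.frame(
    protein_id = c("p1", "p1", "p2"),
    ec = c("1.1.1.1", "1.1.1.-", "2.7.1.1"),
    raw_score = c(0.92, 0.9, 0.3)))
  tab <- read_tool_predictions(path, prof)
  expect_equal(attr(tab, "summary")$n_dropped_partial, 1)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$confidence_level[tab$protein_id == "p1"], "high")
  expect_equal(tab$confidence_level[tab$protein_id == "p2"], "low")
})

test_that("binary tools get the high-confidence bin and no score", {
  prof <- tool_profile("catlike", "binary", high_conf_bin = "high",
                       predictive_range = "2.7.1.1")
  path <- write_pred_tsv(data.frame(protein_id = "p2", ec = "2.7.1.1"))
  tab <- read_tool_predictions(path, prof)
  expect_equal(tab$confidence_level, "high")
  expect_true(is.na(tab$raw_score))
})

test_that("out-of-domain scores raise a validation error naming the row", {
  prof <- two_bin_profile("toolA", "1.1.1.1")
  path <- write_pred_tsv(data.frame(protein_id = "p1", ec = "1.1.1.1",
                                    raw_score = 1.5))
  expect_error(read_tool_predictions(path, prof), "outside declared domain")
})

test_that("duplicate (protein, ec, tool) rows keep the max score with warning", {
  prof <- two_bin_profile("toolA", "1.1.1.1")
  path <- write_pred_tsv(data.frame(
    protein_id = c("p1", "p1"), ec = "1.1.1.1", raw_score = c(0.4, 0.8)))
  expect_warning(tab <- read_tool_predictions(path, prof), "duplicate")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$raw_score, 0.8)
})

test_that("prediction tables round-trip through TSV", {
  syn <- synth_predictions(30, c("1.1.1.1", "2.7.1.1"),
                           list(toolA = list(sensitivity = 0.8, fpr = 0.1)),
                           seed = 11)
  path <- tempfile(fileext = ".tsv")
  write_prediction_table(syn$table, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  orig <- as.data.frame(syn$table)
  rownames(orig) <- NULL
  expect_equal(back, orig, tolerance = 1e-12)
})

test_that("every raw score maps to exactly one confidence bin", {
  prof <- tool_profile("t3", "probability",
                       bins = data.frame(label = c("lo", "mid", "hi"),
                                         lower = c(0, 0.3, 0.7),
                                         upper = c(0.3, 0.7, 1)),
                       high_conf_bin = "hi", predictive_range = "1.1.1.1")
  set.seed(5)
  s <- runif(1000)
  lev <- confidence_level(s, prof)
  expect_false(anyNA(lev))
  counts <- vapply(s, function(x) {
    sum(vapply(seq_len(3), function(i) {
      lo <- prof$bins$lower[i]; hi <- prof$bins$upper[i]
      if (i == 1) x >= lo && x <= hi else x > lo && x <= hi
    }, logical(1)))
  }, 0L)
  expect_true(all(counts == 1))
})

test_that("binary encoding has one column per tool able to predict the EC", {
  profs <- list(two_bin_profile("A", c("1.1.1.1", "2.7.1.1")),
                two_bin_profile("B", "1.1.1.1"),
                two_bin_profile("C", "2.7.1.1"))
  tab <- merge_prediction_tables(data.frame(
    protein_id = "p1", ec = "1.1.1.1", tool = "A", raw_score = 0.9,
    confidence_level = "high"))
  f <- build_feature_matrix(tab, "1.1.1.1", profs, "binary_high_conf",
                            proteins = c("p1", "p2"))
  expect_equal(dim(f), c(2, 2))          # k = 2 tools can predict 1.1.1.1
  expect_equal(unname(f["p1", ]), c(1, 0))
  expect_equal(unname(f["p2", ]), c(0, 0))  # no prediction -> all-zero row
  expect_error(build_feature_matrix(tab, "9.9.9.9", profs),
               "outside every tool")
})

test_that("one-hot and ordinal encodings place predictions correctly", {
  prof3 <- function(nm) tool_profile(
    nm, "probability",
    bins = data.frame(label = c("lo", "mid", "hi"),
                      lower = c(0, 0.3, 0.7), upper = c(0.3, 0.7, 1)),
    high_conf_bin = "hi", predictive_range = "1.1.1.1")
  profs <- list(prof3("A"), prof3("B"))
  tab <- merge_prediction_tables(data.frame(
    protein_id = "p1", ec = "1.1.1.1", tool = "A", raw_score = 0.9,
    confidence_level = "hi"))
  oh <- build_feature_matrix(tab, "1.1.1.1", profs, "one_hot_levels",
                             proteins = "p1")
  expect_equal(ncol(oh), 6)
  expect_equal(sum(oh[1, 1:3]), 1)      # exactly one 1 in tool A's block
  expect_equal(unname(oh[1, "A.hi"]), 1)
  expect_equal(sum(oh[1, 4:6]), 0)      # tool B block all zero
  ord <- build_feature_matrix(tab, "1.1.1.1", profs, "ordinal_levels",
                              proteins = "p1")
  expect_equal(unname(ord[1, ]), c(3, 0))
})
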