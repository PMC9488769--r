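# Shared fixtures built in code.

two_bin_profile <- function(name, range) {
  tool_profile(name, "probability",
               bins = data.frame(label = c("low", "high"),
                                 lower = c(0, 0.5), upper = c(0.5, 1)),
               high_conf_bin = "high", predictive_range = range)
}

write_pred_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_db_json <- function(path = tempfile(fileext = ".json")) {
  doc <- list(
    dialect = "kegg_like",
    reactions = list(
      list(id = "R1", equation = "a -> b", ecs = list("1.1.1.1"),
           spontaneous = FALSE),
      list(id = "R2", equation = "b -> c", ecs = list("1.1.1.1", "2.7.1.1"),
           spontaneous = FALSE),
      list(id = "R3", equation = "2 c <=> d", ecs = list("3.5.1.2"),
           spontaneous = TRUE)),
    non_ec_sequence_index = list(R3 = list("refprotX")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  path
}

# Tiny draft model: uptake -> a, biomass drains b; conversion a -> b missing
# unless include_conv = TRUE.
toy_model <- function(include_conv = TRUE) {
  m <- metabolic_model("toy")
  m <- add_reaction(m, "EX_a", c(a = -1), -1, 1000, provenance = "exchange")
  if (include_conv)
    m <- add_reaction(m, "CONV", c(a = -1, b = 1), 0, 1000,
                      genes = "g1", ecs = "1.1.1.1",
                      provenance = "ec_high_conf")
  m <- add_reaction(m, "BIOMASS", c(b = -1), 0, 1000, provenance = "user")
  set_objective(m, "BIOMASS")
}
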