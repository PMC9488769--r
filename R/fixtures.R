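#' Generate synthetic tool predictions with a gold standard
#'
#' Emulates a panel of upstream EC-annotation tools over a synthetic
#' proteome. Each protein receives one true EC (two, for the multifunctional
#' fraction); each tool predicts each true EC within its predictive range
#' with probability `sensitivity` and each false EC with probability `fpr`.
#' Raw scores for true predictions are drawn uniformly from the high bin
#' (0.5, 1]; false-prediction scores uniformly from the full (0, 1] range, so
#' true predictions skew high. Tools use a two-bin (low/high at 0.5)
#' probability profile. Pure function of its arguments and the seed.
#'
#' @param n_proteins number of proteins.
#' @param ec_classes character vector of EC numbers in the gold universe.
#' @param tool_specs named list, tool -> list(sensitivity, fpr, optional
#'   `range` restricting the tool's predictive range).
#' @param multifunctional_rate fraction of proteins carrying a second EC.
#' @param seed RNG seed.
#' @return list `table` (a `prediction_table`), `gold` (data.frame),
#'   `profiles` (list of [tool_profile()]).
#' @export
synth_predictions <- function(n_proteins, ec_classes, tool_specs,
                              multifunctional_rate = 0.1, seed = 42) {
  stopifnot(n_proteins >= 1, length(ec_classes) >= 1)
  for (ts in tool_specs)
    stopifnot(ts$sensitivity >= 0, ts$sensitivity <= 1,
              ts$fpr >= 0, ts$fpr <= 1)
  with_seed(seed, {
    proteins <- sprintf("prot%04d", seq_len(n_proteins))
    # balanced class assignment, then shuffled
    primary <- sample(rep_len(ec_classes, n_proteins))
    gold <- data.frame(protein_id = proteins, ec = primary,
                       stringsAsFactors = FALSE)
    multi <- proteins[stats::runif(n_proteins) < multifunctional_rate]
    if (length(multi)) {
      second <- vapply(match(multi, proteins), function(i) {
        pool <- setdiff(ec_classes, primary[i])
        if (length(pool)) sample(pool, 1) else primary[i]
      }, "")
      gold <- rbind(gold, data.frame(protein_id = multi, ec = second,
                                     stringsAsFactors = FALSE))
    }
    gold <- unique(gold[order(gold$protein_id, gold$ec), ])
    rownames(gold) <- NULL

    support <- table(gold$ec)
    if (any(support < 10))
      warning("EC classes with fewer than 10 proteins will be excluded ",
              "from training: ", paste(names(support)[support < 10],
                                       collapse = ", "))

    profiles <- list()
    recs <- list()
    bins <- data.frame(label = c("low", "high"), lower = c(0, 0.5),
                       upper = c(0.5, 1))
    gold_by_prot <- split(gold$ec, gold$protein_id)
    for (tool in names(tool_specs)) {
      ts <- tool_specs[[tool]]
      range <- ts$range %||% ec_classes
      profiles[[tool]] <- tool_profile(tool, "probability", bins = bins,
                                       high_conf_bin = "high",
                                       predictive_range = range)
      for (p in proteins) {
        true_ecs <- intersect(gold_by_prot[[p]], range)
        hit <- true_ecs[stats::runif(length(true_ecs)) < ts$sensitivity]
        false_ecs <- setdiff(range, gold_by_prot[[p]])
        fp <- false_ecs[stats::runif(length(false_ecs)) < ts$fpr]
        if (length(hit))
          recs[[length(recs) + 1L]] <- data.frame(
            protein_id = p, ec = hit, tool = tool,
            raw_score = stats::runif(length(hit), 0.5, 1),
            stringsAsFactors = FALSE)
        if (length(fp))
          recs[[length(recs) + 1L]] <- data.frame(
            protein_id = p, ec = fp, tool = tool,
            raw_score = stats::runif(length(fp), 0, 1),
            stringsAsFactors = FALSE)
      }
    }
    recs <- do.call(rbind, recs) %||%
      data.frame(protein_id = character(), ec = character(),
                 tool = character(), raw_score = numeric())
    recs$raw_score <- pmax(recs$raw_score, 1e-12)  # keep inside (0, 1]
    recs$confidence_level <- ifelse(recs$raw_score > 0.5, "high", "low")
    list(table = merge_prediction_tables(recs), gold = gold,
         profiles = unname(profiles))
  })
}

#' Generate a toy metabolic network, database and known gap-fill answer
#'
#' Four network archetypes exercising the reconstruction and simulation
#' stages:
#' \describe{
#'   \item{chain}{a linear pathway EX -> m1 -> ... -> biomass whose FBA
#'     optimum equals the uptake bound.}
#'   \item{parallel}{two redundant routes to biomass (knockouts of one route
#'     are non-essential).}
#'   \item{gapped}{a chain with interior reactions withheld from the draft
#'     model but present in the database together with decoy reactions; the
#'     withheld reactions are the unique minimum-penalty repair, recorded in
#'     `known_optimal_gapfill`. Scored annotations are emitted so the
#'     withheld reactions are low-confidence candidates (score 0.4) and
#'     decoys weaker (score 0.1).}
#'   \item{energy_cycle}{a chain plus a two-reaction loop that regenerates
#'     ATP from nothing, so the zero-substrate yield control is positive
#'     (the energy-cycle sentinel fires).}
#' }
#'
#' @param spec one of `"chain"`, `"parallel"`, `"gapped"`, `"energy_cycle"`.
#' @param size chain length (>= 2); for `gapped`, also controls how many
#'   decoys are added.
#' @param seed RNG seed (used by `gapped` to pick gap positions and scores).
#' @param uptake_bound maximum substrate uptake (default 1).
#' @return list `model` (draft `metabolic_model`), `db` (`reaction_db`),
#'   `scored` (data.frame of EC scores, possibly empty),
#'   `known_optimal_gapfill` (character vector).
#' @export
synth_network <- function(spec = c("chain", "parallel", "gapped",
                                   "energy_cycle"),
                          size = 4, seed = 42, uptake_bound = 1) {
  spec <- match.arg(spec)
  stopifnot(size >= 2)
  with_seed(seed, {
    mets <- paste0("m", seq_len(size))
    chain_rxns <- list()
    chain_rxns[["EX_m1"]] <- list(
      id = "EX_m1", equation = "m1 ->", bounds = c(-uptake_bound, 1000),
      ecs = character(), spontaneous = FALSE)
    for (i in seq_len(size - 1)) {
      id <- sprintf("R%02d", i)
      chain_rxns[[id]] <- list(
        id = id, equation = paste(mets[i], "->", mets[i + 1]),
        bounds = NULL, ecs = sprintf("%d.1.1.%d", (i %% 6) + 1, i),
        spontaneous = FALSE)
    }
    biomass_eq <- paste(mets[size], "->")
    mk_db <- function(rxns, dialect = "kegg_like") {
      entries <- lapply(rxns, function(r) {
        eq <- parse_equation(r$equation)
        new_reaction(r$id, eq$stoichiometry, eq$reversible, ecs = r$ecs,
                     spontaneous = r$spontaneous, bounds = r$bounds)
      })
      db <- structure(list(reactions = entries,
                           ec_index = build_ec_index(entries),
                           dialect = dialect,
                           non_ec_sequence_index = list()),
                      class = "reaction_db")
      db
    }
    build_model <- function(rxn_ids, db, genes = list()) {
      m <- metabolic_model(paste0("synth_", spec))
      for (rid in rxn_ids) {
        r <- db$reactions[[rid]]
        m <- add_reaction(m, rid, r$stoichiometry, r$bounds[1], r$bounds[2],
                          genes = genes[[rid]] %||% character(),
                          ecs = r$ecs,
                          provenance = if (rid == "EX_m1") "exchange"
                                       else "ec_high_conf")
      }
      m <- add_reaction(m, "BIOMASS", parse_equation(biomass_eq)$stoichiometry,
                        0, 1000, provenance = "user", name = "BIOMASS")
      set_objective(m, "BIOMASS")
    }

    if (spec == "chain") {
      db <- mk_db(chain_rxns)
      genes <- stats::setNames(
        lapply(seq_len(size - 1), function(i) sprintf("g%02d", i)),
        sprintf("R%02d", seq_len(size - 1)))
      model <- build_model(names(chain_rxns), db, genes)
      return(list(model = model, db = db,
                  scored = data.frame(protein_id = character(),
                                      ec = character(), score = numeric()),
                  known_optimal_gapfill = character()))
    }

    if (spec == "parallel") {
      rxns <- chain_rxns
      mid <- paste0("p", seq_len(size))
      rxns[["ALT1"]] <- list(id = "ALT1", equation = paste("m1 ->", mid[1]),
                             bounds = NULL, ecs = "9.9.9.1",
                             spontaneous = FALSE)
      rxns[["ALT2"]] <- list(id = "ALT2",
                             equation = paste(mid[1], "->", mets[size]),
                             bounds = NULL, ecs = "9.9.9.2",
                             spontaneous = FALSE)
      db <- mk_db(rxns)
      genes <- c(stats::setNames(
        lapply(seq_len(size - 1), function(i) sprintf("g%02d", i)),
        sprintf("R%02d", seq_len(size - 1))),
        list(ALT1 = "gA1", ALT2 = "gA2"))
      model <- build_model(names(rxns), db, genes)
      return(list(model = model, db = db,
                  scored = data.frame(protein_id = character(),
                                      ec = character(), score = numeric()),
                  known_optimal_gapfill = character()))
    }

    if (spec == "energy_cycle") {
      rxns <- chain_rxns
      # loop regenerating atp with no input: x -> y + atp ; y -> x
      rxns[["CYC1"]] <- list(id = "CYC1", equation = "x -> y + atp",
                             bounds = NULL, ecs = character(),
                             spontaneous = FALSE)
      rxns[["CYC2"]] <- list(id = "CYC2", equation = "y -> x",
                             bounds = NULL, ecs = character(),
                             spontaneous = FALSE)
      rxns[["SEED_X"]] <- list(id = "SEED_X", equation = "x <=>",
                               bounds = c(-0.001, 0.001), ecs = character(),
                               spontaneous = FALSE)
      rxns[["ATPH"]] <- list(id = "ATPH", equation = "atp ->",
                             bounds = NULL, ecs = character(),
                             spontaneous = FALSE)
      db <- mk_db(rxns)
      model <- build_model(names(rxns), db)
      return(list(model = model, db = db,
                  scored = data.frame(protein_id = character(),
                                      ec = character(), score = numeric()),
                  known_optimal_gapfill = character()))
    }

    # gapped: withhold interior chain reactions, add decoys to the db
    interior <- sprintf("R%02d", seq_len(size - 1))
    n_gaps <- min(2, size - 2)
    gaps <- sort(sample(interior[-1], n_gaps))  # keep R01 so m1 is consumed
    rxns <- chain_rxns
    n_decoys <- max(2, min(4, size))
    for (d in seq_len(n_decoys)) {
      id <- sprintf("DEC%02d", d)
      # decoys consume a chain metabolite into a dead-end product
      src <- sample(mets[-size], 1)
      rxns[[id]] <- list(id = id,
                         equation = paste(src, "->", paste0("waste", d)),
                         bounds = NULL, ecs = sprintf("8.8.%d.1", d),
                         spontaneous = FALSE)
    }
    db <- mk_db(rxns)
    model_ids <- c("EX_m1", setdiff(interior, gaps))
    model <- build_model(model_ids, db)
    gap_scores <- stats::setNames(stats::runif(length(gaps), 0.35, 0.45),
                                  gaps)
    decoy_scores <- stats::setNames(
      stats::runif(n_decoys, 0.05, 0.15), sprintf("DEC%02d", seq_len(n_decoys)))
    scored <- do.call(rbind, lapply(names(c(gap_scores, decoy_scores)),
      function(rid) {
        ecs <- db$reactions[[rid]]$ecs
        data.frame(protein_id = paste0("px_", rid), ec = ecs,
                   score = unname(c(gap_scores, decoy_scores)[rid]),
                   stringsAsFactors = FALSE)
      }))
    list(model = model, db = db, scored = scored,
         known_optimal_gapfill = gaps)
  })
}
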