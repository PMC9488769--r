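# Independent oracles used by the acceptance tests.

# Brute-force posterior for a Bernoulli mixture: explicit loop over both
# classes and features, no shared code with nb_posterior().
brute_force_posterior <- function(f, prior_pos, cond_pos, cond_neg) {
  joint <- numeric(2)
  for (cls in c(0, 1)) {
    p <- if (cls == 1) prior_pos else 1 - prior_pos
    for (i in seq_along(f)) {
      cond <- if (cls == 1) cond_pos[i] else cond_neg[i]
      p <- p * (if (f[i] == 1) cond else 1 - cond)
    }
    joint[cls + 1] <- p
  }
  joint[2] / sum(joint)
}

# Exhaustive-enumeration gap-filling: try candidate subsets in increasing
# penalty order, accept the first whose addition lets the model reach beta.
# Feasibility is checked by plain FBA on the augmented network, never by the
# MILP under test.
oracle_gapfill <- function(model, candidate_reactions, penalties, beta,
                           tol = 1e-6) {
  ids <- names(candidate_reactions)
  r <- length(ids)
  stopifnot(r <= 12)
  masks <- 0:(2^r - 1)
  cost <- vapply(masks, function(m)
    sum(penalties[bitwAnd(m, 2^(seq_len(r) - 1)) > 0]), 0)
  for (m in masks[order(cost)]) {
    sel <- ids[bitwAnd(m, 2^(seq_len(r) - 1)) > 0]
    aug <- model
    for (rid in sel) {
      cr <- candidate_reactions[[rid]]
      aug <- add_reaction(aug, rid, cr$stoichiometry, cr$lower, cr$upper,
                          provenance = "gapfill")
    }
    res <- fba(aug)
    if (identical(res$status, "optimal") && res$objective >= beta - tol)
      return(list(objective = sum(penalties[sel]), selected = sel))
  }
  NULL
}
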