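#' Parse a reaction equation string
#'
#' Equations use the dialect `"2 A + B <=> C"` (reversible) or
#' `"A + B -> C"` (irreversible): whitespace-separated terms, optional leading
#' numeric coefficient per metabolite. Substrates get negative coefficients,
#' products positive.
#'
#' @param equation equation string.
#' @return list with `stoichiometry` (named numeric) and `reversible`.
#' @export
parse_equation <- function(equation) {
  reversible <- grepl("<=>", equation, fixed = TRUE)
  arrow <- if (reversible) "<=>" else "->"
  if (!grepl(arrow, equation, fixed = TRUE))
    stop("malformed equation: ", equation)
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")  # boundary reaction "A ->"
  if (length(sides) != 2) stop("malformed equation: ", equation)
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (s == "") return(numeric(0))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (t in terms) {
      m <- regmatches(t, regexec("^([0-9.]+\\s+)?(\\S+)$", t))[[1]]
      if (length(m) < 3 || m[3] == "") stop("malformed term '", t, "' in: ", equation)
      coef <- if (m[2] == "") 1 else as.numeric(trimws(m[2]))
      if (is.na(coef)) stop("malformed coefficient in term '", t, "'")
      cur <- if (m[3] %in% names(out)) out[[m[3]]] else 0
      out[m[3]] <- cur + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (m in names(rhs)) {
    cur <- if (m %in% names(st)) st[[m]] else 0
    st[m] <- cur + rhs[[m]]
  }
  st <- st[st != 0]
  list(stoichiometry = st, reversible = reversible)
}

format_equation <- function(stoichiometry, reversible) {
  fmt <- function(v) paste(vapply(names(v), function(m) {
    co <- abs(v[[m]])
    if (co == 1) m else paste(format(co), m)
  }, ""), collapse = " + ")
  lhs <- fmt(stoichiometry[stoichiometry < 0])
  rhs <- fmt(stoichiometry[stoichiometry > 0])
  paste(lhs, if (reversible) "<=>" else "->", rhs)
}

new_reaction <- function(id, stoichiometry, reversible, ecs = character(),
                         spontaneous = FALSE, bounds = NULL) {
  if (!length(stoichiometry)) stop("reaction ", id, " has empty stoichiometry")
  if (any(stoichiometry == 0)) stop("reaction ", id, " has a zero coefficient")
  bounds <- bounds %||% if (reversible) c(-1000, 1000) else c(0, 1000)
  if (bounds[1] > bounds[2]) stop("reaction ", id, ": lower bound > upper bound")
  list(id = id, stoichiometry = stoichiometry, reversible = reversible,
       ecs = unique(ecs), spontaneous = isTRUE(spontaneous),
       bounds = as.numeric(bounds))
}

#' Load a reaction database
#'
#' The database is a JSON document with fields `dialect` ("kegg_like" or
#' "bigg_like") and `reactions`, an array of objects with `id`, `equation`
#' (see [parse_equation()]), optional `ecs`, `spontaneous`, `bounds`, plus an
#' optional `non_ec_sequence_index` mapping reaction ids to representative
#' protein ids (sequence evidence for non-EC reactions, BiGG-style). A TSV
#' with columns `id`, `equation`, `ecs` (semicolon-separated), `spontaneous`
#' is also accepted.
#'
#' @param path JSON or TSV file.
#' @param dialect overrides the file's dialect tag if given.
#' @return object of class `reaction_db` with `reactions` (named list),
#'   `ec_index`, `dialect`, `non_ec_sequence_index`; a count summary is
#'   attached as attribute `summary`.
#' @export
load_reaction_db <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("cannot read reaction database: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path)
    dialect <- dialect %||% doc$dialect %||% "kegg_like"
    rows <- doc$reactions
    nesi <- lapply(doc$non_ec_sequence_index %||% list(), unlist)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    dialect <- dialect %||% "kegg_like"
    rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    nesi <- list()
  }
  dialect <- match.arg(dialect, c("kegg_like", "bigg_like"))
  reactions <- list()
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (is.null(r$id) || is.null(r$equation))
      stop("reaction entry ", i, " lacks id or equation")
    if (r$id %in% names(reactions)) stop("duplicate reaction id: ", r$id)
    eq <- tryCatch(parse_equation(r$equation),
                   error = function(e) stop("row ", i, " (", r$id, "): ",
                                            conditionMessage(e)))
    ecs <- unlist(r$ecs %||% character())
    if (is.character(ecs) && length(ecs) == 1 && grepl(";", ecs))
      ecs <- trimws(strsplit(ecs, ";")[[1]])
    ecs <- ecs[nzchar(ecs)]
    reactions[[r$id]] <- new_reaction(
      r$id, eq$stoichiometry, eq$reversible, ecs = as.character(ecs),
      spontaneous = isTRUE(r$spontaneous) || identical(r$spontaneous, "TRUE"),
      bounds = if (!is.null(r$bounds)) unlist(r$bounds))
  }
  db <- structure(list(reactions = reactions,
                       ec_index = build_ec_index(reactions),
                       dialect = dialect,
                       non_ec_sequence_index = nesi),
                  class = "reaction_db")
  attr(db, "summary") <- list(n_reactions = length(reactions),
                              n_ecs = length(db$ec_index),
                              dialect = dialect)
  db
}

build_ec_index <- function(reactions) {
  idx <- list()
  for (r in reactions)
    for (ec in r$ecs) idx[[ec]] <- c(idx[[ec]], r$id)
  lapply(idx, unique)
}

#' Save a reaction database as JSON
#' @param db a `reaction_db`.
#' @param path output path.
#' @export
write_reaction_db <- function(db, path) {
  doc <- list(
    dialect = db$dialect,
    reactions = unname(lapply(db$reactions, function(r) list(
      id = r$id, equation = format_equation(r$stoichiometry, r$reversible),
      ecs = as.list(r$ecs), spontaneous = r$spontaneous,
      bounds = r$bounds))),
    non_ec_sequence_index = lapply(db$non_ec_sequence_index, as.list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reactions linked to a set of ECs
#'
#' Returns the union of the EC index over the query set — all reactions of a
#' multi-reaction EC are included indiscriminately. ECs absent from the
#' database are reported separately as a coverage statistic.
#'
#' @param db a `reaction_db`.
#' @param ec_set character vector of ECs.
#' @return list `reaction_ids` (character), `uncovered_ecs` (character).
#' @export
reactions_for_ecs <- function(db, ec_set) {
  ec_set <- unique(ec_set)
  covered <- ec_set[ec_set %in% names(db$ec_index)]
  list(reaction_ids = sort(unique(as.character(unlist(db$ec_index[covered])))),
       uncovered_ecs = sort(setdiff(ec_set, covered)))
}

#' Filter BLAST hits supporting non-EC reactions
#'
#' Keeps tabular hits with E-value at or below the cutoff (inclusive) and maps
#' target proteins to reactions through the database's non-EC sequence index.
#' Hits whose target maps to no reaction are dropped with a warning.
#'
#' @param blast_table data.frame with columns `qseqid`, `sseqid`, `evalue`
#'   (outfmt-6-like; extra columns ignored), or a TSV path of the same.
#' @param db a `reaction_db` with a `non_ec_sequence_index`.
#' @param evalue_cutoff maximum E-value retained (default 1e-20, inclusive).
#' @return named list, reaction id -> character vector of supporting query
#'   genes.
#' @export
filter_similarity_hits <- function(blast_table, db, evalue_cutoff = 1e-20) {
  if (is.character(blast_table))
    blast_table <- utils::read.delim(
      blast_table, header = FALSE,
      col.names = c("qseqid", "sseqid", "evalue"))[, 1:3]
  if (!nrow(blast_table)) return(list())
  hits <- blast_table[blast_table$evalue <= evalue_cutoff, , drop = FALSE]
  prot2rxn <- list()
  for (rid in names(db$non_ec_sequence_index))
    for (p in db$non_ec_sequence_index[[rid]])
      prot2rxn[[p]] <- c(prot2rxn[[p]], rid)
  out <- list()
  unmapped <- character()
  for (i in seq_len(nrow(hits))) {
    rxns <- prot2rxn[[hits$sseqid[i]]]
    if (is.null(rxns)) { unmapped <- c(unmapped, hits$sseqid[i]); next }
    for (r in rxns) out[[r]] <- unique(c(out[[r]], hits$qseqid[i]))
  }
  if (length(unmapped))
    warning("BLAST targets not mapped to any reaction, hits dropped: ",
            paste(unique(unmapped), collapse = ", "))
  out
}
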