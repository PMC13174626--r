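# Build a small ontology by writing OBO text and reading it back, so the
# parser is on the path of every test that uses an ontology.
#
# `edges` is a data frame (child, parent, relation); aspects are inferred
# from `aspects`, a named chr vector term -> MF/BP/CC.
obo_from_edges <- function(edges, aspects, obsolete = NULL) {
  ns <- c(MF = "molecular_function", BP = "biological_process",
          CC = "cellular_component")
  stanzas <- vapply(names(aspects), function(t) {
    e <- edges[edges$child == t, , drop = FALSE]
    rel_lines <- ifelse(e$relation == "is_a",
                        paste0("is_a: ", e$parent),
                        paste0("relationship: ", e$relation, " ", e$parent))
    paste(c("[Term]", paste0("id: ", t), paste0("name: term ", t),
            paste0("namespace: ", ns[[aspects[[t]]]]), rel_lines),
          collapse = "\n")
  }, character(1))
  if (!is.null(obsolete)) {
    stanzas <- c(stanzas, vapply(seq_len(nrow(obsolete)), function(i) {
      paste(c("[Term]", paste0("id: ", obsolete$id[i]),
              "name: gone", "namespace: molecular_function",
              "is_obsolete: true",
              if (!is.na(obsolete$replaced_by[i]))
                paste0("replaced_by: ", obsolete$replaced_by[i])),
            collapse = "\n")
    }, character(1)))
  }
  path <- withr::local_tempfile(fileext = ".obo",
                                .local_envir = parent.frame())
  writeLines(c("format-version: 1.2", "", paste(stanzas, collapse = "\n\n")),
             path)
  path
}

# MF chain root R -> A -> C plus a sibling B under A.
chain_ontology <- function() {
  edges <- data.frame(
    child = c("MF:A", "MF:C", "MF:B"),
    parent = c("MF:R", "MF:A", "MF:A"),
    relation = "is_a"
  )
  aspects <- c("MF:R" = "MF", "MF:A" = "MF", "MF:C" = "MF", "MF:B" = "MF")
  read_obo(obo_from_edges(edges, aspects))
}

# Flat MF ontology: root plus k independent children named MF:T1..Tk.
# Propagation adds nothing (the only ancestor is the root, which is
# dropped), so metric examples can be stated directly on leaf terms.
flat_ontology <- function(k = 5) {
  terms <- paste0("MF:T", seq_len(k))
  edges <- data.frame(child = terms, parent = "MF:R", relation = "is_a")
  aspects <- setNames(rep("MF", k + 1), c("MF:R", terms))
  read_obo(obo_from_edges(edges, aspects))
}

# Snapshot built directly from (protein, term) pairs.
snapshot_of <- function(ontology, protein, term, propagate = TRUE,
                        label = "") {
  rec <- tibble::tibble(object_id = protein, term = term,
                        evidence = "IDA", qualifier = "",
                        aspect = NA_character_)
  build_snapshot(rec, ontology, propagate = propagate, label = label)
}

# Benchmark with explicit prior/gained sets on a flat ontology (terms must
# already be their own closure).
benchmark_of <- function(aspect, prior, gained) {
  truth <- dplyr::bind_rows(
    if (length(prior)) tibble::tibble(
      protein = rep(names(prior), lengths(prior)),
      term = unlist(prior, use.names = FALSE), role = "prior") else NULL,
    tibble::tibble(
      protein = rep(names(gained), lengths(gained)),
      term = unlist(gained, use.names = FALSE), role = "gained")
  )
  funbench:::new_benchmark(truth, aspect = aspect, setting = "NK+LK",
                           proteins = sort(names(gained)))
}

predictions_of <- function(protein, term, score, propagated = TRUE) {
  funbench:::new_predictions(
    tibble::tibble(protein = protein, term = term, score = score),
    team = "test", model = 1L, propagated = propagated
  )
}

ia_of <- function(term, ia, aspect = "MF") {
  structure(tibble::tibble(term = term, aspect = aspect, ia = ia),
            class = c("term_ia", class(tibble::tibble())))
}

# A small randomized evaluation fixture for oracle-equivalence loops:
# deterministic given `seed`. Settings alternate between a pure-gain
# (NK+LK) and a prior-carrying (PK) benchmark; predictions sometimes skip
# a protein so coverage < 1 paths are exercised.
random_eval_fixture <- function(seed, n_proteins = 5, max_terms = 12) {
  spec <- fixture_spec(
    n_terms = 6 + (seed %% (max_terms - 5)), n_aspects = 2,
    n_proteins = n_proteins,
    frac_nk = 0.2, frac_lk = 0.2, frac_pk = 0.6,
    gain_rate = 2, seed = seed
  )
  ont <- random_ontology(spec)
  snaps <- simulate_snapshots(ont, spec)
  setting <- if (seed %% 2 == 0) "PK" else "NK+LK"
  bench <- build_benchmark(snaps$ts, snaps$tb, ont,
                           aspect = snaps$eval_aspect, setting = setting)
  ia <- suppressMessages(term_information(snaps$tb, ont))
  pred <- simulate_predictor(bench, ont, quality = (seed %% 5) / 5,
                             seed = seed + 1000L)
  if (seed %% 3 == 0 && attr(bench, "n") > 1) {
    tbl <- tibble::as_tibble(pred)
    drop <- attr(bench, "proteins")[1]
    pred <- funbench:::new_predictions(tbl[tbl$protein != drop, ],
                                       team = "test", model = 1L,
                                       propagated = TRUE)
  }
  list(ontology = ont, benchmark = bench, ia = ia, predictions = pred)
}
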