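#' Specification for a synthetic evaluation fixture
#'
#' Collects the knobs of the synthetic-data generator: ontology size, corpus
#' size, the NK/LK/PK mixture, the annotation gain rate between the two
#' snapshot times, and the quality of the simulated predictor. Defaults
#' describe a small but non-trivial evaluation: a 20-term DAG per aspect,
#' 50 proteins in a 0.3/0.2/0.5 NK/LK/PK mixture (so every setting is
#' populated, with PK - the common case for well-studied organisms -
#' largest), a mean of 3 newly annotated leaves per protein, and a
#' well-separated (quality 0.8) predictor.
#'
#' @param n_terms Terms per aspect (>= 2; includes the root).
#' @param n_aspects Number of aspects to generate (1-3, using MF, BP, CC in
#'   that order).
#' @param n_proteins Number of proteins.
#' @param frac_nk,frac_lk,frac_pk Fractions of proteins planted as
#'   NK/LK/PK for the evaluation aspect; must sum to at most 1 (the
#'   remainder gains nothing and belongs to no benchmark).
#' @param gain_rate Mean number of newly annotated leaf terms per protein
#'   between ts and tB (Poisson, floored at 1 for benchmark proteins).
#' @param predictor_quality Score separation between true and false terms,
#'   in \[0, 1\]: 0 = exchangeable, 1 = perfectly separated.
#' @param part_of_prob Probability that a generated edge is `part_of`
#'   rather than `is_a`.
#' @param seed Integer seed; every generator call is deterministic given it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_terms = 20, n_aspects = 3, n_proteins = 50,
                         frac_nk = 0.3, frac_lk = 0.2, frac_pk = 0.5,
                         gain_rate = 3, predictor_quality = 0.8,
                         part_of_prob = 0.2, seed = 1) {
  stopifnot(n_terms >= 2, n_aspects %in% 1:3, n_proteins >= 1,
            frac_nk >= 0, frac_lk >= 0, frac_pk >= 0,
            frac_nk + frac_lk + frac_pk <= 1 + 1e-9,
            predictor_quality >= 0, predictor_quality <= 1)
  structure(
    list(n_terms = n_terms, n_aspects = n_aspects, n_proteins = n_proteins,
         frac_nk = frac_nk, frac_lk = frac_lk, frac_pk = frac_pk,
         gain_rate = gain_rate, predictor_quality = predictor_quality,
         part_of_prob = part_of_prob, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate a random rooted ontology
#'
#' Builds one rooted DAG per aspect: terms are added in order, each
#' non-root term attaching to one or two uniformly chosen earlier terms
#' (so acyclicity and reachability from the root hold by construction).
#' Edges are `is_a` or, with probability `part_of_prob`, `part_of`.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return A `go_ontology`.
#' @export
random_ontology <- function(spec) {
  aspects <- c("MF", "BP", "CC")[seq_len(spec$n_aspects)]
  withr::with_seed(spec$seed, {
    tabs <- purrr::imap(setNames(aspects, aspects), function(a, nm) {
      ids <- sprintf("GO:%d%06d", match(a, c("MF", "BP", "CC")),
                     seq_len(spec$n_terms))
      child <- parent <- list()
      for (i in seq_along(ids)[-1]) {
        k <- min(sample(1:2, 1), i - 1)
        parents <- sample(ids[seq_len(i - 1)], k)
        child[[i]] <- rep(ids[i], k)
        parent[[i]] <- parents
      }
      child <- unlist(child); parent <- unlist(parent)
      edges <- tibble::tibble(
        child = child, parent = parent,
        relation = ifelse(runif(length(child)) < spec$part_of_prob,
                          "part_of", "is_a")
      )
      list(
        terms = tibble::tibble(term = ids,
                               name = paste("synthetic term", ids),
                               aspect = a),
        edges = edges
      )
    })
    new_ontology(
      purrr::map_dfr(tabs, "terms"),
      purrr::map_dfr(tabs, "edges"),
      tibble::tibble(alt = character(), term = character()),
      relations = c("is_a", "part_of")
    )
  })
}

#' Simulate deadline-time and benchmark-time annotation snapshots
#'
#' Plants NK/LK/PK roles for the evaluation aspect (the ontology's first
#' aspect) according to the spec's fractions, then draws annotations so the
#' time-delayed setting definitions hold by construction:
#'
#' * NK proteins: nothing at ts anywhere; gained leaves in the evaluation
#'   aspect at tB.
#' * LK proteins: annotations at ts only in a different aspect; gained
#'   leaves in the evaluation aspect at tB.
#' * PK proteins: annotations in the evaluation aspect at ts; additional
#'   leaves at tB drawn outside the propagated ts closure, so the
#'   propagated set strictly grows.
#' * remaining proteins: possibly annotated at ts, nothing gained.
#'
#' Per protein, tB extends ts (no retractions are simulated). Both
#' snapshots are returned propagated.
#'
#' @param ontology A `go_ontology` (from [random_ontology()]).
#' @param spec A [fixture_spec()].
#' @return List: `ts`, `tb` (propagated `go_snapshot`s), `planted` (tibble
#'   `protein`, `setting` for the evaluation aspect), `eval_aspect`.
#' @export
simulate_snapshots <- function(ontology, spec) {
  aspects <- names(ontology$roots)
  eval_aspect <- aspects[1]
  other_aspects <- setdiff(aspects, eval_aspect)
  nonroot <- function(a) {
    setdiff(ontology$terms$term[ontology$terms$aspect == a],
            unname(ontology$roots))
  }
  pool_eval <- nonroot(eval_aspect)

  withr::with_seed(spec$seed + 1L, {
    n <- spec$n_proteins
    prots <- sprintf("P%05d", seq_len(n))
    roles <- sample(c(
      rep("NK", round(spec$frac_nk * n)),
      rep("LK", round(spec$frac_lk * n)),
      rep("PK", round(spec$frac_pk * n)),
      rep("none", n)
    )[seq_len(n)])
    if (!length(other_aspects)) roles[roles == "LK"] <- "NK"

    ts_rows <- list(); tb_rows <- list()
    n_gain <- function() max(1L, rpois(1, spec$gain_rate))
    for (i in seq_len(n)) {
      p <- prots[i]; role <- roles[i]
      ts_terms <- character()
      if (role == "LK" && length(other_aspects)) {
        a <- sample(other_aspects, 1)
        ts_terms <- sample(nonroot(a), min(2L, length(nonroot(a))))
      }
      if (role == "PK") {
        ts_terms <- sample(pool_eval, 1)
      }
      if (role == "none" && runif(1) < 0.5) {
        ts_terms <- sample(pool_eval, 1)
      }
      gained <- character()
      if (role %in% c("NK", "LK", "PK")) {
        closure <- propagate_terms(ontology, ts_terms)
        avail <- setdiff(pool_eval, closure)
        if (!length(avail)) {
          # closure covers the aspect: retry with a smaller prior
          ts_terms <- if (role == "PK") sample(pool_eval, 1) else character()
          avail <- setdiff(pool_eval, propagate_terms(ontology, ts_terms))
        }
        gained <- sample(avail, min(n_gain(), length(avail)))
      }
      if (length(ts_terms)) {
        ts_rows[[length(ts_rows) + 1L]] <-
          c(protein = list(rep(p, length(ts_terms))), term = list(ts_terms))
      }
      both <- c(ts_terms, gained)
      if (length(both)) {
        tb_rows[[length(tb_rows) + 1L]] <-
          c(protein = list(rep(p, length(both))), term = list(both))
      }
    }

    as_snap <- function(rows, label) {
      rec <- tibble::tibble(
        object_id = unlist(purrr::map(rows, "protein")) %||% character(),
        term = unlist(purrr::map(rows, "term")) %||% character(),
        evidence = "IDA", qualifier = "", aspect = NA_character_
      )
      build_snapshot(rec, ontology, propagate = TRUE, label = label)
    }
    list(
      ts = as_snap(ts_rows, "ts"),
      tb = as_snap(tb_rows, "tB"),
      planted = tibble::tibble(protein = prots, setting = roles),
      eval_aspect = eval_aspect
    )
  })
}

#' Simulate a predictor of tunable quality
#'
#' Scores each benchmark protein's gained-truth terms and an equal number
#' of decoy terms (terms of the aspect outside the protein's benchmark-time
#' annotation). True terms are drawn from Unif(3q/4, 1] and decoys from
#' Unif(0, 1 - q/2], where q is the quality: at q = 0 the two
#' distributions coincide (scores carry no signal), at q = 1 they are
#' disjoint (true in (0.75, 1], decoys in (0, 0.5]), so a threshold
#' separates them perfectly and Fmax = 1 / Smin = 0 are achievable.
#' Scores are max-propagated to ancestors before returning. Deterministic
#' given `seed`.
#'
#' @param benchmark A `go_benchmark`.
#' @param ontology A `go_ontology`.
#' @param quality Separation parameter in \[0, 1\].
#' @param seed Integer seed.
#' @param team,model Labels stored on the result.
#' @return A propagated `go_predictions` covering every benchmark protein.
#' @export
simulate_predictor <- function(benchmark, ontology, quality, seed,
                               team = sprintf("sim-q%.2f", quality),
                               model = 1L) {
  stopifnot(quality >= 0, quality <= 1)
  aspect <- attr(benchmark, "aspect")
  pool <- setdiff(ontology$terms$term[ontology$terms$aspect == aspect],
                  unname(ontology$roots))
  truth <- tibble::as_tibble(benchmark)

  proteins <- attr(benchmark, "proteins")
  titb_l <- split(truth$term, factor(truth$protein, levels = proteins))
  gained_l <- split(truth$term[truth$role == "gained"],
                    factor(truth$protein[truth$role == "gained"],
                           levels = proteins))
  withr::with_seed(seed, {
    rows <- vector("list", length(proteins))
    r_true <- function(k) 0.75 * quality + runif(k) * (1 - 0.75 * quality)
    r_false <- function(k) runif(k) * (1 - quality / 2)
    for (j in seq_along(proteins)) {
      gained <- gained_l[[j]]
      cand <- setdiff(pool, titb_l[[j]])
      decoys <- sample(cand, min(length(gained), length(cand)))
      rows[[j]] <- list(
        protein = rep(proteins[j], length(gained) + length(decoys)),
        term = c(gained, decoys),
        score = pmin(1, pmax(1e-6, c(r_true(length(gained)),
                                     r_false(length(decoys)))))
      )
    }
    tbl <- tibble::tibble(
      protein = unlist(purrr::map(rows, "protein")),
      term = unlist(purrr::map(rows, "term")),
      score = unlist(purrr::map(rows, "score"))
    )
    pred <- new_predictions(tbl, team = team, model = model,
                            propagated = FALSE)
    propagate_scores(pred, ontology)
  })
}

#' Generate a complete in-memory fixture
#'
#' Convenience wrapper chaining [random_ontology()],
#' [simulate_snapshots()], [build_benchmark()], [term_information()] (with
#' the tB snapshot as reference) and [simulate_predictor()] at
#' `spec$predictor_quality` plus a perfect (quality 1) predictor.
#'
#' @param spec A [fixture_spec()].
#' @param setting Benchmark setting to build (default `"NK+LK"`).
#' @return List: `ontology`, `ts`, `tb`, `planted`, `benchmark`, `ia`,
#'   `predictions` (named list keyed `"qX.XX"`), `spec`.
#' @export
simulate_fixture <- function(spec = fixture_spec(), setting = "NK+LK") {
  ont <- random_ontology(spec)
  snaps <- simulate_snapshots(ont, spec)
  bench <- build_benchmark(snaps$ts, snaps$tb, ont,
                           aspect = snaps$eval_aspect, setting = setting)
  ia <- suppressMessages(term_information(snaps$tb, ont))
  qs <- unique(c(spec$predictor_quality, 1))
  preds <- setNames(
    purrr::imap(qs, ~ simulate_predictor(bench, ont, .x, spec$seed + 10L + .y)),
    sprintf("q%.2f", qs)
  )
  list(ontology = ont, ts = snaps$ts, tb = snaps$tb, planted = snaps$planted,
       benchmark = bench, ia = ia, predictions = preds, spec = spec)
}

#' Write a fixture to disk
#'
#' Materialises a fixture as real files - OBO ontology, snapshot TSVs,
#' submission-format prediction files, the ia table, and a planted-truth
#' manifest - so that every parser in the package is exercised by tests
#' that read them back.
#'
#' @param fixture Result of [simulate_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; files: `ontology.obo`, `snapshot_ts.tsv`,
#'   `snapshot_tb.tsv`, `ia.tsv`, `pred_<q>.txt`, `planted.tsv`.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_obo(fixture$ontology, file.path(dir, "ontology.obo"))
  write_snapshot(fixture$ts, file.path(dir, "snapshot_ts.tsv"))
  write_snapshot(fixture$tb, file.path(dir, "snapshot_tb.tsv"))
  write_term_information(fixture$ia, file.path(dir, "ia.tsv"))
  readr::write_tsv(fixture$planted, file.path(dir, "planted.tsv"),
                   progress = FALSE)
  purrr::iwalk(fixture$predictions, function(p, nm) {
    write_predictions(p, file.path(dir, paste0("pred_", nm, ".txt")))
  })
  invisible(dir)
}
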