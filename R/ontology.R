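#' Read an OBO ontology
#'
#' Parses an OBO 1.2/1.4 flat file into a `go_ontology` object holding the
#' term table, the child-to-parent edge list, one root per aspect, an
#' alternate-identifier map (including obsolete terms routed through
#' `replaced_by`), and a precomputed within-aspect ancestral closure for
#' every term.
#'
#' Only the stanza fields `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of`, `is_obsolete`, `replaced_by` and `alt_id` are
#' interpreted; everything else is ignored. Obsolete terms without a
#' `replaced_by` target become tombstones (they resolve to `NA` and are
#' dropped, with a warning, wherever they are encountered).
#'
#' @param path Path to an OBO file.
#' @param relations Character vector of relations used for ancestral
#'   propagation. The default, `c("is_a", "part_of")`, follows established
#'   practice for function-prediction evaluation; use `"is_a"` for an
#'   is_a-only closure. Regulates-type relations are never used.
#' @return A `go_ontology` object.
#' @export
#' @examples
#' obo <- system.file("extdata", "toy.obo", package = "funbench")
#' ont <- read_obo(obo)
#' ont
read_obo <- function(path, relations = c("is_a", "part_of")) {
  if (!file.exists(path)) {
    stop("cannot read OBO file: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path)

  # split into [Term] stanzas
  starts <- which(lines == "[Term]")
  other_stanza <- which(grepl("^\\[", lines) & lines != "[Term]")
  bounds <- sort(c(starts, other_stanza, length(lines) + 1L))

  terms <- list()
  for (s in starts) {
    end <- min(bounds[bounds > s]) - 1L
    block <- lines[s:end]
    kv <- block[grepl("^[a-z_]+:", block)]
    key <- sub(":.*$", "", kv)
    val <- sub("^[a-z_]+:\\s*", "", kv)
    val <- sub("\\s*!.*$", "", val)  # strip trailing comments
    get1 <- function(k) if (any(key == k)) val[key == k][1] else NA_character_
    rel <- val[key == "relationship"]
    rel_type <- sub("\\s.*$", "", rel)
    rel_tgt <- sub("^\\S+\\s+", "", rel)
    terms[[length(terms) + 1L]] <- list(
      id = get1("id"),
      name = get1("name"),
      namespace = get1("namespace"),
      is_a = val[key == "is_a"],
      rel_type = rel_type,
      rel_tgt = rel_tgt,
      obsolete = identical(get1("is_obsolete"), "true"),
      replaced_by = get1("replaced_by"),
      alt_id = val[key == "alt_id"]
    )
  }
  if (!length(terms)) stop("no [Term] stanzas found in ", path, call. = FALSE)

  ns_to_aspect <- c(
    molecular_function = "MF", biological_process = "BP",
    cellular_component = "CC", MF = "MF", BP = "BP", CC = "CC"
  )

  live <- purrr::keep(terms, ~ !.x$obsolete)
  dead <- purrr::keep(terms, ~ .x$obsolete)

  term_tbl <- purrr::map_dfr(live, function(t) {
    tibble::tibble(
      term = t$id,
      name = t$name %||% NA_character_,
      aspect = unname(ns_to_aspect[t$namespace] %||% NA_character_)
    )
  })
  if (anyNA(term_tbl$aspect)) {
    bad <- term_tbl$term[is.na(term_tbl$aspect)]
    stop("terms with missing/unknown namespace: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(term_tbl$term)) {
    stop("duplicate term ids in OBO file", call. = FALSE)
  }

  edge_tbl <- purrr::map_dfr(live, function(t) {
    dplyr::bind_rows(
      tibble::tibble(child = t$id, parent = t$is_a, relation = "is_a"),
      tibble::tibble(child = t$id, parent = t$rel_tgt, relation = t$rel_type)
    )
  })
  # keep only relations we know how to interpret, targets that exist
  edge_tbl <- dplyr::filter(
    edge_tbl,
    .data$relation %in% c("is_a", "part_of"),
    .data$parent %in% term_tbl$term
  )

  alt_tbl <- dplyr::bind_rows(
    purrr::map_dfr(terms, function(t) {
      if (length(t$alt_id)) tibble::tibble(alt = t$alt_id, term = t$id) else NULL
    }),
    purrr::map_dfr(dead, function(t) {
      tibble::tibble(alt = t$id, term = t$replaced_by %||% NA_character_)
    })
  )
  if (nrow(alt_tbl)) {
    ok <- is.na(alt_tbl$term) | alt_tbl$term %in% term_tbl$term
    alt_tbl$term[!ok] <- NA_character_  # replaced_by pointing nowhere -> tombstone
  } else {
    alt_tbl <- tibble::tibble(alt = character(), term = character())
  }

  new_ontology(term_tbl, edge_tbl, alt_tbl, relations)
}

#' @keywords internal
new_ontology <- function(term_tbl, edge_tbl, alt_tbl, relations) {
  g <- igraph::graph_from_data_frame(
    edge_tbl[, c("child", "parent")],
    directed = TRUE,
    vertices = term_tbl$term
  )
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    stop("ontology graph contains a cycle involving: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }

  prop_edges <- dplyr::filter(edge_tbl, .data$relation %in% relations)
  aspect_of <- stats::setNames(term_tbl$aspect, term_tbl$term)

  # within-aspect propagation edges only
  wa <- prop_edges[aspect_of[prop_edges$child] == aspect_of[prop_edges$parent], ]

  # roots: exactly one parentless (within aspect, any relation) term per aspect
  all_wa <- edge_tbl[aspect_of[edge_tbl$child] == aspect_of[edge_tbl$parent], ]
  roots <- character()
  for (a in unique(term_tbl$aspect)) {
    tms <- term_tbl$term[term_tbl$aspect == a]
    parentless <- setdiff(tms, all_wa$child[aspect_of[all_wa$child] == a])
    if (length(parentless) != 1L) {
      stop("aspect ", a, " must have exactly one root; found: ",
           paste(parentless, collapse = ", "), call. = FALSE)
    }
    roots[a] <- parentless
  }

  # ancestral closure (self-inclusive, within aspect) in topological order
  gp <- igraph::graph_from_data_frame(
    wa[, c("child", "parent")], directed = TRUE, vertices = term_tbl$term
  )
  ord <- names(igraph::topo_sort(gp, mode = "in"))  # parents before children
  parent_list <- split(wa$parent, factor(wa$child, levels = term_tbl$term))
  anc <- vector("list", nrow(term_tbl))
  names(anc) <- term_tbl$term
  for (t in ord) {
    ps <- parent_list[[t]]
    anc[[t]] <- unique(c(t, unlist(anc[ps], use.names = FALSE)))
  }

  structure(
    list(
      terms = term_tbl,
      edges = edge_tbl,
      roots = roots,
      alt_ids = alt_tbl,
      relations = relations,
      ancestors = anc
    ),
    class = "go_ontology"
  )
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("<go_ontology> ", nrow(x$terms), " terms, ", nrow(x$edges), " edges\n",
      sep = "")
  for (a in names(x$roots)) {
    cat("  ", a, ": ", sum(x$terms$aspect == a), " terms, root ",
        x$roots[[a]], "\n", sep = "")
  }
  cat("  propagation relations: ", paste(x$relations, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Extract the subgraph of one ontology aspect
#'
#' Returns the induced sub-ontology containing exactly the terms of the
#' given aspect and the edges internal to it; cross-aspect edges (e.g. a
#' part_of relation pointing into another aspect) are removed from both
#' sides. Idempotent.
#'
#' @param ontology A `go_ontology`.
#' @param aspect One of `"MF"`, `"BP"`, `"CC"`.
#' @return A `go_ontology` restricted to one aspect.
#' @export
ontology_subgraph <- function(ontology, aspect) {
  stopifnot(inherits(ontology, "go_ontology"))
  aspect <- match.arg(aspect, c("MF", "BP", "CC"))
  if (!aspect %in% ontology$terms$aspect) {
    stop("ontology has no terms in aspect ", aspect, call. = FALSE)
  }
  keep <- ontology$terms$term[ontology$terms$aspect == aspect]
  term_tbl <- dplyr::filter(ontology$terms, .data$aspect == !!aspect)
  edge_tbl <- dplyr::filter(ontology$edges,
                            .data$child %in% keep, .data$parent %in% keep)
  alt_tbl <- dplyr::filter(ontology$alt_ids,
                           is.na(.data$term) | .data$term %in% keep)
  new_ontology(term_tbl, edge_tbl, alt_tbl, ontology$relations)
}

#' Resolve term identifiers through the alternate-id map
#'
#' Primary identifiers pass through; alternate and obsolete-with-replacement
#' identifiers are rewritten to their primary term; tombstoned or unknown
#' identifiers become `NA` (callers warn and drop).
#'
#' @param ontology A `go_ontology`.
#' @param terms Character vector of term identifiers.
#' @return Character vector of the same length with `NA` for unresolvable ids.
#' @export
resolve_terms <- function(ontology, terms) {
  out <- ifelse(terms %in% ontology$terms$term, terms, NA_character_)
  miss <- which(is.na(out))
  if (length(miss) && nrow(ontology$alt_ids)) {
    m <- match(terms[miss], ontology$alt_ids$alt)
    out[miss] <- ontology$alt_ids$term[m]
  }
  out
}

#' Ancestral closure of a term set
#'
#' Propagates a set of terms to all ancestors within their aspect, using the
#' ontology's propagation relations. Aspect roots are removed from the
#' result by default: they are true of every annotated protein and carry no
#' information. Unresolvable terms are dropped with a warning rather than
#' failing.
#'
#' @param ontology A `go_ontology`.
#' @param terms Character vector of term identifiers.
#' @param keep_roots Keep aspect roots in the closure? Default `FALSE`.
#' @return Character vector: the ancestral closure (a superset of the
#'   resolvable input minus roots). Idempotent.
#' @export
#' @examples
#' obo <- system.file("extdata", "toy.obo", package = "funbench")
#' ont <- read_obo(obo)
#' propagate_terms(ont, "GO:0000003")
propagate_terms <- function(ontology, terms, keep_roots = FALSE) {
  stopifnot(inherits(ontology, "go_ontology"))
  res <- resolve_terms(ontology, terms)
  if (anyNA(res)) {
    warning("dropping ", sum(is.na(res)), " unresolvable term(s): ",
            paste(unique(terms[is.na(res)]), collapse = ", "), call. = FALSE)
    res <- res[!is.na(res)]
  }
  out <- unique(unlist(ontology$ancestors[res], use.names = FALSE))
  if (!keep_roots) out <- setdiff(out, unname(ontology$roots))
  out %||% character()
}

#' Restrict ontologies to their common terms
#'
#' Builds the ontology of terms shared by every input version. Terms are the
#' intersection of the term sets; each surviving non-root term is connected
#' to the minimal surviving strict ancestors it has in the *newest* graph
#' (the last element of `graphs`), i.e. the transitive reduction of the
#' newest graph's ancestor relation over the retained terms. This
#' transitive reconnection across removed intermediates preserves the
#' propagation semantics of the newest ontology.
#'
#' @param graphs List of at least two `go_ontology` objects, ordered oldest
#'   to newest.
#' @return A `go_ontology` over the common terms.
#' @export
restrict_common_terms <- function(graphs) {
  stopifnot(is.list(graphs), length(graphs) >= 2,
            all(purrr::map_lgl(graphs, inherits, "go_ontology")))
  newest <- graphs[[length(graphs)]]
  kept <- Reduce(intersect, purrr::map(graphs, ~ .x$terms$term))
  if (!length(kept)) stop("no terms common to all ontology versions",
                          call. = FALSE)

  term_tbl <- dplyr::filter(newest$terms, .data$term %in% kept)
  roots <- newest$roots[newest$roots %in% kept]
  if (!length(roots)) {
    stop("no aspect root survives the common-term restriction", call. = FALSE)
  }
  term_tbl <- dplyr::filter(term_tbl, .data$aspect %in% names(roots))

  # strict retained ancestors per term in the newest graph
  anc_kept <- purrr::map(
    stats::setNames(term_tbl$term, term_tbl$term),
    function(t) setdiff(intersect(newest$ancestors[[t]], term_tbl$term), t)
  )
  edge_tbl <- purrr::imap_dfr(anc_kept, function(a, t) {
    if (!length(a)) return(NULL)
    # minimal elements: ancestors not implied by another retained ancestor
    implied <- unique(unlist(
      purrr::map(a, ~ setdiff(anc_kept[[.x]], .x)), use.names = FALSE
    ))
    tibble::tibble(child = t, parent = setdiff(a, implied), relation = "is_a")
  })

  alt_tbl <- dplyr::filter(newest$alt_ids,
                           is.na(.data$term) | .data$term %in% term_tbl$term)
  new_ontology(term_tbl, edge_tbl, alt_tbl, newest$relations)
}

#' Write an ontology to an OBO file
#'
#' Emits a minimal OBO 1.2 document (format-version, one `[Term]` stanza per
#' term with `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` lines) that `read_obo()` reads back exactly.
#'
#' @param ontology A `go_ontology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "go_ontology"))
  ns <- c(MF = "molecular_function", BP = "biological_process",
          CC = "cellular_component")
  blocks <- purrr::pmap_chr(
    ontology$terms,
    function(term, name, aspect) {
      e <- ontology$edges[ontology$edges$child == term, ]
      lines <- c(
        "[Term]",
        paste0("id: ", term),
        paste0("name: ", if (is.na(name)) term else name),
        paste0("namespace: ", ns[[aspect]]),
        ifelse(e$relation == "is_a",
               paste0("is_a: ", e$parent),
               paste0("relationship: ", e$relation, " ", e$parent))
      )
      paste(lines, collapse = "\n")
    }
  )
  readr::write_lines(c("format-version: 1.2", "", paste(blocks, collapse = "\n\n")),
                     path)
  invisible(path)
}
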