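#' Estimate per-term information accretion
#'
#' Information accretion ia(f) is the negative binary logarithm of the
#' maximum-likelihood estimate of the conditional probability that term f
#' annotates a protein given that all of f's direct parents do:
#' \deqn{ia(f) = -\log_2 \frac{\#\{i : f \in T_i \wedge pa(f) \subseteq T_i\}}
#'                            {\#\{i : pa(f) \subseteq T_i\}}}
#' estimated over a reference corpus of propagated experimental
#' annotations. It weights a term by how much information it adds beyond
#' its parents, so deep specific terms count more than broad ones.
#'
#' Aspect roots have ia = 0 by definition. Parents that are aspect roots
#' are treated as always present (propagated snapshots do not store roots);
#' a term whose only parent is the root is conditioned on the set of
#' proteins annotated anywhere in its aspect. Terms whose conditional
#' frequency cannot be estimated finitely - no reference protein carries
#' all the parents, or the term itself is never annotated - are assigned
#' the maximum finite ia observed in their aspect, and reported in a
#' message; this keeps rare terms maximally informative without
#' introducing infinities into Smin.
#'
#' @param reference A propagated `go_snapshot` of experimentally annotated
#'   proteins.
#' @param ontology A `go_ontology`.
#' @return A `term_ia` tibble (`term`, `aspect`, `ia` in bits) covering
#'   every ontology term, with attribute `reference_size` = number of
#'   distinct reference proteins.
#' @export
#' @examples
#' obo <- system.file("extdata", "toy.obo", package = "funbench")
#' ont <- read_obo(obo)
#' snap <- read_snapshot(system.file("extdata", "toy_snapshot.tsv",
#'                                   package = "funbench"))
#' term_information(snap, ont)
term_information <- function(reference, ontology) {
  stopifnot(inherits(ontology, "go_ontology"))
  ref <- tibble::as_tibble(reference)
  if (nrow(ref) == 0) stop("empty reference snapshot", call. = FALSE)
  if (!isTRUE(attr(reference, "propagated"))) {
    stop("reference snapshot must be propagated", call. = FALSE)
  }

  aspect_of <- setNames(ontology$terms$aspect, ontology$terms$term)
  roots <- unname(ontology$roots)
  prop_edges <- dplyr::filter(
    ontology$edges,
    .data$relation %in% ontology$relations,
    aspect_of[.data$child] == aspect_of[.data$parent]
  )
  parent_list <- split(prop_edges$parent,
                       factor(prop_edges$child, levels = ontology$terms$term))

  out <- purrr::map_dfr(unique(ontology$terms$aspect), function(a) {
    tms <- ontology$terms$term[ontology$terms$aspect == a]
    ref_a <- ref[ref$aspect == a & ref$term %in% tms, ]
    prots <- unique(ref_a$protein)
    # protein x term incidence
    mat <- matrix(FALSE, length(prots), length(tms),
                  dimnames = list(prots, tms))
    if (nrow(ref_a)) mat[cbind(ref_a$protein, ref_a$term)] <- TRUE

    ia <- setNames(numeric(length(tms)), tms)
    for (t in tms) {
      if (t %in% roots) { ia[t] <- 0; next }
      pa <- setdiff(parent_list[[t]], roots)
      if (length(pa) == 0) {
        denom <- length(prots)            # conditioned on the aspect root
        num <- sum(mat[, t])
      } else {
        has_pa <- rowSums(mat[, pa, drop = FALSE]) == length(pa)
        denom <- sum(has_pa)
        num <- sum(has_pa & mat[, t])
      }
      ia[t] <- if (denom > 0) -log2(num / denom) else Inf
    }
    bad <- !is.finite(ia)
    if (any(bad)) {
      cap <- max(c(ia[!bad], 0))
      message("aspect ", a, ": ", sum(bad),
              " term(s) without a finite conditional frequency assigned ia = ",
              format(cap, digits = 4))
      ia[bad] <- cap
    }
    tibble::tibble(term = tms, aspect = a, ia = unname(ia))
  })

  structure(
    dplyr::arrange(out, .data$aspect, .data$term),
    reference_size = length(unique(ref$protein)),
    class = c("term_ia", class(tibble::tibble()))
  )
}

#' Write / read per-term information accretion
#'
#' Three-column TSV (`term`, `aspect`, `ia`) with one header line; numbers
#' written at full precision so the table round-trips exactly.
#'
#' @param ia A `term_ia` tibble.
#' @param path File path.
#' @export
write_term_information <- function(ia, path) {
  tbl <- tibble::as_tibble(ia)[, c("term", "aspect", "ia")]
  tbl$ia <- sprintf("%.17g", tbl$ia)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_term_information
#' @export
read_term_information <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  structure(tbl, class = c("term_ia", class(tibble::tibble())))
}
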