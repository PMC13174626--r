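#' Experimental evidence codes accepted as ground truth
#'
#' The 13 GO evidence codes treated as experimental by the CAFA community
#' when assembling benchmark truth. TAS and IC are author/curator statements
#' in GO's own taxonomy but belong to the challenge's experimental set, so
#' they are retained here.
#'
#' @format Character vector of 13 evidence codes.
#' @export
experimental_evidence_codes <- c(
  "EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC",
  "HTP", "HDA", "HMP", "HGI", "HEP"
)

gaf_aspect_codes <- c(F = "MF", P = "BP", C = "CC",
                      MF = "MF", BP = "BP", CC = "CC")

#' Read raw annotation records
#'
#' Reads protein-to-term annotation records from either a GAF 2.x file
#' (columns 2 = accession, 4 = qualifier, 5 = term, 7 = evidence code,
#' 9 = aspect; `!` comment lines skipped) or a simple headerless TSV with
#' columns `protein`, `term`, `evidence` and an optional fourth `qualifier`
#' column.
#'
#' Malformed rows (missing accession/term/evidence, bad term syntax) are
#' skipped with a counted warning; more than 10% malformed rows is treated
#' as a wrong-format file and fails hard.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gaf"` or `"tsv"`.
#' @return A tibble with columns `object_id`, `term`, `evidence`,
#'   `qualifier`, `aspect` (aspect is `NA` for the TSV dialect; it is
#'   recovered from the ontology when building a snapshot).
#' @export
read_annotations <- function(path, dialect = c("gaf", "tsv")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(
    path, col_names = FALSE, comment = "!", col_types = readr::cols(.default = "c"),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    warning("no annotation rows in ", path, call. = FALSE)
    return(tibble::tibble(object_id = character(), term = character(),
                          evidence = character(), qualifier = character(),
                          aspect = character()))
  }
  if (dialect == "gaf") {
    if (ncol(raw) < 9) stop("GAF file must have >= 9 columns", call. = FALSE)
    rec <- tibble::tibble(
      object_id = raw[[2]],
      term = raw[[5]],
      evidence = raw[[7]],
      qualifier = dplyr::coalesce(raw[[4]], ""),
      aspect = unname(gaf_aspect_codes[raw[[9]]])
    )
  } else {
    if (ncol(raw) < 3) stop("simple TSV must have >= 3 columns", call. = FALSE)
    rec <- tibble::tibble(
      object_id = raw[[1]],
      term = raw[[2]],
      evidence = raw[[3]],
      qualifier = if (ncol(raw) >= 4) dplyr::coalesce(raw[[4]], "") else "",
      aspect = NA_character_
    )
  }
  ok <- !is.na(rec$object_id) & !is.na(rec$term) & !is.na(rec$evidence) &
    grepl("^[A-Za-z]+:[A-Za-z0-9:_-]+$", rec$term)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    if (n_bad / nrow(rec) > 0.1) {
      stop(n_bad, "/", nrow(rec), " malformed annotation rows in ", path,
           call. = FALSE)
    }
    warning("skipped ", n_bad, " malformed annotation row(s)", call. = FALSE)
  }
  rec[ok, ]
}

#' Keep only experimental, positive, non-duplicate annotations
#'
#' Applies the challenge ground-truth filter: only the 13 codes in
#' [experimental_evidence_codes] survive; records whose qualifier contains
#' the token `NOT` (negative
#' annotations) are dropped; duplicate (protein, term) pairs are collapsed;
#' and all annotations to GO:0005515 ("protein binding") are removed. The
#' GO:0005515 exclusion happens before propagation, so its ancestors can
#' still be contributed by other terms.
#'
#' Pure, idempotent and order-independent.
#'
#' @param records Tibble as returned by [read_annotations()].
#' @return Filtered tibble of the same shape.
#' @export
filter_experimental <- function(records) {
  records %>%
    dplyr::filter(
      .data$evidence %in% experimental_evidence_codes,
      !stringr::str_detect(dplyr::coalesce(.data$qualifier, ""),
                           "(^|\\|)NOT(\\||$)"),
      .data$term != "GO:0005515"
    ) %>%
    dplyr::distinct(.data$object_id, .data$term, .keep_all = TRUE)
}

#' Map database accessions to challenge target identifiers
#'
#' Rewrites `object_id` through an accession-to-target map. Records whose
#' accession has no mapping are dropped and counted. The map must be
#' injective (no two accessions pointing to the same target).
#'
#' @param records Annotation record tibble.
#' @param mapping Tibble/data frame with columns `accession`, `target` (or
#'   any two columns in that order).
#' @return Records with `object_id` replaced by target ids.
#' @export
map_ids <- function(records, mapping) {
  mapping <- tibble::as_tibble(mapping)
  names(mapping)[1:2] <- c("accession", "target")
  if (anyDuplicated(mapping$target) || anyDuplicated(mapping$accession)) {
    stop("id mapping must be injective (one accession per target and vice versa)",
         call. = FALSE)
  }
  m <- match(records$object_id, mapping$accession)
  dropped <- sum(is.na(m))
  if (dropped > 0) {
    warning("dropped ", dropped, " record(s) with unmapped accessions",
            call. = FALSE)
  }
  records %>%
    dplyr::mutate(object_id = mapping$target[m]) %>%
    dplyr::filter(!is.na(.data$object_id))
}

#' Build an annotation snapshot
#'
#' Turns filtered, id-mapped records into a snapshot: one row per
#' (protein, term, aspect), with the aspect taken from the ontology.
#' Terms are resolved through the alternate-id map; unresolvable terms are
#' dropped with a warning. With `propagate = TRUE` (the default) every
#' per-protein set is replaced by its ancestral closure, minus aspect roots.
#'
#' @param records Record tibble (post [filter_experimental()] / [map_ids()]).
#' @param ontology A `go_ontology`.
#' @param propagate Propagate to ancestors? Default `TRUE`.
#' @param label Free-text timestamp label stored on the snapshot
#'   (e.g. `"ts"`, `"tB25"`).
#' @return A `go_snapshot`: tibble (`protein`, `term`, `aspect`) with
#'   attributes `propagated` and `label`.
#' @export
build_snapshot <- function(records, ontology, propagate = TRUE, label = "") {
  stopifnot(inherits(ontology, "go_ontology"))
  res <- resolve_terms(ontology, records$term)
  if (anyNA(res)) {
    warning("dropped ", sum(is.na(res)),
            " annotation(s) to terms absent from the ontology: ",
            paste(unique(records$term[is.na(res)]), collapse = ", "),
            call. = FALSE)
  }
  # hot path (called once per simulated fixture): plain vector ops
  keep <- !is.na(res)
  protein <- records$object_id[keep]
  term <- res[keep]
  dup <- duplicated(paste0(protein, "\r", term))
  protein <- protein[!dup]; term <- term[!dup]

  if (propagate && length(term)) {
    anc <- ontology$ancestors[term]
    protein <- rep(protein, lengths(anc))
    term <- unlist(anc, use.names = FALSE)
    dup <- duplicated(paste0(protein, "\r", term))
    keep <- !dup & !term %in% unname(ontology$roots)
    protein <- protein[keep]; term <- term[keep]
  }
  aspect_of <- setNames(ontology$terms$aspect, ontology$terms$term)
  aspect <- unname(aspect_of[term])
  ord <- order(protein, aspect, term)
  snap <- tibble::tibble(protein = protein[ord], term = term[ord],
                         aspect = aspect[ord])
  new_snapshot(snap, propagated = propagate, label = label)
}

new_snapshot <- function(tbl, propagated, label = "") {
  structure(
    tibble::as_tibble(tbl),
    propagated = propagated,
    label = label,
    class = c("go_snapshot", class(tibble::tibble()))
  )
}

#' Snapshot exchange format
#'
#' Writes/reads the three-column TSV exchange format (`protein`, `term`,
#' `aspect`, one header line). Round-trips bit-exactly.
#'
#' @param snapshot A `go_snapshot`.
#' @param path File path.
#' @return `write_snapshot()`: `path` invisibly. `read_snapshot()`: a
#'   `go_snapshot`.
#' @param propagated Flag recorded on the snapshot read back (the format
#'   itself does not store it).
#' @param label Timestamp label for the snapshot read back.
#' @export
write_snapshot <- function(snapshot, path) {
  readr::write_tsv(tibble::as_tibble(snapshot)[, c("protein", "term", "aspect")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path, propagated = TRUE, label = "") {
  tbl <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  stopifnot(identical(names(tbl), c("protein", "term", "aspect")))
  new_snapshot(tbl, propagated = propagated, label = label)
}
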