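#' Read a prediction file
#'
#' Reads per-protein scored term lists from either the community submission
#' format (header lines `AUTHOR`, `MODEL`, `KEYWORDS`; whitespace-separated
#' data rows `target term score`; `END` footer) or a headerless
#' three-column TSV. Scores must lie in the half-open interval (0, 1];
#' rows outside it are rejected and counted. Duplicate (protein, term)
#' rows collapse to the maximum score with a warning - a deterministic,
#' order-independent rule. A `MODEL` index above 3 is an error: a team may
#' field at most three methods.
#'
#' @param path Prediction file.
#' @param format `"auto"` (detect an `AUTHOR` header), `"cafa"` or `"tsv"`.
#' @return A `go_predictions`: tibble (`protein`, `term`, `score`) with
#'   attributes `team`, `model`, `method_id` and `propagated = FALSE`.
#' @export
read_predictions <- function(path, format = c("auto", "cafa", "tsv")) {
  format <- match.arg(format)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "auto") {
    format <- if (length(lines) && grepl("^AUTHOR\\b", lines[1])) "cafa" else "tsv"
  }

  team <- NA_character_; model <- NA_integer_; keywords <- character()
  if (format == "cafa") {
    hdr <- grepl("^(AUTHOR|MODEL|KEYWORDS|END)\\b", lines)
    team <- sub("^AUTHOR\\s+", "", grep("^AUTHOR\\b", lines, value = TRUE)[1])
    model_lines <- grep("^MODEL\\b", lines, value = TRUE)
    if (length(model_lines) > 1) {
      stop("multiple MODEL blocks in one file are not supported", call. = FALSE)
    }
    if (length(model_lines)) {
      model <- as.integer(sub("^MODEL\\s+", "", model_lines[1]))
      if (is.na(model) || model > 3L) {
        stop("MODEL index must be 1-3 (at most three methods per team)",
             call. = FALSE)
      }
    }
    keywords <- sub("^KEYWORDS\\s+", "",
                    grep("^KEYWORDS\\b", lines, value = TRUE))
    lines <- lines[!hdr]
  }

  fields <- stringr::str_split(trimws(lines), "\\s+")
  ok_shape <- lengths(fields) == 3
  rows <- purrr::map_dfr(fields[ok_shape], ~ tibble::tibble(
    protein = .x[1], term = .x[2], score = suppressWarnings(as.numeric(.x[3]))
  ))
  if (!nrow(rows)) {
    rows <- tibble::tibble(protein = character(), term = character(),
                           score = numeric())
  }
  bad_score <- is.na(rows$score) | rows$score <= 0 | rows$score > 1
  n_rej <- sum(!ok_shape) + sum(bad_score)
  if (n_rej > 0) {
    warning("rejected ", n_rej, " prediction row(s) (malformed or score ",
            "outside (0,1])", call. = FALSE)
  }
  rows <- rows[!bad_score, ]

  dups <- anyDuplicated(rows[, c("protein", "term")])
  if (dups) {
    warning("collapsed duplicate (protein, term) rows to the maximum score",
            call. = FALSE)
    rows <- rows %>%
      dplyr::group_by(.data$protein, .data$term) %>%
      dplyr::summarise(score = max(.data$score), .groups = "drop")
  }
  new_predictions(rows, team = team, model = model,
                  keywords = keywords, propagated = FALSE)
}

new_predictions <- function(tbl, team = NA_character_, model = NA_integer_,
                            keywords = character(), propagated = FALSE) {
  structure(
    tibble::as_tibble(tbl),
    team = team, model = model, keywords = keywords,
    method_id = if (is.na(team)) NA_character_ else paste0(team, "-", model),
    propagated = propagated,
    class = c("go_predictions", class(tibble::tibble()))
  )
}

#' Write predictions in the community submission format
#'
#' @param predictions A `go_predictions`.
#' @param path Output path.
#' @param team,model Header values (default from the object's attributes).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path,
                              team = attr(predictions, "team"),
                              model = attr(predictions, "model")) {
  tbl <- tibble::as_tibble(predictions)
  readr::write_lines(c(
    paste("AUTHOR", if (is.na(team)) "anonymous" else team),
    paste("MODEL", if (is.na(model)) 1L else model),
    "KEYWORDS synthetic.",
    sprintf("%s\t%s\t%.6f", tbl$protein, tbl$term, tbl$score),
    "END"
  ), path)
  invisible(path)
}

#' Resolve and restrict predicted terms to one aspect
#'
#' Resolves predicted terms through the ontology's alternate-id map, then
#' drops (with a counted warning) predictions on unresolvable terms, on
#' terms outside the evaluation aspect, and on the aspect root (root terms
#' are excluded from evaluation).
#'
#' @param predictions A `go_predictions`.
#' @param ontology A `go_ontology`.
#' @param aspect Evaluation aspect.
#' @return A `go_predictions` restricted to valid terms of the aspect.
#' @export
validate_predictions <- function(predictions, ontology, aspect) {
  aspect <- match.arg(aspect, c("MF", "BP", "CC"))
  tbl <- tibble::as_tibble(predictions)
  res <- resolve_terms(ontology, tbl$term)
  aspect_of <- setNames(ontology$terms$aspect, ontology$terms$term)
  keep <- !is.na(res) & aspect_of[res] == aspect &
    !res %in% unname(ontology$roots)
  if (any(!keep)) {
    warning("dropped ", sum(!keep), " prediction(s) on unresolvable, ",
            "out-of-aspect or root terms", call. = FALSE)
  }
  tbl$term <- res
  tbl <- tbl[keep, ]
  # resolution can merge an alt id with its primary: re-collapse to max
  if (anyDuplicated(tbl[, c("protein", "term")])) {
    tbl <- tbl %>%
      dplyr::group_by(.data$protein, .data$term) %>%
      dplyr::summarise(score = max(.data$score), .groups = "drop")
  }
  new_predictions(tbl, team = attr(predictions, "team"),
                  model = attr(predictions, "model"),
                  keywords = attr(predictions, "keywords"),
                  propagated = attr(predictions, "propagated") %||% FALSE)
}

#' Propagate prediction scores to ancestors
#'
#' Gives every ancestor of a predicted term a score at least as high as the
#' term's own: each term's propagated score is the maximum over itself and
#' all stored descendants. This is the established propagation rule for
#' ontology-structured predictions: it preserves the (0,1] range and makes
#' every thresholded set ancestor-closed. Aspect roots are not stored.
#' Idempotent; never lowers a stored score.
#'
#' @param predictions A `go_predictions` (validated).
#' @param ontology A `go_ontology`.
#' @return A `go_predictions` with `propagated = TRUE`.
#' @export
propagate_scores <- function(predictions, ontology) {
  tbl <- tibble::as_tibble(predictions)
  if (nrow(tbl)) {
    tbl <- tbl %>%
      dplyr::mutate(term = unname(ontology$ancestors[.data$term])) %>%
      tidyr::unchop("term") %>%
      dplyr::filter(!.data$term %in% unname(ontology$roots)) %>%
      dplyr::group_by(.data$protein, .data$term) %>%
      dplyr::summarise(score = max(.data$score), .groups = "drop")
  }
  new_predictions(tbl, team = attr(predictions, "team"),
                  model = attr(predictions, "model"),
                  keywords = attr(predictions, "keywords"),
                  propagated = TRUE)
}

#' Naive term-frequency baseline
#'
#' The prior-only predictor: every target receives, for every non-root term
#' of the aspect, the relative frequency of that term among the annotated
#' proteins of a propagated reference snapshot. All targets get identical
#' score vectors.
#'
#' @param reference A propagated `go_snapshot`.
#' @param ontology A `go_ontology`.
#' @param targets Character vector of target ids to predict on.
#' @param aspect Evaluation aspect.
#' @return A propagated `go_predictions` labelled team `"Naive"`.
#' @export
naive_baseline <- function(reference, ontology, targets, aspect) {
  aspect <- match.arg(aspect, c("MF", "BP", "CC"))
  ref <- tibble::as_tibble(reference)
  ref <- ref[ref$aspect == aspect, ]
  if (!nrow(ref)) stop("reference has no annotations in aspect ", aspect,
                       call. = FALSE)
  n_ref <- length(unique(ref$protein))
  freq <- ref %>%
    dplyr::distinct(.data$protein, .data$term) %>%
    dplyr::count(.data$term, name = "k") %>%
    dplyr::mutate(score = .data$k / n_ref) %>%
    dplyr::filter(!.data$term %in% unname(ontology$roots))
  tbl <- tidyr::expand_grid(protein = targets, freq[, c("term", "score")])
  new_predictions(tbl, team = "Naive", model = 1L, propagated = TRUE)
}

#' Sequence-similarity transfer baseline
#'
#' BLAST-style annotation transfer from a precomputed similarity hit table:
#' a target's score for a term is the maximum percent identity (divided by
#' 100) over its hits to reference proteins carrying that term. Targets
#' with no hits receive no predictions, which lowers the method's coverage.
#' The alignment step itself is upstream; this consumes its tabular output.
#'
#' @param hits Tibble/data frame with columns `target`, `reference`,
#'   `identity` (percent identity in (0, 100]; rows outside are rejected
#'   with a warning).
#' @param reference A propagated `go_snapshot` annotating the hit subjects.
#' @return A propagated `go_predictions` labelled team `"BLAST"` (all
#'   aspects mixed; restrict with [validate_predictions()]).
#' @export
similarity_baseline <- function(hits, reference) {
  hits <- tibble::as_tibble(hits)
  names(hits)[1:3] <- c("target", "reference", "identity")
  bad <- !is.finite(hits$identity) | hits$identity <= 0 | hits$identity > 100
  if (any(bad)) {
    warning("rejected ", sum(bad), " hit(s) with identity outside (0,100]",
            call. = FALSE)
    hits <- hits[!bad, ]
  }
  ref <- tibble::as_tibble(reference)[, c("protein", "term")]
  tbl <- hits %>%
    dplyr::inner_join(ref, by = c(reference = "protein"),
                      relationship = "many-to-many") %>%
    dplyr::group_by(protein = .data$target, .data$term) %>%
    dplyr::summarise(score = max(.data$identity) / 100, .groups = "drop")
  new_predictions(tbl, team = "BLAST", model = 1L, propagated = TRUE)
}
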