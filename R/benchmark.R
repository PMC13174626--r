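#' Classify proteins into evaluation settings
#'
#' Assigns each (protein, aspect) pair one of the time-delayed evaluation
#' settings, comparing the propagated experimental annotations at the
#' submission deadline (`snapshot_ts`) with those at benchmark time
#' (`snapshot_tb`):
#'
#' * `NK` (No Knowledge): no experimental annotation in *any* aspect at ts,
#'   and terms gained in the evaluation aspect by tB;
#' * `LK` (Limited Knowledge): no annotation in the evaluation aspect at
#'   ts, but some in at least one other aspect, and terms gained in the
#'   evaluation aspect by tB;
#' * `PK` (Partial Knowledge): annotations in the evaluation aspect at ts,
#'   regardless of other aspects, and a strictly larger propagated set in
#'   that aspect by tB;
#' * `none`: no new terms gained in the aspect.
#'
#' Both snapshots are expected to be filtered to experimental evidence,
#' id-mapped and propagated. Annotations present at ts but retracted by tB
#' are tolerated (the gained set is a plain set difference) and can be
#' inspected with `dplyr::anti_join(ts, tb)`.
#'
#' @param snapshot_ts,snapshot_tb Propagated `go_snapshot`s at deadline and
#'   benchmark time.
#' @param aspects Aspects to classify; defaults to those present in either
#'   snapshot.
#' @return Tibble (`protein`, `aspect`, `setting`) covering every protein
#'   seen in either snapshot crossed with `aspects`; `setting` is one of
#'   `"NK"`, `"LK"`, `"PK"`, `"none"`.
#' @export
classify_proteins <- function(snapshot_ts, snapshot_tb,
                              aspects = NULL) {
  ts <- tibble::as_tibble(snapshot_ts)
  tb <- tibble::as_tibble(snapshot_tb)
  aspects <- aspects %||% sort(unique(c(ts$aspect, tb$aspect)))
  proteins <- sort(unique(c(ts$protein, tb$protein)))

  key <- function(p, a) paste0(p, "\r", a)
  ts_key3 <- paste0(ts$protein, "\r", ts$term, "\r", ts$aspect)
  tb_key3 <- paste0(tb$protein, "\r", tb$term, "\r", tb$aspect)
  new_rows <- !(tb_key3 %in% ts_key3)
  gained_keys <- unique(key(tb$protein[new_rows], tb$aspect[new_rows]))
  ts_keys <- unique(key(ts$protein, ts$aspect))
  any_ts <- unique(ts$protein)

  grid_protein <- rep(proteins, each = length(aspects))
  grid_aspect <- rep(aspects, times = length(proteins))
  gk <- key(grid_protein, grid_aspect)
  gained <- gk %in% gained_keys
  has_ts <- gk %in% ts_keys
  setting <- ifelse(!gained, "none",
                    ifelse(has_ts, "PK",
                           ifelse(grid_protein %in% any_ts, "LK", "NK")))
  tibble::tibble(protein = grid_protein, aspect = grid_aspect,
                 setting = setting)
}

#' Assemble a benchmark set
#'
#' Builds the evaluation set B for one (aspect, setting) pair: the proteins
#' classified into that setting by [classify_proteins()], each carrying its
#' prior knowledge (the propagated deadline-time terms in the aspect;
#' empty for NK/LK) and its gained truth (propagated benchmark-time terms
#' minus propagated deadline-time terms). The difference is taken *after*
#' propagation, so a new leaf under an already-annotated branch contributes
#' only its novel ancestors; proteins whose propagated set did not grow are
#' excluded.
#'
#' @param snapshot_ts,snapshot_tb Propagated `go_snapshot`s.
#' @param ontology A `go_ontology` (used for validation of aspect labels).
#' @param aspect `"MF"`, `"BP"` or `"CC"`.
#' @param setting `"NK"`, `"LK"`, `"PK"` or `"NK+LK"`.
#' @return A `go_benchmark`: tibble (`protein`, `term`, `role`) with
#'   `role` in `{"prior", "gained"}` and attributes `aspect`, `setting`,
#'   `proteins`, `n`.
#' @export
build_benchmark <- function(snapshot_ts, snapshot_tb, ontology,
                            aspect, setting = c("NK+LK", "NK", "LK", "PK")) {
  aspect <- match.arg(aspect, c("MF", "BP", "CC"))
  setting <- match.arg(setting)
  wanted <- if (setting == "NK+LK") c("NK", "LK") else setting

  cls <- classify_proteins(snapshot_ts, snapshot_tb, aspects = aspect)
  members <- cls$protein[cls$setting %in% wanted]
  if (!length(members)) {
    stop("empty benchmark for aspect ", aspect, ", setting ", setting,
         call. = FALSE)
  }

  ts <- tibble::as_tibble(snapshot_ts)
  tb <- tibble::as_tibble(snapshot_tb)
  pi <- ts$aspect == aspect & ts$protein %in% members
  prior <- tibble::tibble(protein = ts$protein[pi], term = ts$term[pi],
                          role = "prior")
  gi <- tb$aspect == aspect & tb$protein %in% members
  gkey <- paste0(tb$protein[gi], "\r", tb$term[gi])
  pkey <- paste0(prior$protein, "\r", prior$term)
  new <- !(gkey %in% pkey)
  gained <- tibble::tibble(protein = tb$protein[gi][new],
                           term = tb$term[gi][new], role = "gained")

  truth <- dplyr::bind_rows(prior, gained)
  truth <- truth[order(truth$protein, truth$role, truth$term), ]
  new_benchmark(truth, aspect = aspect, setting = setting,
                proteins = sort(members))
}

new_benchmark <- function(truth, aspect, setting, proteins) {
  truth <- tibble::tibble(protein = truth$protein, term = truth$term,
                          role = truth$role)
  stopifnot(all(truth$protein %in% proteins))
  gained_by <- unique(truth$protein[truth$role == "gained"])
  if (!setequal(gained_by, proteins)) {
    stop("benchmark invariant violated: protein(s) without gained truth: ",
         paste(setdiff(proteins, gained_by), collapse = ", "), call. = FALSE)
  }
  structure(
    tibble::as_tibble(truth),
    aspect = aspect, setting = setting,
    proteins = proteins, n = length(proteins),
    class = c("go_benchmark", class(tibble::tibble()))
  )
}

#' @export
print.go_benchmark <- function(x, ...) {
  cat("<go_benchmark> aspect ", attr(x, "aspect"), ", setting ",
      attr(x, "setting"), ", n = ", attr(x, "n"), " proteins, ",
      sum(x$role == "gained"), " gained / ", sum(x$role == "prior"),
      " prior annotations\n", sep = "")
  invisible(x)
}

#' Benchmark exchange format
#'
#' A benchmark is written as a TSV pair in `dir`: a membership list
#' (`<stem>_proteins.tsv`, one column) and a truth table
#' (`<stem>_truth.tsv`: `protein`, `term`, `role`). The stem encodes aspect
#' and setting, e.g. `MF_NK+LK`.
#'
#' @param benchmark A `go_benchmark`.
#' @param dir Directory (created if needed).
#' @return `write_benchmark()`: the stem path, invisibly.
#'   `read_benchmark()`: a `go_benchmark`.
#' @export
write_benchmark <- function(benchmark, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, paste0(attr(benchmark, "aspect"), "_",
                                attr(benchmark, "setting")))
  readr::write_tsv(tibble::tibble(protein = attr(benchmark, "proteins")),
                   paste0(stem, "_proteins.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(benchmark)[, c("protein", "term", "role")],
                   paste0(stem, "_truth.tsv"), progress = FALSE)
  invisible(stem)
}

#' @rdname write_benchmark
#' @param dir Directory holding the TSV pair.
#' @param aspect,setting Which benchmark to read back.
#' @export
read_benchmark <- function(dir, aspect, setting) {
  stem <- file.path(dir, paste0(aspect, "_", setting))
  proteins <- readr::read_tsv(paste0(stem, "_proteins.tsv"),
                              col_types = "c", progress = FALSE)$protein
  truth <- readr::read_tsv(paste0(stem, "_truth.tsv"),
                           col_types = "ccc", progress = FALSE)
  new_benchmark(truth, aspect = aspect, setting = setting,
                proteins = sort(proteins))
}
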