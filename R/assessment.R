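#' Evaluate one prediction method on a benchmark
#'
#' The full per-method pipeline: read the prediction file (or take a
#' `go_predictions` directly), restrict it to the benchmark's aspect
#' ([validate_predictions()]), propagate scores to ancestors
#' ([propagate_scores()]), sweep thresholds ([sweep_curve()]) and
#' summarise with [fmax()] (both flavours), [smin()] and [coverage()].
#'
#' @param predictions Path to a prediction file, or a `go_predictions`.
#' @param benchmark A `go_benchmark`.
#' @param ontology A `go_ontology`.
#' @param ia Optional `term_ia` table (required for a meaningful Smin).
#' @param mode `"complete"` or `"incomplete"`.
#' @param novelty_only Passed to [sweep_curve()].
#' @return A `funbench_eval` object; see [tidy.funbench_eval()] /
#'   [glance.funbench_eval()] for tabular views and [autoplot.funbench_eval()]
#'   for the curves.
#' @export
#' @examples
#' fix <- simulate_fixture(fixture_spec(n_proteins = 12, seed = 7))
#' ev <- evaluate_method(fix$predictions[["q1.00"]], fix$benchmark,
#'                       fix$ontology, fix$ia)
#' glance(ev)
evaluate_method <- function(predictions, benchmark, ontology, ia = NULL,
                            mode = c("complete", "incomplete"),
                            novelty_only = FALSE) {
  mode <- match.arg(mode)
  if (is.character(predictions)) predictions <- read_predictions(predictions)
  aspect <- attr(benchmark, "aspect")
  pred <- validate_predictions(predictions, ontology, aspect)
  pred <- propagate_scores(pred, ontology)
  curve <- sweep_curve(pred, benchmark, ia = ia, mode = mode,
                       novelty_only = novelty_only)
  fm <- fmax(curve, "macro")
  fu <- fmax(curve, "micro")
  sm <- smin(curve)
  structure(
    list(
      team = attr(predictions, "team"),
      model = attr(predictions, "model"),
      method_id = attr(predictions, "method_id"),
      aspect = aspect,
      setting = attr(benchmark, "setting"),
      mode = mode,
      n = attr(benchmark, "n"),
      curve = curve,
      fmax_macro = fm$fmax, tau_macro = fm$tau,
      fmax_micro = fu$fmax, tau_micro = fu$tau,
      smin = if (is.null(ia)) NA_real_ else sm$smin,
      tau_smin = if (is.null(ia)) NA_real_ else sm$tau,
      coverage = coverage(pred, benchmark)
    ),
    class = "funbench_eval"
  )
}

#' @export
print.funbench_eval <- function(x, ...) {
  cat("<funbench_eval> ", x$method_id %||% "(unnamed)", " on ", x$aspect,
      "/", x$setting, " (", x$mode, " mode, n = ", x$n, ")\n", sep = "")
  cat(sprintf("  Fmax (macro) %.4f @ tau=%.3g | Fmax (micro) %.4f @ tau=%.3g\n",
              x$fmax_macro, x$tau_macro, x$fmax_micro, x$tau_micro))
  if (!is.na(x$smin)) {
    cat(sprintf("  Smin %.4f bits @ tau=%.3g\n", x$smin, x$tau_smin))
  }
  cat(sprintf("  coverage %.3f\n", x$coverage))
  invisible(x)
}

#' Select each team's best method
#'
#' A team may field up to three methods; for reporting, the one with the
#' best value of the chosen metric on the benchmark represents the team
#' (highest Fmax; lowest Smin). Ties go to the lowest model index.
#'
#' @param results Tibble of per-method summaries (as rows of
#'   [glance.funbench_eval()] output), with columns `team`, `model` and the
#'   metric columns.
#' @param metric `"fmax_macro"`, `"fmax_micro"` or `"smin"`.
#' @return One row per team.
#' @export
select_team_best <- function(results,
                             metric = c("fmax_macro", "fmax_micro", "smin")) {
  metric <- match.arg(metric)
  sgn <- if (metric == "smin") 1 else -1
  results %>%
    dplyr::group_by(.data$team) %>%
    dplyr::arrange(sgn * .data[[metric]], .data$model, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()
}

#' Bootstrap confidence interval for an evaluation metric
#'
#' Resamples the benchmark proteins with replacement `n_iter` times,
#' recomputes the metric on every resample (the threshold sweep is redone
#' per resample over the union grid of distinct scores, on which the
#' resampled curves are exact), and returns the 2.5th and 97.5th
#' percentiles of the resampled values. Percentiles use linear
#' interpolation between order statistics (type-7 quantiles).
#' Deterministic given `seed`.
#'
#' @param predictions A `go_predictions` (validated + propagated, or raw -
#'   it is put through the same pipeline as [evaluate_method()]).
#' @param benchmark A `go_benchmark`.
#' @param ontology A `go_ontology`.
#' @param ia Optional `term_ia` (required for `metric = "smin"`).
#' @param metric `"fmax_macro"`, `"fmax_micro"` or `"smin"`.
#' @param n_iter Number of bootstrap iterations (1000 in standard use).
#' @param seed Integer RNG seed.
#' @param mode Evaluation mode.
#' @return A `bootstrap_ci` list: `point`, `lo`, `hi`, `n_iter`, `seed`,
#'   `metric`, plus the resample vector in `$samples`.
#' @export
bootstrap_ci <- function(predictions, benchmark, ontology, ia = NULL,
                         metric = c("fmax_macro", "fmax_micro", "smin"),
                         n_iter = 1000, seed = 1,
                         mode = c("complete", "incomplete")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  stopifnot(n_iter >= 1)
  if (metric == "smin" && is.null(ia)) {
    stop("metric = \"smin\" requires an ia table", call. = FALSE)
  }
  pred <- validate_predictions(predictions, ontology, attr(benchmark, "aspect"))
  pred <- propagate_scores(pred, ontology)
  st <- sweep_stats(pred, benchmark, ia = ia)

  metric_from <- function(w) {
    curve <- curve_from_stats(st, mode = mode, w = w)
    switch(metric,
           fmax_macro = fmax(curve, "macro")$fmax,
           fmax_micro = fmax(curve, "micro")$fmax,
           smin = smin(curve)$smin)
  }
  point <- metric_from(rep(1, st$n))

  samples <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(st$n, st$n, replace = TRUE)
      metric_from(tabulate(idx, nbins = st$n))
    }, numeric(1))
  })
  qs <- unname(quantile(samples, c(0.025, 0.975), type = 7))
  structure(
    list(point = point, lo = qs[1], hi = qs[2], n_iter = n_iter,
         seed = seed, metric = metric, samples = samples),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> %s = %.4f [%.4f, %.4f] (%d iterations, seed %d)\n",
              x$metric, x$point, x$lo, x$hi, x$n_iter, x$seed))
  invisible(x)
}

# Stable per-method RNG stream derived from a master seed, so adding or
# reordering methods never perturbs another method's interval.
derive_seed <- function(master, key) {
  h <- sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 31 + 1))
  as.integer((as.numeric(master) * 10007 + h) %% .Machine$integer.max)
}

#' Rank methods on a benchmark
#'
#' Produces a leaderboard from per-method evaluations: team-best selection
#' ([select_team_best()]), ordering by the metric (descending for Fmax,
#' ascending for Smin), truncation to the top `top_k` teams, and optional
#' bootstrap confidence intervals. Baseline methods (teams in `baselines`)
#' are always appended regardless of rank. Ranking ties are broken by
#' higher coverage, then lexicographic team name, so leaderboards are
#' deterministic.
#'
#' @param evaluations List of `funbench_eval` objects (the candidate
#'   methods, all on the same benchmark).
#' @param metric `"fmax_macro"`, `"fmax_micro"` or `"smin"`.
#' @param top_k Number of teams to keep (baselines excluded from the
#'   count). Default 10.
#' @param baselines Character vector of team names treated as baselines.
#' @param bootstrap If non-`NULL`, a list of the arguments needed to attach
#'   CIs: `predictions` (named list of `go_predictions` keyed by
#'   `method_id`), `benchmark`, `ontology`, `ia`, `n_iter`, `seed` (master
#'   seed; each method gets a derived stream).
#' @return A tibble leaderboard (`rank`, `team`, `model`, metric value,
#'   `lo`, `hi`, `coverage`, `is_baseline`).
#' @export
rank_methods <- function(evaluations,
                         metric = c("fmax_macro", "fmax_micro", "smin"),
                         top_k = 10, baselines = c("Naive", "BLAST"),
                         bootstrap = NULL) {
  metric <- match.arg(metric)
  tbl <- purrr::map_dfr(evaluations, glance)
  best <- select_team_best(tbl, metric)
  sgn <- if (metric == "smin") 1 else -1
  best <- best %>%
    dplyr::mutate(is_baseline = .data$team %in% baselines) %>%
    dplyr::arrange(sgn * .data[[metric]], dplyr::desc(.data$coverage),
                   .data$team)

  ranked <- best %>%
    dplyr::filter(!.data$is_baseline) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::slice_head(n = top_k)
  board <- dplyr::bind_rows(
    ranked,
    dplyr::filter(best, .data$is_baseline) %>% dplyr::mutate(rank = NA_integer_)
  )

  if (!is.null(bootstrap)) {
    cis <- purrr::map(board$method_id, function(id) {
      bootstrap_ci(
        bootstrap$predictions[[id]], bootstrap$benchmark,
        bootstrap$ontology, ia = bootstrap$ia, metric = metric,
        n_iter = bootstrap$n_iter %||% 1000,
        seed = derive_seed(bootstrap$seed %||% 1, id)
      )
    })
    board$lo <- purrr::map_dbl(cis, "lo")
    board$hi <- purrr::map_dbl(cis, "hi")
  } else {
    board$lo <- NA_real_
    board$hi <- NA_real_
  }
  board %>%
    dplyr::select("rank", "team", "model", "method_id",
                  dplyr::all_of(metric), "lo", "hi", "coverage",
                  "is_baseline")
}
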