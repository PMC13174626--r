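# Per-protein step-function statistics underlying the threshold sweep.
#
# For each benchmark protein and each threshold tau in `thresholds`
# (ascending), the matrices hold counts over the thresholded prediction set
# Pi(tau) = {f : score(i, f) >= tau}, with "effective" meaning Pi(tau)
# minus the protein's prior knowledge:
#   n_eff      |effective|
#   tp_full    |effective intersect TitB|       (precision numerator)
#   tp_gain_eff|effective intersect gained|     (strict-novelty numerator)
#   tp_gain    |Pi(tau) intersect gained|       (recall numerator)
#   ia_mi      sum of ia over Pi(tau) \ TitB    (misinformation)
#   ia_cap     sum of ia over Pi(tau) intersect gained (captured truth)
# Everything downstream (macro/micro pr-rc, ru/mi, Fmax, Smin, bootstrap
# reweighting) is a per-column aggregation of these matrices.
sweep_stats <- function(predictions, benchmark, ia = NULL,
                        thresholds = NULL) {
  stopifnot(inherits(benchmark, "go_benchmark"))
  if (!isTRUE(attr(predictions, "propagated"))) {
    warning("predictions are not flagged as propagated; metrics assume ",
            "ancestor-consistent scores", call. = FALSE)
  }
  proteins <- attr(benchmark, "proteins")
  truth <- tibble::as_tibble(benchmark)
  prior_l <- split(truth$term[truth$role == "prior"],
                   factor(truth$protein[truth$role == "prior"],
                          levels = proteins))
  gained_l <- split(truth$term[truth$role == "gained"],
                    factor(truth$protein[truth$role == "gained"],
                           levels = proteins))

  ia_of <- if (is.null(ia)) NULL else setNames(ia$ia, ia$term)
  ia_val <- function(terms) {
    if (is.null(ia_of)) return(rep(0, length(terms)))
    v <- ia_of[terms]
    v[is.na(v)] <- 0
    unname(v)
  }

  pred <- tibble::as_tibble(predictions)
  pred <- pred[pred$protein %in% proteins, ]
  pred_l <- split(pred[, c("term", "score")],
                  factor(pred$protein, levels = proteins))

  if (is.null(thresholds)) {
    thresholds <- sort(unique(c(pred$score, 1)))
  } else {
    thresholds <- sort(unique(thresholds))
  }
  nt <- length(thresholds)
  np <- length(proteins)

  zeros <- function() matrix(0, np, nt, dimnames = list(proteins, NULL))
  M <- list(n_eff = zeros(), tp_full = zeros(), tp_gain_eff = zeros(),
            tp_gain = zeros(), ia_mi = zeros(), ia_cap = zeros())
  has_pred <- logical(np)

  for (p in seq_len(np)) {
    pp <- pred_l[[p]]
    if (is.null(pp) || nrow(pp) == 0) next
    has_pred[p] <- TRUE
    prior <- prior_l[[p]]
    gained <- gained_l[[p]]
    titb <- c(prior, gained)

    ord <- order(pp$score, decreasing = TRUE)
    sc <- pp$score[ord]
    tm <- pp$term[ord]
    eff <- !(tm %in% prior)
    in_titb <- tm %in% titb
    in_gain <- tm %in% gained
    iav <- ia_val(tm)

    # k(tau) = number of rows with score >= tau
    k <- length(sc) - findInterval(thresholds, sort(sc), left.open = TRUE)
    at <- function(cum) c(0, cum)[k + 1L]
    M$n_eff[p, ] <- at(cumsum(eff))
    M$tp_full[p, ] <- at(cumsum(eff & in_titb))
    M$tp_gain_eff[p, ] <- at(cumsum(eff & in_gain))
    M$tp_gain[p, ] <- at(cumsum(in_gain))
    M$ia_mi[p, ] <- at(cumsum(iav * !in_titb))
    M$ia_cap[p, ] <- at(cumsum(iav * in_gain))
  }

  list(
    thresholds = thresholds,
    M = M,
    has_pred = has_pred,
    gained_size = lengths(gained_l),
    ia_gained = vapply(gained_l, function(g) sum(ia_val(g)), numeric(1)),
    proteins = proteins,
    n = np
  )
}

# Aggregate per-protein statistics into a curve, with optional integer
# resampling weights w (the bootstrap path).
curve_from_stats <- function(st, mode = c("complete", "incomplete"),
                             w = NULL, novelty_only = FALSE) {
  mode <- match.arg(mode)
  w <- w %||% rep(1, st$n)
  M <- st$M
  predicted_on <- M$n_eff[, 1] > 0          # non-empty effective set at min tau

  active <- M$n_eff > 0
  m_tau <- as.vector(crossprod(w, active))

  num <- if (novelty_only) M$tp_gain_eff else M$tp_full
  ratio <- ifelse(active, num / pmax(M$n_eff, 1), 0)
  pr_macro <- ifelse(m_tau > 0, as.vector(crossprod(w, ratio)) / m_tau, 0)
  pr_mic_num <- as.vector(crossprod(w, num))
  pr_mic_den <- as.vector(crossprod(w, M$n_eff))
  pr_micro <- ifelse(pr_mic_den > 0, pr_mic_num / pr_mic_den, 0)

  # recall / ru / mi denominators depend on the evaluation mode
  count_i <- if (mode == "complete") rep(TRUE, st$n) else predicted_on
  wi <- w * count_i
  ne <- sum(wi)

  rc_ratio <- M$tp_gain / st$gained_size     # gained_size >= 1 by invariant
  rc_macro <- if (ne > 0) as.vector(crossprod(wi, rc_ratio)) / ne else
    rep(0, length(m_tau))
  rc_mic_den <- sum(wi * st$gained_size)
  rc_micro <- if (rc_mic_den > 0) as.vector(crossprod(wi, M$tp_gain)) / rc_mic_den else
    rep(0, length(m_tau))

  total_ia <- sum(wi * st$ia_gained)
  ru <- if (ne > 0) (total_ia - as.vector(crossprod(wi, M$ia_cap))) / ne else
    rep(0, length(m_tau))
  mi <- if (ne > 0) as.vector(crossprod(wi, M$ia_mi)) / ne else
    rep(0, length(m_tau))

  structure(
    tibble::tibble(
      tau = st$thresholds,
      pr_macro = pr_macro, rc_macro = rc_macro,
      pr_micro = pr_micro, rc_micro = rc_micro,
      ru = ru, mi = mi, m = m_tau
    ),
    mode = mode, ne = ne, n = sum(w),
    class = c("eval_curve", class(tibble::tibble()))
  )
}

#' Threshold sweep: precision-recall and ru-mi curves
#'
#' Evaluates a propagated prediction set against a benchmark at every
#' decision threshold tau. For protein i, Pi(tau) is the set of terms
#' scored at or above tau; the *effective* prediction set subtracts the
#' protein's prior knowledge (empty in NK/LK, so the subtraction is a
#' no-op there). Per threshold the curve reports:
#'
#' * macro precision: mean, over the m(tau) proteins with a non-empty
#'   effective set, of the fraction of effective terms that are in the
#'   protein's benchmark-time truth;
#' * macro recall: mean over ne proteins of the fraction of gained truth
#'   recovered by Pi(tau);
#' * micro precision/recall: the same numerators and denominators pooled
#'   over proteins before dividing;
#' * ru (remaining uncertainty): mean ia-weight of gained truth missed by
#'   Pi(tau); mi (misinformation): mean ia-weight of predicted terms
#'   outside the benchmark-time truth;
#' * m(tau): the number of proteins with a non-empty effective set.
#'
#' In `"complete"` mode ne = n, the benchmark size; in `"incomplete"` mode
#' ne = m(0), the number of proteins the method predicted on, which
#' restricts the recall/ru/mi averages to those proteins.
#'
#' The default threshold grid is every distinct submitted score plus 1.0,
#' which makes the sweep exact (the curve is a step function changing only
#' at those values); `thresholds = "fixed101"` gives the historical
#' 101-point grid 0.00, 0.01, ..., 1.00 for backward comparability.
#'
#' @param predictions A propagated, validated `go_predictions`.
#' @param benchmark A `go_benchmark` for the same aspect.
#' @param ia Optional `term_ia` table; without it ru/mi are computed with
#'   zero weights (and [smin()] is meaningless).
#' @param mode `"complete"` (default) or `"incomplete"`.
#' @param thresholds `"exact"` (default), `"fixed101"`, or a numeric grid.
#' @param novelty_only Score precision against only the gained truth
#'   rather than the full benchmark-time annotation (see the methods
#'   vignette); default `FALSE`, the literal definition.
#' @return An `eval_curve` tibble with attributes `mode`, `ne`, `n`.
#' @export
sweep_curve <- function(predictions, benchmark, ia = NULL,
                        mode = c("complete", "incomplete"),
                        thresholds = "exact", novelty_only = FALSE) {
  mode <- match.arg(mode)
  grid <- NULL
  if (is.numeric(thresholds)) {
    grid <- thresholds
  } else if (identical(thresholds, "fixed101")) {
    grid <- seq(0, 1, by = 0.01)
  } else if (!identical(thresholds, "exact")) {
    stop("thresholds must be \"exact\", \"fixed101\" or a numeric vector",
         call. = FALSE)
  }
  st <- sweep_stats(predictions, benchmark, ia = ia, thresholds = grid)
  curve_from_stats(st, mode = mode, novelty_only = novelty_only)
}

f1 <- function(pr, rc) ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0)

#' Fmax: the optimal-threshold F-measure
#'
#' The maximum over thresholds of the harmonic mean of precision and
#' recall, in the macro (average of per-protein ratios) or micro (pooled
#' counts) flavour; 0/0 is taken as 0. Ties are broken toward the smallest
#' threshold.
#'
#' @param curve An `eval_curve`.
#' @param flavor `"macro"` or `"micro"`.
#' @return One-row tibble: `flavor`, `fmax`, `tau`.
#' @export
fmax <- function(curve, flavor = c("macro", "micro")) {
  flavor <- match.arg(flavor)
  f <- if (flavor == "macro") f1(curve$pr_macro, curve$rc_macro) else
    f1(curve$pr_micro, curve$rc_micro)
  i <- which.max(f)   # first index among ties; thresholds ascend
  tibble::tibble(flavor = flavor, fmax = f[i], tau = curve$tau[i])
}

#' Smin: minimum semantic distance
#'
#' The minimum over thresholds of the Euclidean norm of the
#' (remaining uncertainty, misinformation) pair,
#' \eqn{\min_\tau \sqrt{ru(\tau)^2 + mi(\tau)^2}}, in bits. ru and mi only
#' have micro versions. Ties are broken toward the smallest threshold.
#'
#' @param curve An `eval_curve` computed with ia weights.
#' @return One-row tibble: `smin`, `tau`.
#' @export
smin <- function(curve) {
  s <- sqrt(curve$ru^2 + curve$mi^2)
  i <- which.min(s)
  tibble::tibble(smin = s[i], tau = curve$tau[i])
}

#' Coverage: fraction of benchmark proteins predicted on
#'
#' The number of benchmark proteins for which the method supplied at least
#' one (in-aspect, validated) score, divided by the benchmark size n.
#'
#' @param predictions A `go_predictions`.
#' @param benchmark A `go_benchmark`.
#' @return A number in \[0, 1\].
#' @export
coverage <- function(predictions, benchmark) {
  proteins <- attr(benchmark, "proteins")
  pred <- tibble::as_tibble(predictions)
  length(intersect(unique(pred$protein), proteins)) / length(proteins)
}

#' Write an evaluation curve as TSV
#'
#' @param curve An `eval_curve`.
#' @param path Output path.
#' @export
write_curve <- function(curve, path) {
  readr::write_tsv(tibble::as_tibble(curve), path, progress = FALSE)
  invisible(path)
}
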