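# Independent brute-force implementations used as oracles. They share no
# code with the package internals: closures are computed by fixpoint
# iteration over the raw edge list, and every per-threshold quantity is
# recomputed from scratch with plain set primitives.

# Ancestral closure by repeated parent expansion (no precomputed maps).
oracle_closure <- function(terms, edges, relations = c("is_a", "part_of"),
                           aspects = NULL, drop = character()) {
  e <- edges[edges$relation %in% relations, , drop = FALSE]
  if (!is.null(aspects)) {
    e <- e[aspects[e$child] == aspects[e$parent], , drop = FALSE]
  }
  out <- unique(terms)
  repeat {
    parents <- unique(e$parent[e$child %in% out])
    grown <- union(out, parents)
    if (setequal(grown, out)) break
    out <- grown
  }
  setdiff(out, drop)
}

# Full evaluation oracle. Inputs are plain lists keyed by protein:
#   scores[[p]]: named numeric vector term -> score
#   prior[[p]], gained[[p]]: character vectors
# ia_map: named numeric term -> bits (absent terms count 0).
# Enumerates every distinct score plus 1 as a threshold and recomputes all
# sums per threshold.
oracle_eval <- function(scores, prior, gained, ia_map = NULL,
                        mode = "complete") {
  proteins <- names(gained)
  taus <- sort(unique(c(unlist(lapply(scores, unname)), 1)))
  iaw <- function(terms) {
    if (is.null(ia_map) || !length(terms)) return(0)
    sum(ifelse(is.na(ia_map[terms]), 0, ia_map[terms]))
  }
  predicted_on <- vapply(proteins, function(p) {
    sc <- scores[[p]]
    length(setdiff(names(sc), prior[[p]])) > 0
  }, logical(1))
  counted <- if (mode == "complete") rep(TRUE, length(proteins)) else
    predicted_on
  ne <- sum(counted)

  rows <- lapply(taus, function(tau) {
    pr_terms <- 0; pr_n <- 0; m <- 0
    mic_tp <- 0; mic_pred <- 0
    rc_sum <- 0; rc_tp <- 0; rc_den <- 0
    ru_sum <- 0; mi_sum <- 0
    for (j in seq_along(proteins)) {
      p <- proteins[j]
      sc <- scores[[p]]
      Pi <- names(sc)[sc >= tau]
      eff <- setdiff(Pi, prior[[p]])
      titb <- union(prior[[p]], gained[[p]])
      if (length(eff) > 0) {
        m <- m + 1
        pr_terms <- pr_terms + length(intersect(eff, titb)) / length(eff)
      }
      mic_tp <- mic_tp + length(intersect(eff, titb))
      mic_pred <- mic_pred + length(eff)
      if (counted[j]) {
        rc_sum <- rc_sum + length(intersect(Pi, gained[[p]])) /
          length(gained[[p]])
        rc_tp <- rc_tp + length(intersect(Pi, gained[[p]]))
        rc_den <- rc_den + length(gained[[p]])
        ru_sum <- ru_sum + iaw(setdiff(gained[[p]], Pi))
        mi_sum <- mi_sum + iaw(setdiff(Pi, titb))
      }
    }
    data.frame(
      tau = tau,
      pr_macro = if (m > 0) pr_terms / m else 0,
      rc_macro = if (ne > 0) rc_sum / ne else 0,
      pr_micro = if (mic_pred > 0) mic_tp / mic_pred else 0,
      rc_micro = if (rc_den > 0) rc_tp / rc_den else 0,
      ru = if (ne > 0) ru_sum / ne else 0,
      mi = if (ne > 0) mi_sum / ne else 0,
      m = m
    )
  })
  curve <- do.call(rbind, rows)
  fm <- function(pr, rc) {
    f <- ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0)
    list(f = max(f), tau = curve$tau[which.max(f)])
  }
  s <- sqrt(curve$ru^2 + curve$mi^2)
  list(
    curve = curve,
    fmax_macro = fm(curve$pr_macro, curve$rc_macro)$f,
    fmax_micro = fm(curve$pr_micro, curve$rc_micro)$f,
    smin = min(s), tau_smin = curve$tau[which.min(s)],
    ne = ne
  )
}

# Adapters: package objects -> the plain structures the oracle consumes.
oracle_inputs <- function(predictions, benchmark) {
  proteins <- attr(benchmark, "proteins")
  truth <- tibble::as_tibble(benchmark)
  pred <- tibble::as_tibble(predictions)
  pred <- pred[pred$protein %in% proteins, ]
  scores <- lapply(setNames(proteins, proteins), function(p) {
    q <- pred[pred$protein == p, ]
    setNames(q$score, q$term)
  })
  prior <- lapply(setNames(proteins, proteins), function(p) {
    truth$term[truth$protein == p & truth$role == "prior"]
  })
  gained <- lapply(setNames(proteins, proteins), function(p) {
    truth$term[truth$protein == p & truth$role == "gained"]
  })
  list(scores = scores, prior = prior, gained = gained)
}

oracle_eval_pkg <- function(predictions, benchmark, ia = NULL,
                            mode = "complete") {
  inp <- oracle_inputs(predictions, benchmark)
  ia_map <- if (is.null(ia)) NULL else setNames(ia$ia, ia$term)
  oracle_eval(inp$scores, inp$prior, inp$gained, ia_map, mode)
}

# Conditional-frequency oracle for information accretion: counts sets
# directly, using its own direct-parent lookup from the edge table.
oracle_ia <- function(snapshot, ontology) {
  snap <- tibble::as_tibble(snapshot)
  aspects <- setNames(ontology$terms$aspect, ontology$terms$term)
  roots <- unname(ontology$roots)
  e <- ontology$edges
  e <- e[e$relation %in% ontology$relations &
           aspects[e$child] == aspects[e$parent], , drop = FALSE]
  sets_all <- split(snap$term, snap$protein)
  out <- numeric(0)
  for (t in ontology$terms$term) {
    if (t %in% roots) { out[t] <- 0; next }
    a <- aspects[[t]]
    sets <- lapply(sets_all, function(s) s[aspects[s] == a])
    sets <- sets[lengths(sets) > 0]
    pa <- setdiff(e$parent[e$child == t], roots)
    with_pa <- vapply(sets, function(s) all(pa %in% s), logical(1))
    denom <- sum(with_pa)
    num <- sum(vapply(sets, function(s) all(pa %in% s) && t %in% s,
                      logical(1)))
    out[t] <- if (denom > 0 && num > 0) -log2(num / denom) else Inf
  }
  # cap non-finite values at the per-aspect maximum finite value
  for (a in unique(aspects)) {
    idx <- names(out)[aspects[names(out)] == a]
    bad <- idx[!is.finite(out[idx])]
    if (length(bad)) out[bad] <- max(c(out[idx][is.finite(out[idx])], 0))
  }
  out
}
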