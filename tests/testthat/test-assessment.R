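test_that("the full pipeline scores a perfect and an empty method correctly", {
  fix <- simulate_fixture(fixture_spec(n_proteins = 15, seed = 21))
  ev <- evaluate_method(fix$predictions[["q1.00"]], fix$benchmark,
                        fix$ontology, fix$ia)
  expect_equal(ev$fmax_macro, 1)
  expect_equal(ev$fmax_micro, 1)
  expect_equal(ev$smin, 0)
  expect_equal(ev$coverage, 1)

  empty <- predictions_of(character(), character(), numeric())
  ev0 <- suppressWarnings(
    evaluate_method(empty, fix$benchmark, fix$ontology, fix$ia))
  expect_equal(ev0$coverage, 0)
  expect_equal(ev0$fmax_macro, 0)

  g <- glance(ev)
  expect_equal(nrow(g), 1)
  expect_named(g, c("team", "model", "method_id", "aspect", "setting",
                    "mode", "n", "fmax_macro", "tau_macro", "fmax_micro",
                    "tau_micro", "smin", "tau_smin", "coverage"))
  td <- tidy(ev)
  expect_true(all(c("tau", "pr_macro", "ru") %in% names(td)))
})

test_that("evaluating the Naive baseline through the pipeline is consistent", {
  fix <- simulate_fixture(fixture_spec(n_proteins = 15, seed = 22))
  naive <- naive_baseline(fix$tb, fix$ontology,
                          attr(fix$benchmark, "proteins"), "MF")
  ev <- evaluate_method(naive, fix$benchmark, fix$ontology, fix$ia)
  direct <- sweep_curve(naive, fix$benchmark, ia = fix$ia)
  expect_equal(ev$fmax_macro, fmax(direct, "macro")$fmax)
  expect_equal(ev$smin, smin(direct)$smin)
  expect_equal(ev$coverage, 1)
})

test_that("team-best selection maximizes Fmax, minimizes Smin, breaks ties low", {
  results <- tibble::tibble(
    team = c("a", "a", "a", "b", "b", "c", "c"),
    model = c(1L, 2L, 3L, 1L, 2L, 1L, 2L),
    fmax_macro = c(0.4, 0.6, 0.5, 0.3, 0.3, 0.2, 0.1),
    smin = c(3, 2.5, 2.8, 2.0, 1.5, 4, 4)
  )
  best_f <- select_team_best(results, "fmax_macro")
  expect_equal(best_f$model[best_f$team == "a"], 2L)
  expect_equal(best_f$model[best_f$team == "b"], 1L)  # tie -> model 1

  best_s <- select_team_best(results, "smin")
  expect_equal(best_s$model[best_s$team == "b"], 2L)  # smaller smin wins
  expect_equal(best_s$model[best_s$team == "c"], 1L)
  # never worse than any of the team's own records
  for (tm in unique(results$team)) {
    expect_equal(best_f$fmax_macro[best_f$team == tm],
                 max(results$fmax_macro[results$team == tm]))
  }
})

test_that("bootstrap intervals are deterministic and degenerate correctly", {
  fix <- simulate_fixture(fixture_spec(n_proteins = 12, seed = 23,
                                       predictor_quality = 0.5))
  pred <- fix$predictions[["q0.50"]]
  ci1 <- bootstrap_ci(pred, fix$benchmark, fix$ontology, fix$ia,
                      metric = "fmax_macro", n_iter = 100, seed = 7)
  ci2 <- bootstrap_ci(pred, fix$benchmark, fix$ontology, fix$ia,
                      metric = "fmax_macro", n_iter = 100, seed = 7)
  expect_identical(ci1$samples, ci2$samples)
  expect_identical(c(ci1$lo, ci1$hi), c(ci2$lo, ci2$hi))
  expect_lte(ci1$lo, ci1$hi)

  # a benchmark of identical copies of one protein: zero-width interval
  prot <- attr(fix$benchmark, "proteins")[1]
  truth <- tibble::as_tibble(fix$benchmark)
  truth1 <- truth[truth$protein == prot, ]
  clones <- paste0(prot, "_", 1:6)
  btruth <- dplyr::bind_rows(lapply(clones, function(p) {
    dplyr::mutate(truth1, protein = p)
  }))
  bench1 <- funbench:::new_benchmark(btruth, aspect = "MF",
                                     setting = "NK+LK", proteins = clones)
  ptbl <- tibble::as_tibble(pred)
  ptbl1 <- ptbl[ptbl$protein == prot, ]
  pclone <- funbench:::new_predictions(
    dplyr::bind_rows(lapply(clones, function(p) {
      dplyr::mutate(ptbl1, protein = p)
    })), team = "clone", model = 1L, propagated = TRUE)
  ci <- bootstrap_ci(pclone, bench1, fix$ontology, fix$ia,
                     metric = "fmax_macro", n_iter = 50, seed = 1)
  expect_equal(ci$lo, ci$hi)
  expect_equal(ci$lo, ci$point)
})

test_that("bootstrap percentiles match a sort-and-index oracle", {
  fix <- simulate_fixture(fixture_spec(n_proteins = 12, seed = 24))
  ci <- bootstrap_ci(fix$predictions[["q0.80"]], fix$benchmark,
                     fix$ontology, fix$ia, metric = "fmax_macro",
                     n_iter = 200, seed = 3)
  s <- sort(ci$samples)
  interp <- function(p) {
    h <- (length(s) - 1) * p + 1          # type-7 plotting position
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  expect_equal(ci$lo, interp(0.025))
  expect_equal(ci$hi, interp(0.975))
})

test_that("bootstrap reweighting equals re-evaluating the resampled benchmark", {
  # the union threshold grid makes weighted resampling exact: compare one
  # resample computed by weights against a from-scratch evaluation of the
  # duplicated-protein benchmark
  fix <- simulate_fixture(fixture_spec(n_proteins = 8, seed = 25))
  bench <- fix$benchmark
  pred <- fix$predictions[["q0.80"]]
  prots <- attr(bench, "proteins")
  idx <- withr::with_seed(11, sample(seq_along(prots), length(prots),
                                     replace = TRUE))
  w <- tabulate(idx, nbins = length(prots))
  st <- funbench:::sweep_stats(pred, bench, ia = fix$ia)
  got <- fmax(funbench:::curve_from_stats(st, w = w), "macro")$fmax

  # explicit duplication with fresh protein ids
  truth <- tibble::as_tibble(bench)
  ptbl <- tibble::as_tibble(pred)
  dup_truth <- dup_pred <- list()
  for (k in seq_along(idx)) {
    p <- prots[idx[k]]; nm <- paste0("dup", k)
    dup_truth[[k]] <- dplyr::mutate(truth[truth$protein == p, ], protein = nm)
    dup_pred[[k]] <- dplyr::mutate(ptbl[ptbl$protein == p, ], protein = nm)
  }
  bench2 <- funbench:::new_benchmark(dplyr::bind_rows(dup_truth),
                                     aspect = "MF", setting = "NK+LK",
                                     proteins = paste0("dup", seq_along(idx)))
  pred2 <- funbench:::new_predictions(dplyr::bind_rows(dup_pred),
                                      team = "dup", model = 1L,
                                      propagated = TRUE)
  want <- fmax(sweep_curve(pred2, bench2, ia = fix$ia), "macro")$fmax
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("bootstrap intervals usually contain the point estimate", {
  fix <- simulate_fixture(fixture_spec(n_proteins = 30, seed = 26,
                                       predictor_quality = 0.4))
  pred <- fix$predictions[["q0.40"]]
  hits <- vapply(1:10, function(r) {
    ci <- bootstrap_ci(pred, fix$benchmark, fix$ontology, fix$ia,
                       metric = "fmax_macro", n_iter = 200, seed = 100 + r)
    ci$lo <= ci$point && ci$point <= ci$hi
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("leaderboards rank correctly, append baselines, and are deterministic", {
  fix <- simulate_fixture(fixture_spec(n_proteins = 20, seed = 27))
  qualities <- seq(0.05, 0.95, length.out = 12)
  evs <- lapply(seq_along(qualities), function(i) {
    p <- simulate_predictor(fix$benchmark, fix$ontology, qualities[i],
                            seed = 500 + i,
                            team = sprintf("team%02d", i), model = 1L)
    evaluate_method(p, fix$benchmark, fix$ontology, fix$ia)
  })
  naive <- evaluate_method(
    naive_baseline(fix$tb, fix$ontology, attr(fix$benchmark, "proteins"),
                   "MF"),
    fix$benchmark, fix$ontology, fix$ia)

  board <- rank_methods(c(evs, list(naive)), metric = "fmax_macro",
                        top_k = 10)
  expect_equal(sum(!board$is_baseline), 10)   # 12 teams truncated to 10
  expect_true(any(board$is_baseline))         # Naive appended regardless
  expect_equal(board$rank[!board$is_baseline], 1:10)
  expect_true(all(diff(board$fmax_macro[!board$is_baseline]) <= 1e-12))

  sboard <- rank_methods(c(evs, list(naive)), metric = "smin", top_k = 10)
  expect_true(all(diff(sboard$smin[!sboard$is_baseline]) >= -1e-12))

  board2 <- rank_methods(c(evs, list(naive)), metric = "fmax_macro",
                         top_k = 10)
  expect_identical(board, board2)

  # byte-identical leaderboard files from identical inputs
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(board, f1)
  readr::write_tsv(board2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
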