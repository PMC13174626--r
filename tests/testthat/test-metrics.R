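# Metric examples are stated on a flat ontology (every term a direct child
# of the root), so propagation adds nothing and the arithmetic is visible.

test_that("the threshold sweep reproduces hand-enumerated precision/recall", {
  bench <- benchmark_of("MF", prior = list(),
                        gained = list(P1 = c("MF:T1", "MF:T3")))
  pred <- predictions_of(rep("P1", 3), c("MF:T1", "MF:T3", "MF:T2"),
                         c(0.8, 0.5, 0.3))
  curve <- sweep_curve(pred, bench)
  at <- function(tau) curve[curve$tau == tau, ]
  # tau = 0.5: P = {T1, T3}, both true -> pr 1; plus T2 at 0.3 is excluded
  expect_equal(at(0.5)$pr_macro, 1)
  expect_equal(at(0.5)$rc_macro, 1)
  # tau = 0.3: P = {T1, T2, T3} -> pr 2/3, rc 1
  expect_equal(at(0.3)$pr_macro, 2 / 3)
  expect_equal(at(0.3)$rc_macro, 1)
  # tau = 0.8: P = {T1} -> pr 1, rc 1/2
  expect_equal(at(0.8)$pr_macro, 1)
  expect_equal(at(0.8)$rc_macro, 0.5)
  # single protein: micro equals macro everywhere
  expect_equal(curve$pr_micro, curve$pr_macro)
  expect_equal(curve$rc_micro, curve$rc_macro)
  expect_equal(fmax(curve, "macro")$fmax, fmax(curve, "micro")$fmax)
  expect_equal(fmax(curve, "macro")$fmax, 1)
})

test_that("prior knowledge is subtracted from the effective prediction set", {
  bench <- benchmark_of("MF", prior = list(P1 = "MF:T1"),
                        gained = list(P1 = "MF:T3"))
  pred <- predictions_of(c("P1", "P1"), c("MF:T1", "MF:T3"), c(0.9, 0.7))
  curve <- sweep_curve(pred, bench)
  at7 <- curve[curve$tau == 0.7, ]
  # effective set at 0.7 is {T3}: precision 1 and recall 1
  expect_equal(at7$pr_macro, 1)
  expect_equal(at7$rc_macro, 1)
  # at 0.9 only the prior term is predicted: effective empty, m drops to 0
  at9 <- curve[curve$tau == 0.9, ]
  expect_equal(at9$m, 0)
  expect_equal(at9$pr_macro, 0)
})

test_that("a method predicting nothing scores zero everywhere except ru", {
  bench <- benchmark_of("MF", prior = list(),
                        gained = list(P1 = "MF:T1", P2 = "MF:T2"))
  ia <- ia_of(c("MF:T1", "MF:T2"), c(1, 3))
  empty <- predictions_of(character(), character(), numeric())
  curve <- sweep_curve(empty, bench, ia = ia)
  expect_true(all(curve$m == 0))
  expect_true(all(curve$rc_macro == 0))
  expect_true(all(curve$rc_micro == 0))
  expect_true(all(curve$mi == 0))
  expect_equal(unique(curve$ru), 2)  # mean total ia of gained truth
  expect_equal(fmax(curve, "macro")$fmax, 0)
  expect_equal(smin(curve)$smin, 2)
  expect_equal(coverage(empty, bench), 0)
})

test_that("an all-wrong predictor has fmax 0", {
  bench <- benchmark_of("MF", prior = list(), gained = list(P1 = "MF:T1"))
  pred <- predictions_of("P1", "MF:T2", 0.9)
  curve <- sweep_curve(pred, bench)
  expect_equal(fmax(curve, "macro")$fmax, 0)
  expect_equal(fmax(curve, "micro")$fmax, 0)
})

test_that("smin worked examples hold", {
  # empty predictor, one protein, gained {T1} with ia 1 bit -> smin 1
  bench <- benchmark_of("MF", prior = list(), gained = list(P1 = "MF:T1"))
  ia <- ia_of("MF:T1", 1)
  empty <- predictions_of(character(), character(), numeric())
  expect_equal(smin(sweep_curve(empty, bench, ia))$smin, 1)
  # perfect predictor -> ru = mi = 0 somewhere, smin 0
  perfect <- predictions_of("P1", "MF:T1", 1)
  expect_equal(smin(sweep_curve(perfect, bench, ia))$smin, 0)
})

test_that("sweep, fmax and smin agree exactly with the brute-force oracle", {
  for (seed in 1:25) {
    fx <- random_eval_fixture(seed)
    curve <- sweep_curve(fx$predictions, fx$benchmark, ia = fx$ia)
    want <- oracle_eval_pkg(fx$predictions, fx$benchmark, ia = fx$ia)
    expect_equal(curve$tau, want$curve$tau)
    for (col in c("pr_macro", "rc_macro", "pr_micro", "rc_micro",
                  "ru", "mi", "m")) {
      expect_equal(curve[[col]], want$curve[[col]], tolerance = 1e-12)
    }
    expect_equal(fmax(curve, "macro")$fmax, want$fmax_macro,
                 tolerance = 1e-12)
    expect_equal(fmax(curve, "micro")$fmax, want$fmax_micro,
                 tolerance = 1e-12)
    expect_equal(smin(curve)$smin, want$smin, tolerance = 1e-12)
  }
})

test_that("incomplete mode agrees with the oracle and bounds complete-mode recall", {
  hit <- 0
  for (seed in c(3, 6, 9, 12, 15, 18)) {  # seeds whose fixture drops a protein
    fx <- random_eval_fixture(seed)
    if (coverage(fx$predictions, fx$benchmark) == 1) next
    hit <- hit + 1
    cc <- sweep_curve(fx$predictions, fx$benchmark, ia = fx$ia,
                      mode = "complete")
    ci <- sweep_curve(fx$predictions, fx$benchmark, ia = fx$ia,
                      mode = "incomplete")
    want <- oracle_eval_pkg(fx$predictions, fx$benchmark, ia = fx$ia,
                            mode = "incomplete")
    expect_equal(ci$rc_macro, want$curve$rc_macro, tolerance = 1e-12)
    expect_equal(ci$ru, want$curve$ru, tolerance = 1e-12)
    expect_equal(attr(ci, "ne"), want$ne)
    # complete-mode recall can only be lower when coverage < 1
    expect_true(all(cc$rc_macro <= ci$rc_macro + 1e-12))
    expect_true(all(cc$rc_micro <= ci$rc_micro + 1e-12))
  }
  expect_gt(hit, 0)
  # equality at full coverage
  fx <- random_eval_fixture(2)
  expect_equal(coverage(fx$predictions, fx$benchmark), 1)
  cc <- sweep_curve(fx$predictions, fx$benchmark, mode = "complete")
  ci <- sweep_curve(fx$predictions, fx$benchmark, mode = "incomplete")
  expect_equal(cc$rc_macro, ci$rc_macro)
})

test_that("with empty priors the prior-subtracting formulas reduce exactly", {
  for (seed in c(1, 5, 7)) {
    fx <- random_eval_fixture(seed)  # odd seeds -> NK+LK, priors empty
    expect_equal(sum(tibble::as_tibble(fx$benchmark)$role == "prior"), 0)
    plain <- sweep_curve(fx$predictions, fx$benchmark, ia = fx$ia)
    strict <- sweep_curve(fx$predictions, fx$benchmark, ia = fx$ia,
                          novelty_only = TRUE)
    expect_identical(as.data.frame(plain), as.data.frame(strict))
  }
})

test_that("fmax is invariant to strictly monotone score transformations", {
  for (seed in 1:8) {
    fx <- random_eval_fixture(seed)
    tbl <- tibble::as_tibble(fx$predictions)
    warped <- funbench:::new_predictions(
      dplyr::mutate(tbl, score = score^3),  # strictly monotone on (0,1]
      team = "warped", model = 1L, propagated = TRUE
    )
    f0 <- fmax(sweep_curve(fx$predictions, fx$benchmark), "macro")$fmax
    f1 <- fmax(sweep_curve(warped, fx$benchmark), "macro")$fmax
    expect_equal(f0, f1, tolerance = 1e-12)
  }
})

test_that("curves are monotone in the threshold", {
  for (seed in 1:10) {
    fx <- random_eval_fixture(seed)
    curve <- sweep_curve(fx$predictions, fx$benchmark, ia = fx$ia)
    expect_true(all(diff(curve$rc_macro) <= 1e-12))
    expect_true(all(diff(curve$rc_micro) <= 1e-12))
    expect_true(all(diff(curve$m) <= 0))
    expect_true(all(diff(curve$ru) >= -1e-12))
    expect_true(all(diff(curve$mi) <= 1e-12))
  }
})

test_that("the fixed 101-point grid brackets the exact Fmax", {
  fx <- random_eval_fixture(4)
  exact <- fmax(sweep_curve(fx$predictions, fx$benchmark), "macro")$fmax
  grid <- fmax(sweep_curve(fx$predictions, fx$benchmark,
                           thresholds = "fixed101"), "macro")$fmax
  expect_lte(grid, exact + 1e-12)
  expect_gt(grid, 0)
})

test_that("curve TSV export is stable", {
  fx <- random_eval_fixture(1)
  curve <- sweep_curve(fx$predictions, fx$benchmark, ia = fx$ia)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curve(curve, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$tau, curve$tau)
  expect_equal(back$pr_macro, curve$pr_macro)
})
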