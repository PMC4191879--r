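lib <- default_channel_library()

rep_table <- function(r1, r2, enzyme = "E") {
  # r1, r2: named by channel; Inf = NO_POSE
  ids <- c(paste0(names(r1), "-I1"), paste0(names(r2), "-I2"))
  vals <- c(ifelse(is.finite(r1), r1, NA), ifelse(is.finite(r2), r2, NA))
  score_table(enzyme, ids, vals)
}

test_that("two-round ranking reproduces the worked A=B>C example", {
  # round 1: A and B within 1 kcal/mol, both better than C; round 2: A2
  # beats B2 -> final ranking A > B > C
  tab <- rep_table(c(A = -60.2, B = -60.0, C = -52.3),
                   c(A = -55.0, B = -50.1, C = -49.0))
  cp <- rank_channels(tab, "E", lib)
  expect_equal(cp$ranked_channels, c("A", "B", "C"))
  expect_equal(cp$best_channel, "A")
  expect_setequal(cp$tie_group, c("A", "B"))
  expect_false(cp$ambiguous)
  expect_equal(predict_channel(tab, "E", lib), "A")
})

test_that("ranking edge cases: missing entries, all NO_POSE, degenerate ties", {
  # missing representative entry is an error
  tab <- score_table("E", c("A-I1", "A-I2", "B-I1", "B-I2", "C-I1"),
                     c(-60, -55, -58, -50, -52))
  expect_error(rank_channels(tab, "E", lib), "no score entry")

  # all representatives NO_POSE: ambiguous, no best channel
  tab2 <- rep_table(c(A = Inf, B = Inf, C = Inf), c(A = Inf, B = Inf, C = Inf))
  cp <- rank_channels(tab2, "E", lib)
  expect_true(cp$ambiguous)
  expect_true(is.na(cp$best_channel))

  # perfectly symmetric input stays deterministic but is flagged ambiguous
  tab3 <- rep_table(c(A = -50, B = -50, C = -50), c(A = -40, B = -40, C = -40))
  cp3 <- rank_channels(tab3, "E", lib)
  expect_true(cp3$ambiguous)
  expect_equal(cp3$ranked_channels, c("A", "B", "C"))  # library order

  # disabled channel D is ignored unless included
  tab4 <- rep_table(c(A = -50, B = -45, C = -44, D = -90),
                    c(A = -40, B = -39, C = -38, D = -90))
  expect_equal(predict_channel(tab4, "E", lib), "A")
  libD <- set_channel_enabled(lib, "D", TRUE)
  expect_equal(predict_channel(tab4, "E", libD), "D")

  # relative-mode tables must not be ranked
  rel <- score_table("E", "A-I1", -1, mode = "relative")
  expect_error(rank_channels(rel, "E", lib), "absolute-mode")
})

test_that("two-round rule matches the lexicographic oracle on random tables", {
  set.seed(42)
  n_bad <- 0
  for (k in 1:1500) {
    rs <- random_rep_scores()
    if (all(!is.finite(rs$r1))) next
    got <- rank_channels(rep_table(rs$r1, rs$r2), "E", lib)$ranked_channels
    want <- oracle_rank(rs$r1, rs$r2, tie = 1.0)
    if (!identical(got, want)) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("ranking is invariant to a uniform additive shift of all scores", {
  set.seed(7)
  for (k in 1:50) {
    rs <- random_rep_scores(p_no_pose = 0.15)
    if (all(!is.finite(rs$r1))) next
    shift <- stats::runif(1, -30, 30)
    base <- rank_channels(rep_table(rs$r1, rs$r2), "E", lib)
    shifted <- rank_channels(rep_table(rs$r1 + shift, rs$r2 + shift), "E", lib)
    expect_identical(shifted$ranked_channels, base$ranked_channels)
    expect_identical(shifted$best_channel, base$best_channel)
  }
})

test_that("planted channels are recovered from synthetic score tables", {
  # strong plant: representatives 5 kcal/mol better, moderate noise
  sim <- gen_profiles(profile_spec(planted_channel = c("A", "B", "C"),
                                   representative_gap = 5, noise = 1,
                                   n_enzymes = 60, seed = 11), lib)
  pred <- vapply(sim$truth$enzyme,
                 function(e) predict_channel(sim$scores, e, lib), "")
  expect_gte(mean(pred == sim$truth$channel), 0.95)

  # noiseless: recovery is exact
  sim0 <- gen_profiles(profile_spec(planted_channel = c("A", "B", "C"),
                                    noise = 0, n_enzymes = 30, seed = 2), lib)
  pred0 <- vapply(sim0$truth$enzyme,
                  function(e) predict_channel(sim0$scores, e, lib), "")
  expect_equal(unname(pred0), sim0$truth$channel)
})

test_that("intermediate ranking sorts by score with NO_POSE last, ties stable", {
  ids <- channel_intermediates(lib, "C")$id
  # lanosterol-synthase-like profile: C-I6 is the downstream minimum
  tab <- make_table(stats::setNames(
    c(-80, -45, -47, -50, -53, -60, -57, NA, -40), ids))
  rk <- rank_intermediates(tab, "E", "C", lib)
  expect_equal(rk$intermediate[1], "C-I1")
  downstream_only <- rk$intermediate[rk$intermediate != "C-I1"]
  expect_equal(downstream_only[1], "C-I6")
  expect_equal(rk$intermediate[nrow(rk)], "C-I8")  # NO_POSE last
  expect_true(rk$no_pose[nrow(rk)])

  # all-equal scores keep library order
  tab2 <- make_table(stats::setNames(rep(-50, 9), ids))
  expect_equal(rank_intermediates(tab2, "E", "C", lib)$intermediate, ids)

  # random profiles match a naive sort oracle
  set.seed(3)
  for (k in 1:30) {
    sc <- round(stats::runif(9, -80, 10), 2)
    sc[stats::runif(9) < 0.2] <- NA
    tab3 <- make_table(stats::setNames(sc, ids))
    rk3 <- rank_intermediates(tab3, "E", "C", lib)
    want <- ids[order(ifelse(is.na(sc), Inf, sc), seq_along(ids))]
    expect_equal(rk3$intermediate, want)
  }
})

test_that("endpoint prediction terminates before the first downstream non-binder", {
  ids <- channel_intermediates(lib, "C")$id
  # 1W6K-like: best downstream binder C-I6, C-I8 fails to dock ->
  # terminate at C-I7, ruling out cycloartenol (C-I8) and cucurbitadienol (C-I9)
  tab <- make_table(stats::setNames(
    c(-80, -45, -47, -50, -53, -60, -57, NA, -40), ids))
  ep <- predict_endpoint(tab, "E", "C", lib)
  expect_equal(ep$best_intermediate, "C-I6")
  expect_equal(ep$terminate_after, 7)
  expect_setequal(ep$ruled_out_products$product,
                  c("cycloartenol", "cucurbitadienol"))
  expect_true(ep$rise_check_passed)

  # monotonically improving, no non-binder: nothing ruled out, rise check fails
  tab2 <- make_table(stats::setNames(seq(-40, -80, length.out = 9), ids))
  ep2 <- predict_endpoint(tab2, "E", "C", lib)
  expect_equal(ep2$best_intermediate, "C-I9")
  expect_equal(ep2$terminate_after, 9)
  expect_equal(nrow(ep2$ruled_out_products), 0)
  expect_false(ep2$rise_check_passed)

  # a channel needs at least two scored intermediates
  expect_error(predict_endpoint(make_table(c("C-I1" = -50)), "E", "C", lib),
               "at least two")
})

test_that("endpoint ruled-out sets equal the first-non-binder scan oracle", {
  ids <- channel_intermediates(lib, "C")$id
  set.seed(19)
  for (k in 1:300) {
    sc <- round(stats::runif(9, -70, 20), 1)
    sc[stats::runif(9) < 0.25] <- NA
    if (all(is.na(sc[2:9]))) next
    tab <- make_table(stats::setNames(sc, ids))
    ep <- predict_endpoint(tab, "E", "C", lib)
    want <- oracle_endpoint(sc, 1:9, binder_threshold = 0)
    expect_equal(ep$best_intermediate, ids[want$best_i])
    expect_equal(ep$terminate_after, want$terminate_after)
    want_prods <- lib$products$product[
      lib$products$precursor %in% ids[want$ruled_out_idx]]
    expect_setequal(ep$ruled_out_products$product, want_prods)
  }
})

test_that("mutant classification reproduces the published Y609X/L607K pattern", {
  f <- system.file("extdata", "shc_mutant_relative_scores.csv",
                   package = "terpchannel")
  rel <- read_scores_csv(f, lib, mode = "relative")

  # Y609C: only the bridged cation A-I3 (+32.1) is destabilized
  y609c <- compare_mutant(rel, mut_enzyme = "1SQC-Y609C", channel = "A",
                          lib = lib)
  expect_equal(y609c$classification,
               c("unaffected", "unaffected", "destabilized", "unaffected"))
  expect_equal(y609c$delta, c(3.7, 2.0, 32.1, 1.7))

  # Y609L / Y609S: A-I3 cannot be docked at all
  for (m in c("1SQC-Y609L", "1SQC-Y609S")) {
    cmp <- compare_mutant(rel, mut_enzyme = m, channel = "A", lib = lib)
    expect_equal(cmp$classification[cmp$intermediate == "A-I3"], "abolished")
    expect_true(all(cmp$classification[cmp$intermediate != "A-I3"] ==
                      "unaffected"))
  }

  # L607K: cation repelled everywhere past A-I1; A-I1 itself destabilized
  l607k <- compare_mutant(rel, mut_enzyme = "1SQC-L607K", channel = "A",
                          lib = lib)
  expect_equal(l607k$classification,
               c("destabilized", "abolished", "abolished", "abolished"))

  # wild type against itself: all zero deltas, all unaffected
  wt <- compare_mutant(rel, mut_enzyme = "1SQC-wild", channel = "A", lib = lib)
  expect_true(all(wt$delta == 0))
  expect_true(all(wt$classification == "unaffected"))
})

test_that("mutant comparison on absolute tables and mode mixing", {
  wt <- score_table("WT", c("A-I1", "A-I2"), c(-60, -55))
  mut <- score_table("M", c("A-I1", "A-I2"), c(-57, NA))
  cmp <- compare_mutant(mut, wt, mut_enzyme = "M", wt_enzyme = "WT",
                        channel = "A", lib = lib)
  expect_equal(cmp$delta, c(3, NA))
  expect_equal(cmp$classification, c("unaffected", "abolished"))

  # intermediate present only in the mutant table propagates an error
  wt2 <- score_table("WT", "A-I1", -60)
  expect_error(compare_mutant(mut, wt2, mut_enzyme = "M", wt_enzyme = "WT",
                              channel = "A", lib = lib), "no score entry")

  # mixing a relative wild-type table is refused
  relwt <- score_table("WT", c("A-I1", "A-I2"), c(0, 0), mode = "relative")
  expect_error(compare_mutant(mut, relwt, mut_enzyme = "M", wt_enzyme = "WT",
                              channel = "A", lib = lib), "mix")
})

test_that("evaluation report tallies match a brute-force count", {
  # perfect predictions: 100% everywhere
  pred <- c(E1 = "A", E2 = "B", E3 = "C")
  truth <- c(E1 = "A", E2 = "B", E3 = "C")
  cl <- c(E1 = "1SQC", E2 = "1SQC", E3 = "1W6K")
  ev <- evaluate_predictions(pred, truth, cl)
  expect_true(all(ev$by_cluster$success_rate == 100))
  expect_equal(ev$total$success_rate, 100)

  # missing truth is an error
  expect_error(evaluate_predictions(c(E9 = "A"), truth, cl), "missing truth")

  # random label sets against an independent tally
  set.seed(5)
  for (k in 1:20) {
    n <- 30
    enz <- sprintf("Z%02d", 1:n)
    pred <- stats::setNames(sample(c("A", "B", "C"), n, TRUE), enz)
    truth <- stats::setNames(sample(c("A", "B", "C"), n, TRUE), enz)
    cl <- stats::setNames(sample(c("1SQC", "1W6K"), n, TRUE), enz)
    ev <- evaluate_predictions(pred, truth, cl)
    for (g in unique(cl)) {
      want <- sum(pred[cl == g] == truth[cl == g])
      expect_equal(ev$by_cluster$n_correct[ev$by_cluster$cluster == g], want)
    }
    expect_equal(ev$total$n_correct, sum(pred == truth))
  }

  # precursor statistics count models whose best binder is in the stated set
  best <- c(E1 = "C-I6", E2 = "C-I7", E3 = "C-I9")
  ev2 <- evaluate_predictions(pred = c(E1 = "C", E2 = "C", E3 = "C"),
                              truth = c(E1 = "C", E2 = "C", E3 = "C"),
                              clusters = c(E1 = "1W6K", E2 = "1W6K",
                                           E3 = "1W6K"),
                              best_intermediates = best,
                              precursor_sets = list(
                                lanosterol = list(enzymes = c("E1", "E2", "E3"),
                                                  expected = c("C-I6", "C-I7"))))
  expect_equal(ev2$precursor_stats$n_in_expected_set, 2)
  expect_equal(ev2$precursor_stats$n_models, 3)
})
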