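test_that("entropy and relative entropy reproduce the worked answer patterns", {
  unanimous <- tally(make_set(rep("A", 5)))
  spread <- tally(make_set(c("A", "B", "C", "D", "E")))
  expect_equal(shannon_entropy(unanimous), 0)
  expect_equal(relative_entropy_score(unanimous), 1)
  expect_equal(shannon_entropy(spread), log2(5))
  expect_equal(log2(5), 2.322, tolerance = 5e-4)
  expect_equal(relative_entropy_score(spread), 0)

  aaabb <- tally(make_set(c("A", "A", "A", "B", "B")))
  aaabc <- tally(make_set(c("A", "A", "A", "B", "C")))
  expect_equal(shannon_entropy(aaabb), -(0.6 * log2(0.6) + 0.4 * log2(0.4)))
  # concentrated dissent is more coherent than scattered dissent
  expect_gt(relative_entropy_score(aaabb), relative_entropy_score(aaabc))
  # ...while the modal metric cannot tell them apart
  expect_equal(majority_vote(aaabb)$pct, 60)
  expect_equal(majority_vote(aaabc)$pct, 60)
  expect_equal(majority_vote(aaabb)$option, "A")
})

test_that("weighted scores reproduce the 12x80 / 8x90 worked example", {
  set <- make_set(c(rep("A", 12), rep("B", 8)),
                  conf = c(rep(80, 12), rep(90, 8)))
  tal <- tally(set)
  expect_equal(tal$count[tal$option == "A"], 12L)
  expect_equal(tal$weighted_score[tal$option == "A"], 48)
  expect_equal(tal$weighted_score[tal$option == "B"], 36)
  tws <- top_weighted_score(tal)
  expect_equal(tws$option, "A")
  expect_equal(tws$score, 48)
  expect_false(tws$tie)
})

test_that("tallies count, average and guard their domain", {
  set <- make_set(c("A", "A", "A", "B", "B"), conf = c(70, 80, 90, 60, 60))
  tal <- tally(set, 5)
  expect_equal(tal$count, c(3L, 2L, 0L, 0L, 0L))
  expect_equal(tal$mean_conf[1:2], c(80, 60))
  # zero-count options carry missing mean confidence, never zero
  expect_true(all(is.na(tal$mean_conf[3:5])))
  expect_true(all(is.na(tal$weighted_score[3:5])))
  expect_error(tally(set, 0), "depth")
  expect_error(tally(set, 6), "depth")
  # truncation acts on the leading repetitions in generation order
  expect_equal(tally(set, 2)$count[1:2], c(2L, 0L))
})

test_that("frequency and score ties break by canonical option order and are flagged", {
  tied <- tally(make_set(c("A", "A", "B", "B", "C")))
  mv <- majority_vote(tied)
  expect_equal(mv$option, "A")
  expect_equal(mv$pct, 40)
  expect_true(mv$tie)

  set <- make_set(c("B", "B", "A", "A"), conf = 75)
  tws <- top_weighted_score(tally(set))
  expect_equal(tws$option, "A")
  expect_true(tws$tie)
})

test_that("self-reported metrics follow the majority-at-depth rule", {
  set <- make_set(c("A", "A", "B"), conf = c(70, 90, 50))
  sr <- self_reported(set, 3)
  expect_equal(sr$first_conf, 70)
  expect_equal(sr$mean_conf_majority, 80)

  single <- make_set("A", conf = 55)
  sr1 <- self_reported(single, 1)
  expect_equal(sr1$first_conf, 55)
  expect_equal(sr1$mean_conf_majority, 55)

  # missing first confidence propagates without touching the mean
  set2 <- make_set(c("A", "A", "B"), conf = c(NA, 90, 50))
  sr2 <- self_reported(set2, 3)
  expect_true(is.na(sr2$first_conf))
  expect_equal(sr2$mean_conf_majority, 90)

  # majority choosers without confidence leave the mean missing
  set3 <- make_set(c("A", "A", "B"), conf = c(NA, NA, 50))
  expect_true(is.na(self_reported(set3, 3)$mean_conf_majority))
  expect_error(top_weighted_score(tally(make_set(c("A", "B"), conf = NA))),
               "no option has a mean confidence")
})

test_that("the correctness map pairs each metric with its representative answer", {
  # majority A (correct), but B's weighted score wins
  set <- make_set(c("A", "A", "A", "B", "B"),
                  conf = c(10, 10, 10, 100, 100), truth = "A")
  prof <- build_profile(set, 5)
  expect_equal(prof$majority_option, "A")
  expect_equal(prof$tws_option, "B")
  expect_true(prof$correct_majority)
  expect_true(prof$correct_rh)
  expect_true(prof$correct_mean)
  expect_false(prof$correct_tws)
  expect_true(prof$correct_first)

  # unanimous correct responses: every flag correct
  una <- build_profile(make_set(rep("A", 5), conf = 90, truth = "A"))
  expect_true(all(unlist(una[grep("^correct_", names(una))])))

  # depth changes the majority: BBAAA is wrong at depth 2, right at depth 5
  flip <- make_set(c("B", "B", "A", "A", "A"), conf = 80, truth = "A")
  expect_false(build_profile(flip, 2)$correct_majority)
  expect_true(build_profile(flip, 5)$correct_majority)
  expect_false(build_profile(flip, 5)$correct_first)
})

test_that("metric invariants hold on random response sets", {
  set.seed(401)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    n <- sample(1:25, 1)
    set <- random_set(n, k)
    tal <- tally(set)
    expect_equal(sum(tal$count) , n)
    H <- shannon_entropy(tal)
    rh <- relative_entropy_score(tal)
    expect_true(H >= 0 && H <= log2(k) + 1e-12)
    expect_true(rh >= -1e-12 && rh <= 1 + 1e-12)
    expect_close(rh, 1 - H / log2(k))
    mv <- majority_vote(tal)
    expect_true(mv$pct > 0 && mv$pct <= 100)
    tws <- top_weighted_score(tal)
    expect_true(tws$score >= 0 && tws$score <= 100)
    prof <- build_profile(set)
    expect_close(prof$r_h, 1 - prof$entropy_H / log2(k))
  }
})

test_that("all-100 confidences collapse the hybrid onto the majority metric", {
  set.seed(402)
  for (i in 1:50) {
    set <- make_set(sample(LETTERS[1:4], 12, replace = TRUE), conf = 100,
                    options = "A|B|C|D", truth = "A")
    tal <- tally(set)
    mv <- majority_vote(tal)
    tws <- top_weighted_score(tal)
    expect_equal(tws$score, mv$pct, tolerance = 1e-9)
    expect_identical(tws$option, mv$option)
    expect_identical(tws$tie, mv$tie)
  }
})

test_that("relabeling options permutes but never changes metric values", {
  set.seed(403)
  perm_map <- c(A = "D", B = "A", C = "E", D = "B", E = "C")
  for (i in 1:30) {
    ans <- sample(LETTERS[1:5], 15, replace = TRUE)
    conf <- round(runif(15, 30, 100), 1)
    truth <- sample(LETTERS[1:5], 1)
    s1 <- make_set(ans, conf = conf, truth = truth)
    s2 <- make_set(unname(perm_map[ans]), conf = conf,
                   truth = unname(perm_map[truth]))
    t1 <- tally(s1); t2 <- tally(s2)
    expect_close(shannon_entropy(t1), shannon_entropy(t2))
    expect_close(relative_entropy_score(t1), relative_entropy_score(t2))
    expect_close(majority_vote(t1)$pct, majority_vote(t2)$pct)
    expect_close(top_weighted_score(t1)$score, top_weighted_score(t2)$score)
  }
  # majority percentage ignores how the dissenting answers are arranged
  expect_equal(majority_vote(tally(make_set(c("A","A","A","B","B"))))$pct,
               majority_vote(tally(make_set(c("A","A","A","D","E"))))$pct)
})

test_that("weighted scores match brute-force recomputation on all small sets", {
  opts <- c("A", "B", "C")
  for (n in 1:6) {
    grids <- do.call(expand.grid, c(rep(list(1:3), n), stringsAsFactors = FALSE))
    # deterministic confidence pattern tied to position
    conf <- 40 + 7 * seq_len(n)
    for (g in seq_len(nrow(grids))) {
      ans <- opts[as.integer(grids[g, ])]
      set <- make_set(ans, conf = conf, options = "A|B|C", truth = "A")
      tal <- tally(set)
      for (o in opts) {
        cnt <- sum(ans == o)
        expected <- if (cnt == 0) NA_real_ else cnt * mean(conf[ans == o]) / n
        got <- tal$weighted_score[tal$option == o]
        if (is.na(expected)) expect_true(is.na(got))
        else expect_close(got, expected, tol = 1e-10)
      }
    }
  }
})
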