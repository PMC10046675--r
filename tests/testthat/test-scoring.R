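test_that("performance time inflates execution time for omissions", {
  expect_equal(performance_time(50, 0), 50)
  expect_equal(performance_time(48, 1), 50)
  expect_equal(performance_time(60, 5), 75)  # 25 * 60 / 20
  # strictly increasing in omissions at fixed execution time
  pt <- performance_time(rep(60, 25), 0:24)
  expect_true(all(diff(pt) > 0))
  expect_equal(pt[1], 60)
})

test_that("unscoreable or invalid cards raise informative errors", {
  expect_error(performance_time(60, 25, card_id = 3), "card 3",
               class = "brevis_scoring_error")
  expect_error(performance_time(60, 26), "omissions")
  expect_error(performance_time(60, -1), "omissions")
  expect_error(performance_time(0, 0), "positive")
  expect_error(performance_time(60, 2.5), "omissions")
})

test_that("indexes follow their defining card contrasts", {
  coh <- make_cards(times = c(50, 60, 70, 80))
  idx <- compute_indexes(coh)
  expect_equal(idx$SA, 50)
  expect_equal(idx$OA, 20)
  expect_equal(idx$FA, 10)
  expect_equal(idx$Err, 0)

  flat <- compute_indexes(make_cards(times = rep(60, 4)))
  expect_equal(flat$SA, 60)
  expect_equal(flat$OA, 0)
  expect_equal(flat$FA, 0)
})

test_that("index computation chains performance times through omissions", {
  coh <- make_cards(times = c(48, 54, 66, 72), om = c(1, 2, 3, 4))
  idx <- compute_indexes(coh)
  # oracle: per-card performance times by direct arithmetic
  P <- 25 * c(48, 54, 66, 72) / (25 - 1:4)
  expect_equal(round(P, 1), c(50.0, 58.7, 75.0, 85.7))
  expect_equal(idx$SA, P[1])
  expect_equal(idx$OA, (P[3] + P[4]) / 2 - (P[1] + P[2]) / 2)
  expect_equal(round(idx$OA, 1), 26.0)
  expect_equal(round(idx$FA, 1), 9.7)
  expect_equal(idx$Err, 10)
})

test_that("errors sum omissions and substitutions but not autocorrections", {
  coh <- make_cards(times = c(50, 60, 70, 80), om = c(1, 0, 2, 0),
                    sub = c(0, 3, 0, 1), auto = c(2, 2, 0, 0))
  idx <- compute_indexes(coh)
  expect_equal(idx$Err, 7)
  expect_equal(idx$autocorrections, 4)
})

test_that("OA and FA are shift-invariant while SA tracks the shift", {
  set.seed(42)
  for (i in 1:20) {
    P <- runif(4, 40, 120)
    c0 <- compute_indexes(make_cards(times = P))
    shift <- runif(1, -10, 30)
    c1 <- compute_indexes(make_cards(times = P + shift))
    expect_equal(c1$OA, c0$OA, tolerance = 1e-10)
    expect_equal(c1$FA, c0$FA, tolerance = 1e-10)
    expect_equal(c1$SA, c0$SA + shift, tolerance = 1e-10)
    # the three time indexes always reconstruct card 4: SA + OA + FA = P4
    expect_equal(c0$SA + c0$OA + c0$FA, P[4], tolerance = 1e-10)
  }
})

test_that("a card with 25 omissions aborts scoring and names the card", {
  coh <- make_cards(times = c(50, 60, 70, 80), om = c(0, 0, 25, 0))
  expect_error(compute_indexes(coh), "card 3", class = "brevis_scoring_error")
})

test_that("cohort validation rejects duplicate and missing cards", {
  coh <- make_cards(times = c(50, 60, 70, 80))
  expect_error(compute_indexes(coh[-4, ]), "missing card 4")
  dup <- rbind(coh, coh[2, ])
  expect_error(compute_indexes(dup), "duplicate")
})
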