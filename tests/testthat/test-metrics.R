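test_that("precision and accuracy order match hand-computed examples", {
  pred <- structure(data.frame(i = c(1L, 2L, 1L), j = c(3L, 4L, 1L),
                               score = c(0.9, 0.8, 0.7)),
                    class = c("ranked_contacts", "data.frame"))
  attr(pred, "L") <- 4L
  truth <- matrix(0L, 4, 4)
  truth[2, 4] <- 1L  # only the second prediction is correct
  expect_equal(precision_at(pred, truth, 1), 0)
  expect_equal(precision_at(pred, truth, 2), 0.5)
  expect_equal(precision_at(pred, truth, 3), 1 / 3)
  # n beyond the list: denominator is the list length
  expect_equal(precision_at(pred, truth, 100), 1 / 3)
  # truth consulted as unordered pairs
  truth_t <- t(truth)
  expect_equal(precision_at(pred, truth_t, 2), 0.5)

  # accuracy order: first hit at rank 2, L = 4 -> 1000 * 2 / 10
  expect_equal(accuracy_order(pred, truth), 200)
  # rank-1 hit on an L = 100 target -> 1000 / 5050
  p100 <- structure(data.frame(i = 1L, j = 2L, score = 1),
                    class = c("ranked_contacts", "data.frame"))
  attr(p100, "L") <- 100L
  t100 <- matrix(0L, 100, 100); t100[1, 2] <- 1L
  expect_equal(accuracy_order(p100, t100), 1000 / 5050)
  # no true contact at all -> NA
  expect_true(is.na(accuracy_order(pred, matrix(0L, 4, 4))))
})

test_that("top-L/K precision promotes the count floor for short chains", {
  pred <- structure(data.frame(i = 1L, j = 2L, score = 1),
                    class = c("ranked_contacts", "data.frame"))
  attr(pred, "L") <- 25L
  truth <- matrix(0L, 25, 25); truth[1, 2] <- 1L
  # floor(25 / 30) = 0 promoted to 1
  expect_equal(topLK_precision(pred, truth, K = 30), 1)
  expect_equal(topLK_precision(pred, truth, K = 2), 1)  # list shorter than n
})

test_that("metrics agree with brute-force recomputation on random toys", {
  for (s in 1:50) {
    L <- sample(5:20, 1)
    tg <- random_toy_target(L, seed = 100 + s)
    pred <- tg$pred; tv <- tg$truth$values
    n <- sample(1:nrow(pred), 1)
    hits <- mapply(function(i, j) tv[i, j] == 1 || tv[j, i] == 1,
                   pred$i, pred$j)
    expect_equal(precision_at(pred, tg$truth, n),
                 sum(hits[1:min(n, length(hits))]) / min(n, length(hits)))
    ao <- accuracy_order(pred, tg$truth)
    if (sum(tv) == 0 || !any(hits)) {
      expect_true(is.na(ao))
    } else {
      expect_equal(ao, 1000 * which(hits)[1] / (L * (L + 1) / 2))
    }
  }
})

test_that("accuracy rate is monotone in the list depth", {
  targets <- lapply(1:8, function(s) random_toy_target(12, seed = 200 + s))
  rates <- vapply(c(1, 5, 20, 78), function(n) accuracy_rate(targets, n),
                  numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_true(all(rates >= 0 & rates <= 1))
  # brute force at n = 5
  brute <- mean(vapply(targets, function(tg) {
    tv <- tg$truth$values
    any(mapply(function(i, j) tv[i, j] == 1, tg$pred$i[1:5], tg$pred$j[1:5]))
  }, logical(1)))
  expect_equal(accuracy_rate(targets, 5), brute)
})

test_that("the evaluation report aggregates across targets", {
  targets <- lapply(1:4, function(s) random_toy_target(15, seed = 300 + s))
  rep <- eval_report(targets)
  expect_s3_class(rep, "eval_report")
  expect_equal(names(rep$precision_at), c("1", "10", "100"))
  expect_equal(names(rep$topLK), c("30", "20", "10", "5", "2"))
  expect_equal(unname(rep$precision_at["1"]),
               mean(vapply(targets, function(tg) {
                 precision_at(tg$pred, tg$truth, 1)
               }, numeric(1))))
  expect_output(print(rep), "accuracy order")
})
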