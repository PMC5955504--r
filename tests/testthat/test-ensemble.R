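test_that("folds are patient-grouped, balanced and seed-deterministic", {
  plan <- make_folds(sprintf("P%03d", 1:100), n_folds = 10, rng_seed = 3)
  expect_equal(as.integer(table(plan$fold)), rep(10L, 10))
  plan2 <- make_folds(rep(sprintf("P%03d", 1:101), each = 3), n_folds = 10,
                      rng_seed = 3)
  sizes <- sort(as.integer(table(plan2$fold)))
  expect_equal(sizes, c(rep(10L, 9), 11L))
  expect_identical(make_folds(sprintf("P%03d", 1:100), 10, 3), plan)
  expect_error(make_folds(c("a", "b"), n_folds = 3), "cannot make 3 folds")
  # all images of a patient land in one fold by construction
  expect_equal(nrow(plan2), 101)
})

test_that("majority vote equals brute-force per-pixel counting, including the tie", {
  set.seed(8)
  for (trial in 1:25) {
    n_m <- sample(3:11, 1)
    maps <- replicate(n_m, matrix(runif(36), 6, 6), simplify = FALSE)
    for (thr in c(0.3, 0.5, 0.7)) {
      cfg <- ensemble_config(vote_threshold = thr)
      got <- majority_vote(maps, cfg)$pixels
      want <- matrix(0L, 6, 6)
      for (r in 1:6) for (c in 1:6) {
        votes <- 0
        for (m in maps) if (m[r, c] >= 0.5) votes <- votes + 1
        want[r, c] <- as.integer(votes / n_m >= thr)
      }
      expect_identical(got, want)
    }
  }
  # the 5-of-10 tie at threshold 0.5 is positive (inclusive >=)
  maps <- c(replicate(5, matrix(1, 2, 2), simplify = FALSE),
            replicate(5, matrix(0, 2, 2), simplify = FALSE))
  expect_identical(majority_vote(maps, ensemble_config(0.5))$pixels,
                   matrix(1L, 2, 2))
})

test_that("unanimous maps are threshold-invariant and fusion is order-invariant", {
  set.seed(11)
  m <- matrix(runif(25), 5, 5)
  maps <- replicate(7, m, simplify = FALSE)
  for (thr in c(0.1, 0.5, 1)) {
    expect_identical(majority_vote(maps, ensemble_config(thr))$pixels,
                     matrix(as.integer(m >= 0.5), 5, 5))
  }
  maps2 <- replicate(7, matrix(runif(25), 5, 5), simplify = FALSE)
  a <- majority_vote(maps2, ensemble_config(0.5))
  b <- majority_vote(rev(maps2), ensemble_config(0.5))
  expect_identical(a$pixels, b$pixels)
  expect_error(majority_vote(list(matrix(0.1, 2, 2), matrix(0.2, 3, 3))),
               "one grid")
  expect_error(majority_vote(list()), "nonempty")
})

test_that("vote masks nest as the threshold rises", {
  set.seed(13)
  maps <- replicate(9, matrix(runif(64), 8, 8), simplify = FALSE)
  thresholds <- seq(0.1, 1, by = 0.1)
  prev <- NULL
  for (thr in thresholds) {
    cur <- majority_vote(maps, ensemble_config(thr))$pixels
    if (!is.null(prev)) expect_true(all(cur <= prev))
    prev <- cur
  }
  # unanimity mask is a subset of the any-vote mask
  unan <- majority_vote(maps, ensemble_config(1))$pixels
  any1 <- majority_vote(maps, ensemble_config(1 / 9))$pixels
  expect_true(all(unan <= any1))
})

test_that("threshold sweep reports non-increasing areas and member sweep endpoints match", {
  set.seed(17)
  maps_per_image <- replicate(4, replicate(6, matrix(runif(49), 7, 7),
                                           simplify = FALSE), simplify = FALSE)
  truths <- replicate(4, matrix(rbinom(49, 1, 0.4), 7, 7), simplify = FALSE)
  sw <- vote_threshold_sweep(maps_per_image, truths, seq(0.1, 1, 0.1))
  expect_equal(nrow(sw), 10)
  expect_true(all(diff(sw$mean_area) <= 1e-12))
  expect_error(vote_threshold_sweep(list(), list(), c(0.3, 0.5)), "empty")
  expect_error(vote_threshold_sweep(maps_per_image, truths, 0.5), "two thresholds")

  ms <- member_count_sweep(maps_per_image, truths, counts = c(1, 3, 6))
  one <- mean(purrr::map2_dbl(maps_per_image, truths, function(m, tr) {
    dice_coef((m[[1]] >= 0.5) * 1L, tr)
  }))
  expect_equal(ms$mean_dice[ms$n_members == 1], one)
  full <- mean(purrr::map2_dbl(maps_per_image, truths, function(m, tr) {
    dice_coef(majority_vote(m), tr)
  }))
  expect_equal(ms$mean_dice[ms$n_members == 6], full)
  expect_error(member_count_sweep(maps_per_image, truths, counts = 7), "available")
})

test_that("ensemble training demands full patient coverage", {
  ds <- generate_dataset(6, 1, rng_seed = 5)
  plan <- make_folds(ds$patient_id[1:4], n_folds = 2, rng_seed = 1)
  expect_error(train_ensemble(ds, plan, scale_profile()), "does not cover")
})
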