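test_that("fold enumeration matches combinatorial counts", {
  expect_equal(nrow(enumerate_folds(1:2)), 1)
  expect_equal(nrow(enumerate_folds(1:8)), 35)   # C(8,4)/2
  expect_equal(nrow(enumerate_folds(1:5)), 10)   # C(5,2), 2-vs-3 splits
  f8 <- enumerate_folds(1:8)
  expect_true(all(vapply(seq_len(nrow(f8)), function(i) {
    length(intersect(f8$half_a[[i]], f8$half_b[[i]])) == 0 &&
      setequal(union(f8$half_a[[i]], f8$half_b[[i]]), 1:8)
  }, logical(1))))
  # every partition unique regardless of orientation
  keys <- vapply(seq_len(nrow(f8)), function(i) {
    paste(sort(c(paste(f8$half_a[[i]], collapse = ","),
                 paste(f8$half_b[[i]], collapse = ","))), collapse = "|")
  }, character(1))
  expect_equal(anyDuplicated(keys), 0)
  f5 <- enumerate_folds(1:5)
  expect_true(all(lengths(f5$half_a) == 2))
  expect_true(all(lengths(f5$half_b) == 3))
  expect_error(enumerate_folds(1), "at least 2")
})

test_that("cross-split distances obey the metric's arithmetic", {
  # 3-4-5 triangle
  a <- matrix(c(0, 0, 3, 4), 2, 2, dimnames = list(1:2, c("i", "j")))
  d <- cross_split_distances(a, a)
  expect_equal(d["i", "j"], 5)
  expect_equal(diag(d), c(i = 0, j = 0))  # identical halves: zero diagonal
  # brute-force oracle on random patterns
  set.seed(5)
  for (rep in 1:10) {
    A <- matrix(rnorm(60), 6, 10, dimnames = list(1:6, 1:10))
    B <- matrix(rnorm(60), 6, 10, dimnames = list(1:6, 1:10))
    d <- cross_split_distances(A, B)
    oracle <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10) {
      dij <- sqrt(sum((A[, i] - B[, j])^2))
      dji <- sqrt(sum((B[, i] - A[, j])^2))
      oracle[i, j] <- (dij + dji) / 2
    }
    expect_equal(unname(d), oracle, tolerance = 1e-10)
    # axioms: non-negativity and orientation symmetry
    expect_true(all(d >= 0))
    expect_equal(d, t(d), tolerance = 1e-12)
    expect_equal(d, cross_split_distances(B, A), tolerance = 1e-12)
  }
  bad <- matrix(rnorm(50), 5, 10, dimnames = list(1:5, 1:10))
  A <- matrix(rnorm(60), 6, 10, dimnames = list(1:6, 1:10))
  expect_error(cross_split_distances(A, bad), "voxel")
})

test_that("fold averaging is the element-wise mean", {
  d1 <- matrix(1, 3, 3)
  expect_equal(average_over_folds(list(d1)), d1)
  expect_equal(average_over_folds(list(d1, 3 * d1)), 2 * d1)
  set.seed(2)
  stack <- replicate(7, matrix(rnorm(9), 3, 3), simplify = FALSE)
  expect_equal(average_over_folds(stack), Reduce(`+`, stack) / 7)
  expect_error(average_over_folds(list(d1, matrix(1, 2, 2))), "differ")
  expect_error(average_over_folds(list()), "no fold")
})

test_that("hypothesis matrices encode the published condition groupings", {
  aff <- build_hypothesis_matrix("affordance_overall")
  # left-door pair (2,5): same affordance -> within
  expect_equal(aff["2", "5"], "within")
  expect_equal(aff["1", "4"], "within")
  expect_equal(aff["2", "3"], "between")
  expect_equal(aff["2", "2"], "within")      # self-pairs included
  expect_true(all(aff[7:10, ] == "excluded"))  # turn conditions excluded

  gen <- build_hypothesis_matrix("affordance_generalize")
  expect_equal(gen["1", "4"], "within")      # cross-motion, same affordance
  expect_equal(gen["2", "6"], "between")     # cross-motion, different side
  expect_equal(gen["2", "3"], "excluded")    # same ego-motion
  expect_equal(gen["1", "1"], "excluded")    # self-pairs drop out

  ego <- build_hypothesis_matrix("egomotion_overall")
  expect_equal(ego["1", "2"], "within")
  expect_equal(ego["7", "8"], "within")
  expect_equal(ego["1", "4"], "between")     # forward vs backward
  expect_equal(ego["7", "9"], "between")     # left vs right turn
  expect_equal(ego["1", "7"], "excluded")    # unmatched pair

  egog <- build_hypothesis_matrix("egomotion_generalize")
  expect_equal(egog["1", "2"], "within")     # both vs left door
  expect_equal(egog["7", "8"], "within")
  expect_equal(egog["7", "9"], "excluded")   # both left-door turns
  expect_equal(egog["7", "10"], "between")
  expect_equal(egog["2", "5"], "excluded")   # same affordance

  conf <- build_hypothesis_matrix("conflict")
  expect_equal(conf["7", "10"], "within")
  expect_equal(conf["8", "9"], "within")
  expect_equal(conf["7", "9"], "between")
  expect_true(all(conf[1:6, ] == "excluded"))

  room <- build_hypothesis_matrix("room_texture")
  expect_equal(dim(unclass(room)), c(8, 8))
  expect_true(all(diag(unclass(room)) == "within"))
  expect_equal(sum(room == "between"), 56)

  expect_error(build_hypothesis_matrix("bogus"))
})

test_that("hypothesis labels are symmetric and generalization nests in overall", {
  for (s in c("affordance_overall", "affordance_generalize",
              "egomotion_overall", "egomotion_generalize", "conflict",
              "room_texture")) {
    h <- unclass(build_hypothesis_matrix(s))
    expect_equal(h, t(h))
  }
  nests <- list(c("affordance_generalize", "affordance_overall"),
                c("egomotion_generalize", "egomotion_overall"))
  for (pair in nests) {
    g <- unclass(build_hypothesis_matrix(pair[1]))
    o <- unclass(build_hypothesis_matrix(pair[2]))
    labeled <- g != "excluded"
    expect_true(all(g[labeled] == o[labeled]))
  }
})

test_that("decoding scores follow their defining arithmetic", {
  h <- build_hypothesis_matrix("conflict")
  d <- matrix(0, 10, 10, dimnames = list(1:10, 1:10))
  d[unclass(h) == "within"] <- 1
  d[unclass(h) == "between"] <- 2
  s <- score_decoding(d, h)
  expect_equal(s$within_mean, 1)
  expect_equal(s$between_mean, 2)
  expect_equal(s$diff, 1)
  # equal within and between -> zero difference
  s0 <- score_decoding(matrix(3, 10, 10, dimnames = list(1:10, 1:10)), h)
  expect_equal(s0$diff, 0)
  expect_error(score_decoding(matrix(0, 8, 8), h), "condition set")
})

test_that("decoding scores scale with the patterns (scale equivariance)", {
  cfg <- tiny_config(seed = 31)
  b <- simulate_betas(cfg)
  b3 <- b
  b3$betas <- lapply(b$betas, function(m) 3 * m)
  s1 <- decode_patterns(b, c("affordance_overall", "egomotion_overall"))
  s3 <- decode_patterns(b3, c("affordance_overall", "egomotion_overall"))
  expect_equal(s3$diff, 3 * s1$diff, tolerance = 1e-10)
  expect_equal(s3$within_mean, 3 * s1$within_mean, tolerance = 1e-10)
})

test_that("subject distances agree with the explicit fold-by-fold route", {
  cfg <- tiny_config(seed = 17, n_runs = 4)
  b <- simulate_betas(cfg)
  fast <- subject_distances(b)
  # manual: combine hemispheres, enumerate folds, average halves, distance
  runs <- 1:4
  mats <- lapply(runs, function(r) {
    sub <- b[b$run == r, ]
    sub <- sub[order(sub$hemisphere), ]
    do.call(rbind, sub$betas)
  })
  folds <- enumerate_folds(runs)
  ds <- lapply(seq_len(nrow(folds)), function(i) {
    A <- Reduce(`+`, mats[folds$half_a[[i]]]) / length(folds$half_a[[i]])
    B <- Reduce(`+`, mats[folds$half_b[[i]]]) / length(folds$half_b[[i]])
    cross_split_distances(A, B)
  })
  manual <- average_over_folds(ds)
  expect_equal(unname(fast$distances[[1]]), unname(manual), tolerance = 1e-10)
  expect_equal(fast$n_folds, nrow(folds))
})

test_that("group decoding test matches the closed-form paired t", {
  scores <- tibble::tibble(
    subject = 1:4, roi = "OPA", scheme = "affordance_overall",
    within_mean = c(1, 1.5, 2, 1.2), between_mean = c(2, 2.5, 4, 1.4),
    diff = between_mean - within_mean)
  res <- group_decoding_test(scores)
  d <- scores$diff
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p, pt(t_hand, 3, lower.tail = FALSE), tolerance = 1e-12)
  # zero differences give t = 0
  sc0 <- scores
  sc0$between_mean <- sc0$within_mean
  sc0$diff <- 0
  expect_equal(group_decoding_test(sc0)$t, 0)
  expect_error(group_decoding_test(scores[1:2, ]), "3 subjects")
})
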