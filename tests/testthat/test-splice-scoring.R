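# Donor-window extraction, PWM and maximum-entropy models, scoring in
# bits, donor statistics and serialisation.

test_that("donor windows are 3 exonic + 6 intron-side bases around the cut", {
  w <- extract_donor_window("TTTACG", "GTAAGTCC", cut = 6)
  expect_equal(w$window, "ACGGTAAGT")
  # an internal cut takes the right-side bases from the exon remainder
  w2 <- extract_donor_window("TTTACGGTAAGTCC", "", cut = 6)
  expect_equal(w2$window, "ACGGTAAGT")
  expect_error(extract_donor_window("TTTACG", "GTAAGTCC", cut = 2), "left")
  expect_error(extract_donor_window("TTTACG", "GTA", cut = 6), "flank")
  expect_false(extract_donor_window("TTTACN", "GTAAGTCC", cut = 6)$valid)
})

test_that("PWM training applies additive smoothing per position", {
  # four identical windows, no pseudocount: indicator columns
  m0 <- train_pwm(rep("ACGGTAAGT", 4), pseudocount = 0)
  expect_equal(m0$probs[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(m0$probs[5, ], c(A = 0, C = 0, G = 0, T = 1))

  # counts {A:3, C:1} at position 1 with alpha = 0.5
  wins <- c("AAAAAAAAA", "AAAAAAAAA", "AAAAAAAAA", "CAAAAAAAA")
  m <- train_pwm(wins, pseudocount = 0.5)
  expect_equal(unname(m$probs[1, ]), c(3.5, 1.5, 0.5, 0.5) / 6)
  expect_equal(rowSums(m$probs), rep(1, 9))

  expect_error(train_pwm("NNNNNNNNN"), "no valid")
  # N-containing windows are excluded from training, not counted
  m2 <- train_pwm(c(wins, "NAAAAAAAA"), pseudocount = 0.5)
  expect_equal(m2$probs, m$probs)
})

test_that("scores are log-odds in bits with the stated closed forms", {
  uniform <- train_pwm(c("ACGTACGTA", "CGTACGTAC", "GTACGTACG", "TACGTACGT"),
                       pseudocount = 1e9)  # huge pseudocount -> uniform
  expect_equal(score_window(uniform, "GGGGGGGGG"), 0, tolerance = 1e-6)

  # alpha = 0 single-sequence PWM scoring its own sequence vs uniform
  self <- train_pwm("ACGGTAAGT", pseudocount = 0)
  expect_equal(score_window(self, "ACGGTAAGT"), 9 * log2(4))

  # the consensus window maximises the score under its own PWM
  cons <- paste(colnames(shared_pwm$probs)[apply(shared_pwm$probs, 1, which.max)],
                collapse = "")
  cons_score <- score_window(shared_pwm, cons)
  withr::with_seed(31, {
    others <- vapply(1:50, function(i) score_window(shared_pwm, random_dna(9)),
                     numeric(1))
    expect_true(all(others <= cons_score))
  })

  # N-containing windows are flagged, not scored
  scored <- score_windows(shared_pwm, c("ACGGTAAGT", "ACGGTNAGT"))
  expect_false(scored$valid[2])
  expect_true(is.na(scored$score[2]))
})

test_that("maxent with singleton constraints reproduces the PWM exactly", {
  tr <- simulate_donor_training_set(n = 150, seed = 21)
  pwm <- train_pwm(tr$positives)
  me <- train_maxent(tr$positives, constraints = as.list(1:9))
  withr::with_seed(22, {
    wins <- vapply(1:100, function(i) random_dna(9), character(1))
  })
  expect_lt(max(abs(score_windows(me, wins)$score -
                    score_windows(pwm, wins)$score)), 1e-6)
})

test_that("maxent with a pair constraint matches a full-enumeration IPF oracle", {
  withr::with_seed(5, {
    toys <- vapply(1:40, function(i) random_dna(3), character(1))
  })
  cons <- list(1L, 2L, 3L, c(1L, 2L))
  me <- train_maxent(toys, constraints = cons, pseudocount = 0.5, tol = 1e-10)
  oracle <- ipf_oracle(toys, cons, pseudocount = 0.5, tol = 1e-12)

  # model probability of every enumerated 3-mer from the stored factors
  probs <- vapply(names(oracle), function(s) {
    b <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    lp <- log2(0.25^3) - me$log2_norm
    for (ci in seq_along(me$constraints)) {
      idx <- 0L
      for (j in me$constraints[[ci]]) idx <- idx * 4L + (b[j] - 1L)
      lp <- lp + log2(me$factors[[ci]][idx + 1L])
    }
    2^lp
  }, numeric(1))
  expect_equal(sum(probs), 1, tolerance = 1e-8)
  expect_lt(max(abs(probs - oracle)), 1e-6)

  # fitted pair marginal equals the (pseudocounted) empirical pair marginal
  pair_fit <- tapply(probs, substr(names(probs), 1, 2), sum)
  emp <- table(factor(substr(toys, 1, 2),
                      levels = names(pair_fit)))
  pair_emp <- (as.numeric(emp) + 2 / 16) / (length(toys) + 2)
  expect_lt(max(abs(pair_fit - pair_emp)), 1e-8)
})

test_that("maxent rejects bad constraint sets and reports non-convergence", {
  tr <- simulate_donor_training_set(n = 20, seed = 2)
  expect_error(train_maxent(tr$positives, constraints = as.list(1:8)),
               "singleton")
  expect_error(
    train_maxent(tr$positives, constraints = c(as.list(1:9), list(c(9L, 10L)))),
    "out of range"
  )
  expect_error(train_maxent(tr$positives, max_iter = 0), "converge")
})

test_that("donor statistics give mean and sample SD of scores", {
  tab <- table_model(tibble::tibble(
    window = c("AAAAAAAAA", "CCCCCCCCC", "GGGGGGGGG"),
    score = c(7, 8, 9)
  ))
  st <- donor_score_stats(c("AAAAAAAAA", "CCCCCCCCC", "GGGGGGGGG"), tab)
  expect_equal(st$mean, 8)
  expect_equal(st$sd, 1)
  expect_equal(st$n, 3L)

  same <- table_model(tibble::tibble(window = c("AAAAAAAAA", "CCCCCCCCC"),
                                     score = c(5, 5)))
  expect_equal(donor_score_stats(c("AAAAAAAAA", "CCCCCCCCC"), same)$sd, 0)
  expect_error(donor_score_stats("AAAAAAAAA", tab), "at least 2")

  # independent two-pass mean/SD on random windows
  withr::with_seed(77, {
    wins <- vapply(1:100, function(i) random_dna(9), character(1))
  })
  st2 <- donor_score_stats(wins, shared_pwm)
  s <- score_windows(shared_pwm, wins)$score
  mu <- sum(s) / length(s)
  expect_equal(st2$mean, mu)
  expect_equal(st2$sd, sqrt(sum((s - mu)^2) / (length(s) - 1)))
})

test_that("unsmoothed scores are invariant under duplication of the training set", {
  # duplication leaves empirical frequencies unchanged; with additive
  # smoothing the effective pseudocount weight halves, so the invariance
  # is exact at pseudocount 0
  tr <- simulate_donor_training_set(n = 80, seed = 8)
  doubled <- dplyr::bind_rows(tr$positives, tr$positives)
  withr::with_seed(9, {
    wins <- vapply(1:30, function(i) random_dna(9), character(1))
  })
  expect_equal(score_windows(train_pwm(tr$positives, pseudocount = 0), wins)$score,
               score_windows(train_pwm(doubled, pseudocount = 0), wins)$score)
  s1 <- score_windows(train_maxent(tr$positives, pseudocount = 0), wins)$score
  s2 <- score_windows(train_maxent(doubled, pseudocount = 0), wins)$score
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("model serialisation round-trips bit-exactly", {
  tr <- simulate_donor_training_set(n = 60, seed = 13)
  withr::with_seed(14, {
    wins <- vapply(1:25, function(i) random_dna(9), character(1))
  })
  for (model in list(train_pwm(tr$positives),
                     train_maxent(tr$positives),
                     table_model(stats::setNames(rnorm(5),
                                                 vapply(1:5, function(i)
                                                   random_dna(9), character(1)))))) {
    f <- withr::local_tempfile()
    write_splice_model(model, f)
    back <- read_splice_model(f)
    if (model$kind == "table") {
      expect_identical(back$table, model$table)
    } else {
      expect_identical(score_windows(back, wins)$score,
                       score_windows(model, wins)$score)
    }
  }
})

test_that("a decoy background replaces the base-frequency background", {
  tr <- simulate_donor_training_set(n = 100, seed = 17)
  pos <- train_pwm(tr$positives)
  dec <- train_pwm(tr$decoys)
  with_decoy <- attach_decoy(pos, dec)
  w <- "CAGGTAAGT"
  expect_equal(score_window(with_decoy, w),
               score_window(pos, w) - score_window(dec, w) +
                 sum(log2(0.25) - log2(0.25)),  # same uniform bg cancels
               tolerance = 1e-9)
})

test_that("tidy and glance summarise splice models", {
  td <- tidy(shared_pwm)
  expect_equal(nrow(td), 36)
  expect_equal(sum(td$freq), 9, tolerance = 1e-9)
  gl <- glance(shared_pwm)
  expect_equal(gl$kind, "pwm")
  expect_equal(gl$n_train, 300L)
})
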