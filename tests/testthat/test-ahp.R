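test_that("comparison matrix validation names the offending entry", {
  expect_s3_class(default_judgment_matrix(), "comparison_matrix")
  expect_s3_class(comparison_matrix(matrix(1, 5, 5)), "comparison_matrix")

  m <- matrix(1, 3, 3); m[1, 2] <- 2   # a21 should be 1/2, not 1
  expect_error(comparison_matrix(m), "\\(2,1\\)")
  m <- matrix(1, 3, 3); m[2, 2] <- 3
  expect_error(comparison_matrix(m), "diagonal")
  m <- matrix(1, 3, 3); m[3, 1] <- -1; m[1, 3] <- -1
  expect_error(comparison_matrix(m), "not positive")
  expect_error(comparison_matrix(matrix(1, 2, 3)), "square")
})

test_that("column sums of the default judgment matrix match the known fractions", {
  M <- default_judgment_matrix()
  expect_equal(unname(colSums(M)), c(11 / 3, 21 / 5, 11, 5, 7))
})

test_that("column-normalization weights sum to one and match references", {
  # bundled matrix: the reference weight vector at printed precision
  w <- ahp_weights(default_judgment_matrix())
  expect_equal(sum(w), 1)
  expect_lt(max(abs(w - ref_weights)), 1e-4)   # printed-precision agreement
  # reference vector was reported truncated at 4 decimals
  expect_equal(unname(floor(w * 1e4) / 1e4), unname(ref_weights))

  # uniform matrix -> uniform weights
  expect_equal(unname(ahp_weights(comparison_matrix(matrix(1, 4, 4)))),
               rep(0.25, 4))

  # 2x2 worked by hand: columns (1, 1/2) and (2, 1) both normalize to (2/3, 1/3)
  w2 <- ahp_weights(comparison_matrix(matrix(c(1, 0.5, 2, 1), 2, 2)))
  expect_equal(unname(w2), c(2 / 3, 1 / 3))
})

test_that("weights are invariant to reciprocity-preserving column rescaling", {
  # a_ij -> (s_i/s_j) a_ij keeps reciprocity; consistent part of the weights
  # must transform accordingly; for consistent matrices recovery is exact
  set.seed(19)
  for (i in 1:50) {
    wtrue <- runif(5, 0.1, 5)
    M <- comparison_matrix(outer(wtrue, wtrue, "/"))
    w <- ahp_weights(M)
    expect_equal(unname(w), wtrue / sum(wtrue), tolerance = 1e-12)
    cons <- ahp_consistency(M, w)
    expect_equal(cons$lambda_max, 5, tolerance = 1e-9)
    expect_equal(cons$CR, 0, tolerance = 1e-9)
    expect_true(cons$pass)
  }
})

test_that("consistency test follows Saaty's CI/RI/CR convention", {
  M <- default_judgment_matrix()
  cons <- ahp_consistency(M)
  expect_equal(cons$CI, (cons$lambda_max - 5) / 4)
  expect_equal(cons$RI, 1.12)
  expect_equal(cons$CR, cons$CI / 1.12)
  expect_true(cons$pass)                      # CR ~ 0.084 < 0.1
  # the mean-ratio estimate agrees with the dominant eigenvalue
  expect_equal(cons$lambda_max, power_eigen(M), tolerance = 0.05)

  # any reciprocal 2x2 matrix is consistent
  cons2 <- ahp_consistency(comparison_matrix(matrix(c(1, 1 / 7, 7, 1), 2, 2)))
  expect_true(cons2$pass)
  expect_equal(cons2$CR, 0)

  # a contradictory 3x3 matrix fails (A > B > C > A)
  bad <- comparison_matrix(matrix(c(1, 1 / 9, 9, 9, 1, 1 / 9, 1 / 9, 9, 1),
                                  3, 3, byrow = TRUE))
  consb <- ahp_consistency(bad)
  expect_false(consb$pass)
  expect_equal(consb$lambda_max, power_eigen(bad), tolerance = 0.5)
})

test_that("max normalization puts every column on (0, 1] with max exactly 1", {
  norm <- normalize_features(wheat_features())
  x <- as.matrix(norm[c("A", "P", "C", "E", "R")])
  expect_true(all(x > 0 & x <= 1))
  expect_equal(unname(apply(x, 2, max)), rep(1, 5))
  # reference normalized table at 4 decimals
  expect_equal(unname(wheatgrade:::round_half_up(x, 4)),
               unname(ref_normalized))

  const <- data.frame(Num = 1:3, A = 5, P = 5, C = 5, E = 5, R = 5)
  xc <- as.matrix(normalize_features(const)[c("A", "P", "C", "E", "R")])
  expect_true(all(xc == 1))

  bad <- data.frame(Num = 1, A = -1, P = 1, C = 1, E = 1, R = 1)
  expect_error(normalize_features(bad), "positive")
})

test_that("comprehensive score is the weighted sum and bounded by 1", {
  w <- ahp_weights(default_judgment_matrix())
  expect_equal(comprehensive_score(rep(1, 5), w), 1)
  expect_error(comprehensive_score(rep(1, 4), w), "length")

  # any normalized table scores in (0, 1]; the row-wise column max scores 1
  set.seed(23)
  for (i in 1:20) {
    feats <- data.frame(Num = 1:8,
                        A = runif(8, 1, 9), P = runif(8, 1, 9),
                        C = runif(8, 1, 9), E = runif(8, 1, 9),
                        R = runif(8, 1, 9))
    # add a seed attaining every column maximum
    feats <- rbind(feats, data.frame(Num = 9, A = 9.5, P = 9.5, C = 9.5,
                                     E = 9.5, R = 9.5))
    x <- as.matrix(normalize_features(feats)[c("A", "P", "C", "E", "R")])
    S <- comprehensive_score(x, w)
    expect_true(all(S > 0 & S <= 1 + 1e-12))
    expect_equal(S[9], 1)
  }
})

test_that("ranking is a permutation, descending, with ties broken by seed number", {
  r <- rank_seeds(c(0.5, 0.9))
  expect_equal(r, c(2L, 1L))
  r <- rank_seeds(rep(0.7, 5), num = 1:5)
  expect_equal(r, 1:5)
  set.seed(3)
  s <- runif(20)
  r <- rank_seeds(s)
  expect_setequal(r, 1:20)
  expect_true(all(diff(s[order(r)]) <= 0))
})

test_that("grade assignment is monotone with inclusive cut lines", {
  expect_equal(assign_grade(c(0.888, 0.52, 0.75)),
               c("excellent", "poor", "good"))
  expect_equal(assign_grade(0.8), "excellent")     # boundary inclusive
  expect_equal(assign_grade(0.7), "poor")          # boundary inclusive
  s <- seq(0, 1, by = 0.01)
  g <- assign_grade(s)
  lvl <- c(poor = 1, good = 2, excellent = 3)
  expect_true(all(diff(lvl[g]) >= 0))
  expect_error(assign_grade(0.5, excellent_cut = 0.6, poor_cut = 0.7),
               "exceed")
})

test_that("grade_seeds reproduces the bundled worked example end to end", {
  rep14 <- grade_seeds(wheat_features())
  expect_s3_class(rep14, "grade_report")
  expect_equal(rep14$Num, ref_order)                      # full ranking
  expect_equal(rep14$rank, 1:14)
  byNum <- rep14[order(rep14$Num), ]
  expect_equal(byNum$S, ref_scores$S)                     # all 14 coefficients
  expect_equal(sort(rep14$Num[rep14$grade == "excellent"]),
               c(4, 8, 9, 12, 13, 14))
  # full-precision mode differs only at reporting precision
  full <- grade_seeds(wheat_features(), digits = NULL)
  expect_equal(full[order(full$Num), ]$S, ref_scores$S, tolerance = 3e-4)
  expect_equal(full$Num[full$rank == 1], 12)
})

test_that("grade_seeds flags inconsistent judgment matrices", {
  contradictory <- matrix(1, 5, 5)
  contradictory[1, 2] <- 9; contradictory[2, 1] <- 1 / 9
  contradictory[2, 3] <- 9; contradictory[3, 2] <- 1 / 9
  contradictory[3, 1] <- 9; contradictory[1, 3] <- 1 / 9
  M <- comparison_matrix(contradictory, criteria = c("A", "P", "C", "E", "R"))
  expect_warning(grade_seeds(wheat_features(), M), "consistency")
  expect_error(grade_seeds(wheat_features(), M, strict_consistency = TRUE),
               "consistency")
})

test_that("evaluate_grading reports exact mismatch rates", {
  rep14 <- grade_seeds(wheat_features())
  truth <- wheat_truth()

  # identical prediction and truth -> 0%
  self <- data.frame(Num = rep14$Num, grade = rep14$grade)
  expect_equal(evaluate_grading(rep14, self)$error_rate, 0)

  # k planted flips among n -> 100 * k/n
  set.seed(9)
  for (k in c(1, 3, 5)) {
    flipped <- self
    idx <- sample(nrow(flipped), k)
    flipped$grade[idx] <- ifelse(flipped$grade[idx] == "poor",
                                 "excellent", "poor")
    ev <- evaluate_grading(rep14, flipped)
    expect_equal(ev$error_rate, 100 * k / 14)
    expect_equal(ev$n_errors, k)
  }

  # against the expert labels the bundled example disagrees on seeds 1, 2, 3
  ev <- evaluate_grading(rep14, truth)
  expect_equal(ev$n_errors, 3)
  expect_equal(ev$mismatches$Num, c(1, 2, 3))
  expect_equal(ev$error_rate, 100 * 3 / 14)

  expect_error(evaluate_grading(rep14, truth[1:10, ]), "missing ground-truth")
})

test_that("comparison matrices round-trip through CSV (with fractions) and JSON", {
  path <- system.file("extdata", "judgment_matrix.csv", package = "wheatgrade")
  M <- read_comparison_matrix(path)
  expect_equal(unclass(M), unclass(default_judgment_matrix()))

  jpath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(criteria = c("A", "P", "C", "E", "R"),
                            matrix = unclass(default_judgment_matrix())),
                       jpath, digits = NA, auto_unbox = TRUE)
  expect_equal(unclass(read_comparison_matrix(jpath)),
               unclass(default_judgment_matrix()))
})

test_that("grade reports are written as CSV plus JSON summary", {
  rep14 <- grade_seeds(wheat_features())
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_grade_report(rep14, csv, json_path = js, truth = wheat_truth())
  back <- read.csv(csv)
  expect_equal(names(back), c("Num", "S", "rank", "grade"))
  expect_equal(back$Num, ref_order)
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(summ$CR, ahp_consistency(default_judgment_matrix())$CR)
  expect_equal(summ$error_rate, 100 * 3 / 14)
})
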