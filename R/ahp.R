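#' Pairwise comparison (judgment) matrix
#'
#' Constructs and validates an AHP judgment matrix: a positive reciprocal
#' matrix whose entry \eqn{a_{ij}} expresses, on Saaty's 1--9 scale, how much
#' more important criterion \eqn{i} is than criterion \eqn{j}. Validation
#' requires \eqn{a_{ij} > 0}, a unit diagonal and reciprocity
#' \eqn{a_{ij} = 1/a_{ji}} within `tol`.
#'
#' @param x an `n x n` numeric matrix.
#' @param criteria character vector of criterion names; defaults to existing
#'   dimnames or `C1..Cn`. The seed-grading model uses
#'   `c("A","P","C","E","R")`: area, perimeter, circularity, elongation,
#'   rectangularity, in that fixed order.
#' @param tol tolerance for the reciprocity and unit-diagonal checks.
#' @return a matrix of class `comparison_matrix`.
#' @seealso [default_judgment_matrix()] for the bundled seed-grading matrix.
#' @export
comparison_matrix <- function(x, criteria = NULL, tol = 1e-9) {
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) != ncol(x))
    stop("a comparison matrix must be a square numeric matrix")
  n <- nrow(x)
  if (is.null(criteria)) criteria <- colnames(x)
  if (is.null(criteria)) criteria <- paste0("C", seq_len(n))
  if (length(criteria) != n) stop("`criteria` must have one name per row")
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("entry (%d,%d) = %g is not positive",
                 bad[1L, 1L], bad[1L, 2L], x[bad[1L, , drop = FALSE]]))
  bad <- which(abs(diag(x) - 1) > tol)
  if (length(bad))
    stop(sprintf("diagonal entry (%d,%d) = %g must be 1",
                 bad[1L], bad[1L], x[bad[1L], bad[1L]]))
  rec <- abs(x * t(x) - 1) > tol
  if (any(rec)) {
    ij <- which(rec, arr.ind = TRUE)
    ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE][1L, ]
    stop(sprintf(
      "reciprocity violated at (%d,%d): a[%d,%d] = %g but a[%d,%d] = %g",
      ij[2L], ij[1L], ij[1L], ij[2L], x[ij[1L], ij[2L]],
      ij[2L], ij[1L], x[ij[2L], ij[1L]]))
  }
  dimnames(x) <- list(criteria, criteria)
  structure(x, class = c("comparison_matrix", "matrix"))
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat("Pairwise comparison matrix (", nrow(x), " criteria)\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Default judgment matrix for the five seed descriptors
#'
#' The bundled expert judgment matrix over (A, P, C, E, R). Area and
#' perimeter are judged independent measurements and weighted up against
#' circularity (derived from A and P) and rectangularity (derived from A and
#' the axes); elongation sits in between.
#'
#' @return a 5x5 `comparison_matrix`.
#' @export
default_judgment_matrix <- function() {
  m <- matrix(c(1,     1,    3, 1, 3,
                1,     1,    5, 1, 1,
                1 / 3, 1 / 5, 1, 1, 1,
                1,     1,    1, 1, 1,
                1 / 3, 1,    1, 1, 1),
              nrow = 5L, byrow = TRUE)
  comparison_matrix(m, criteria = c("A", "P", "C", "E", "R"))
}

#' AHP weight vector by the column-normalization (arithmetic mean) method
#'
#' Each column of the judgment matrix is divided by its column sum, and the
#' normalized rows are averaged:
#' \deqn{\omega_i = \frac{1}{n} \sum_j \frac{a_{ij}}{\sum_k a_{kj}}.}
#' The result always sums to 1. For a perfectly consistent matrix
#' (\eqn{a_{ij} = w_i / w_j}) this recovers \eqn{w / \sum w} exactly.
#'
#' @param M a `comparison_matrix` (validated on the way in).
#' @return a named numeric weight vector summing to 1.
#' @export
ahp_weights <- function(M) {
  M <- comparison_matrix(M)
  w <- rowMeans(sweep(unclass(M), 2L, colSums(M), "/"))
  names(w) <- rownames(M)
  w
}

# Saaty's random consistency index by matrix order n (n = 1..10)
.saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Consistency test of a judgment matrix
#'
#' Estimates the principal eigenvalue as
#' \eqn{\lambda_{max} = \frac{1}{n}\sum_i (M\omega)_i / \omega_i} using the
#' arithmetic-mean weights (the same computation path that produced
#' \eqn{\omega}), then applies Saaty's test: consistency index
#' \eqn{CI = (\lambda_{max} - n)/(n - 1)}, consistency ratio
#' \eqn{CR = CI / RI} with the random index \eqn{RI} tabulated for matrix
#' order \eqn{n}. Judgments are acceptably consistent when \eqn{CR < 0.1};
#' matrices of order 2 or less are always consistent.
#'
#' @param M a `comparison_matrix`.
#' @param w optional weight vector; defaults to [ahp_weights()] of `M`.
#' @return a list with `lambda_max`, `CI`, `RI`, `CR` and logical `pass`.
#' @export
ahp_consistency <- function(M, w = ahp_weights(M)) {
  M <- comparison_matrix(M)
  n <- nrow(M)
  if (any(w <= 0)) stop("weights must be positive")
  lambda_max <- mean((unclass(M) %*% w) / w)
  if (n <= 2L)
    return(list(lambda_max = lambda_max, CI = 0, RI = 0, CR = 0, pass = TRUE))
  CI <- (lambda_max - n) / (n - 1)
  RI <- if (n <= length(.saaty_ri)) .saaty_ri[n] else 1.49
  CR <- if (RI > 0) CI / RI else 0
  list(lambda_max = lambda_max, CI = CI, RI = RI, CR = CR, pass = CR < 0.1)
}

#' Normalize a feature table by its column maxima
#'
#' Each of the five feature columns is divided by its column maximum
#' (\eqn{A' = A/A_0}, etc., with \eqn{A_0} the sample maximum), putting all
#' criteria on a common (0, 1] scale in which the best-in-sample seed scores
#' 1 on each criterion.
#'
#' @param features a data frame with columns `Num, A, P, C, E, R` (or just
#'   the five feature columns).
#' @return a data frame of the same shape with normalized feature columns;
#'   the column maxima are attached as attribute `column_max`.
#' @export
normalize_features <- function(features) {
  cols <- c("A", "P", "C", "E", "R")
  if (!all(cols %in% names(features)))
    stop("`features` must have columns A, P, C, E, R")
  out <- features
  cmax <- vapply(features[cols], max, numeric(1L))
  if (any(!is.finite(cmax)) || any(cmax <= 0))
    stop("all column maxima must be positive and finite")
  if (any(features[cols] <= 0)) stop("all feature values must be positive")
  for (cl in cols) out[[cl]] <- features[[cl]] / cmax[[cl]]
  attr(out, "column_max") <- cmax
  out
}

#' Comprehensive evaluation coefficient
#'
#' The weighted sum \eqn{S = \sum_i \omega_i x_i} of a seed's normalized
#' feature row. With weights summing to 1 and normalized features in
#' (0, 1\], \eqn{S \in (0, 1]}; a seed attaining the sample maximum on every
#' criterion scores exactly 1.
#'
#' @param x a normalized feature row (length-n numeric) or an `m x n` matrix
#'   / data frame of rows, ordered as the weights.
#' @param w a weight vector from [ahp_weights()].
#' @return the score(s) `S`.
#' @export
comprehensive_score <- function(x, w) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (ncol(x) != length(w))
      stop("`x` has ", ncol(x), " columns but `w` has length ", length(w))
    return(as.vector(x %*% w))
  }
  if (length(x) != length(w))
    stop("`x` has length ", length(x), " but `w` has length ", length(w))
  sum(x * w)
}

#' Rank seeds by score
#'
#' Rank 1 is the largest score; ties are broken by ascending seed number.
#'
#' @param scores numeric scores, one per seed.
#' @param num seed numbers (default `1..n`), used for tie-breaking.
#' @return an integer rank vector aligned with `scores`.
#' @export
rank_seeds <- function(scores, num = seq_along(scores)) {
  ord <- order(-scores, num)
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  ranks
}

#' Assign a grade from the comprehensive coefficient
#'
#' `excellent` for \eqn{S \ge} the excellent cut line (default 0.8), `poor`
#' for \eqn{S \le} the poor cut line (default 0.7), `good` in between. Both
#' cut lines are inclusive.
#'
#' @param S numeric score(s).
#' @param excellent_cut,poor_cut the two cut lines
#'   (`excellent_cut > poor_cut`).
#' @return a character vector of grades.
#' @export
assign_grade <- function(S, excellent_cut = 0.8, poor_cut = 0.7) {
  if (excellent_cut <= poor_cut)
    stop("`excellent_cut` must exceed `poor_cut`")
  ifelse(S >= excellent_cut, "excellent",
         ifelse(S <= poor_cut, "poor", "good"))
}

#' Grade a table of seed features by the AHP model
#'
#' Runs the full grading engine: validates the judgment matrix, derives the
#' weight vector, tests consistency, normalizes the features by column
#' maxima, computes each seed's comprehensive coefficient
#' \eqn{S = \omega \cdot (A', P', C', E', R')}, ranks the seeds by descending
#' \eqn{S}, and assigns grades at the two cut lines.
#'
#' `digits` controls the reporting precision of the intermediate tables, as
#' in a hand-computed AHP worksheet: normalized features are rounded
#' (half-up) and the weight vector truncated to `digits` decimals before the
#' weighted sum, and \eqn{S} is reported rounded to `digits`. Truncation of
#' the weights keeps their reported sum from exceeding 1. Set
#' `digits = NULL` for full-precision arithmetic throughout.
#'
#' @param features a feature data frame `Num, A, P, C, E, R` (e.g. from
#'   [feature_table()] or [wheat_features()]).
#' @param matrix a `comparison_matrix`; default [default_judgment_matrix()].
#' @param digits intermediate/reporting precision (default 4); `NULL` for
#'   full precision.
#' @param excellent_cut,poor_cut grade cut lines, passed to
#'   [assign_grade()].
#' @param strict_consistency if `TRUE`, a judgment matrix failing Saaty's
#'   CR < 0.1 test is an error; by default it only warns.
#' @return a `grade_report`: a data frame `Num, S, rank, grade` sorted by
#'   rank, with attributes `weights` (the full-precision weight vector),
#'   `consistency` (see [ahp_consistency()]), `normalized` (the normalized
#'   feature table as used for scoring) and `column_max`.
#' @export
grade_seeds <- function(features, matrix = default_judgment_matrix(),
                        digits = 4L, excellent_cut = 0.8, poor_cut = 0.7,
                        strict_consistency = FALSE) {
  cols <- c("A", "P", "C", "E", "R")
  M <- comparison_matrix(matrix)
  if (nrow(M) != length(cols) || !identical(rownames(M), cols))
    stop("the judgment matrix must be 5 x 5 over criteria A, P, C, E, R")
  if (!"Num" %in% names(features))
    features$Num <- seq_len(nrow(features))
  if (nrow(features) == 0L) stop("`features` has no rows")

  w <- ahp_weights(M)
  cons <- ahp_consistency(M, w)
  if (!cons$pass) {
    msg <- sprintf("judgment matrix fails the consistency test (CR = %.3f >= 0.1)",
                   cons$CR)
    if (strict_consistency) stop(msg) else warning(msg)
  }
  norm <- normalize_features(features)
  x <- as.matrix(norm[cols])
  w_used <- w
  if (!is.null(digits)) {
    x <- round_half_up(x, digits)
    w_used <- trunc_digits(w, digits)
  }
  S <- comprehensive_score(x, w_used)
  if (!is.null(digits)) S <- round_half_up(S, digits)
  rank <- rank_seeds(S, features$Num)
  report <- data.frame(Num = features$Num, S = S, rank = rank,
                       grade = assign_grade(S, excellent_cut, poor_cut))
  report <- report[order(report$rank), ]
  rownames(report) <- NULL
  structure(report,
            class = c("grade_report", "data.frame"),
            weights = w, consistency = cons,
            normalized = norm, column_max = attr(norm, "column_max"),
            digits = digits)
}

#' @export
print.grade_report <- function(x, ...) {
  cons <- attr(x, "consistency")
  w <- attr(x, "weights")
  dg <- attr(x, "digits")
  wshow <- if (is.null(dg)) w else trunc_digits(w, dg)
  cat("AHP seed grade report (", nrow(x), " seeds)\n", sep = "")
  cat("weights (", paste(names(w), collapse = " "), "): ",
      paste(format(wshow, trim = TRUE), collapse = " "), "\n", sep = "")
  cat(sprintf("lambda_max = %.4f, CI = %.4f, CR = %.4f (%s)\n",
              cons$lambda_max, cons$CI, cons$CR,
              if (cons$pass) "consistent" else "NOT consistent"))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Compare predicted grades with ground truth
#'
#' @param report a `grade_report` from [grade_seeds()], or any data frame
#'   with columns `Num` and `grade`.
#' @param truth a data frame with columns `Num` and `grade` covering every
#'   graded seed.
#' @return a list with `error_rate` (percent), `n`, `n_errors`,
#'   `mismatches` (data frame `Num, predicted, truth`) and `confusion`
#'   (a predicted x truth contingency table).
#' @export
evaluate_grading <- function(report, truth) {
  if (!all(c("Num", "grade") %in% names(truth)))
    stop("`truth` must have columns Num and grade")
  i <- match(report$Num, truth$Num)
  if (anyNA(i))
    stop("missing ground-truth label for seed(s): ",
         paste(report$Num[is.na(i)], collapse = ", "))
  pred <- as.character(report$grade)
  tr <- as.character(truth$grade[i])
  lev <- c("excellent", "good", "poor")
  bad <- pred != tr
  mism <- data.frame(Num = report$Num[bad], predicted = pred[bad],
                     truth = tr[bad])
  mism <- mism[order(mism$Num), ]
  rownames(mism) <- NULL
  list(error_rate = 100 * sum(bad) / length(bad),
       n = length(bad), n_errors = sum(bad),
       mismatches = mism,
       confusion = table(predicted = factor(pred, lev),
                         truth = factor(tr, lev)))
}

#' Write a grade report to CSV, with a JSON summary
#'
#' Writes `Num,S,rank,grade` as CSV; if `json_path` is given, also writes a
#' JSON summary with the weight vector, `lambda_max`, `CR`, and (when
#' `truth` is supplied) the error rate in percent.
#'
#' @param report a `grade_report`.
#' @param path output CSV path.
#' @param json_path optional JSON summary path.
#' @param truth optional ground-truth data frame for [evaluate_grading()].
#' @return `path`, invisibly.
#' @export
write_grade_report <- function(report, path, json_path = NULL, truth = NULL) {
  write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    cons <- attr(report, "consistency")
    summary <- list(weights = as.list(attr(report, "weights")),
                    lambda_max = cons$lambda_max, CR = cons$CR,
                    consistency_pass = cons$pass)
    if (!is.null(truth))
      summary$error_rate <- evaluate_grading(report, truth)$error_rate
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
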