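#' Bundled 14-seed example dataset
#'
#' A reference table of five geometric descriptors for 14 wheat seeds
#' (numbers 1--14), together with expert grade labels: 6 excellent seeds
#' (4, 8, 9, 12, 13, 14), 4 good (1, 6, 10, 11) and 4 poor (2, 3, 5, 7).
#' Grading this table with the [default_judgment_matrix()] is the package's
#' worked example (see [grade_demo()]). The feature table was transcribed
#' with the perimeter entries of seeds 4 and 5 reconciled against its
#' published normalized counterpart, whose row order fixes the two values.
#'
#' The descriptor columns are on the instrument's own scales (the
#' circularity and rectangularity magnitudes imply a hidden unit
#' conversion); the grading model is insensitive to per-column scale because
#' every column is normalized by its maximum.
#'
#' @return `wheat_features()`: a 14-row data frame `Num, A, P, C, E, R`.
#' @export
wheat_features <- function() {
  read_feature_table(system.file("extdata", "wheat14_features.csv",
                                 package = "wheatgrade", mustWork = TRUE))
}

#' @rdname wheat_features
#' @return `wheat_truth()`: a 14-row data frame `Num, grade` with the expert
#'   labels.
#' @export
wheat_truth <- function() {
  df <- read.csv(system.file("extdata", "wheat14_grades.csv",
                             package = "wheatgrade", mustWork = TRUE))
  df$grade <- as.character(df$grade)
  df
}
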