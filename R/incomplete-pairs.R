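#' Partially paired two-sample data
#'
#' Container for a partially paired (incomplete correlated) dataset: `n`
#' subjects observed under both conditions (complete pairs), `n1` subjects
#' with only the first measurement and `n2` with only the second. This is the
#' design of a crossover or pre/post study in which missingness is completely
#' at random, so the three blocks can be treated as independent samples.
#'
#' @param x1 Numeric vector of first-condition measurements, `NA` where
#'   missing.
#' @param x2 Numeric vector of second-condition measurements, same length as
#'   `x1`. A row with both values missing is rejected.
#' @return An object of class `"incomplete_pairs"`: a list with components
#'   `paired` (two-column matrix of complete pairs), `x1_only`, `x2_only`.
#' @examples
#' d <- incomplete_pairs(c(1.2, 3.1, 2.0, 4.5, NA), c(1.0, 2.8, NA, 4.0, 2.2))
#' d
#' @seealso [read_incomplete_pairs()], [fev1_formoterol()], [pair_summary()]
#' @export
incomplete_pairs <- function(x1, x2) {
  x1 <- as.numeric(x1)
  x2 <- as.numeric(x2)
  if (length(x1) != length(x2))
    stop("'x1' and 'x2' must have the same length", call. = FALSE)
  both_na <- is.na(x1) & is.na(x2)
  if (any(both_na))
    stop("row(s) ", paste(which(both_na), collapse = ", "),
         " have both values missing", call. = FALSE)
  vals <- c(x1[!is.na(x1)], x2[!is.na(x2)])
  if (any(!is.finite(vals)))
    stop("all observed values must be finite", call. = FALSE)
  p <- !is.na(x1) & !is.na(x2)
  out <- list(
    paired  = cbind(x1 = x1[p], x2 = x2[p]),
    x1_only = x1[!is.na(x1) & is.na(x2)],
    x2_only = x2[is.na(x1) & !is.na(x2)]
  )
  class(out) <- "incomplete_pairs"
  validate_incomplete_pairs(out)
}

validate_incomplete_pairs <- function(x) {
  if (nrow(x$paired) < 2L)
    stop("at least 2 complete pairs are required (variances over the paired ",
         "block need n >= 2); got ", nrow(x$paired), call. = FALSE)
  x
}

#' @rdname incomplete_pairs
#' @param paired Two-column matrix (or data frame) of complete pairs.
#' @param x1_only,x2_only Numeric vectors of unpaired observations.
#' @export
incomplete_pairs_blocks <- function(paired, x1_only = numeric(),
                                    x2_only = numeric()) {
  paired <- as.matrix(paired)
  storage.mode(paired) <- "double"
  if (ncol(paired) != 2L)
    stop("'paired' must have two columns", call. = FALSE)
  colnames(paired) <- c("x1", "x2")
  out <- list(paired = paired, x1_only = as.numeric(x1_only),
              x2_only = as.numeric(x2_only))
  if (any(!is.finite(unlist(out, use.names = FALSE))))
    stop("all values must be finite", call. = FALSE)
  class(out) <- "incomplete_pairs"
  validate_incomplete_pairs(out)
}

#' Read a partially paired dataset from CSV
#'
#' Expects two named columns `x1` and `x2`. Missing values may be encoded as
#' an empty cell, `NA`, or `NaN`. A row with both values missing is an error
#' that names the offending row. Row order carries no meaning.
#'
#' @param path Path to a CSV file.
#' @return An [incomplete_pairs()] object.
#' @export
read_incomplete_pairs <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA", "NaN"),
                        stringsAsFactors = FALSE)
  if (!all(c("x1", "x2") %in% names(df)))
    stop("CSV must contain columns 'x1' and 'x2'", call. = FALSE)
  incomplete_pairs(df$x1, df$x2)
}

#' FEV1 formoterol crossover data
#'
#' Forced expiratory volume in one second (litres) for 24 asthma patients in
#' a crossover trial of two doses (12 ug, 24 ug) of formoterol solution
#' aerosol: 7 patients measured under both doses, 9 under the 12 ug dose only
#' (`x1`) and 8 under the 24 ug dose only (`x2`).
#'
#' @return An [incomplete_pairs()] object with `n = 7`, `n1 = 9`, `n2 = 8`.
#' @examples
#' d <- fev1_formoterol()
#' summary(pair_summary(d))
#' @export
fev1_formoterol <- function() {
  incomplete_pairs_blocks(
    paired = cbind(
      c(2.250, 0.925, 1.010, 2.100, 2.500, 1.750, 1.370),
      c(2.700, 0.900, 1.270, 2.150, 2.450, 1.725, 1.120)),
    x1_only = c(3.400, 2.250, 1.460, 1.480, 2.050, 3.500, 2.650, 2.190, 0.840),
    x2_only = c(1.750, 2.525, 1.080, 3.120, 3.100, 2.700, 1.870, 0.940))
}

#' @export
print.incomplete_pairs <- function(x, ...) {
  cat("Partially paired sample\n")
  cat(sprintf("  complete pairs: n  = %d\n", nrow(x$paired)))
  cat(sprintf("  x1 only:        n1 = %d\n", length(x$x1_only)))
  cat(sprintf("  x2 only:        n2 = %d\n", length(x$x2_only)))
  invisible(x)
}

#' @export
as.data.frame.incomplete_pairs <- function(x, ...) {
  data.frame(
    x1 = c(x$paired[, 1L], x$x1_only, rep(NA_real_, length(x$x2_only))),
    x2 = c(x$paired[, 2L], rep(NA_real_, length(x$x1_only)), x$x2_only)
  )
}

# label swap: exchange the roles of x1 and x2 (used for antisymmetry checks)
#' Swap the two measurement labels
#'
#' Returns the sample with `x1` and `x2` exchanged (and the unpaired blocks
#' swapped accordingly). Every interval method is antisymmetric under this
#' swap: the interval for the swapped sample is the negated, reversed
#' interval.
#'
#' @param x An [incomplete_pairs()] object.
#' @export
swap_labels <- function(x) {
  incomplete_pairs_blocks(x$paired[, c(2L, 1L)], x$x2_only, x$x1_only)
}
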