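#' Tabulate a pair of elements into a 2x2 table
#'
#' @param x a binary matrix (elements in rows, samples in columns), as
#'   returned by [read_binary_matrix()] or [sample_states()].
#' @param a,b distinct row labels (or indices) of \code{x}.
#' @return A \code{pair_table}: list with counts \code{n00}, \code{n01},
#'   \code{n10}, \code{n11} and total \code{N}, where \code{nab} counts
#'   samples with element \code{a} in state \code{a} and element \code{b}
#'   in state \code{b}.
#' @examples
#' tabulate_pair(fig2_fixture()$states, "A", "B")
#' @export
tabulate_pair <- function(x, a, b) {
  x <- .check_binary_matrix(x)
  if (is.numeric(a)) a <- rownames(x)[a]
  if (is.numeric(b)) b <- rownames(x)[b]
  if (is.na(a) || is.na(b) || !(a %in% rownames(x)) || !(b %in% rownames(x)))
    stop("unknown element label", call. = FALSE)
  if (identical(a, b))
    stop("a pair needs two distinct elements", call. = FALSE)
  av <- x[a, ]; bv <- x[b, ]
  pair_table(n00 = sum(av == 0 & bv == 0), n01 = sum(av == 0 & bv == 1),
             n10 = sum(av == 1 & bv == 0), n11 = sum(av == 1 & bv == 1))
}

#' Construct a 2x2 pair table from cell counts
#'
#' @param n00,n01,n10,n11 non-negative cell counts.
#' @return An object of class \code{pair_table}.
#' @export
pair_table <- function(n00, n01, n10, n11) {
  n <- c(n00 = n00, n01 = n01, n10 = n10, n11 = n11)
  if (any(n < 0) || any(n != round(n)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  out <- as.list(stats::setNames(as.integer(n), names(n)))
  out$N <- as.integer(sum(n))
  if (out$N < 1L) stop("a pair table needs at least one sample",
                       call. = FALSE)
  structure(out, class = "pair_table")
}

.cell_counts <- function(table) {
  c(n00 = table$n00, n01 = table$n01, n10 = table$n10, n11 = table$n11)
}

.cell_name <- function(a, b) paste0("n", a, b)

#' @export
print.pair_table <- function(x, ...) {
  m <- matrix(c(x$n00, x$n01, x$n10, x$n11), 2, 2, byrow = TRUE,
              dimnames = list(a = c(0, 1), b = c(0, 1)))
  cat("2x2 pair table, N =", x$N, "\n")
  print(m)
  invisible(x)
}

#' Counting numbers of the six relationships
#'
#' For each relationship kind, the counting number is the number of
#' samples whose observed cell is allowed under that relationship.  With a
#' true relationship and no measurement error the counting number equals
#' the sample size.
#'
#' @param table a [pair_table()].
#' @return A named integer vector over [relationship_kinds()].  Satisfies
#'   \code{SIM + SIM_DUAL = N} and \code{F01+F10+F00+F11 = 3N}.
#' @examples
#' relationship_counts(pair_table(1, 0, 6, 6))
#' @export
relationship_counts <- function(table) {
  stopifnot(inherits(table, "pair_table"))
  n <- .cell_counts(table)
  out <- vapply(relationship_kinds(), function(k) {
    ac <- allowed_cells(k)
    sum(n[.cell_name(ac[, 1], ac[, 2])])
  }, integer(1))
  out
}

#' Recover the 2x2 cells from the six counting numbers
#'
#' Inverse of [relationship_counts()]: each one-forbidden-cell count is
#' \code{N} minus the forbidden cell, so \code{nab = N - counts[Fab]}.
#'
#' @param counts named vector over [relationship_kinds()] (names may be in
#'   any order).
#' @param N the sample size.
#' @return A [pair_table()].
#' @examples
#' cells_from_counts(c(SIM = 55, SIM_DUAL = 45, F01 = 98, F10 = 57,
#'                     F00 = 90, F11 = 55), N = 100)
#' @export
cells_from_counts <- function(counts, N) {
  need <- relationship_kinds()
  if (!all(need %in% names(counts)))
    stop("counts must be named by the six relationship kinds",
         call. = FALSE)
  counts <- counts[need]
  if (counts[["SIM"]] + counts[["SIM_DUAL"]] != N ||
      sum(counts[c("F01", "F10", "F00", "F11")]) != 3 * N)
    stop("inconsistent counting numbers: SIM+SIM_DUAL must equal N and ",
         "the four prerequisite counts must sum to 3N", call. = FALSE)
  tab <- pair_table(n00 = N - counts[["F00"]], n01 = N - counts[["F01"]],
                    n10 = N - counts[["F10"]], n11 = N - counts[["F11"]])
  if (!identical(unname(relationship_counts(tab)), unname(as.integer(counts))))
    stop("inconsistent counting numbers", call. = FALSE)
  tab
}

.check_eps <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon < 0 || epsilon >= 0.5)
    stop("epsilon must lie in [0, 0.5)", call. = FALSE)
  epsilon
}

#' Counting-number threshold for the similar relationships
#'
#' Lower confidence bound for the counting number of a true similar
#' relationship under independent per-entry misclassification at rate
#' \code{epsilon}.  A sample stays in an allowed (diagonal) cell when both
#' entries are kept or both flipped, so the counting number is binomial
#' with success probability \eqn{\pi = (1-\epsilon)^2 + \epsilon^2}; the
#' threshold is \eqn{N\pi - z_\alpha\sqrt{N\pi(1-\pi)}}.
#'
#' @param N sample size.
#' @param epsilon misclassification probability, in \eqn{[0, 0.5)}.
#' @param alpha one-sided tail probability of the bound (default 0.05).
#' @return The real-valued bound; the integer screening threshold is its
#'   ceiling (see [screen_counts()]).
#' @examples
#' ceiling(similar_threshold(100, 0.05))   # 86
#' ceiling(similar_threshold(81, 0.1))     # 61
#' @export
similar_threshold <- function(N, epsilon, alpha = 0.05) {
  .check_eps(epsilon)
  p <- (1 - epsilon)^2 + epsilon^2
  N * p - stats::qnorm(1 - alpha) * sqrt(N * p * (1 - p))
}

#' Counting-number threshold for the prerequisite relationships
#'
#' Lower confidence bound for the counting number of a true prerequisite
#' relationship.  A single forbidden cell leaks at most
#' \eqn{\epsilon(1-\epsilon)} probability through single-coordinate flips
#' plus at most \eqn{\epsilon^2 \le \epsilon(1-\epsilon)/2} (for
#' \eqn{\epsilon \le 1/3}) through double flips, giving the conservative
#' mean bound \eqn{N[1 - \tfrac{3}{2}\epsilon(1-\epsilon)]}; the
#' fluctuation term is evaluated at the double-flip rate,
#' \eqn{z_\alpha\,\epsilon\sqrt{N(1-\epsilon^2)}}.
#'
#' @inheritParams similar_threshold
#' @return The real-valued bound; ceiling gives the integer threshold.
#' @examples
#' ceiling(prerequisite_threshold(100, 0.05))   # 93
#' ceiling(prerequisite_threshold(81, 0.1))     # 69
#' @export
prerequisite_threshold <- function(N, epsilon, alpha = 0.05) {
  .check_eps(epsilon)
  N * (1 - 1.5 * epsilon * (1 - epsilon)) -
    stats::qnorm(1 - alpha) * epsilon * sqrt(N * (1 - epsilon^2))
}

#' Step-1 screening of the counting numbers
#'
#' Selects the relationship kinds whose counting number reaches the
#' integer (ceiling) threshold: [similar_threshold()] for \code{SIM} and
#' \code{SIM_DUAL}, [prerequisite_threshold()] for the four prerequisite
#' kinds.
#'
#' @param counts a vector from [relationship_counts()].
#' @param N sample size the counts refer to.
#' @inheritParams similar_threshold
#' @return Character vector of selected kinds (possibly empty).
#' @export
screen_counts <- function(counts, N, epsilon, alpha = 0.05) {
  t_sim <- ceiling(similar_threshold(N, epsilon, alpha))
  t_pre <- ceiling(prerequisite_threshold(N, epsilon, alpha))
  ks <- relationship_kinds()
  thr <- ifelse(ks %in% c("SIM", "SIM_DUAL"), t_sim, t_pre)
  ks[counts[ks] >= thr]
}
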