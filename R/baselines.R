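#' Boolean-implication (sparseness) statistics for one quadrant
#'
#' The comparison baseline tests an implication between two elements by
#' checking that its predicted-empty quadrant of the 2x2 table is sparse:
#' the sparseness statistic is \eqn{(E - O)/\sqrt{E}} with
#' \eqn{E = (\mathrm{row\ total} \times \mathrm{column\ total})/N} the
#' independence expectation of the quadrant and \eqn{O} its observed
#' count; the error-rate statistic is the symmetric mean of the quadrant
#' fraction against its two margins,
#' \eqn{\tfrac12 (O/\mathrm{row} + O/\mathrm{col})}.  An implication is
#' called when the sparseness exceeds \code{s_min} and the error rate
#' stays below \code{err_max}.
#'
#' @param table a [pair_table()].
#' @param direction the sparse quadrant, one of \code{"01"}, \code{"10"},
#'   \code{"00"}, \code{"11"} (the quadrant an \code{F}-relationship of
#'   the same name forbids).
#' @param s_min,err_max decision cutoffs (defaults 3 and 0.1).
#' @return A list of class \code{sahoo_result}: \code{direction},
#'   \code{sparseness_stat}, \code{error_rate}, \code{called}.
#' @examples
#' sahoo_statistics(pair_table(30, 1, 30, 30), "01")  # sparseness 2.94
#' @export
sahoo_statistics <- function(table, direction = c("01", "10", "00", "11"),
                             s_min = 3, err_max = 0.1) {
  stopifnot(inherits(table, "pair_table"))
  direction <- match.arg(direction)
  n <- .cell_counts(table); N <- table$N
  av <- as.integer(substr(direction, 1, 1))
  bv <- as.integer(substr(direction, 2, 2))
  O <- n[[.cell_name(av, bv)]]
  row_tot <- n[[.cell_name(av, 0)]] + n[[.cell_name(av, 1)]]
  col_tot <- n[[.cell_name(0, bv)]] + n[[.cell_name(1, bv)]]
  if (row_tot == 0 || col_tot == 0) {
    s <- NA_real_; err <- NA_real_
    warning("zero margin: sparseness statistic undefined", call. = FALSE)
  } else {
    E <- row_tot * col_tot / N
    s <- (E - O) / sqrt(E)
    err <- 0.5 * (O / row_tot + O / col_tot)
  }
  structure(list(direction = direction, sparseness_stat = s,
                 error_rate = err,
                 called = isTRUE(s > s_min) && isTRUE(err < err_max)),
            class = "sahoo_result")
}

#' @export
print.sahoo_result <- function(x, ...) {
  cat(sprintf("quadrant (%s,%s): sparseness %.2f, error rate %.3f -> %s\n",
              substr(x$direction, 1, 1), substr(x$direction, 2, 2),
              x$sparseness_stat, x$error_rate,
              if (x$called) "called" else "not called"))
  invisible(x)
}

#' Boolean-implication screen over a binary matrix
#'
#' Applies [sahoo_statistics()] to every quadrant of every element pair.
#' A called quadrant maps to the prerequisite relationship forbidding that
#' quadrant; two called off-diagonal (diagonal) quadrants merge into a
#' similarity (dual-similarity) call.
#'
#' @param x binary matrix, elements in rows.
#' @param s_min,err_max decision cutoffs (defaults 3 and 0.1).
#' @return A [pair_relations()] set of called relationships.
#' @export
sahoo_screen <- function(x, s_min = 3, err_max = 0.1) {
  x <- .check_binary_matrix(x)
  els <- rownames(x)
  a <- character(); b <- character(); kind <- character()
  if (nrow(x) >= 2) for (i in seq_len(nrow(x) - 1L)) for (j in (i + 1L):nrow(x)) {
    tb <- tabulate_pair(x, els[i], els[j])
    hit <- vapply(c("01", "10", "00", "11"), function(d)
      suppressWarnings(sahoo_statistics(tb, d, s_min, err_max)$called),
      logical(1))
    ks <- if (any(hit)) paste0("F", names(hit)[hit]) else character(0)
    if (all(c("F01", "F10") %in% ks)) ks <- c("SIM", setdiff(ks, c("F01", "F10")))
    if (all(c("F00", "F11") %in% ks)) ks <- c(setdiff(ks, c("F00", "F11")), "SIM_DUAL")
    if (length(ks)) {
      a <- c(a, rep(els[i], length(ks)))
      b <- c(b, rep(els[j], length(ks)))
      kind <- c(kind, ks)
    }
  }
  pair_relations(a, b, kind)
}

#' Relationship-constrained misclassification rate (comparison criterion)
#'
#' The second comparison baseline scores a candidate relationship by the
#' maximum-likelihood misclassification rate under the multinomial model
#' constrained to that relationship (forbidden true cells carry zero
#' probability): a true relationship needs only a small error rate to
#' explain the data.
#'
#' @param table a [pair_table()].
#' @param kind a tag from [relationship_kinds()].
#' @return The constrained estimate \eqn{\hat\epsilon \in [0, 0.5)}.
#' @examples
#' lilu_relation_epsilon(pair_table(50, 0, 0, 50), "SIM")   # 0
#' @export
lilu_relation_epsilon <- function(table, kind) {
  estimate_epsilon(table, kind = kind)$epsilon_hat
}

#' Constrained-epsilon screen over a binary matrix
#'
#' Calls, for every pair, the relationship kinds whose constrained
#' misclassification estimate [lilu_relation_epsilon()] falls below
#' \code{eps_cutoff}; the minimum-estimate kind per pair is flagged in the
#' attribute \code{"best"}.
#'
#' @param x binary matrix, elements in rows.
#' @param eps_cutoff cutoff on the constrained estimate.
#' @return A [pair_relations()] set with attribute \code{"best"} (data
#'   frame of the per-pair minimising kind and its estimate).
#' @export
lilu_screen <- function(x, eps_cutoff) {
  x <- .check_binary_matrix(x)
  els <- rownames(x)
  a <- character(); b <- character(); kind <- character()
  best <- NULL
  if (nrow(x) >= 2) for (i in seq_len(nrow(x) - 1L)) for (j in (i + 1L):nrow(x)) {
    tb <- tabulate_pair(x, els[i], els[j])
    eh <- vapply(relationship_kinds(), function(k)
      lilu_relation_epsilon(tb, k), numeric(1))
    ks <- names(eh)[eh < eps_cutoff]
    if ("SIM" %in% ks) ks <- setdiff(ks, c("F01", "F10"))
    if ("SIM_DUAL" %in% ks) ks <- setdiff(ks, c("F00", "F11"))
    if (length(ks)) {
      a <- c(a, rep(els[i], length(ks)))
      b <- c(b, rep(els[j], length(ks)))
      kind <- c(kind, ks)
    }
    best <- rbind(best, data.frame(a = els[i], b = els[j],
                                   kind = names(which.min(eh)),
                                   epsilon_hat = min(eh),
                                   stringsAsFactors = FALSE))
  }
  out <- pair_relations(a, b, kind)
  attr(out, "best") <- best
  out
}
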