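# 4x4 flip kernel on cell probabilities: entry [obs, true] is the
# probability that a sample in true cell `true` is observed in cell `obs`
# when each coordinate flips independently with probability epsilon.
# Cell order: (0,0), (0,1), (1,0), (1,1).
.flip_kernel <- function(epsilon) {
  A <- matrix(c(1 - epsilon, epsilon, epsilon, 1 - epsilon), 2, 2)
  kronecker(A, A)
}

#' Observed cell probabilities under misclassification
#'
#' Pushes a true cell distribution through the independent per-coordinate
#' bit-flip error model.
#'
#' @param true_probs numeric vector of length 4 over the cells
#'   \code{(0,0), (0,1), (1,0), (1,1)}; must be non-negative and sum to 1.
#' @param epsilon misclassification probability in \eqn{[0, 0.5]}.
#' @return The observed cell distribution (length 4, sums to 1).
#' @examples
#' observed_cell_probs(c(0.5, 0, 0, 0.5), 0.05)
#' @export
observed_cell_probs <- function(true_probs, epsilon) {
  if (length(true_probs) != 4L || any(true_probs < 0) ||
      abs(sum(true_probs) - 1) > 1e-8)
    stop("true_probs must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  if (epsilon < 0 || epsilon > 0.5)
    stop("epsilon must lie in [0, 0.5]", call. = FALSE)
  as.numeric(.flip_kernel(epsilon) %*% true_probs)
}

#' Misclassification-corrected cell probability estimates
#'
#' Applies the exact algebraic inverse of the flip kernel to the empirical
#' observed frequencies; this is the closed-form estimator of the true
#' cell probabilities when \code{epsilon} is known.  The raw inverse may
#' leave \eqn{[0,1]}; a clipped-and-renormalised copy is returned
#' alongside with a flag.
#'
#' @param table a [pair_table()].
#' @inheritParams observed_cell_probs
#' @return A list of class \code{cell_prob_estimate} with components
#'   \code{raw} (exact inverse), \code{clipped} (non-negative,
#'   renormalised), \code{out_of_range} flag and \code{epsilon}.
#' @examples
#' estimate_true_probs(pair_table(10, 2, 43, 45), 0.05)
#' @export
estimate_true_probs <- function(table, epsilon) {
  stopifnot(inherits(table, "pair_table"))
  if (epsilon >= 0.5)
    stop("the noise map is not invertible at epsilon = 0.5", call. = FALSE)
  .check_eps(epsilon)
  qhat <- .cell_counts(table) / table$N
  raw <- as.numeric(solve(.flip_kernel(epsilon), qhat))
  names(raw) <- names(qhat) <- c("p00", "p01", "p10", "p11")
  oor <- any(raw < 0) || any(raw > 1)
  clipped <- pmax(raw, 0)
  clipped <- clipped / sum(clipped)
  structure(list(raw = raw, clipped = clipped, out_of_range = oor,
                 epsilon = epsilon),
            class = "cell_prob_estimate")
}

#' @export
print.cell_prob_estimate <- function(x, ...) {
  cat("corrected cell probabilities (epsilon =", x$epsilon, ")\n")
  print(round(rbind(raw = x$raw, clipped = x$clipped), 4))
  if (x$out_of_range)
    cat("note: raw inverse left [0,1]; clipped copy renormalised\n")
  invisible(x)
}

# forbidden / reference cells per kind on the (n00,n01,n10,n11) layout
.cell_index <- c(n00 = 1L, n01 = 2L, n10 = 3L, n11 = 4L)

#' Asymptotic p-value of a relationship hypothesis
#'
#' Tests the null hypothesis that the relationship \code{kind} holds, i.e.
#' that its forbidden true cell(s) carry probability zero, using a
#' forbidden-mass contrast:
#'
#' \itemize{
#'   \item For the four prerequisite kinds the forbidden cell count
#'     \eqn{n_F} is contrasted against the smallest competing cell count
#'     \eqn{n_m}: \eqn{z = (n_F - n_m) / (2\sqrt{N\bar q(1-\bar q)})} with
#'     the pooled rate \eqn{\bar q = (n_F + n_m)/(2N)}.  Under the null
#'     the forbidden cell has zero true mass, so it is in truth the
#'     smallest cell, and misclassification only shrinks the contrast: for
#'     the mirror cell the null mean of \eqn{q_F - q_M} is exactly
#'     \eqn{-(1-2\epsilon)\,p_M \le 0} for every \eqn{\epsilon < 1/2}
#'     (the \eqn{1-2\epsilon} factors cancel from the standardised
#'     corrected-scale contrast, which is why \eqn{\epsilon} does not
#'     appear in the statistic).
#'   \item For \code{SIM} (\code{SIM_DUAL}) the total forbidden mass
#'     \eqn{V} is contrasted against the allowed mass \eqn{D = N - V}:
#'     \eqn{z = (V - D)/\sqrt{N}} (pooled rate one half).
#' }
#'
#' The p-value is the folded upper tail clipped at one,
#' \eqn{p = \min\{1,\; 2[1 - \Phi(z)]\}}: a forbidden mass no larger than
#' its competitor yields \eqn{p = 1}, the value the Step-2 screen selects.
#'
#' @param kind a tag from [relationship_kinds()].
#' @param table a [pair_table()].
#' @param epsilon misclassification probability in \eqn{[0, 0.5)}; enters
#'   only through validation because the standardised contrast is free of
#'   \eqn{\epsilon} (see above).
#' @return A p-value in \eqn{[0, 1]}.
#' @examples
#' asymptotic_pvalue("F01", pair_table(10, 2, 43, 45), 0.05)  # about 1
#' asymptotic_pvalue("F10", pair_table(10, 2, 43, 45), 0.05)  # about 0
#' @export
asymptotic_pvalue <- function(kind, table, epsilon) {
  .check_kind(kind)
  stopifnot(inherits(table, "pair_table"))
  .check_eps(epsilon)
  n <- .cell_counts(table)
  N <- table$N
  if (kind %in% c("SIM", "SIM_DUAL")) {
    f <- forbidden_cells(kind)
    V <- sum(n[.cell_name(f[, 1], f[, 2])])
    z <- (V - (N - V) + 0.5) / sqrt(N)
  } else {
    f <- forbidden_cells(kind)
    nf <- n[[.cell_name(f[1, 1], f[1, 2])]]
    nm <- min(n[-.cell_index[[.cell_name(f[1, 1], f[1, 2])]]])
    qbar <- (nf + nm) / (2 * N)
    if (qbar == 0 || qbar == 1) {
      # degenerate variance: both compared counts at the boundary, the
      # contrast is exactly its null mean
      z <- 0
    } else {
      # continuity-corrected contrast of two discrete counts; the +1/2
      # keeps an exact tie between the forbidden and the smallest
      # competing cell from counting as full support for the null
      z <- (nf - nm + 0.5) / (2 * sqrt(N * qbar * (1 - qbar)))
    }
  }
  min(1, max(0, 2 * (1 - stats::pnorm(z))))
}

# ---- epsilon estimation -----------------------------------------------------

.loglik_cells <- function(n, q) {
  q <- pmax(q, 1e-12)
  sum(n * log(q))
}

# constrained profile log-likelihood for a one-forbidden-cell kind at a
# given epsilon: the best true distribution puts zero on the forbidden
# cell; the remaining three cells are fitted by maximising the multinomial
# likelihood of q = K p over the constrained simplex.
.fit_F_given_eps <- function(n, fidx, epsilon) {
  K <- .flip_kernel(epsilon)
  # parameterise the three free cells on the simplex via softmax
  free <- setdiff(1:4, fidx)
  obj <- function(theta) {
    w <- exp(c(0, theta)); p3 <- w / sum(w)
    p <- numeric(4); p[free] <- p3
    -.loglik_cells(n, as.numeric(K %*% p))
  }
  st <- log(pmax(n[free] / sum(n), 1e-3))[-1] - log(pmax(n[free][1] / sum(n), 1e-3))
  opt <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  w <- exp(c(0, opt$par)); p3 <- w / sum(w)
  p <- numeric(4); p[free] <- p3
  list(loglik = -opt$value, p = p, converged = opt$convergence == 0)
}

.fit_SIM_given_eps <- function(n, kind, epsilon) {
  # allowed cells carry true mass theta / (1 - theta)
  ac <- allowed_cells(kind)
  aidx <- .cell_index[.cell_name(ac[, 1], ac[, 2])]
  K <- .flip_kernel(epsilon)
  obj <- function(lt) {
    th <- stats::plogis(lt)
    p <- numeric(4); p[aidx] <- c(th, 1 - th)
    -.loglik_cells(n, as.numeric(K %*% p))
  }
  opt <- stats::optimize(obj, c(-12, 12), tol = 1e-9)
  th <- stats::plogis(opt$minimum)
  p <- numeric(4); p[aidx] <- c(th, 1 - th)
  list(loglik = -opt$objective, p = p, converged = TRUE)
}

.constrained_fit <- function(n, kind, epsilon) {
  if (kind %in% c("SIM", "SIM_DUAL")) .fit_SIM_given_eps(n, kind, epsilon)
  else {
    f <- forbidden_cells(kind)
    .fit_F_given_eps(n, .cell_index[[.cell_name(f[1, 1], f[1, 2])]], epsilon)
  }
}

#' Constrained maximum-likelihood estimate of the misclassification rate
#'
#' Maximises the multinomial likelihood of the observed 2x2 counts over
#' the misclassification probability \eqn{\epsilon \in [0, 0.5)} and a
#' true cell distribution constrained to the relationship \code{kind}
#' (forbidden true cells carry probability zero).  Without a constraint
#' the model is saturated for a whole interval of \eqn{\epsilon} and the
#' rate is not identifiable; \code{kind = NULL} therefore fits all six
#' constrained models and returns the estimate under the best-fitting
#' relationship.
#'
#' @param table a [pair_table()].
#' @param kind a tag from [relationship_kinds()], or \code{NULL} for the
#'   best-fitting relationship.
#' @return A list of class \code{epsilon_estimate}: \code{epsilon_hat},
#'   \code{loglik}, \code{probs_hat} (constrained true distribution),
#'   \code{kind}, \code{converged}.
#' @examples
#' estimate_epsilon(pair_table(48, 5, 4, 43), kind = "SIM")
#' @export
estimate_epsilon <- function(table, kind = NULL) {
  stopifnot(inherits(table, "pair_table"))
  n <- .cell_counts(table)
  if (table$N < 4L)
    warning("epsilon estimation from fewer than 4 samples is unreliable",
            call. = FALSE)
  fit_kind <- function(k) {
    prof <- function(e) .constrained_fit(n, k, e)$loglik
    # coarse deterministic grid then local refinement; the grid guards
    # against the flat/multimodal profiles of boundary tables
    grid <- seq(0, 0.49, by = 0.01)
    ll <- vapply(grid, prof, numeric(1))
    e0 <- grid[which.max(ll)]
    lo <- max(0, e0 - 0.01); hi <- min(0.49, e0 + 0.01)
    opt <- stats::optimize(function(e) -prof(e), c(lo, hi), tol = 1e-6)
    eh <- opt$minimum
    # prefer the exact boundary when it is as good (perfect-fit tables)
    if (prof(0) >= -opt$objective - 1e-9) eh <- 0
    fit <- .constrained_fit(n, k, eh)
    list(epsilon_hat = eh, loglik = fit$loglik, p = fit$p,
         converged = fit$converged)
  }
  if (!is.null(kind)) {
    .check_kind(kind)
    f <- fit_kind(kind)
    best_kind <- kind
  } else {
    fits <- lapply(relationship_kinds(), fit_kind)
    i <- which.max(vapply(fits, `[[`, numeric(1), "loglik"))
    f <- fits[[i]]
    best_kind <- relationship_kinds()[i]
  }
  p <- f$p
  names(p) <- c("p00", "p01", "p10", "p11")
  structure(list(epsilon_hat = f$epsilon_hat, loglik = f$loglik,
                 probs_hat = p, kind = best_kind,
                 converged = isTRUE(f$converged)),
            class = "epsilon_estimate")
}

#' @export
print.epsilon_estimate <- function(x, ...) {
  cat(sprintf("epsilon-hat = %.4f under %s (loglik %.3f%s)\n",
              x$epsilon_hat, x$kind, x$loglik,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
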