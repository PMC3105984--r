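#' The seven-element worked example
#'
#' The classic seven-element DAB network used throughout the package's
#' examples and tests: its 13 compatible states are embedded verbatim and
#' the 12 defining relationships are recovered programmatically as the
#' relationships whose counting number equals the number of states (with
#' prerequisite calls implied by an exact similarity folded into it).
#'
#' @return A list with \code{states} (7 x 13 binary matrix) and
#'   \code{relations} (a [pair_relations()] set of the 12 relationships).
#' @examples
#' fx <- fig2_fixture()
#' ncol(fx$states)     # 13
#' nrow(fx$relations)  # 12
#' @export
fig2_fixture <- function() {
  states <- matrix(c(
    0,1,1,1,1,1,1,1,1,1,1,1,1,   # A
    0,0,1,1,1,1,1,1,0,0,0,0,0,   # B
    0,0,0,1,1,1,1,1,1,1,1,1,1,   # C
    1,1,1,1,0,1,0,0,1,0,1,0,0,   # D
    0,0,1,1,1,1,1,1,0,0,0,0,0,   # E
    0,0,0,0,0,1,1,1,0,0,1,1,1,   # F
    0,0,0,0,0,0,0,1,0,0,0,0,1),  # G
    nrow = 7, byrow = TRUE,
    dimnames = list(c("A","B","C","D","E","F","G"), NULL))
  storage.mode(states) <- "integer"
  relations <- exact_relations(states)
  list(states = states, relations = relations)
}

#' Relationships holding in every column of a state matrix
#'
#' For each pair, collects the relationship kinds whose counting number
#' equals the number of states; a similarity subsumes the two prerequisite
#' patterns it implies, so each relationship is reported once.
#'
#' @param states binary matrix, elements in rows, states in columns.
#' @return A [pair_relations()] set.
#' @export
exact_relations <- function(states) {
  states <- .check_binary_matrix(states)
  els <- rownames(states)
  N <- ncol(states)
  a <- character(); b <- character(); kind <- character()
  for (i in seq_len(nrow(states) - 1L)) for (j in (i + 1L):nrow(states)) {
    cnt <- relationship_counts(tabulate_pair(states, els[i], els[j]))
    ks <- names(cnt)[cnt == N]
    if ("SIM" %in% ks) ks <- setdiff(ks, c("F01", "F10"))
    if ("SIM_DUAL" %in% ks) ks <- setdiff(ks, c("F00", "F11"))
    if (length(ks)) {
      a <- c(a, rep(els[i], length(ks)))
      b <- c(b, rep(els[j], length(ks)))
      kind <- c(kind, ks)
    }
  }
  pair_relations(a, b, kind)
}

#' Sample observations from a set of network states
#'
#' Draws \code{n_samples} columns independently from the given state set,
#' by default uniformly.
#'
#' @param states binary matrix of states (elements in rows).
#' @param n_samples number of columns to draw.
#' @param weights optional probability vector over the states (columns of
#'   \code{states}); default uniform.
#' @param seed optional integer seed (local to this call).
#' @return A binary matrix with \code{n_samples} columns.
#' @export
sample_states <- function(states, n_samples, weights = NULL, seed = NULL) {
  states <- .check_binary_matrix(states)
  if (ncol(states) == 0L) stop("empty state set", call. = FALSE)
  if (n_samples == 0L) {
    warning("drawing 0 samples", call. = FALSE)
    return(states[, integer(0), drop = FALSE])
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == ncol(states), all(weights >= 0))
    if (abs(sum(weights) - 1) > 1e-8)
      stop("state weights must sum to 1", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  idx <- sample.int(ncol(states), n_samples, replace = TRUE, prob = weights)
  out <- states[, idx, drop = FALSE]
  colnames(out) <- NULL
  out
}

#' Flip matrix entries independently with probability epsilon
#'
#' The measurement-error model: each observed on/off entry is recorded
#' wrongly with probability \code{epsilon}, independently of everything
#' else.
#'
#' @param x binary matrix.
#' @param epsilon flip probability in \eqn{[0, 0.5]}.
#' @param seed optional integer seed (local to this call).
#' @return A binary matrix of the same shape.
#' @export
perturb <- function(x, epsilon, seed = NULL) {
  x <- .check_binary_matrix(x)
  if (epsilon < 0 || epsilon > 0.5)
    stop("epsilon must lie in [0, 0.5]", call. = FALSE)
  if (epsilon == 0 || length(x) == 0L) return(x)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  flips <- matrix(stats::runif(length(x)) < epsilon, nrow(x), ncol(x))
  out <- (x + flips) %% 2L
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(x)
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  } else assign(".Random.seed", old, envir = .GlobalEnv)
}

#' Generate a random directed acyclic Boolean network
#'
#' Draws a random class-level partial order: elements are assigned to
#' similarity classes (occasionally with flipped polarity, yielding dual
#' relations), classes are placed in a random topological order and
#' forward edges are included independently with probability
#' \code{density}.
#'
#' @param m number of elements (at least 2).
#' @param density edge probability between class pairs, in \eqn{(0, 1]}.
#' @param seed optional integer seed.
#' @param sim_prob probability that an element joins an existing class
#'   instead of founding a new one (default 0.15).
#' @param dual_prob probability that a link is expressed through the dual
#'   element (default 0.15).
#' @return A [pair_relations()] set with an acyclic covering structure.
#' @export
random_dab_network <- function(m, density, seed = NULL, sim_prob = 0.15,
                               dual_prob = 0.15) {
  stopifnot(m >= 2, density > 0, density <= 1)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  els <- sprintf("e%02d", seq_len(m))
  cls <- integer(m); pol <- integer(m)
  cls[1] <- 1L; pol[1] <- 1L
  for (i in seq_len(m)[-1]) {
    if (stats::runif(1) < sim_prob) {
      cls[i] <- sample.int(max(cls), 1)
      pol[i] <- if (stats::runif(1) < dual_prob) -1L else 1L
    } else {
      cls[i] <- max(cls) + 1L
      pol[i] <- 1L
    }
  }
  nclass <- max(cls)
  a <- character(); b <- character(); kind <- character()
  # within-class links
  for (cl in seq_len(nclass)) {
    idx <- which(cls == cl)
    if (length(idx) > 1L) for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      a <- c(a, els[i]); b <- c(b, els[j])
      kind <- c(kind, if (pol[i] == pol[j]) "SIM" else "SIM_DUAL")
    }
  }
  # forward class edges in a random topological order
  ord <- sample.int(nclass)
  for (ui in seq_len(nclass - 1L)) for (vi in (ui + 1L):nclass) {
    if (stats::runif(1) >= density) next
    u <- which(cls == ord[ui])[1]; v <- which(cls == ord[vi])[1]
    # u is a prerequisite of v, expressed through the member polarities
    k <- if (pol[u] == 1L && pol[v] == 1L) "F01"
         else if (pol[u] == -1L && pol[v] == 1L) "F00"
         else if (pol[u] == 1L && pol[v] == -1L) "F11"
         else "F10"
    a <- c(a, els[u]); b <- c(b, els[v]); kind <- c(kind, k)
  }
  r <- pair_relations(a, b, kind)
  attr(r, "elements") <- els
  r
}

#' Recovery experiment: sample, corrupt, infer, compare
#'
#' End-to-end benchmark: draws samples from the compatible states of a
#' ground-truth relation set, flips entries at rate \code{epsilon}, runs
#' one or more inference methods and scores the called relationships
#' against the closure of the ground truth.
#'
#' @param relations ground-truth [pair_relations()] set.
#' @param n_samples number of samples to draw.
#' @param epsilon flip probability.
#' @param seed integer seed (split internally into independent sampling
#'   and perturbation streams).
#' @param methods character subset of \code{c("two_step", "sahoo",
#'   "lilu")}.
#' @param elements optional element labels (defaults to those appearing
#'   in \code{relations}).
#' @param lilu_cutoff constrained-epsilon cutoff for the \code{"lilu"}
#'   baseline (default 0.01).
#' @param ... further arguments passed to [dab_infer()].
#' @return A list per method with components \code{called}
#'   ([pair_relations()]), \code{true_positives}, \code{false_positives},
#'   \code{false_negatives} and \code{exact_recovery}; the truth used for
#'   scoring is in attribute \code{"truth"}.
#' @export
recovery_experiment <- function(relations, n_samples, epsilon, seed = NULL,
                                methods = "two_step", elements = NULL,
                                lilu_cutoff = 0.01, ...) {
  relations <- .as_relations(relations)
  if (is.null(elements))
    elements <- attr(relations, "elements") %||%
      .relation_elements(relations)
  states <- enumerate_compatible_states(elements, relations)
  s1 <- if (is.null(seed)) NULL else as.integer(seed)
  s2 <- if (is.null(seed)) NULL else as.integer(seed) + 1000003L
  x <- sample_states(states, n_samples, seed = s1)
  x <- perturb(x, epsilon, seed = s2)
  truth <- exact_relations(states)
  score <- function(called) {
    key <- function(r) paste(r$a, r$b, r$kind)
    tp <- sum(key(called) %in% key(truth))
    list(called = called,
         true_positives = tp,
         false_positives = nrow(called) - tp,
         false_negatives = nrow(truth) - tp,
         exact_recovery = setequal(key(called), key(truth)))
  }
  out <- list()
  for (mth in methods) {
    called <- switch(mth,
      two_step = dab_infer(x, epsilon = epsilon, ...)$selected,
      sahoo    = sahoo_screen(x),
      lilu     = lilu_screen(x, eps_cutoff = lilu_cutoff),
      stop("unknown method: ", mth, call. = FALSE))
    out[[mth]] <- score(called)
  }
  attr(out, "truth") <- truth
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
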