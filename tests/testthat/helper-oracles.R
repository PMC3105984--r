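# brute-force oracles used across the suite

# relations holding in every compatible state of a relation set, computed
# by a literal per-state, per-relation double loop (independent of the
# implication-graph closure)
oracle_closure <- function(relations, elements = NULL) {
  if (is.null(elements))
    elements <- sort(unique(c(relations$a, relations$b)))
  st <- oracle_enumerate(elements, relations)
  if (ncol(st) == 0L) return(NULL)   # contradictory: everything holds
  a <- character(); b <- character(); kind <- character()
  m <- length(elements)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    for (k in relationship_kinds()) {
      ok <- all(vapply(seq_len(ncol(st)), function(s)
        holds_in_state(k, st[i, s], st[j, s]), logical(1)))
      if (ok) { a <- c(a, elements[i]); b <- c(b, elements[j])
                kind <- c(kind, k) }
    }
  }
  pair_relations(a, b, kind)
}

# per-state, per-relation double loop enumeration
oracle_enumerate <- function(elements, relations) {
  m <- length(elements)
  out <- matrix(0L, m, 0, dimnames = list(elements, NULL))
  for (idx in 0:(2^m - 1)) {
    state <- as.integer((idx %/% 2^((m - 1):0)) %% 2)
    names(state) <- elements
    ok <- TRUE
    for (r in seq_len(nrow(relations))) {
      if (!holds_in_state(relations$kind[r], state[[relations$a[r]]],
                          state[[relations$b[r]]])) { ok <- FALSE; break }
    }
    if (ok) out <- cbind(out, state)
  }
  colnames(out) <- NULL
  out
}

# canonical key for relation-set comparison; a SIM subsumes its two
# prerequisite components (and SIM_DUAL its two), so compare reduced sets
rel_key <- function(r) sort(paste(r$a, r$b, r$kind))

# grid-search oracle for the constrained epsilon MLE
oracle_constrained_eps <- function(table, kind, grid = seq(0, 0.49, 5e-3)) {
  n <- c(table$n00, table$n01, table$n10, table$n11)
  ll <- vapply(grid, function(e)
    dabnet:::.constrained_fit(n, kind, e)$loglik, numeric(1))
  grid[which.max(ll)]
}

table1_states <- function() fig2_fixture()$states
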