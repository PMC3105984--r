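#' Construct a set of pairwise relations
#'
#' Relations are stored in a data frame with columns \code{a}, \code{b},
#' \code{kind}.  Each pair is stored once with the lexicographically
#' smaller element first; \code{F01}/\code{F10} (and the symmetric
#' \code{F00}/\code{F11}) convert into one another under the swap, so the
#' same fact is never recorded twice.
#'
#' @param a,b character vectors of element labels.
#' @param kind character vector of kind tags ([relationship_kinds()]).
#' @return A data frame of class \code{dab_relations}.
#' @examples
#' pair_relations(c("A", "B"), c("B", "C"), c("SIM", "F01"))
#' @export
pair_relations <- function(a = character(), b = character(),
                           kind = character()) {
  a <- as.character(a); b <- as.character(b); kind <- as.character(kind)
  stopifnot(length(a) == length(b), length(a) == length(kind))
  if (any(a == b)) stop("a relation needs two distinct elements",
                        call. = FALSE)
  vapply(kind, .check_kind, character(1))
  flip <- a > b
  kind[flip] <- .swap_kind[kind[flip]]
  tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
  r <- data.frame(a = a, b = b, kind = kind, stringsAsFactors = FALSE)
  r <- unique(r)
  r <- r[order(r$a, r$b, match(r$kind, relationship_kinds())), ,
         drop = FALSE]
  rownames(r) <- NULL
  class(r) <- c("dab_relations", "data.frame")
  r
}

.as_relations <- function(r) {
  if (inherits(r, "dab_relations")) return(r)
  if (is.data.frame(r)) return(pair_relations(r$a, r$b, r$kind))
  stop("expected a dab_relations object", call. = FALSE)
}

.relation_elements <- function(relations, elements = NULL) {
  e <- sort(unique(c(relations$a, relations$b, elements)))
  if (!is.null(elements)) {
    miss <- setdiff(unique(c(relations$a, relations$b)), elements)
    if (length(miss))
      stop("relations reference unknown elements: ",
           paste(miss, collapse = ", "), call. = FALSE)
    e <- elements
  }
  e
}

#' Is a full network state compatible with a relation set?
#'
#' @param state a 0/1 vector, named by element or aligned with
#'   \code{elements}.
#' @param relations a [pair_relations()] set.
#' @param elements optional element ordering for an unnamed state.
#' @return \code{TRUE} iff every relation holds in the state.
#' @export
is_compatible <- function(state, relations, elements = NULL) {
  relations <- .as_relations(relations)
  if (is.null(names(state))) {
    if (is.null(elements))
      elements <- .relation_elements(relations)
    if (length(state) != length(elements))
      stop("state length does not match the number of elements",
           call. = FALSE)
    names(state) <- elements
  }
  miss <- setdiff(unique(c(relations$a, relations$b)), names(state))
  if (length(miss))
    stop("relations reference unknown elements: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(state %in% c(0, 1))) stop("state must be 0/1", call. = FALSE)
  for (i in seq_len(nrow(relations))) {
    if (!holds_in_state(relations$kind[i],
                        state[[relations$a[i]]],
                        state[[relations$b[i]]]))
      return(FALSE)
  }
  TRUE
}

#' Enumerate all compatible network states
#'
#' Sweeps the full \eqn{2^m} state space (chunked, so memory stays modest)
#' and keeps the states in which every relation holds.  States are returned
#' in lexicographic order of the bit vector.
#'
#' @param elements element labels, or a single integer \eqn{m} (elements
#'   are then labelled \code{e1..em}).
#' @param relations a [pair_relations()] set (may be empty).
#' @return A 0/1 matrix, elements in rows, compatible states in columns.
#' @examples
#' r <- pair_relations("A", "B", "F01")
#' enumerate_compatible_states(c("A", "B"), r)
#' @export
enumerate_compatible_states <- function(elements, relations = pair_relations()) {
  if (is.numeric(elements) && length(elements) == 1L)
    elements <- paste0("e", seq_len(elements))
  m <- length(elements)
  if (m > 25L)
    stop("exhaustive enumeration limited to m <= 25; ",
         "use sampling for larger networks", call. = FALSE)
  relations <- .as_relations(relations)
  .relation_elements(relations, elements)
  total <- 2^m
  chunk <- min(total, 2^16)
  keep <- vector("list", ceiling(total / chunk))
  # bit j of the state index: element j is the most significant bit so the
  # column order is lexicographic in the element ordering
  for (ci in seq_along(keep)) {
    idx <- ((ci - 1) * chunk):min(ci * chunk - 1, total - 1)
    bits <- matrix(0L, nrow = m, ncol = length(idx),
                   dimnames = list(elements, NULL))
    for (j in seq_len(m))
      bits[j, ] <- (idx %/% 2^(m - j)) %% 2
    ok <- rep(TRUE, length(idx))
    for (i in seq_len(nrow(relations))) {
      f <- .forbidden[[relations$kind[i]]]
      av <- bits[relations$a[i], ]; bv <- bits[relations$b[i], ]
      for (k in seq_len(nrow(f)))
        ok <- ok & !(av == f[k, 1] & bv == f[k, 2])
      if (!any(ok)) break
    }
    keep[[ci]] <- bits[, ok, drop = FALSE]
  }
  out <- do.call(cbind, keep)
  storage.mode(out) <- "integer"
  out
}

# ---- implication-graph machinery -------------------------------------------
# Each element e yields two literals, "e" (on) and "e*" (off).  Every
# relation is a 2-clause and contributes implication edges; transitive
# closure of the literal graph yields every entailed pairwise relation
# (resolution is complete for 2-clauses).

.literal_graph <- function(relations, elements) {
  m <- length(elements)
  n <- 2L * m                       # literal i: element i on; m+i: off
  g <- matrix(FALSE, n, n)
  pos <- function(e) match(e, elements)
  neg <- function(e) m + match(e, elements)
  add <- function(from, to) g[from, to] <<- TRUE
  for (i in seq_len(nrow(relations))) {
    a <- relations$a[i]; b <- relations$b[i]
    switch(relations$kind[i],
      F01 = { add(pos(b), pos(a)); add(neg(a), neg(b)) },
      F10 = { add(pos(a), pos(b)); add(neg(b), neg(a)) },
      F00 = { add(neg(a), pos(b)); add(neg(b), pos(a)) },
      F11 = { add(pos(a), neg(b)); add(pos(b), neg(a)) },
      SIM = { add(pos(a), pos(b)); add(pos(b), pos(a))
              add(neg(a), neg(b)); add(neg(b), neg(a)) },
      SIM_DUAL = { add(pos(a), neg(b)); add(neg(b), pos(a))
                   add(neg(a), pos(b)); add(pos(b), neg(a)) })
  }
  g
}

.reachability <- function(g) {
  n <- nrow(g)
  r <- g | diag(TRUE, n)
  repeat {
    r2 <- r | ((r %*% r) > 0)
    if (identical(r2, r)) break
    r <- r2
  }
  r
}

#' Transitive closure of a relation set
#'
#' Returns every pairwise relationship entailed by the input set: the
#' prerequisite relation is transitive, similar elements are substitutable,
#' and the dual forms compose accordingly.  Internally the relations are
#' treated as implications between element literals and the literal graph
#' is transitively closed, which is complete for this clause class.
#'
#' @param relations a [pair_relations()] set.
#' @param reduce if \code{TRUE} (default) a pair entailed to satisfy both
#'   \code{F01} and \code{F10} is reported as the single relation
#'   \code{SIM} (and \code{F00} + \code{F11} as \code{SIM_DUAL}) rather
#'   than as its two prerequisite components.
#' @return A [pair_relations()] set.  Contradictory inputs are allowed;
#'   pairs whose four cells are all forbidden trigger a warning and an
#'   attribute \code{contradictory = TRUE}.
#' @examples
#' r <- pair_relations(c("A", "B"), c("B", "C"), c("F01", "F01"))
#' closure(r)       # contains A F01 C
#' @export
closure <- function(relations, reduce = TRUE) {
  relations <- .as_relations(relations)
  elements <- .relation_elements(relations)
  m <- length(elements)
  if (m == 0L) return(pair_relations())
  r <- .reachability(.literal_graph(relations, elements))
  # a literal is impossible when it implies both some literal and its
  # negation (the 2-clause merge rule, which plain transitive closure
  # alone would miss); impossibility propagates backwards through r
  # automatically because implications compose
  dual_idx <- c((m + 1L):(2L * m), 1L:m)
  imp <- vapply(seq_len(2L * m),
                function(l) any(r[l, ] & r[l, dual_idx]), logical(1))
  cell_dead <- function(la, lb)
    r[la, dual_idx[lb]] || imp[la] || imp[lb]
  a <- character(); b <- character(); kind <- character()
  contradictory <- FALSE
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    pi_ <- i; ni <- m + i; pj <- j; nj <- m + j
    has <- c(F01 = cell_dead(ni, pj),    # cell (0,1)
             F10 = cell_dead(pi_, nj),   # cell (1,0)
             F00 = cell_dead(ni, nj),    # cell (0,0)
             F11 = cell_dead(pi_, pj))   # cell (1,1)
    if (all(has)) contradictory <- TRUE
    ks <- names(has)[has]
    if (reduce) {
      if (all(c("F01", "F10") %in% ks))
        ks <- c("SIM", setdiff(ks, c("F01", "F10")))
      if (all(c("F00", "F11") %in% ks))
        ks <- c(setdiff(ks, c("F00", "F11")), "SIM_DUAL")
    }
    if (length(ks)) {
      a <- c(a, rep(elements[i], length(ks)))
      b <- c(b, rep(elements[j], length(ks)))
      kind <- c(kind, ks)
    }
  }
  out <- pair_relations(a, b, kind)
  if (contradictory) {
    warning("relation set is contradictory for at least one pair; ",
            "contradictions are reported, not resolved", call. = FALSE)
    attr(out, "contradictory") <- TRUE
  }
  out
}

#' Similarity classes of a relation set
#'
#' Groups elements connected by (entailed) similarity into classes; a
#' \code{SIM_DUAL} link joins two elements with opposite polarity.
#'
#' @param relations a [pair_relations()] set.
#' @return A data frame with columns \code{element}, \code{class} and
#'   \code{polarity} (+1/-1 within the class).
#' @export
similarity_classes <- function(relations) {
  relations <- .as_relations(relations)
  elements <- .relation_elements(relations)
  cl <- closure(relations, reduce = TRUE)
  parent <- seq_along(elements); pol <- rep(1L, length(elements))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nrow(cl))) {
    k <- cl$kind[i]
    if (!k %in% c("SIM", "SIM_DUAL")) next
    ia <- match(cl$a[i], elements); ib <- match(cl$b[i], elements)
    s <- if (k == "SIM") 1L else -1L
    ra <- find(ia); rb <- find(ib)
    if (ra != rb) {
      # polarity of ib relative to its root, adjusted so that
      # pol[ia]*s == pol[ib] holds after the union
      pa <- .path_pol(parent, pol, ia); pb <- .path_pol(parent, pol, ib)
      parent[rb] <- ra
      pol[rb] <- pa * s * pb
    }
  }
  root <- vapply(seq_along(elements), find, integer(1))
  p <- vapply(seq_along(elements),
              function(i) .path_pol(parent, pol, i), integer(1))
  data.frame(element = elements,
             class = match(root, unique(root)),
             polarity = p, stringsAsFactors = FALSE)
}

.path_pol <- function(parent, pol, x) {
  s <- 1L
  while (parent[x] != x) { s <- s * pol[x]; x <- parent[x] }
  s
}

#' Covering edges (transitive reduction) of a relation set
#'
#' Collapses similar elements into classes, forms the class-level partial
#' order induced by the prerequisite relations and removes every edge
#' implied by transitivity.  The closure of the covering edges together
#' with the within-class similarity links equals the closure of the input.
#'
#' @param relations a [pair_relations()] set whose prerequisite structure
#'   is acyclic across distinct similarity classes.
#' @return A [pair_relations()] set of immediate (covering) relations.
#' @examples
#' r <- pair_relations(c("A", "B", "A"), c("B", "C", "C"),
#'                     c("F01", "F01", "F01"))
#' covering_edges(r)   # the chain A -> B -> C, without the implied A -> C
#' @export
covering_edges <- function(relations) {
  relations <- .as_relations(relations)
  if (nrow(relations) == 0L) return(pair_relations())
  elements <- .relation_elements(relations)
  m <- length(elements)
  r <- .reachability(.literal_graph(relations, elements))
  n <- 2L * m
  # literal strongly connected components = (signed) similarity classes
  mutual <- r & t(r)
  comp <- integer(n)
  for (i in seq_len(n)) comp[i] <- which(mutual[i, ])[1]
  comps <- unique(comp)
  # the declared similarity structure alone: a mutual reachability that is
  # not already present there means the prerequisite part is cyclic across
  # distinct similarity classes, which the model forbids
  sims <- relations[relations$kind %in% c("SIM", "SIM_DUAL"), ,
                    drop = FALSE]
  rs <- .reachability(.literal_graph(pair_relations(sims$a, sims$b,
                                                    sims$kind), elements))
  bad <- which(mutual & !(rs & t(rs)), arr.ind = TRUE)
  bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
  if (nrow(bad)) {
    lit <- function(i) if (i <= m) elements[i]
                       else paste0(elements[i - m], "*")
    stop("prerequisite cycle across distinct similarity classes: ",
         lit(bad[1, 1]), " <-> ", lit(bad[1, 2]), call. = FALSE)
  }
  # quotient DAG over literal components and its transitive reduction
  qedge <- matrix(FALSE, length(comps), length(comps),
                  dimnames = list(comps, comps))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (r[i, j] && comp[i] != comp[j])
      qedge[as.character(comp[i]), as.character(comp[j])] <- TRUE
  }
  red <- qedge
  nc <- length(comps)
  for (u in seq_len(nc)) for (v in seq_len(nc)) {
    if (!red[u, v]) next
    for (w in seq_len(nc)) {
      if (w != u && w != v && qedge[u, w] && qedge[w, v]) {
        red[u, v] <- FALSE; break
      }
    }
  }
  # map covering quotient edges back to pair relations; each implication
  # and its dual describe the same relation, so deduplication happens in
  # pair_relations()
  lit_of <- function(cp) which(comp == cp)[1]
  a <- character(); b <- character(); kind <- character()
  for (u in seq_len(nc)) for (v in seq_len(nc)) {
    if (!red[u, v]) next
    li <- lit_of(comps[u]); lj <- lit_of(comps[v])
    ei <- if (li <= m) li else li - m; si <- li <= m
    ej <- if (lj <= m) lj else lj - m; sj <- lj <= m
    if (ei == ej) next                      # element with its own dual
    # implication lit_i => lit_j kills the cell (lit_i true, lit_j false)
    k <- if (si && sj) "F10"                # a=1 => b=1 forbids (1,0)
         else if (si && !sj) "F11"          # a=1 => b=0 forbids (1,1)
         else if (!si && sj) "F00"          # a=0 => b=1 forbids (0,0)
         else "F01"                         # a=0 => b=0 forbids (0,1)
    a <- c(a, elements[ei]); b <- c(b, elements[ej]); kind <- c(kind, k)
  }
  pair_relations(a, b, kind)
}

# within-class similarity links (a spanning chain per class), used when
# checking or rebuilding a network from its covering edges
.class_links <- function(sc) {
  a <- character(); b <- character(); kind <- character()
  for (cl in unique(sc$class)) {
    idx <- which(sc$class == cl)
    if (length(idx) < 2L) next
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      a <- c(a, sc$element[i]); b <- c(b, sc$element[j])
      kind <- c(kind, if (sc$polarity[i] == sc$polarity[j]) "SIM"
                      else "SIM_DUAL")
    }
  }
  pair_relations(a, b, kind)
}
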