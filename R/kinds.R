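#' The six pairwise relationship kinds
#'
#' A directed acyclic Boolean (DAB) network is characterised by pairwise
#' constraints on the joint on/off states of two elements.  Six patterns
#' exist: two similarity patterns that forbid two of the four joint states,
#' and four prerequisite patterns that each forbid exactly one.
#'
#' \describe{
#'   \item{\code{SIM}}{A and B are similar: they are on and off together.
#'     Forbidden cells (0,1) and (1,0).}
#'   \item{\code{SIM_DUAL}}{A is similar to the dual (complement) of B.
#'     Forbidden cells (0,0) and (1,1).}
#'   \item{\code{F01}}{A is a prerequisite of B (B on requires A on).
#'     Forbidden cell (0,1).}
#'   \item{\code{F10}}{B is a prerequisite of A.  Forbidden cell (1,0).}
#'   \item{\code{F00}}{The dual of A is a prerequisite of B (A off forces
#'     B on).  Forbidden cell (0,0).}
#'   \item{\code{F11}}{A is a prerequisite of the dual of B (A on forces
#'     B off).  Forbidden cell (1,1).}
#' }
#'
#' @return \code{relationship_kinds()} returns the six kind tags in their
#'   canonical order.
#' @examples
#' relationship_kinds()
#' allowed_cells("SIM")
#' @export
relationship_kinds <- function() {
  c("SIM", "SIM_DUAL", "F01", "F10", "F00", "F11")
}

# cells are stored as two-column integer matrices, rows = (a_val, b_val)
.cell_mat <- function(...) {
  m <- matrix(unlist(list(...)), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("a", "b")
  m
}

.forbidden <- list(
  SIM      = .cell_mat(c(0L, 1L), c(1L, 0L)),
  SIM_DUAL = .cell_mat(c(0L, 0L), c(1L, 1L)),
  F01      = .cell_mat(c(0L, 1L)),
  F10      = .cell_mat(c(1L, 0L)),
  F00      = .cell_mat(c(0L, 0L)),
  F11      = .cell_mat(c(1L, 1L))
)

.check_kind <- function(kind) {
  if (!(is.character(kind) && length(kind) == 1L &&
        kind %in% relationship_kinds()))
    stop("unknown relationship kind: ", paste(kind, collapse = ", "),
         call. = FALSE)
  kind
}

#' Forbidden cells of a relationship kind
#'
#' @param kind one of the six tags from [relationship_kinds()].
#' @return An integer matrix with columns \code{a}, \code{b}; each row is a
#'   joint state the relationship rules out.
#' @export
forbidden_cells <- function(kind) .forbidden[[.check_kind(kind)]]

#' Allowed cells of a relationship kind
#'
#' The complement of [forbidden_cells()] within the four joint states.
#'
#' @inheritParams forbidden_cells
#' @return An integer matrix with columns \code{a}, \code{b}.
#' @examples
#' allowed_cells("F01")   # (0,0), (1,0), (1,1)
#' @export
allowed_cells <- function(kind) {
  all4 <- .cell_mat(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  f <- forbidden_cells(kind)
  keep <- !(paste(all4[, 1], all4[, 2]) %in% paste(f[, 1], f[, 2]))
  all4[keep, , drop = FALSE]
}

#' Does a relationship hold in a single joint state?
#'
#' @inheritParams forbidden_cells
#' @param a_val,b_val bits (0 or 1).
#' @return \code{TRUE} iff the state \code{(a_val, b_val)} is an allowed
#'   cell of \code{kind}.
#' @export
holds_in_state <- function(kind, a_val, b_val) {
  .check_kind(kind)
  if (!all(c(a_val, b_val) %in% c(0L, 1L)))
    stop("state values must be 0 or 1", call. = FALSE)
  f <- .forbidden[[kind]]
  !any(f[, 1] == a_val & f[, 2] == b_val)
}

# kind obtained when the two elements of a pair are swapped
.swap_kind <- c(SIM = "SIM", SIM_DUAL = "SIM_DUAL",
                F01 = "F10", F10 = "F01", F00 = "F00", F11 = "F11")
# note: F00 forbids (0,0) which is symmetric under swap, as is F11.
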