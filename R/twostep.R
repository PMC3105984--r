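#' Score the six relationships for one pair (Steps 1-3)
#'
#' Applies the counting-number screen (Step 1) and the asymptotic p-value
#' screen (Step 2) to one 2x2 table and intersects them (Step 3).
#'
#' @param table a [pair_table()].
#' @param epsilon misclassification probability in \eqn{[0, 0.5)}.
#' @param alpha tail probability of the Step-1 confidence-bound
#'   thresholds (default 0.05).
#' @param pvalue_threshold Step-2 selection threshold on the rounded
#'   p-value (default 1, the value used throughout the worked analyses).
#' @param pvalue_decimals decimals the p-value is rounded to before the
#'   comparison (default 4).
#' @return A data frame with one row per kind: \code{kind}, \code{count},
#'   \code{pvalue}, \code{passed_count}, \code{passed_pvalue},
#'   \code{selected} (the conjunction).
#' @examples
#' infer_pair(pair_table(10, 2, 43, 45), epsilon = 0.05)
#' @export
infer_pair <- function(table, epsilon, alpha = 0.05,
                       pvalue_threshold = 1, pvalue_decimals = 4) {
  stopifnot(inherits(table, "pair_table"))
  .check_eps(epsilon)
  counts <- relationship_counts(table)
  sel_count <- screen_counts(counts, table$N, epsilon, alpha)
  ks <- relationship_kinds()
  pv <- vapply(ks, function(k) asymptotic_pvalue(k, table, epsilon),
               numeric(1))
  passed_count <- ks %in% sel_count
  passed_pvalue <- round(pv, pvalue_decimals) >= pvalue_threshold
  data.frame(kind = ks, count = as.integer(counts[ks]), pvalue = pv,
             passed_count = passed_count, passed_pvalue = passed_pvalue,
             selected = passed_count & passed_pvalue,
             row.names = NULL, stringsAsFactors = FALSE)
}

# drop prerequisite calls that are logically implied by a selected
# similarity call on the same pair (SIM = F01 and F10; SIM_DUAL = F00 and
# F11); they are the same relationship, not an extra one
.subsume <- function(calls) {
  out <- calls
  for (p in unique(out$pair)) {
    rows <- out$pair == p & out$selected
    ks <- out$kind[rows]
    drop <- character()
    if ("SIM" %in% ks) drop <- c(drop, "F01", "F10")
    if ("SIM_DUAL" %in% ks) drop <- c(drop, "F00", "F11")
    out$selected[rows & out$kind %in% drop] <- FALSE
  }
  out
}

#' Infer a DAB network from a noisy binary matrix
#'
#' The main fitting function: runs the two-step counting procedure over
#' all \eqn{m(m-1)/2} element pairs of a binary matrix and assembles the
#' selected relationships into a network model with similarity classes and
#' covering (immediate) prerequisite edges.
#'
#' @param x binary matrix, elements in rows, samples in columns.
#' @param epsilon misclassification probability, \code{"estimate"} for a
#'   pooled maximum-likelihood estimate across pairs, or a number in
#'   \eqn{[0, 0.5)}.  There is no silent default: the rate must be given
#'   or estimated.
#' @inheritParams infer_pair
#' @param subsume if \code{TRUE} (default) a prerequisite call implied by
#'   a selected similarity call on the same pair is folded into it, so
#'   each selected relationship is reported once.
#' @return An object of class \code{dab_network} with components
#'   \code{report} (all pairs by all kinds: counts, p-values, screen
#'   flags), \code{selected} ([pair_relations()]), \code{classes},
#'   \code{covering}, \code{thresholds}, \code{epsilon}, \code{call}.
#' @examples
#' fx <- fig2_fixture()
#' fit <- dab_infer(fx$states, epsilon = 0)
#' fit
#' @export
dab_infer <- function(x, epsilon, alpha = 0.05, pvalue_threshold = 1,
                      pvalue_decimals = 4, subsume = TRUE) {
  x <- .check_binary_matrix(x)
  m <- nrow(x)
  if (m < 2L) stop("network inference needs at least two elements",
                   call. = FALSE)
  N <- ncol(x)
  elements <- rownames(x)
  constant <- elements[apply(x, 1, function(v) length(unique(v)) == 1L)]

  pairs <- t(utils::combn(elements, 2L))
  tables <- lapply(seq_len(nrow(pairs)),
                   function(i) tabulate_pair(x, pairs[i, 1], pairs[i, 2]))

  eps_estimated <- identical(epsilon, "estimate")
  if (eps_estimated) {
    eh <- vapply(tables, function(tb) estimate_epsilon(tb)$epsilon_hat,
                 numeric(1))
    epsilon <- stats::median(eh)
  }
  .check_eps(epsilon)

  rep_list <- lapply(seq_along(tables), function(i) {
    r <- infer_pair(tables[[i]], epsilon, alpha,
                    pvalue_threshold, pvalue_decimals)
    cbind(pair = paste0("(", pairs[i, 1], ",", pairs[i, 2], ")"),
          a = pairs[i, 1], b = pairs[i, 2], r, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_list)
  rownames(report) <- NULL
  if (subsume) report <- .subsume(report)

  sel <- report[report$selected, , drop = FALSE]
  selected <- pair_relations(sel$a, sel$b, sel$kind)
  classes <- similarity_classes(selected)
  # fill in singleton classes for untouched elements
  missing <- setdiff(elements, classes$element)
  if (length(missing))
    classes <- rbind(classes,
                     data.frame(element = missing,
                                class = max(classes$class, 0L) +
                                  seq_along(missing),
                                polarity = 1L, stringsAsFactors = FALSE))
  covering <- tryCatch(covering_edges(selected),
                       error = function(e) {
                         warning(conditionMessage(e), call. = FALSE)
                         pair_relations()
                       })
  structure(list(
    report = report, selected = selected, classes = classes,
    covering = covering, elements = elements, N = N,
    epsilon = epsilon, epsilon_estimated = eps_estimated,
    alpha = alpha, pvalue_threshold = pvalue_threshold,
    pvalue_decimals = pvalue_decimals,
    thresholds = c(similar = ceiling(similar_threshold(N, epsilon, alpha)),
                   prerequisite = ceiling(prerequisite_threshold(N, epsilon,
                                                                 alpha))),
    constant_elements = constant,
    call = match.call()), class = "dab_network")
}

#' @export
print.dab_network <- function(x, ...) {
  cat("Directed acyclic Boolean network fit (two-step counting)\n")
  cat(sprintf("  %d elements, %d samples, epsilon = %.3g%s\n",
              length(x$elements), x$N, x$epsilon,
              if (x$epsilon_estimated) " (estimated)" else ""))
  cat(sprintf("  count thresholds: similar %d, prerequisite %d; p-value >= %g at %d decimals\n",
              x$thresholds[["similar"]], x$thresholds[["prerequisite"]],
              x$pvalue_threshold, x$pvalue_decimals))
  cat(sprintf("  %d selected relationship(s)\n", nrow(x$selected)))
  if (nrow(x$selected)) {
    lab <- c(SIM = "~", SIM_DUAL = "~*", F01 = "->", F10 = "<-",
             F00 = "*->", F11 = "->*")
    cat("  ", paste0(x$selected$a, " ", lab[x$selected$kind], " ",
                     x$selected$b, collapse = ", "), "\n", sep = "")
  }
  if (length(x$constant_elements))
    cat("  constant elements:",
        paste(x$constant_elements, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dab_network <- function(object, ...) {
  r <- object$report
  s <- list(fit = object,
            n_selected = sum(r$selected),
            n_count_only = sum(r$passed_count & !r$passed_pvalue),
            n_pvalue_only = sum(r$passed_pvalue & !r$passed_count),
            selected = r[r$selected, c("pair", "kind", "count", "pvalue")])
  class(s) <- "summary.dab_network"
  s
}

#' @export
print.summary.dab_network <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nScreen overlap: %d pass both, %d count-only, %d p-value-only\n",
              x$n_selected, x$n_count_only, x$n_pvalue_only))
  if (nrow(x$selected)) {
    cat("\nSelected relationships:\n")
    print(x$selected, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.dab_network <- function(object, ...) {
  c(epsilon = object$epsilon,
    threshold_similar = unname(object$thresholds["similar"]),
    threshold_prerequisite = unname(object$thresholds["prerequisite"]),
    pvalue_threshold = object$pvalue_threshold)
}

#' Simulate new observations from a fitted DAB network
#'
#' Draws states uniformly from the compatible state space of the selected
#' relationships and applies the fitted bit-flip noise.
#'
#' @param object a [dab_infer()] fit.
#' @param nsim number of samples (columns).
#' @param seed integer seed.
#' @param epsilon flip probability; defaults to the fitted value.
#' @param ... unused.
#' @return A binary matrix with the fit's elements in rows.
#' @export
simulate.dab_network <- function(object, nsim = 1, seed = NULL,
                                 epsilon = object$epsilon, ...) {
  states <- enumerate_compatible_states(object$elements, object$selected)
  out <- sample_states(states, n_samples = nsim, seed = seed)
  perturb(out, epsilon, seed = if (is.null(seed)) NULL else seed + 1L)
}

#' Plot the covering structure of a fitted DAB network
#'
#' Draws the similarity classes as nodes on topological levels of the
#' covering (immediate prerequisite) DAG; similar elements share a node.
#'
#' @param x a [dab_infer()] fit.
#' @param ... passed to [graphics::text()] for the node labels.
#' @export
plot.dab_network <- function(x, ...) {
  sc <- x$classes
  cov <- x$covering
  labs <- vapply(unique(sc$class), function(cl) {
    e <- sc$element[sc$class == cl]
    p <- sc$polarity[sc$class == cl]
    paste0(ifelse(p < 0, paste0(e, "*"), e), collapse = "~")
  }, character(1))
  ncl <- length(labs)
  cls_of <- function(el) sc$class[match(el, sc$element)]
  edges <- if (nrow(cov)) {
    data.frame(from = cls_of(cov$a), to = cls_of(cov$b),
               kind = cov$kind, stringsAsFactors = FALSE)
  } else data.frame(from = integer(), to = integer(), kind = character())
  # direction: F01/F00 run a -> b, F10/F11 run b -> a
  swap <- edges$kind %in% c("F10", "F11")
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  level <- rep(0L, ncl)
  repeat {
    new <- level
    for (i in seq_len(nrow(edges)))
      new[edges$to[i]] <- max(new[edges$to[i]], level[edges$from[i]] + 1L)
    if (identical(new, level)) break
    level <- new
  }
  xs <- stats::ave(seq_len(ncl), level, FUN = seq_along)
  wid <- stats::ave(seq_len(ncl), level, FUN = length)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(-0.5, max(level) + 0.5),
                 axes = FALSE, xlab = "", ylab = "",
                 main = "DAB network covering structure")
  px <- (xs - 0.5) / wid; py <- max(level) - level
  for (i in seq_len(nrow(edges)))
    graphics::arrows(px[edges$from[i]], py[edges$from[i]] - 0.08,
                     px[edges$to[i]], py[edges$to[i]] + 0.08,
                     length = 0.1)
  graphics::text(px, py, labs, ...)
  invisible(x)
}
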