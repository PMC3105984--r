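.check_binary_matrix <- function(x) {
  if (!is.matrix(x)) stop("expected a matrix", call. = FALSE)
  if (is.null(rownames(x)))
    rownames(x) <- paste0("e", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate element labels", call. = FALSE)
  bad <- which(!(x %in% c(0L, 1L)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(x))
    stop(sprintf("non-binary value %s at element '%s', sample %d",
                 format(x[bad[1]]), rownames(x)[rc[1]], rc[2]),
         call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

#' Read a binary element-by-sample matrix
#'
#' Reads a delimited text file with element labels in the first column, a
#' header row of sample labels and 0/1 entries.  The delimiter is sniffed
#' from the header (tab versus comma) unless given.
#'
#' @param path file path.
#' @param sep field delimiter; \code{NULL} (default) sniffs tab vs comma.
#' @return A validated binary matrix (elements in rows).
#' @export
read_binary_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(hdr, gregexpr("\t", hdr))) >=
               lengths(regmatches(hdr, gregexpr(",", hdr)))) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          row.names = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop(sprintf("non-binary cell '%s' at row '%s', column '%s'",
                 format(m[bad[1]]), rownames(m)[rc[1]],
                 colnames(m)[rc[2]]), call. = FALSE)
  }
  .check_binary_matrix(m)
}

#' Write a binary matrix
#'
#' @param x binary matrix.
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @export
write_binary_matrix <- function(x, path, sep = "\t") {
  x <- .check_binary_matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  df <- data.frame(element = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Binarize a real-valued expression matrix
#'
#' Converts log-ratio expression values to on/off states: a gene is on
#' when its log ratio is above zero and off when below; an exact zero is
#' treated as off by default.  Samples containing missing values are
#' dropped by default, mirroring the exclusion of incomplete arrays;
#' alternatively missing entries can be kept as \code{NA} for pairwise
#' handling downstream.
#'
#' @param x numeric matrix of log ratios (elements in rows), possibly
#'   with \code{NA}s.
#' @param zero state assigned to exact zeros, \code{0} (default) or
#'   \code{1}.
#' @param missing \code{"drop_sample"} (default) removes every column
#'   containing an \code{NA} (with a message); \code{"keep_na"} keeps
#'   them as \code{NA}.
#' @return A binary matrix (possibly with fewer columns).
#' @examples
#' binarize_expression(matrix(c(0.3, -1.2, 0), 1,
#'                            dimnames = list("g1", NULL)))
#' @export
binarize_expression <- function(x, zero = 0L,
                                missing = c("drop_sample", "keep_na")) {
  stopifnot(is.matrix(x), is.numeric(x))
  missing <- match.arg(missing)
  if (missing == "drop_sample") {
    bad <- apply(x, 2, anyNA)
    if (any(bad)) {
      message("dropping ", sum(bad), " sample(s) with missing values")
      x <- x[, !bad, drop = FALSE]
    }
  }
  b <- ifelse(x > 0, 1L, ifelse(x < 0, 0L, as.integer(zero)))
  dimnames(b) <- dimnames(x)
  if (anyNA(b)) return(b)      # pairwise handling left to the caller
  .check_binary_matrix(b)
}

#' Write a fitted network
#'
#' \code{"tsv"} writes the full per-pair report as a tab-separated edge
#' list (element_a, element_b, relation, count, pvalue, selected);
#' \code{"sif"} and \code{"dot"} render the covering edges (similarity as
#' undirected links).
#'
#' @param model a [dab_infer()] fit.
#' @param path output path.
#' @param format \code{"tsv"}, \code{"sif"} or \code{"dot"}.
#' @export
write_network <- function(model, path, format = c("tsv", "sif", "dot")) {
  stopifnot(inherits(model, "dab_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    r <- model$report
    out <- data.frame(element_a = r$a, element_b = r$b,
                      relation = r$kind, count = r$count,
                      pvalue = round(r$pvalue, model$pvalue_decimals),
                      selected = r$selected, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    cov <- model$covering
    sims <- .class_links(model$classes)
    lines <- character()
    if (format == "sif") {
      if (nrow(cov))
        lines <- c(lines, paste(cov$a, cov$kind, cov$b))
      if (nrow(sims))
        lines <- c(lines, paste(sims$a, sims$kind, sims$b))
    } else {
      lines <- c("digraph dab {")
      if (nrow(cov)) {
        swap <- cov$kind %in% c("F10", "F11")
        from <- ifelse(swap, cov$b, cov$a)
        to <- ifelse(swap, cov$a, cov$b)
        lines <- c(lines, sprintf("  %s -> %s [label=\"%s\"];",
                                  from, to, cov$kind))
      }
      if (nrow(sims))
        lines <- c(lines, sprintf("  %s -> %s [dir=none, label=\"%s\"];",
                                  sims$a, sims$b, sims$kind))
      lines <- c(lines, "}")
    }
    writeLines(lines, path)
  }
  invisible(path)
}
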