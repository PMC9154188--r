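#' Read a network from a file
#'
#' Reads a unipartite network (symmetric adjacency) or bipartite network
#' (binary incidence) from one of four plain-text formats:
#'
#' * `edgelist`: CSV/TSV with header `source,target[,weight]`; a missing
#'   weight column means all weights are 1. With `bipartite = TRUE` the two
#'   columns are read as agent and artifact.
#' * `dense`: CSV dense matrix with row and column labels in the first
#'   column / header row. A rectangular matrix is returned as an incidence
#'   matrix.
#' * `mtx`: Matrix Market coordinate format (labels are not part of the
#'   format; default labels are assigned).
#' * `graphml`: GraphML interchange, via igraph.
#'
#' @param path Path to the file.
#' @param format One of `"auto"`, `"edgelist"`, `"dense"`, `"mtx"`,
#'   `"graphml"`. `"auto"` dispatches on the file extension
#'   (`.mtx`, `.graphml`, otherwise edgelist).
#' @param bipartite Logical; read the file as a bipartite incidence structure.
#' @return A labelled numeric matrix: symmetric adjacency (unipartite) or
#'   binary incidence (bipartite, agents in rows).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("source,target,weight", "a,b,2", "a,c,1", "b,c,3"), f)
#' read_graph(f)
#' @seealso [write_graph()]
#' @export
read_graph <- function(path,
                       format = c("auto", "edgelist", "dense", "mtx", "graphml"),
                       bipartite = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      mtx = "mtx",
      graphml = "graphml",
      "edgelist"
    )
  }
  switch(format,
    edgelist = read_edgelist(path, bipartite),
    dense = read_dense(path, bipartite),
    mtx = read_mtx(path, bipartite),
    graphml = as_adjacency(igraph::read_graph(path, format = "graphml"))
  )
}

read_edgelist <- function(path, bipartite) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  fields <- count.fields(path, sep = sep)
  bad <- which(!is.na(fields) & fields != fields[1])
  if (length(bad)) {
    abort(sprintf("parse error in %s at line %d: expected %d fields, found %d.",
                  path, bad[1], fields[1], fields[bad[1]]))
  }
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 colClasses = "character", blank.lines.skip = TRUE)
  if (ncol(df) >= 3) {
    w <- suppressWarnings(as.numeric(df[[3]]))
    if (any(is.na(w))) {
      abort(sprintf("parse error in %s at line %d: non-numeric weight '%s'.",
                    path, which(is.na(w))[1] + 1L, df[[3]][which(is.na(w))[1]]))
    }
    df[[3]] <- w
  }
  if (bipartite) as_incidence(df) else as_adjacency(df)
}

read_dense <- function(path, bipartite) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (bipartite || nrow(m) != ncol(m)) as_incidence(m) else as_adjacency(m)
}

read_mtx <- function(path, bipartite) {
  m <- as.matrix(Matrix::readMM(path))
  if (bipartite || nrow(m) != ncol(m)) {
    as_incidence(ensure_dimnames(m, "a", "f"))
  } else {
    as_adjacency(ensure_dimnames(m))
  }
}

#' Write a network to a file
#'
#' Inverse of [read_graph()]. The edgelist writer emits a canonical form:
#' header `source,target,weight`, each undirected edge once with its endpoint
#' labels in (min, max) lexicographic order, rows sorted; reading and
#' re-writing a canonical edgelist is byte-identical. Incidence matrices
#' (rectangular, or passed with `bipartite = TRUE`) are written as two-mode
#' edgelists, dense matrices, or Matrix Market files.
#'
#' @param x A network matrix as returned by [read_graph()], or anything
#'   coercible by the package (edgelist data frame, igraph, Matrix).
#' @param path Output path.
#' @param format One of `"auto"`, `"edgelist"`, `"dense"`, `"mtx"`,
#'   `"graphml"`.
#' @param bipartite Logical; treat `x` as an incidence matrix even if square.
#' @return `path`, invisibly.
#' @export
write_graph <- function(x, path,
                        format = c("auto", "edgelist", "dense", "mtx", "graphml"),
                        bipartite = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", graphml = "graphml", "edgelist")
  }
  is_bip <- bipartite || (is.matrix(x) && nrow(x) != ncol(x))
  m <- if (is_bip) as_incidence(x) else as_adjacency(x)
  switch(format,
    edgelist = write_edgelist(m, path, is_bip),
    dense = write.csv(m, path),
    mtx = Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), path),
    graphml = {
      g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected", weighted = TRUE)
      igraph::write_graph(g, path, format = "graphml")
    }
  )
  invisible(path)
}

fmt_num <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE, digits = 15),
         character(1))
}

write_edgelist <- function(m, path, is_bip) {
  if (is_bip) {
    idx <- which(m != 0, arr.ind = TRUE)
    df <- data.frame(source = rownames(m)[idx[, 1]],
                     target = colnames(m)[idx[, 2]],
                     weight = m[idx])
    df <- df[order(df$source, df$target), , drop = FALSE]
  } else {
    et <- edge_table(m)
    df <- data.frame(source = pmin(et$from, et$to),
                     target = pmax(et$from, et$to),
                     weight = et$weight)
    df <- df[order(df$source, df$target), , drop = FALSE]
  }
  lines <- c("source,target,weight",
             paste(df$source, df$target, fmt_num(df$weight), sep = ","))
  writeLines(lines, path)
}
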