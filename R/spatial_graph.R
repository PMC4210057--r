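#' District adjacency graph
#'
#' Builds a symmetric adjacency graph over district ids from an edge list.
#' Duplicate and reversed edges collapse to a single adjacency; self-loops
#' are an error. Isolated districts (no neighbours) are retained and flagged,
#' but are rejected by [car_structure()] unless explicitly allowed.
#'
#' @param edges two-column matrix or data frame of district id pairs
#'   (character or integer).
#' @param ids optional vector fixing the district ordering; defaults to
#'   first appearance in `edges`. Ids in `ids` absent from `edges` become
#'   isolated districts.
#' @return An object of class `district_graph`: list with `ids` (ordered
#'   character vector), `neighbors` (named list of character vectors),
#'   `n_neighbors` (named integer), `isolated` (character vector).
#' @examples
#' g <- district_graph(cbind(c(1, 2), c(2, 3)))
#' g$neighbors[["2"]]
#' @export
district_graph <- function(edges, ids = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  a <- trimws(as.character(edges[, 1])); b <- trimws(as.character(edges[, 2]))
  if (any(a == b)) stop(sprintf("self-loop edge on id '%s'", a[a == b][1]))
  if (is.null(ids)) {
    ids <- unique(as.vector(t(cbind(a, b))))  # first-appearance order
  } else {
    ids <- as.character(ids)
    if (anyDuplicated(ids)) stop("duplicate ids")
    unknown <- setdiff(unique(c(a, b)), ids)
    if (length(unknown))
      stop(sprintf("edge references unknown id(s): %s", paste(unknown, collapse = ", ")))
  }
  nb <- lapply(setNames(ids, ids), function(i)
    sort(unique(c(b[a == i], a[b == i]))))
  nn <- vapply(nb, length, integer(1))
  structure(list(ids = ids, neighbors = nb, n_neighbors = nn,
                 isolated = ids[nn == 0L]),
            class = "district_graph")
}

#' Read a district adjacency graph from file
#'
#' Accepts either a whitespace-separated edge list (one `"id_a id_b"` row
#' per edge) or a symmetric 0/1 adjacency matrix CSV with ids in the header
#' and first column.
#'
#' @param path file path.
#' @param format `"edges"` (default) or `"matrix"`.
#' @inheritParams district_graph
#' @return a [district_graph].
#' @export
read_adjacency <- function(path, format = c("edges", "matrix"), ids = NULL) {
  format <- match.arg(format)
  if (format == "edges") {
    tab <- utils::read.table(path, header = FALSE, colClasses = "character")
    return(district_graph(tab[, 1:2], ids = ids))
  }
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  if (!isSymmetric(unname(m))) stop("adjacency matrix must be symmetric")
  idx <- which(m != 0 & upper.tri(m), arr.ind = TRUE)
  district_graph(cbind(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]]),
                 ids = if (is.null(ids)) rownames(m) else ids)
}

#' Intrinsic CAR (Markov random field) structure matrix
#'
#' The structure matrix `K` of the intrinsic conditional-autoregressive
#' prior is the graph Laplacian: diagonal `N_d` (neighbour counts),
#' off-diagonal -1 for adjacent districts. Rows sum to zero; `K` is positive
#' semidefinite with rank `n - #components`. The implied conditional prior of
#' one district effect given the rest is Gaussian with mean the neighbour
#' average and variance `sigma2 / N_d`.
#'
#' @param graph a [district_graph].
#' @param allow_isolated keep isolated districts (zero row/col in `K`)
#'   instead of erroring. Default `FALSE`: the intended study areas are
#'   contiguous, and an isolated district has an undefined conditional mean.
#' @return An object of class `car_structure`: list with `K` (dense matrix,
#'   dimnames = ids), `ids`, `components` (integer labels), `n_components`.
#' @export
car_structure <- function(graph, allow_isolated = FALSE) {
  stopifnot(inherits(graph, "district_graph"))
  if (length(graph$isolated) && !allow_isolated)
    stop(sprintf(paste0("isolated district(s) %s: merge them with a neighbour ",
                        "via an extra edge, drop them, or set allow_isolated = TRUE"),
                 paste(graph$isolated, collapse = ", ")))
  ids <- graph$ids
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    nb <- graph$neighbors[[ids[i]]]
    K[i, i] <- length(nb)
    K[i, match(nb, ids)] <- -1
  }
  comp <- .graph_components(graph)
  structure(list(K = K, ids = ids, components = comp,
                 n_components = max(comp)),
            class = "car_structure")
}

.graph_components <- function(graph) {
  ids <- graph$ids
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  label <- 0L
  for (root in ids) {
    if (!is.na(comp[root])) next
    label <- label + 1L
    queue <- root
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- label
      queue <- c(queue, graph$neighbors[[v]][is.na(comp[graph$neighbors[[v]]])])
    }
  }
  unname(comp[ids])
}

#' Conditional prior moments of a CAR district effect
#'
#' Given the effects of all other districts and the CAR variance, returns
#' the conditional Gaussian mean (neighbour average) and variance
#' (`sigma2 / N_d`) for one district.
#'
#' @param graph a [district_graph].
#' @param d district id.
#' @param values named numeric vector of effects for all districts.
#' @param sigma2 CAR variance parameter (> 0).
#' @return list with `mean` and `variance`.
#' @export
conditional_moments <- function(graph, d, values, sigma2) {
  stopifnot(inherits(graph, "district_graph"), sigma2 > 0)
  d <- as.character(d)
  if (!d %in% graph$ids) stop(sprintf("unknown district '%s'", d))
  nb <- graph$neighbors[[d]]
  if (!length(nb))
    stop(sprintf("district '%s' has no neighbours; merge or drop it", d))
  if (!all(nb %in% names(values))) stop("values must be named by district id")
  list(mean = mean(values[nb]), variance = sigma2 / length(nb))
}

#' Synthetic near-square lattice graph
#'
#' Rook-adjacency lattice over `n` districts, used as a documented synthetic
#' stand-in for an unpublished study-area adjacency (ids `"D01"`, `"D02"`,
#' ...). Cells fill an `nrow x ceiling(n/nrow)` grid row-major; the trailing
#' incomplete row keeps the graph connected.
#'
#' @param n number of districts (default 41).
#' @param nrow grid rows (default `floor(sqrt(n))`).
#' @return a [district_graph].
#' @export
lattice_graph <- function(n = 41L, nrow = floor(sqrt(n))) {
  stopifnot(n >= 2L, nrow >= 1L)
  ncol <- ceiling(n / nrow)
  ids <- sprintf("D%02d", seq_len(n))
  pos <- cbind(row = (seq_len(n) - 1L) %/% ncol, col = (seq_len(n) - 1L) %% ncol)
  edges <- NULL
  for (i in seq_len(n)) {
    right <- which(pos[, 1] == pos[i, 1] & pos[, 2] == pos[i, 2] + 1L)
    down <- which(pos[, 1] == pos[i, 1] + 1L & pos[, 2] == pos[i, 2])
    for (j in c(right, down)) edges <- rbind(edges, c(ids[i], ids[j]))
  }
  district_graph(edges, ids = ids)
}

#' Write a graph as an edge list
#' @param graph a [district_graph].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(graph, path) {
  stopifnot(inherits(graph, "district_graph"))
  rows <- character(0)
  for (i in seq_along(graph$ids)) {
    a <- graph$ids[i]
    for (b in graph$neighbors[[a]])
      if (match(b, graph$ids) > i) rows <- c(rows, paste(a, b))
  }
  writeLines(rows, path)
  invisible(path)
}
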