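#' Binary incidence matrix of a dataset
#'
#' @param dataset a [complexome_dataset()].
#' @param roles membership roles to include.
#' @return Sparse binary protein x complex membership matrix (the U matrix:
#'   `U[i, j] = 1` if protein i is a component of complex j under the chosen
#'   role filter).
#' @export
incidence_matrix <- function(dataset,
                             roles = c("all", "core", "attachment")) {
  roles <- match.arg(roles)
  m <- dataset$memberships
  if (roles != "all") m <- m[m$role == roles, , drop = FALSE]
  i <- match(m$protein, dataset$proteins)
  j <- match(m$complex, dataset$complexes)
  U <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(dataset$proteins),
                                     length(dataset$complexes)),
                            dimnames = list(dataset$proteins,
                                            dataset$complexes))
  # a protein can hold both roles in one complex; membership is binary
  U@x[U@x > 1] <- 1
  U
}

#' Build the complex-protein bipartite graph
#'
#' Complexes and proteins are the two node types; a complex is linked to a
#' protein if the protein is one of its components under the chosen role
#' filter. Nodes left without any edge by the filter are dropped from the
#' graph (and counted in a message), so degree averages are taken over
#' participating nodes only.
#'
#' @inheritParams incidence_matrix
#' @param roles `"all"`, `"core"` (core memberships only) or `"attachment"`.
#' @return Object of class `bipartite_graph` with fields `complexes`,
#'   `proteins` (participating nodes), `edges` (data.frame complex/protein),
#'   `roles`, and `dropped` counts.
#' @export
#' @examples
#' g <- build_bipartite(figure1_toy())
#' degree_summary(g, "protein")$degrees[["b"]]  # 3
build_bipartite <- function(dataset,
                            roles = c("all", "core", "attachment")) {
  roles <- match.arg(roles)
  m <- dataset$memberships
  if (roles != "all") m <- m[m$role == roles, , drop = FALSE]
  e <- unique(m[, c("complex", "protein")])
  e <- e[order(e$complex, e$protein), , drop = FALSE]
  rownames(e) <- NULL
  complexes <- sort(unique(e$complex))
  proteins <- sort(unique(e$protein))
  dropped <- list(complexes = setdiff(dataset$complexes, complexes),
                  proteins = setdiff(dataset$proteins, proteins))
  if (length(dropped$complexes) + length(dropped$proteins) > 0)
    message("role filter '", roles, "' dropped ",
            length(dropped$complexes), " complexes and ",
            length(dropped$proteins), " proteins left without edges")
  structure(list(complexes = complexes, proteins = proteins, edges = e,
                 roles = roles, dropped = dropped),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat("bipartite graph (roles =", x$roles, "):", length(x$complexes),
      "complexes,", length(x$proteins), "proteins,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

.bip_incidence <- function(graph) {
  Matrix::sparseMatrix(i = match(graph$edges$protein, graph$proteins),
                       j = match(graph$edges$complex, graph$complexes),
                       x = 1,
                       dims = c(length(graph$proteins),
                                length(graph$complexes)),
                       dimnames = list(graph$proteins, graph$complexes))
}

#' One-mode weighted projection of a bipartite graph
#'
#' In protein mode two proteins are linked if they share at least one
#' complex, the link weight being the number of complexes they share; in
#' complex mode two complexes are linked with weight equal to the number of
#' proteins they share. Projections carry no self-loops; nodes isolated in
#' the projection are kept (with strength 0).
#'
#' @param graph a [build_bipartite()] graph.
#' @param mode `"protein"` or `"complex"`.
#' @return Object of class `weighted_projection` with `nodes`, `edges`
#'   (data.frame from/to/weight, from < to), `mode`.
#' @export
#' @examples
#' pr <- project(build_bipartite(figure1_toy()), "protein")
#' projection_weight(pr, "b", "e")  # 2: shared complexes B and C
project <- function(graph, mode = c("protein", "complex")) {
  mode <- match.arg(mode)
  B <- .bip_incidence(graph)
  W <- if (mode == "protein") Matrix::tcrossprod(B) else Matrix::crossprod(B)
  s <- Matrix::summary(Matrix::triu(W, 1))
  nodes <- if (mode == "protein") graph$proteins else graph$complexes
  e <- data.frame(from = nodes[s$i], to = nodes[s$j],
                  weight = as.integer(s$x), stringsAsFactors = FALSE)
  swap <- e$from > e$to
  tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  structure(list(nodes = nodes, edges = e, mode = mode,
                 roles = graph$roles),
            class = "weighted_projection")
}

#' @export
print.weighted_projection <- function(x, ...) {
  cat("weighted", x$mode, "projection (roles =", x$roles, "):",
      length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Weight of a projected link
#'
#' @param projection a [project()]ion.
#' @param u,v node ids.
#' @return Integer weight; 0 if the pair shares no partner.
#' @export
projection_weight <- function(projection, u, v) {
  if (!all(c(u, v) %in% projection$nodes))
    stop("unknown node", call. = FALSE)
  e <- projection$edges
  hit <- (e$from == u & e$to == v) | (e$from == v & e$to == u)
  if (any(hit)) e$weight[which(hit)[1]] else 0L
}

#' Node strength in a weighted projection
#'
#' The strength of node i is the sum of the weights of its incident links,
#' the weighted extension of the degree. Isolated nodes have strength 0.
#'
#' @param projection a [project()]ion.
#' @param node optional single node id; if `NULL`, all nodes.
#' @return Named numeric vector (or scalar if `node` given).
#' @export
node_strength <- function(projection, node = NULL) {
  s <- setNames(numeric(length(projection$nodes)), projection$nodes)
  e <- projection$edges
  if (nrow(e) > 0) {
    add <- tapply(c(e$weight, e$weight), c(e$from, e$to), sum)
    s[names(add)] <- add
  }
  if (is.null(node)) return(s)
  if (!node %in% projection$nodes) stop("unknown node: ", node, call. = FALSE)
  s[[node]]
}

.proj_degrees <- function(projection) {
  d <- setNames(integer(length(projection$nodes)), projection$nodes)
  e <- projection$edges
  if (nrow(e) > 0) {
    add <- table(c(e$from, e$to))
    d[names(add)] <- as.integer(add)
  }
  d
}

#' Degree summary of one side of a bipartite graph or of a projection
#'
#' Computes the per-node degree map, its mean, standard deviation and
#' maximum, and the cumulative degree distribution
#' `P(k) = sum_{k' >= k} p(k')` over observed degrees.
#'
#' @param x a `bipartite_graph` or `weighted_projection`.
#' @param side for a bipartite graph, `"complex"` or `"protein"`; ignored for
#'   projections.
#' @return Object of class `degree_summary`: list with `degrees`, `mean`,
#'   `sd`, `max`, `cumulative` (data.frame k, P).
#' @export
degree_summary <- function(x, side = c("complex", "protein")) {
  if (inherits(x, "bipartite_graph")) {
    side <- match.arg(side)
    nodes <- if (side == "complex") x$complexes else x$proteins
    if (length(nodes) == 0) stop("empty ", side, " side", call. = FALSE)
    col <- x$edges[[side]]
    d <- setNames(integer(length(nodes)), nodes)
    tab <- table(col)
    d[names(tab)] <- as.integer(tab)
  } else if (inherits(x, "weighted_projection")) {
    if (length(x$nodes) == 0) stop("empty projection", call. = FALSE)
    d <- .proj_degrees(x)
  } else stop("unsupported input", call. = FALSE)
  structure(list(degrees = d, mean = mean(d),
                 sd = if (length(d) > 1) sd(d) else 0,
                 max = max(d), cumulative = cumulative_dist(d)),
            class = "degree_summary")
}

#' @export
print.degree_summary <- function(x, ...) {
  cat("degree summary over", length(x$degrees), "nodes: mean",
      round(x$mean, 3), "sd", round(x$sd, 3), "max", x$max, "\n")
  invisible(x)
}

#' Connected components of a projection
#'
#' @param projection a [project()]ion.
#' @return List of node-id vectors, ordered by decreasing size then by
#'   lexicographic smallest member; isolated nodes form singleton components.
#' @export
connected_components <- function(projection) {
  g <- to_igraph(projection)
  comp <- igraph::components(g)
  parts <- split(names(comp$membership), comp$membership)
  parts <- lapply(parts, sort)
  mins <- vapply(parts, `[`, character(1), 1)
  parts <- parts[order(-lengths(parts), mins)]
  names(parts) <- NULL
  parts
}

#' Top-ranked nodes by a metric
#'
#' @param values named numeric vector (degrees or strengths).
#' @param n number of rows to keep (capped at the node count).
#' @return data.frame (node, value) sorted by decreasing value, ties broken
#'   lexicographically on node id.
#' @export
top_nodes <- function(values, n = 10) {
  stopifnot(n >= 1, !is.null(names(values)))
  ord <- order(-values, names(values))
  out <- data.frame(node = names(values)[ord], value = unname(values[ord]),
                    stringsAsFactors = FALSE)
  head(out, n)
}

#' Convert package graphs to igraph
#'
#' @param x a `bipartite_graph` or `weighted_projection`.
#' @return An igraph graph; bipartite graphs carry a logical `type` vertex
#'   attribute (TRUE for proteins), projections an edge `weight` attribute.
#' @export
to_igraph <- function(x) {
  if (inherits(x, "bipartite_graph")) {
    g <- igraph::graph_from_data_frame(
      x$edges, directed = FALSE,
      vertices = data.frame(name = c(x$complexes, x$proteins),
                            type = c(rep(FALSE, length(x$complexes)),
                                     rep(TRUE, length(x$proteins)))))
    return(g)
  }
  if (inherits(x, "weighted_projection")) {
    g <- igraph::graph_from_data_frame(
      x$edges, directed = FALSE,
      vertices = data.frame(name = x$nodes))
    return(g)
  }
  stop("unsupported input", call. = FALSE)
}

#' Export a graph
#'
#' `write_graphml` writes GraphML via igraph; `write_edgelist` writes the
#' weighted edge list (`u<TAB>v<TAB>weight`, weight 1 for bipartite edges).
#'
#' @param x a `bipartite_graph` or `weighted_projection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(x, path) {
  igraph::write_graph(to_igraph(x), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edgelist <- function(x, path) {
  e <- if (inherits(x, "bipartite_graph")) {
    data.frame(from = x$edges$complex, to = x$edges$protein, weight = 1L)
  } else x$edges
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
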