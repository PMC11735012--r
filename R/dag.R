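#' Construct a causal directed acyclic graph
#'
#' A lightweight DAG representation used for identification: nodes, directed
#' edges, and an optional role annotation per node (\code{"outcome"},
#' \code{"treatment"}, \code{"exposure-candidate"}, \code{"mediator"},
#' \code{"covariate"}).
#'
#' @param edges a two-column matrix or data frame of edges (from, to), or
#'   \code{NULL} for an edgeless graph.
#' @param nodes character vector of node names; defaults to the union of edge
#'   endpoints.  Nodes without edges must be listed here explicitly.
#' @param roles optional named character vector mapping nodes to roles.
#' @return an object of class \code{causal_dag} with elements \code{nodes},
#'   \code{parents} (named list), \code{children} (named list) and
#'   \code{roles}.
#' @examples
#' g <- causal_dag(rbind(c("a", "b"), c("b", "c")))
#' topological_sort(g)
#' @export
causal_dag <- function(edges = NULL, nodes = NULL, roles = NULL) {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("`edges` must have two columns (from, to)")
    storage.mode(edges) <- "character"
  } else {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (is.null(nodes)) nodes <- unique(as.vector(t(edges)))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  bad <- setdiff(as.vector(edges), nodes)
  if (length(bad)) stop("edge endpoint(s) not declared as nodes: ",
                        paste(bad, collapse = ", "))
  parents <- children <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    parents[[v]]  <- unname(edges[edges[, 2L] == v, 1L])
    children[[v]] <- unname(edges[edges[, 1L] == v, 2L])
  }
  dag <- structure(list(nodes = nodes, parents = parents,
                        children = children, roles = roles),
                   class = "causal_dag")
  if (is.null(topological_sort(dag, strict = FALSE)))
    stop("graph is cyclic")
  if (!is.null(roles)) {
    out <- names(roles)[roles == "outcome"]
    for (v in out)
      if (length(children[[v]]))
        stop("outcome node '", v, "' has outgoing edges")
  }
  dag
}

#' @export
print.causal_dag <- function(x, ...) {
  ne <- sum(lengths(x$children))
  cat("causal_dag:", length(x$nodes), "nodes,", ne, "edges\n")
  for (v in topological_sort(x)) {
    p <- x$parents[[v]]
    cat("  ", v, if (length(p)) paste0(" <- {", paste(p, collapse = ", "), "}")
        else "  (exogenous)", "\n", sep = "")
  }
  invisible(x)
}

#' Topological ordering of a DAG
#'
#' @param dag a \code{causal_dag}.
#' @param strict if \code{TRUE} (default) a cycle is an error; otherwise
#'   \code{NULL} is returned for cyclic input.
#' @return character vector of nodes, parents before children.
#' @export
topological_sort <- function(dag, strict = TRUE) {
  indeg <- lengths(dag$parents)
  order <- character(0)
  avail <- names(indeg)[indeg == 0L]
  while (length(avail)) {
    avail <- sort(avail)          # deterministic order
    v <- avail[1L]; avail <- avail[-1L]
    order <- c(order, v)
    for (w in dag$children[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) avail <- c(avail, w)
    }
  }
  if (length(order) < length(dag$nodes)) {
    if (strict) stop("graph is cyclic") else return(NULL)
  }
  order
}

reachable_set <- function(adj, start) {
  seen <- character(0); frontier <- start
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  seen
}

#' Descendants / ancestors of a node
#'
#' Proper descendants (or ancestors): the node itself is excluded.
#'
#' @param dag a \code{causal_dag}.
#' @param node node name.
#' @return character vector (possibly empty).
#' @export
descendants <- function(dag, node) {
  stopifnot(node %in% dag$nodes)
  sort(reachable_set(dag$children, node))
}

#' @rdname descendants
#' @export
ancestors <- function(dag, node) {
  stopifnot(node %in% dag$nodes)
  sort(reachable_set(dag$parents, node))
}

#' Test d-separation by Bayes-ball reachability
#'
#' Determines whether every path between \code{x} and \code{y} is blocked by
#' the conditioning set \code{z} under the d-separation rules (chains and
#' forks blocked by conditioning; colliders open when the collider or one of
#' its descendants is conditioned on).
#'
#' @param dag a \code{causal_dag}.
#' @param x,y node names (disjoint from \code{z}).
#' @param z character vector of conditioning nodes (may be empty).
#' @return \code{TRUE} if \code{x} and \code{y} are d-separated given
#'   \code{z}.
#' @export
d_separated <- function(dag, x, y, z = character(0)) {
  stopifnot(x %in% dag$nodes, y %in% dag$nodes, all(z %in% dag$nodes))
  if (x == y) stop("x and y must differ")
  if (x %in% z || y %in% z) stop("x and y must not be in z")
  # nodes that are in z or have a descendant in z (collider activation)
  in_z <- dag$nodes %in% z
  names(in_z) <- dag$nodes
  anc_z <- in_z
  for (v in rev(topological_sort(dag)))
    if (!anc_z[[v]] && any(anc_z[dag$children[[v]]])) anc_z[[v]] <- TRUE
  # ball states: (node, direction); "up" = arrived from a child,
  # "down" = arrived from a parent
  visited <- matrix(FALSE, nrow = length(dag$nodes), ncol = 2L,
                    dimnames = list(dag$nodes, c("up", "down")))
  queue <- list(c(x, "up"))
  while (length(queue)) {
    st <- queue[[1L]]; queue <- queue[-1L]
    v <- st[1L]; dir <- st[2L]
    if (visited[v, dir]) next
    visited[v, dir] <- TRUE
    if (dir == "up") {
      if (!in_z[[v]]) {
        for (p in dag$parents[[v]])  queue <- c(queue, list(c(p, "up")))
        for (w in dag$children[[v]]) queue <- c(queue, list(c(w, "down")))
      }
    } else {
      if (!in_z[[v]])
        for (w in dag$children[[v]]) queue <- c(queue, list(c(w, "down")))
      if (anc_z[[v]])
        for (p in dag$parents[[v]])  queue <- c(queue, list(c(p, "up")))
    }
  }
  !(visited[y, "up"] || visited[y, "down"])
}

drop_outgoing <- function(dag, node) {
  keep_edges <- do.call(rbind, lapply(dag$nodes, function(v) {
    ch <- dag$children[[v]]
    if (v == node || !length(ch)) return(NULL)
    cbind(v, ch)
  }))
  causal_dag(keep_edges, nodes = dag$nodes, roles = NULL)
}

#' Minimal backdoor adjustment set
#'
#' Searches for the smallest covariate set that blocks every backdoor path
#' (path entering the exposure through an incoming edge) between exposure and
#' outcome, contains no descendant of the exposure, and excludes exposure and
#' outcome themselves.  Validity is tested by d-separation in the graph with
#' the exposure's outgoing edges removed.  Among minimal sets, ties are
#' broken lexicographically, so the result is deterministic.
#'
#' @param dag a \code{causal_dag}.
#' @param exposure,outcome node names.
#' @return character vector (sorted); length zero when no adjustment is
#'   needed.  Errors if no valid backdoor set exists.
#' @examples
#' g <- stroke_dag()
#' backdoor_adjustment_set(g, "ht", "y")   # {age, dlp, dm}
#' @export
backdoor_adjustment_set <- function(dag, exposure, outcome) {
  stopifnot(exposure %in% dag$nodes, outcome %in% dag$nodes)
  if (exposure == outcome) stop("exposure and outcome must differ")
  g_back <- drop_outgoing(dag, exposure)
  cand <- sort(setdiff(dag$nodes,
                       c(exposure, outcome, descendants(dag, exposure))))
  for (k in 0:length(cand)) {
    if (k == 0L) {
      if (d_separated(g_back, exposure, outcome)) return(character(0))
      next
    }
    sets <- utils::combn(cand, k, simplify = FALSE)
    for (z in sets)
      if (d_separated(g_back, exposure, outcome, z)) return(z)
  }
  stop("no valid backdoor adjustment set exists for '", exposure, "'")
}

#' The default stroke causal diagram
#'
#' The clinical causal structure used throughout the package: age, sex and
#' BMI are exogenous; diabetes (dm) and dyslipidemia (dlp) precede
#' hypertension (ht); ht precedes chronic kidney disease (ckd) and atrial
#' fibrillation (af); antiplatelet treatment (t) is assigned based on ht, dm,
#' dlp and age (confounding by indication); stroke (y) is the terminal
#' outcome.  Hypertension acts on stroke partly through ckd and af, diabetes
#' through ht and ckd, and dyslipidemia through ht.
#'
#' @return a \code{causal_dag} over nodes \code{age, sex, bmi, dm, dlp, ht,
#'   ckd, af, t, y}.
#' @export
stroke_dag <- function() {
  e <- rbind(
    c("age", "dm"), c("age", "dlp"), c("age", "ht"), c("age", "ckd"),
    c("age", "af"), c("age", "y"),  c("age", "t"),
    c("bmi", "dm"), c("bmi", "y"),
    c("dm", "ht"),  c("dm", "ckd"), c("dm", "y"),  c("dm", "t"),
    c("dlp", "ht"), c("dlp", "y"),  c("dlp", "t"),
    c("ht", "ckd"), c("ht", "af"),  c("ht", "y"),  c("ht", "t"),
    c("ckd", "y"),
    c("af", "y"),
    c("t", "y"))
  roles <- c(age = "covariate", sex = "covariate", bmi = "covariate",
             dm = "exposure-candidate", dlp = "exposure-candidate",
             ht = "exposure-candidate", af = "exposure-candidate",
             ckd = "mediator", t = "treatment", y = "outcome")
  causal_dag(e, nodes = c("age", "sex", "bmi", "dm", "dlp", "ht", "ckd",
                          "af", "t", "y"),
             roles = roles)
}

#' Default stroke estimands
#'
#' The four risk-factor estimands analysed in the package, each with its
#' backdoor adjustment set derived from \code{\link{stroke_dag}} and a
#' human-readable conditional-probability expression.
#'
#' @param dag a \code{causal_dag}; defaults to \code{stroke_dag()}.
#' @return a named list of lists with elements \code{exposure},
#'   \code{outcome}, \code{adjustment_set}, \code{expression}.
#' @export
default_estimands <- function(dag = stroke_dag()) {
  exposures <- c("ht", "af", "dlp", "dm")
  out <- lapply(exposures, function(x) {
    adj <- backdoor_adjustment_set(dag, x, "y")
    list(exposure = x, outcome = "y", adjustment_set = adj,
         expression = sprintf("P(stroke | %s)",
                              paste(c(x, adj), collapse = ", ")))
  })
  stats::setNames(out, exposures)
}

#' Serialize a DAG
#'
#' \code{dag_edge_list} returns (and optionally writes) a two-column
#' from/to edge table; \code{dag_to_dot} renders Graphviz DOT source.
#'
#' @param dag a \code{causal_dag}.
#' @param path optional file path to write to.
#' @return \code{dag_edge_list}: a data frame with columns \code{from},
#'   \code{to}; \code{dag_to_dot}: a character scalar of DOT source.
#' @export
dag_edge_list <- function(dag, path = NULL) {
  e <- do.call(rbind, lapply(dag$nodes, function(v) {
    ch <- dag$children[[v]]
    if (!length(ch)) return(NULL)
    data.frame(from = v, to = ch, stringsAsFactors = FALSE)
  }))
  if (is.null(e)) e <- data.frame(from = character(0), to = character(0))
  if (!is.null(path))
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  e
}

#' @rdname dag_edge_list
#' @export
dag_to_dot <- function(dag, path = NULL) {
  e <- dag_edge_list(dag)
  body <- paste(sprintf("  %s -> %s;", e$from, e$to), collapse = "\n")
  iso <- setdiff(dag$nodes, unique(c(e$from, e$to)))
  if (length(iso))
    body <- paste(body, paste(sprintf("  %s;", iso), collapse = "\n"),
                  sep = "\n")
  dot <- paste0("digraph causal_dag {\n", body, "\n}\n")
  if (!is.null(path)) writeLines(dot, path)
  dot
}
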