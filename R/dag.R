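#' Directed acyclic graph specification for a recursive path model
#'
#' A `dag_spec` holds the temporal ordering of the modelled (endogenous)
#' variables -- exposure first, outcome last -- the directed edges among them,
#' and the exogenous covariates (confounders) that send an edge into every
#' endogenous node.
#'
#' @param endogenous character vector of endogenous node names in temporal
#'   order. The first element is the exposure, the last the outcome.
#' @param edges two-column character matrix (or data.frame) of directed edges
#'   `from -> to` among the endogenous nodes.
#' @param covariates character vector of exogenous covariate names. Each
#'   covariate is given an edge to every endogenous node when the model is
#'   fitted.
#' @return An object of class `dag_spec`.
#' @export
dag_spec <- function(endogenous, edges, covariates = character()) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L && length(edges) > 0L)
    stop("`edges` must have two columns (from, to)")
  if (length(edges) == 0L) edges <- matrix(character(), ncol = 2L)
  colnames(edges) <- c("from", "to")
  miss <- setdiff(unique(c(edges)), endogenous)
  if (length(miss))
    stop("edge endpoints not in `endogenous`: ", paste(miss, collapse = ", "))
  if (anyDuplicated(endogenous)) stop("duplicated endogenous node names")
  if (length(intersect(endogenous, covariates)))
    stop("covariates overlap endogenous nodes")
  spec <- structure(
    list(endogenous = endogenous, edges = edges, covariates = covariates,
         exposure = endogenous[1L], outcome = endogenous[length(endogenous)]),
    class = "dag_spec")
  topological_order(spec)   # errors on cycles
  if (nrow(edges) && any(match(edges[, "from"], endogenous) >=
                         match(edges[, "to"], endogenous)))
    stop("edges must respect the declared temporal order of `endogenous`")
  if (any(edges[, "to"] == spec$exposure))
    stop("exposure node must have no parents among endogenous nodes")
  if (any(edges[, "from"] == spec$outcome))
    stop("outcome node must have no children")
  spec
}

#' @export
print.dag_spec <- function(x, ...) {
  cat("dag_spec:", length(x$endogenous), "endogenous nodes,",
      nrow(x$edges), "edges,", length(x$covariates), "covariates\n")
  cat("  order:", paste(x$endogenous, collapse = " -> "), "\n")
  invisible(x)
}

#' Topological order of the endogenous nodes (Kahn's algorithm)
#'
#' @param dag a `dag_spec` (or a list with `endogenous` and `edges`).
#' @return character vector of node names; errors if the edge set is cyclic.
#' @export
topological_order <- function(dag) {
  nodes <- dag$endogenous
  edges <- dag$edges
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(factor(edges[, "to"], levels = nodes))
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- character(0)
  avail <- nodes[indeg == 0L]
  indeg <- indeg
  remaining <- edges
  while (length(avail)) {
    # keep declared order for determinism
    nxt <- avail[order(match(avail, nodes))][1L]
    out <- c(out, nxt)
    avail <- setdiff(avail, nxt)
    if (nrow(remaining)) {
      hit <- remaining[, "from"] == nxt
      for (child in remaining[hit, "to"]) {
        indeg[child] <- indeg[child] - 1L
        if (indeg[child] == 0L) avail <- c(avail, child)
      }
      remaining <- remaining[!hit, , drop = FALSE]
    }
  }
  if (length(out) != length(nodes))
    stop("edge map is cyclic: no topological order exists")
  out
}

parents_of <- function(dag, node) {
  dag$edges[dag$edges[, "to"] == node, "from"]
}

children_of <- function(dag, node) {
  dag$edges[dag$edges[, "from"] == node, "to"]
}

# nodes reachable from `node` by directed paths (excluding node itself)
descendants_of <- function(dag, node) {
  seen <- character(0)
  frontier <- children_of(dag, node)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, children_of, dag = dag))), seen)
  }
  seen
}

#' Enumerate all simple directed paths between two nodes
#'
#' Paths are returned in deterministic lexicographic order of their node
#' sequences (using the declared endogenous node order).
#'
#' @param dag a `dag_spec`.
#' @param from,to node names; default exposure and outcome.
#' @return list of character vectors, each a node sequence from `from` to `to`.
#' @export
enumerate_paths <- function(dag, from = dag$exposure, to = dag$outcome) {
  if (!from %in% dag$endogenous) stop("unknown node: ", from)
  if (!to %in% dag$endogenous) stop("unknown node: ", to)
  paths <- list()
  walk <- function(path) {
    head <- path[length(path)]
    if (head == to) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    kids <- children_of(dag, head)
    kids <- kids[order(match(kids, dag$endogenous))]
    for (k in kids) if (!k %in% path) walk(c(path, k))
  }
  walk(from)
  paths
}

#' Intermediate confounders of a mediator
#'
#' An intermediate confounder of mediator `m` is a modelled variable affected
#' by the exposure that directly affects the mediator and also affects the
#' outcome. These are the variables excluded in the "through m but not through
#' its intermediate confounders" pathway quantity.
#'
#' @param dag a `dag_spec`.
#' @param mediator mediator node name.
#' @return character vector (possibly empty) of node names.
#' @export
intermediate_confounders <- function(dag, mediator) {
  if (!mediator %in% dag$endogenous) stop("unknown mediator: ", mediator)
  cand <- setdiff(parents_of(dag, mediator), dag$exposure)
  affected <- descendants_of(dag, dag$exposure)
  keep <- vapply(cand, function(z) {
    z %in% affected && dag$outcome %in% descendants_of(dag, z)
  }, logical(1))
  cand[keep]
}

#' Default path-model DAGs for the cardiac-arrest survival analysis
#'
#' The full-population model runs from binarized socioeconomic position (SEP)
#' through witnessed status, bystander CPR, initial shockable rhythm and ED
#' level to survival; the admitted-only model adds coronary angiography (CAG)
#' and targeted temperature management (TTM) as post-admission mediators.
#' Age, sex, diabetes, hypertension and metropolitan residence enter as
#' exogenous confounders of every equation.
#'
#' @param population `"all"` or `"admitted"`.
#' @param outcome outcome column name (default survival to discharge).
#' @param exposure exposure column name (default binarized SEP).
#' @return a `dag_spec`.
#' @export
default_dag <- function(population = c("all", "admitted"),
                        outcome = "surv_discharge",
                        exposure = "sep_binary") {
  population <- match.arg(population)
  med <- c("witnessed", "bystander_cpr", "shockable", "ed_level12")
  e <- rbind(
    cbind(exposure, c(med, outcome)),
    c("witnessed", "bystander_cpr"),
    c("witnessed", "shockable"),
    c("bystander_cpr", "shockable"),
    c("witnessed", outcome),
    c("bystander_cpr", outcome),
    c("shockable", outcome),
    c("ed_level12", outcome))
  if (population == "admitted") {
    med <- c(med, "cag", "ttm")
    e <- rbind(e,
               cbind(exposure, c("cag", "ttm")),
               c("shockable", "cag"),
               c("ed_level12", "cag"),
               c("ed_level12", "ttm"),
               c("cag", outcome),
               c("ttm", outcome))
  }
  dag_spec(endogenous = c(exposure, med, outcome), edges = e,
           covariates = c("age", "sex", "diabetes", "hypertension",
                          "metropolitan"))
}
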