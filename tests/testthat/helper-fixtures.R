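# small deterministic fixtures and independent oracles used across tests

# independent brute-force DFS over an adjacency matrix; written separately
# from enumerate_paths on purpose (list-of-children recursion vs matrix scan)
oracle_paths <- function(adj, from, to) {
  nodes <- rownames(adj)
  out <- list()
  stack <- list(from)
  while (length(stack)) {
    path <- stack[[1L]]
    stack <- stack[-1L]
    last <- path[length(path)]
    if (last == to) {
      out[[length(out) + 1L]] <- path
      next
    }
    nxt <- nodes[adj[last, ] == 1 & !(nodes %in% path)]
    for (v in rev(nxt)) stack <- c(list(c(path, v)), stack)
  }
  out
}

# random recursive DAG over m endogenous nodes (exposure first, outcome
# last), each forward edge present with probability p_edge
random_dag <- function(m = 5L, p_edge = 0.6, k_cov = 2L, seed = 1L) {
  set.seed(seed)
  nodes <- c("x", paste0("m", seq_len(m - 2L)), "y")
  edges <- NULL
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    keep <- stats::runif(1) < p_edge
    if (i == 1L && j == m) keep <- TRUE    # always keep the direct edge
    if (keep) edges <- rbind(edges, c(nodes[i], nodes[j]))
  }
  cov <- if (k_cov > 0) paste0("c", seq_len(k_cov)) else character()
  dag_spec(nodes, edges, covariates = cov)
}

# simulate linear-Gaussian data from a dag with random coefficients
simulate_dag_data <- function(dag, n = 1000L, seed = 1L, extra_edge = NULL,
                              coef_range = c(0.2, 0.6)) {
  set.seed(seed)
  q <- length(dag$endogenous)
  B <- matrix(0, q, q, dimnames = list(dag$endogenous, dag$endogenous))
  if (nrow(dag$edges))
    B[cbind(dag$edges[, "to"], dag$edges[, "from"])] <-
      stats::runif(nrow(dag$edges), coef_range[1L], coef_range[2L]) *
      sample(c(-1, 1), nrow(dag$edges), replace = TRUE)
  if (!is.null(extra_edge)) B[extra_edge[2L], extra_edge[1L]] <- 0.4
  k <- length(dag$covariates)
  X <- matrix(stats::rnorm(n * k), n, k, dimnames = list(NULL, dag$covariates))
  G <- matrix(stats::runif(q * k, -0.3, 0.3), q, k)
  Y <- matrix(0, n, q, dimnames = list(NULL, dag$endogenous))
  for (j in seq_len(q))
    Y[, j] <- drop(X %*% G[j, ]) + drop(Y %*% B[j, ]) + stats::rnorm(n)
  list(data = as.data.frame(cbind(X, Y)), B = B, Gamma = G)
}

# negative Bernoulli log-likelihood for the brute-force logistic oracle
negloglik_logistic <- function(beta, y, X) {
  eta <- drop(X %*% beta)
  sum(log1p(exp(eta))) - sum(y * eta)
}

# small config for fast end-to-end runs (~12k subjects)
small_config <- function(seed = 1L, scale = 0.1, ...) {
  n <- round(c(NHI_Q1 = 40483, NHI_Q2 = 26955, NHI_Q3 = 21625,
               NHI_Q4 = 22201, MA = 10252) * scale)
  synthetic_config(n_per_group = n, seed = seed, ...)
}

# hand-built path_model_fit for closed-form delta-method checks
manual_chain_fit <- function(a = 0.5, b = 0.4, d = 0.1,
                             va = 0.01, vb = 0.02, vd = 0.005, cab = 0.003) {
  dag <- dag_spec(c("x", "m", "y"),
                  rbind(c("x", "m"), c("m", "y"), c("x", "y")))
  B <- matrix(0, 3, 3, dimnames = list(dag$endogenous, dag$endogenous))
  B["m", "x"] <- a; B["y", "m"] <- b; B["y", "x"] <- d
  nm <- c("m~x", "y~m", "y~x")
  V <- diag(c(va, vb, vd)); dimnames(V) <- list(nm, nm)
  V["m~x", "y~m"] <- V["y~m", "m~x"] <- cab
  structure(list(B = B, vcov_coef = V, coef = c(a, b, d), converged = TRUE,
                 dag = dag), class = "path_model_fit")
}
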