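# Independent oracles and shared fixtures for the test suite.

# -- cached synthetic cohorts (generation is deterministic, so caching only
#    saves time, never changes results)
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(n, seed, randomized = FALSE) {
  key <- paste(n, seed, randomized, sep = "_")
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- generate_cohort(
      default_cohort_spec(n = n, seed = seed, randomized = randomized))
  .sim_cache[[key]]
}

# -- d-separation oracle: enumerate every simple path between x and y and
#    apply the blocking rules triple by triple (collider opens when it or a
#    descendant is conditioned on; chain/fork blocks when the middle node is
#    conditioned on).  Exponential, fine for <= 6 nodes.
oracle_d_separated <- function(dag, x, y, z = character(0)) {
  desc_in_z <- function(v) v %in% z ||
    length(intersect(descendants(dag, v), z)) > 0L
  path_blocked <- function(path) {
    if (length(path) == 2L) return(FALSE)
    for (i in 2:(length(path) - 1L)) {
      a <- path[i - 1L]; b <- path[i]; cc <- path[i + 1L]
      collider <- b %in% dag$children[[a]] && b %in% dag$children[[cc]]
      if (collider) {
        if (!desc_in_z(b)) return(TRUE)
      } else if (b %in% z) {
        return(TRUE)
      }
    }
    FALSE
  }
  found_open <- FALSE
  walk <- function(path) {
    if (found_open) return()
    last <- path[length(path)]
    if (last == y) {
      if (!path_blocked(path)) found_open <<- TRUE
      return()
    }
    nb <- union(dag$children[[last]], dag$parents[[last]])
    for (v in setdiff(nb, path)) walk(c(path, v))
  }
  walk(x)
  !found_open
}

# random DAG on `k` nodes with a fixed variable order (guarantees acyclicity)
random_dag <- function(k, p_edge = 0.4) {
  nodes <- letters[seq_len(k)]
  edges <- NULL
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k)
      if (stats::runif(1) < p_edge)
        edges <- rbind(edges, c(nodes[i], nodes[j]))
  causal_dag(edges, nodes = nodes)
}

all_subsets <- function(v, max_size = length(v)) {
  out <- list(character(0))
  for (k in seq_len(min(length(v), max_size)))
    out <- c(out, utils::combn(v, k, simplify = FALSE))
  out
}

# brute-force minimal backdoor set: smallest subset (lexicographic
# tie-break) of non-descendants that d-separates exposure and outcome in
# the graph with the exposure's outgoing edges removed, judged by the path
# oracle
oracle_backdoor <- function(dag, exposure, outcome) {
  el <- dag_edge_list(dag)
  el <- el[el$from != exposure, , drop = FALSE]
  g_back <- causal_dag(as.matrix(el), nodes = dag$nodes)
  cand <- sort(setdiff(dag$nodes,
                       c(exposure, outcome, descendants(dag, exposure))))
  for (z in all_subsets(cand))
    if (oracle_d_separated(g_back, exposure, outcome, z)) return(z)
  NULL
}

# independent brute-force two-world simulator: samples every node
# (including the outcome) with rbinom, re-deriving the structural
# equations directly from the spec fields; worlds are not coupled
oracle_two_world <- function(spec, exposure, n, seed) {
  ex <- spec$exogenous
  set.seed(seed)
  one_world <- function(forced) {
    p_lo <- pnorm(ex$age_min, ex$age_mean, ex$age_sd)
    d <- data.frame(
      age = qnorm(runif(n, p_lo, 1), ex$age_mean, ex$age_sd),
      sex = rbinom(n, 1, ex$sex_p),
      bmi = rnorm(n, ex$bmi_mean, ex$bmi_sd))
    lp <- function(node, dat) {
      out <- rep(spec$intercepts[[node]], n)
      for (p in names(spec$coefficients[[node]])) {
        val <- switch(p,
                      age = (dat$age - ex$age_mean) / ex$age_sd,
                      bmi = (dat$bmi - ex$bmi_mean) / ex$bmi_sd,
                      dat[[p]])
        out <- out + spec$coefficients[[node]][[p]] * val
      }
      out
    }
    for (v in c("dm", "dlp", "ht", "ckd", "af", "t"))
      d[[v]] <- if (v == exposure) rep(forced, n)
        else rbinom(n, 1, plogis(lp(v, d)))
    tau <- spec$treatment_effect[["base"]] +
      spec$treatment_effect[["dm"]] * d$dm +
      spec$treatment_effect[["ht"]] * d$ht
    rbinom(n, 1, plogis(lp("y", d) + tau * d$t))
  }
  y1 <- one_world(1)
  y0 <- one_world(0)
  list(rd = mean(y1) - mean(y0),
       se = sqrt(var(y1) / n + var(y0) / n))
}

# mean pinball (quantile) loss
pinball <- function(y, pred, q) {
  r <- y - pred
  mean(pmax(q * r, (q - 1) * r))
}
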