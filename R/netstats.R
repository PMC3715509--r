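#' Degree and coreness of a static network
#'
#' `net_degree()` returns the number of neighbors of each vertex;
#' `net_coreness()` the coreness \eqn{c_i}: the largest \eqn{k} such that
#' the vertex belongs to the \eqn{k}-core (the maximal subgraph with all
#' degrees \eqn{\ge k}), i.e. the depth at which iterative minimum-degree
#' peeling removes it.  Both are local-to-mesoscale predictors of spreading
#' importance.
#'
#' @param net an igraph graph with named vertices.
#' @return A named integer vector over the network's vertices.
#' @export
net_degree <- function(net) {
  d <- igraph::degree(net)
  storage.mode(d) <- "integer"
  d
}

#' @rdname net_degree
#' @export
net_coreness <- function(net) {
  k <- igraph::coreness(net)
  storage.mode(k) <- "integer"
  k
}

#' Largest connected component
#'
#' @param net a non-empty igraph graph.
#' @return A list with `S`, the fraction of the network's own vertices in
#'   the largest connected component (the denominator is the constructed
#'   network's vertex set, not the original data's), and `members`, the
#'   names of the vertices in that component.
#' @export
largest_component <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  comp <- igraph::components(net)
  big <- which.max(comp$csize)
  members <- igraph::V(net)$name[comp$membership == big]
  list(S = comp$csize[big] / igraph::vcount(net), members = members)
}

#' Mean shortest-path distance within the largest component
#'
#' The number of edges in the shortest path between two vertices of the
#' largest connected component, averaged over all its unordered pairs.
#'
#' @param net an igraph graph whose largest component has at least 2
#'   vertices.
#' @return A single number \eqn{\ge 1}.
#' @export
mean_distance_lcc <- function(net) {
  lc <- largest_component(net)
  if (length(lc$members) < 2)
    stop("mean distance undefined: largest component has a single vertex")
  sub <- igraph::induced_subgraph(net, lc$members)
  igraph::mean_distance(sub, directed = FALSE)
}

#' Degree-preserving rewiring null model
#'
#' One randomized instance of the network with the same degree sequence
#' but otherwise no structure.  Sequentially for every edge \eqn{(i, j)} a
#' random partner edge \eqn{(i', j')} is drawn and, with equal probability,
#' the two are replaced by \eqn{(i, j')} and \eqn{(i', j)} or by
#' \eqn{(i, i')} and \eqn{(j, j')}; a replacement that would introduce a
#' self- or multi-edge triggers a fresh partner draw.  The degree sequence
#' is preserved exactly.  For rigid graphs (e.g. complete graphs) only
#' identity swaps are admissible and the input is returned unchanged up to
#' relabeling.
#'
#' @param net an igraph graph with at least 2 edges.
#' @param give_up maximum consecutive failed partner draws for one edge
#'   before an error is raised.
#' @return An igraph graph on the same named vertex set.
#' @export
rewire_null <- function(net, give_up = 10000) {
  if (igraph::ecount(net) < 2) stop("need at least two edges to rewire")
  el <- igraph::as_edgelist(net, names = FALSE)
  res <- rewire_cpp(el[, 1], el[, 2], igraph::vcount(net),
                    as.integer(give_up))
  out <- igraph::make_empty_graph(igraph::vcount(net), directed = FALSE)
  out <- igraph::add_edges(out, rbind(res$i, res$j))
  igraph::V(out)$name <- igraph::V(net)$name
  out
}

#' Null-model reference values for S and d
#'
#' Mean and standard deviation of the largest-component fraction S and the
#' mean intra-component distance d over `n_reps` independent
#' degree-preserving rewirings ([rewire_null()]).
#'
#' @param net an igraph graph with at least 2 edges.
#' @param n_reps number of randomizations; the reference analyses use
#'   10^4, desk-scale checks far fewer.
#' @param rng_seed optional integer seed.
#' @return A list with `S0`, `S0_sd`, `d0`, `d0_sd` and `n_reps`.  With
#'   `n_reps = 1` the standard deviations are `NA`.
#' @export
null_summary <- function(net, n_reps = 10000, rng_seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  S <- numeric(n_reps)
  d <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    g0 <- rewire_null(net)
    S[r] <- largest_component(g0)$S
    d[r] <- mean_distance_lcc(g0)
  }
  list(S0 = mean(S), S0_sd = if (n_reps > 1) stats::sd(S) else NA_real_,
       d0 = mean(d), d0_sd = if (n_reps > 1) stats::sd(d) else NA_real_,
       n_reps = n_reps)
}

#' One-row structural summary of a static network
#'
#' The diagnostics used to compare optimized representations: vertex and
#' edge counts, largest-component fraction S, mean intra-component
#' distance d, and (optionally) their null-model references
#' \eqn{S_0, d_0} from degree-preserving rewiring.
#'
#' @param net an igraph graph.
#' @param n_reps null-model randomizations; `0` skips the null model.
#' @param rng_seed optional integer seed for the null model.
#' @return A one-row data frame with columns `N`, `M`, `S`, `d` and, when
#'   `n_reps > 0`, `S0`, `S0_sd`, `d0`, `d0_sd`.
#' @export
network_summary <- function(net, n_reps = 0, rng_seed = NULL) {
  out <- data.frame(
    N = igraph::vcount(net),
    M = igraph::ecount(net),
    S = largest_component(net)$S,
    d = mean_distance_lcc(net)
  )
  if (n_reps > 0) {
    ns <- null_summary(net, n_reps, rng_seed)
    out$S0 <- ns$S0
    out$S0_sd <- ns$S0_sd
    out$d0 <- ns$d0
    out$d0_sd <- ns$d0_sd
  }
  out
}
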