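# simple undirected igraph from canonical pair indices; vertices are the
# contacted ones only, named by their original labels
graph_from_pairs <- function(ii, jj, labels) {
  keys <- unique((ii - 1) * length(labels) + jj)
  ui <- (keys - 1) %/% length(labels) + 1
  uj <- (keys - 1) %% length(labels) + 1
  el <- cbind(labels[ui], labels[uj])
  if (nrow(el) == 0)
    return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  stopifnot(igraph::is_simple(g))
  g
}

check_window <- function(cs, t_start, t_stop) {
  T_ <- sampling_time(cs)
  if (!is.numeric(t_start) || !is.numeric(t_stop) ||
      length(t_start) != 1 || length(t_stop) != 1)
    stop("t_start and t_stop must be single numbers")
  if (t_start > t_stop)
    stop("invalid window: t_start > t_stop")
  if (t_start < 0 || t_stop > T_)
    stop("window must lie within [0, T]")
  invisible(TRUE)
}

#' Time-slice network
#'
#' The simplest static representation of a contact sequence: vertices
#' \eqn{i} and \eqn{j} are connected if they have one or more contacts
#' \eqn{(i, j, t)} with \eqn{t_{start} \le t \le t_{stop}} (closed
#' interval).  The full window `[0, T]` gives the accumulated network.
#'
#' @param cs a `contact_seq` object.
#' @param t_start,t_stop window endpoints in native time units (the data's
#'   timestep, with the first contact at 0).
#' @return A simple undirected [igraph][igraph::graph] graph whose vertices
#'   are the individuals with at least one qualifying contact, named by
#'   their labels.
#' @seealso [ongoing()], [exp_threshold()], [accumulated()]
#' @export
time_slice <- function(cs, t_start, t_stop) {
  stopifnot(inherits(cs, "contact_seq"))
  check_window(cs, t_start, t_stop)
  keep <- cs$contacts$t >= t_start & cs$contacts$t <= t_stop
  graph_from_pairs(cs$contacts$i[keep], cs$contacts$j[keep], cs$labels)
}

#' Ongoing (concurrent-partnership) network
#'
#' Vertices \eqn{i} and \eqn{j} are connected if the pair has at least two
#' contacts \eqn{(i,j,t)} and \eqn{(i,j,t')} with
#' \eqn{t < t_{start} \le t_{stop} < t'} -- i.e. the relationship straddles
#' the window: one contact strictly before it and one strictly after.  This
#' is the network of partnerships concurrently active over the window, a
#' central construct in the epidemiology of sexually transmitted
#' infections.  With `t_start == t_stop` it reduces to the partnerships
#' active at a single instant.
#'
#' @inheritParams time_slice
#' @return A simple undirected igraph graph (contacted vertices only).
#' @export
ongoing <- function(cs, t_start, t_stop) {
  stopifnot(inherits(cs, "contact_seq"))
  check_window(cs, t_start, t_stop)
  pid <- pair_id(cs)
  tmin <- tapply(cs$contacts$t, pid, min)
  tmax <- tapply(cs$contacts$t, pid, max)
  keys <- as.numeric(names(tmin))[tmin < t_start & tmax > t_stop]
  N <- length(cs$labels)
  graph_from_pairs((keys - 1) %/% N + 1, (keys - 1) %% N + 1, cs$labels)
}

#' Exponentially decaying pair weights
#'
#' Each contact \eqn{(i, j, t)} contributes a weight \eqn{e^{-t/\tau}} to
#' its pair, with \eqn{t} counted from the data's first contact.  Recent
#' history is thus discounted smoothly: contacts far from the introduction
#' of the disease (which happens early in the sampling period) weigh more,
#' and many late contacts can equal a few early ones.
#'
#' @param cs a `contact_seq` object.
#' @param tau decay time, in native time units; must be positive.
#' @return A data frame with columns `i`, `j` (labels, canonical order) and
#'   `weight`, one row per pair with at least one contact.
#' @export
exp_threshold_weights <- function(cs, tau) {
  stopifnot(inherits(cs, "contact_seq"))
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0)
    stop("tau must be a single positive number")
  pid <- pair_id(cs)
  w <- tapply(exp(-cs$contacts$t / tau), pid, sum)
  keys <- as.numeric(names(w))
  N <- length(cs$labels)
  data.frame(
    i = cs$labels[(keys - 1) %/% N + 1],
    j = cs$labels[(keys - 1) %% N + 1],
    weight = as.numeric(w),
    stringsAsFactors = FALSE
  )
}

#' Exponential-threshold network
#'
#' Thresholds the decayed pair weights of [exp_threshold_weights()]: an
#' edge is placed between \eqn{i} and \eqn{j} when their accumulated weight
#' strictly exceeds \eqn{\Omega}.  In the \eqn{\tau \to \infty} limit every
#' contact has weight 1, so with \eqn{\Omega = n - 1/2} the result is the
#' aggregated-threshold network of pairs with at least \eqn{n} contacts
#' (half-integer thresholds avoid ties against integer weights).
#'
#' @inheritParams exp_threshold_weights
#' @param omega threshold; an edge requires pair weight `> omega` (strict).
#' @return A simple undirected igraph graph (contacted vertices only).
#' @export
exp_threshold <- function(cs, tau, omega) {
  if (!is.numeric(omega) || length(omega) != 1 || omega <= 0)
    stop("omega must be a single positive number")
  w <- exp_threshold_weights(cs, tau)
  keep <- w$weight > omega
  el <- cbind(w$i[keep], w$j[keep])
  if (nrow(el) == 0)
    return(igraph::make_empty_graph(0, directed = FALSE))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Accumulated (aggregated) network
#'
#' The network of accumulated contacts over the entire sampling time:
#' an edge for every pair with at least one contact.  Identical to
#' `time_slice(cs, 0, sampling_time(cs))`; this is the most common -- and,
#' for predicting influential spreaders, often poorest -- static
#' representation of temporal contact data.
#'
#' @param cs a `contact_seq` object.
#' @return A simple undirected igraph graph.
#' @export
accumulated <- function(cs) {
  stopifnot(inherits(cs, "contact_seq"))
  graph_from_pairs(cs$contacts$i, cs$contacts$j, cs$labels)
}

#' Export or import a static network
#'
#' `write_static()` writes a representation either as a sorted two-column
#' edge list of vertex labels (`format = "edgelist"`) or as GraphML;
#' `read_edgelist()` reads the edge-list format back into an igraph graph.
#'
#' @param net an igraph graph with named vertices.
#' @param file path.
#' @param format `"edgelist"` (default) or `"graphml"`.
#' @return `net` (write) or an igraph graph (read), invisibly for write.
#' @export
write_static <- function(net, file, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, file, format = "graphml")
    return(invisible(net))
  }
  el <- igraph::as_edgelist(net)
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  ord <- order(a, b)
  writeLines(paste(a[ord], b[ord]), file)
  invisible(net)
}

#' @rdname write_static
#' @export
read_edgelist <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) != 2L))
    stop("edge list rows must have exactly 2 fields")
  m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  igraph::graph_from_edgelist(m, directed = FALSE)
}
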