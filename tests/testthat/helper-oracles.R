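# Independent brute-force oracles and fixture builders shared across tests.
# Oracles are deliberately naive (per-row filters, repeated peeling, full
# enumeration) and share no code with the package internals they check.

# random raw contact rows (labels, unshifted times); may contain duplicates
random_rows <- function(n_vertices = 10, n_contacts = 50, t_max = 100,
                        distinct_times = FALSE) {
  labs <- paste0("v", seq_len(n_vertices))
  repeat {
    i <- sample(labs, n_contacts, replace = TRUE)
    j <- sample(labs, n_contacts, replace = TRUE)
    ok <- i != j
    if (sum(ok) >= 2) break
  }
  i <- i[ok]; j <- j[ok]
  t <- if (distinct_times) {
    sample.int(max(t_max, length(i) * 3), length(i))
  } else {
    sample.int(t_max, length(i), replace = TRUE)
  }
  data.frame(i = i, j = j, t = t, stringsAsFactors = FALSE)
}

random_cs <- function(...) {
  r <- random_rows(...)
  contact_sequence(r$i, r$j, r$t)
}

# independent recount of N, L, M, T from raw rows
oracle_counts <- function(rows) {
  key <- ifelse(rows$i < rows$j, paste(rows$i, rows$j), paste(rows$j, rows$i))
  list(N = length(unique(c(rows$i, rows$j))), L = nrow(rows),
       M = length(unique(key)), T = max(rows$t) - min(rows$t))
}

# per-pair brute-force interevent differences
oracle_interevents <- function(cs) {
  df <- contacts(cs)
  key <- paste(df$i, df$j)
  out <- integer(0)
  for (k in unique(key)) {
    tt <- sort(df$t[key == k])
    if (length(tt) >= 2) out <- c(out, diff(tt))
  }
  out
}

# edge set of an igraph graph as sorted "a|b" strings
edge_key <- function(net) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0) return(character(0))
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
}

# brute-force representation edge sets from the contact data frame
oracle_time_slice <- function(cs, t_start, t_stop) {
  df <- contacts(cs)
  keep <- df$t >= t_start & df$t <= t_stop
  sort(unique(paste(pmin(df$i, df$j), pmax(df$i, df$j),
                    sep = "|")[keep]))
}

oracle_ongoing <- function(cs, t_start, t_stop) {
  df <- contacts(cs)
  key <- paste(pmin(df$i, df$j), pmax(df$i, df$j), sep = "|")
  out <- character(0)
  for (k in unique(key)) {
    tt <- df$t[key == k]
    if (any(tt < t_start) && any(tt > t_stop)) out <- c(out, k)
  }
  sort(out)
}

oracle_weights <- function(cs, tau) {
  df <- contacts(cs)
  key <- paste(pmin(df$i, df$j), pmax(df$i, df$j), sep = "|")
  w <- numeric(0)
  for (k in unique(key)) {
    w[k] <- sum(exp(-df$t[key == k] / tau))
  }
  w
}

# time-respecting reachability (lambda = 1, delta > T, distinct timestamps):
# the set reachable from the seed starting at the seed's first contact
oracle_reach_size <- function(cs, seed) {
  df <- contacts(cs)
  df <- df[order(df$t), ]
  t0 <- min(df$t[df$i == seed | df$j == seed])
  inf <- seed
  for (k in seq_len(nrow(df))) {
    if (df$t[k] < t0) next
    a <- df$i[k]; b <- df$j[k]
    if (a %in% inf && !(b %in% inf)) inf <- c(inf, b)
    else if (b %in% inf && !(a %in% inf)) inf <- c(inf, a)
  }
  length(inf)
}

# all permutations of a small vector
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (k in seq_along(v))
    for (p in perms(v[-k])) out <- c(out, list(c(v[k], p)))
  out
}

# exact expected outbreak size by enumeration over all tie orders and all
# transmission coin flips (feasible for <= 6 contacts)
oracle_expected_size <- function(cs, seed, lambda, delta) {
  df <- contacts(cs)
  groups <- split(seq_len(nrow(df)), df$t)
  order_sets <- Reduce(function(acc, g) {
    unlist(lapply(acc, function(pre)
      lapply(perms(g), function(p) c(pre, p))), recursive = FALSE)
  }, groups, accumulate = FALSE, init = list(integer(0)))
  t0 <- min(df$t[df$i == seed | df$j == seed])

  walk <- function(ord, k, inf_time) {
    if (k > length(ord)) return(sum(!is.na(inf_time)))
    row <- ord[k]
    a <- df$i[row]; b <- df$j[row]; t <- df$t[row]
    ia <- !is.na(inf_time[a]) && inf_time[a] <= t && t < inf_time[a] + delta
    ib <- !is.na(inf_time[b]) && inf_time[b] <= t && t < inf_time[b] + delta
    target <- NULL
    if (ia && is.na(inf_time[b])) target <- b
    if (ib && is.na(inf_time[a])) target <- a
    if (is.null(target) || lambda == 0) return(walk(ord, k + 1, inf_time))
    with_inf <- inf_time
    with_inf[target] <- t
    lambda * walk(ord, k + 1, with_inf) +
      (1 - lambda) * walk(ord, k + 1, inf_time)
  }

  vals <- vapply(order_sets, function(ord) {
    inf_time <- stats::setNames(rep(NA_real_, n_vertices(cs)),
                                vertex_labels(cs))
    inf_time[seed] <- t0
    walk(ord, 1, inf_time)
  }, numeric(1))
  mean(vals)
}

# naive k-core by repeated minimum-degree peeling on an adjacency list
oracle_coreness <- function(net) {
  labs <- igraph::V(net)$name
  el <- igraph::as_edgelist(net)
  core <- stats::setNames(rep(0L, length(labs)), labs)
  alive <- stats::setNames(rep(TRUE, length(labs)), labs)
  k <- 0L
  while (any(alive)) {
    repeat {
      deg <- stats::setNames(rep(0L, length(labs)), labs)
      keep <- alive[el[, 1]] & alive[el[, 2]]
      for (r in which(keep)) {
        deg[el[r, 1]] <- deg[el[r, 1]] + 1L
        deg[el[r, 2]] <- deg[el[r, 2]] + 1L
      }
      peel <- alive & deg < k
      if (!any(peel)) break
      core[peel] <- k - 1L
      alive[peel] <- FALSE
    }
    k <- k + 1L
  }
  core
}

# naive connected components / distances by breadth-first search
oracle_components <- function(net) {
  labs <- igraph::V(net)$name
  el <- igraph::as_edgelist(net)
  nbr <- stats::setNames(vector("list", length(labs)), labs)
  for (r in seq_len(nrow(el))) {
    nbr[[el[r, 1]]] <- c(nbr[[el[r, 1]]], el[r, 2])
    nbr[[el[r, 2]]] <- c(nbr[[el[r, 2]]], el[r, 1])
  }
  seen <- character(0)
  comps <- list()
  for (v in labs) {
    if (v %in% seen) next
    q <- v; comp <- character(0)
    while (length(q)) {
      x <- q[1]; q <- q[-1]
      if (x %in% comp) next
      comp <- c(comp, x)
      q <- c(q, setdiff(nbr[[x]], comp))
    }
    seen <- c(seen, comp)
    comps <- c(comps, list(comp))
  }
  comps
}

oracle_mean_distance <- function(net) {
  comps <- oracle_components(net)
  big <- comps[[which.max(lengths(comps))]]
  el <- igraph::as_edgelist(net)
  nbr <- stats::setNames(vector("list", length(big)), big)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    if (a %in% big && b %in% big) {
      nbr[[a]] <- c(nbr[[a]], b)
      nbr[[b]] <- c(nbr[[b]], a)
    }
  }
  tot <- 0; npairs <- 0
  for (s in big) {
    dist <- stats::setNames(rep(NA_real_, length(big)), big)
    dist[s] <- 0
    q <- s
    while (length(q)) {
      x <- q[1]; q <- q[-1]
      for (y in nbr[[x]]) if (is.na(dist[y])) {
        dist[y] <- dist[x] + 1
        q <- c(q, y)
      }
    }
    tot <- tot + sum(dist[names(dist) != s])
    npairs <- npairs + length(big) - 1
  }
  tot / npairs  # ordered pairs == unordered average by symmetry
}

# midranks + Pearson by explicit sums
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (k in seq_along(v)) r[k] <- mean(which(sort(v) == v[k]))
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# planted fixture: a "staircase" graph (edge iff i + j >= N + 1, so degrees
# are nearly all distinct and roughly equal to the vertex index) with one
# contact per edge at distinct times in the first half of the sampling
# period, plus unstructured noise contacts in the second half.  Under SIR
# with intermediate lambda the expected outbreak size is monotone in the
# degree of the [0, T/2] time slice.
planted_cs <- function(N = 200, n_noise = 400, T_total = 40000) {
  pairs <- which(outer(1:N, 1:N, function(a, b) a < b & a + b >= N + 1),
                 arr.ind = TRUE)
  M <- nrow(pairs)
  half <- floor(T_total / 2)
  sig_t <- sample(1:(half - 1), M, replace = FALSE)
  ni <- sample.int(N, n_noise, replace = TRUE)
  nj <- sample.int(N, n_noise, replace = TRUE)
  ok <- ni != nj
  ni <- ni[ok]; nj <- nj[ok]
  noise_t <- sample((half + 1):(T_total - 1), length(ni))
  i <- c(1, pairs[, 1], ni, 1)
  j <- c(N, pairs[, 2], nj, N)
  t <- c(0, sig_t, noise_t, T_total)  # anchors pin t = 0 and t = T
  contact_sequence(sprintf("v%03d", i), sprintf("v%03d", j), t)
}
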