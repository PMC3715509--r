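#' Construct a contact sequence
#'
#' A contact sequence is the package's central data object: an ordered
#' multiset of timestamped, undirected contacts \eqn{(i, j, t)} between
#' individuals, recorded at discrete times.  On construction the sequence is
#' brought to a canonical form: vertex labels are mapped to dense integer
#' indices, each pair is stored in a fixed orientation, times are shifted so
#' the first contact occurs at \eqn{t = 0}, and contacts are sorted by time
#' (ties keep their input order).  Identical duplicate rows are kept --
#' several contacts between the same pair in one timestep are meaningful
#' because simultaneous contacts are processed in random order by the SIR
#' simulator.
#'
#' @param i,j vectors of vertex labels (coerced to character); `i[k]` and
#'   `j[k]` are the endpoints of the k-th contact.  Self-contacts are an
#'   error.
#' @param t integer-valued vector of contact times.  Real-valued times are
#'   rejected, not rounded: the model is defined in discrete time.
#' @return An object of class `contact_seq`: a list with elements
#'   `contacts` (data frame of integer vertex indices `i < j` and shifted
#'   integer times `t`, sorted by `t`) and `labels` (character vector mapping
#'   index to original label).
#' @seealso [read_contacts()], [interevent_times()], [burstiness()]
#' @examples
#' cs <- contact_sequence(c("a", "b"), c("b", "c"), c(5, 7))
#' n_vertices(cs)   # 3
#' sampling_time(cs)  # 2: times are shifted to start at 0
#' @export
contact_sequence <- function(i, j, t) {
  if (length(i) != length(j) || length(i) != length(t))
    stop("i, j and t must have equal length")
  if (length(i) == 0L)
    stop("a contact sequence must contain at least one contact")
  i <- as.character(i)
  j <- as.character(j)
  if (anyNA(i) || anyNA(j) || anyNA(t))
    stop("missing values are not allowed in contacts")
  if (!is.numeric(t) || any(t != round(t)))
    stop("contact times must be integers (discrete time)")
  if (any(i == j))
    stop("self-contacts (i == j) are not allowed")
  labels <- sort(unique(c(i, j)))
  ii <- match(i, labels)
  jj <- match(j, labels)
  swap <- ii > jj
  tmp <- ii[swap]
  ii[swap] <- jj[swap]
  jj[swap] <- tmp
  t <- as.integer(round(t) - min(t))
  ord <- order(t)  # stable: ties keep input order
  obj <- list(
    contacts = data.frame(i = ii[ord], j = jj[ord], t = t[ord]),
    labels = labels
  )
  class(obj) <- "contact_seq"
  obj
}

#' @export
print.contact_seq <- function(x, ...) {
  cat(sprintf(
    "Contact sequence: N = %d vertices, L = %d contacts, M = %d pairs, T = %d\n",
    n_vertices(x), n_contacts(x), n_pairs(x), sampling_time(x)
  ))
  invisible(x)
}

#' Basic counts of a contact sequence
#'
#' `n_vertices()`, `n_contacts()`, `n_pairs()` and `sampling_time()` return
#' the number of distinct individuals N, the number of contacts L, the
#' number of distinct vertex pairs with at least one contact M (the edge
#' count of the accumulated network), and the total sampling time T (time of
#' the last contact, with the first at 0).
#'
#' @param cs a `contact_seq` object.
#' @return A single integer.
#' @export
n_vertices <- function(cs) {
  stopifnot(inherits(cs, "contact_seq"))
  length(cs$labels)
}

#' @rdname n_vertices
#' @export
n_contacts <- function(cs) {
  stopifnot(inherits(cs, "contact_seq"))
  nrow(cs$contacts)
}

#' @rdname n_vertices
#' @export
n_pairs <- function(cs) {
  stopifnot(inherits(cs, "contact_seq"))
  length(unique(pair_id(cs)))
}

#' @rdname n_vertices
#' @export
sampling_time <- function(cs) {
  stopifnot(inherits(cs, "contact_seq"))
  max(cs$contacts$t)
}

#' @rdname n_vertices
#' @export
vertex_labels <- function(cs) {
  stopifnot(inherits(cs, "contact_seq"))
  cs$labels
}

#' Contacts as a data frame of labels
#'
#' @param cs a `contact_seq` object.
#' @return A data frame with character columns `i`, `j` and integer `t`,
#'   sorted by time, pairs in canonical orientation.
#' @export
contacts <- function(cs) {
  stopifnot(inherits(cs, "contact_seq"))
  data.frame(
    i = cs$labels[cs$contacts$i],
    j = cs$labels[cs$contacts$j],
    t = cs$contacts$t,
    stringsAsFactors = FALSE
  )
}

# dense numeric id per vertex pair (exact for N well below 2^26)
pair_id <- function(cs) {
  (cs$contacts$i - 1) * length(cs$labels) + cs$contacts$j
}

#' Read a contact sequence from a three-column text file
#'
#' The native format is plain text with one contact per row, `i j t`,
#' whitespace- or tab-separated; lines starting with `#` and blank lines
#' are ignored.  Duplicate rows are kept.  The sequence is canonicalized
#' on construction (see [contact_sequence()]).
#'
#' @param file path or connection.
#' @return A `contact_seq` object.
#' @export
read_contacts <- function(file) {
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L)
    stop("no contacts found in input")
  parts <- strsplit(trimws(lines[rows]), "\\s+")
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    bad <- rows[which(nf != 3L)[1]]
    stop(sprintf("malformed row at line %d: expected 3 fields", bad))
  }
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  tval <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(tval) || any(tval != round(tval))) {
    bad <- rows[which(is.na(tval) | tval != round(tval))[1]]
    stop(sprintf("malformed row at line %d: time must be an integer", bad))
  }
  if (any(m[, 1] == m[, 2])) {
    bad <- rows[which(m[, 1] == m[, 2])[1]]
    stop(sprintf("self-contact at line %d", bad))
  }
  contact_sequence(m[, 1], m[, 2], tval)
}

#' Write a contact sequence in the native three-column format
#'
#' Writes canonical form (shifted times, canonical pair orientation, sorted
#' by time), so `read_contacts(write_contacts(cs))` reproduces `cs` exactly
#' and a second write is byte-identical.
#'
#' @param cs a `contact_seq` object.
#' @param file path or connection.
#' @return `cs`, invisibly.
#' @export
write_contacts <- function(cs, file) {
  stopifnot(inherits(cs, "contact_seq"))
  df <- contacts(cs)
  writeLines(paste(df$i, df$j, df$t), file)
  invisible(cs)
}

#' Pooled interevent times of a contact sequence
#'
#' For every vertex pair with at least two contacts, the successive time
#' differences between that pair's contacts, concatenated over pairs into
#' one series.  Pairs with fewer than two contacts contribute nothing.
#'
#' @param cs a `contact_seq` object.
#' @return Integer vector (possibly empty) of positive interevent times.
#'   Zero differences can occur when a pair has several contacts in one
#'   timestep.
#' @export
interevent_times <- function(cs) {
  stopifnot(inherits(cs, "contact_seq"))
  ts <- split(cs$contacts$t, pair_id(cs))
  unlist(lapply(ts, function(x) if (length(x) >= 2) diff(x) else integer(0)),
         use.names = FALSE)
}

#' Burstiness of the pooled interevent-time series
#'
#' Measures how far the pooled interevent times (see [interevent_times()])
#' depart from a Poisson process.  The default is the normalized form
#' \deqn{B = (\sigma - m) / (\sigma + m)}
#' where \eqn{m} and \eqn{\sigma} are the mean and standard deviation of the
#' series: \eqn{B = 0} for exponential (Poissonian) interevent times,
#' \eqn{B \to 1} for extremely bursty series and \eqn{B = -1} for a
#' perfectly periodic one.  With `normalized = FALSE` the raw coefficient of
#' variation \eqn{\sigma / m} is returned instead; it is unbounded above for
#' heavy-tailed series, which is why the bounded form is the default.
#'
#' @param cs a `contact_seq` object.
#' @param normalized if `TRUE` (default) return \eqn{(\sigma-m)/(\sigma+m)},
#'   otherwise the raw coefficient of variation \eqn{\sigma/m}.
#' @return A number in \eqn{[-1, 1]} (normalized) or \eqn{[0, \infty)} (raw).
#' @export
burstiness <- function(cs, normalized = TRUE) {
  x <- interevent_times(cs)
  if (length(x) < 2)
    stop("burstiness is undefined: fewer than 2 interevent times")
  m <- mean(x)
  s <- stats::sd(x)
  if (normalized) (s - m) / (s + m) else s / m
}
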