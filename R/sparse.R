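# Event-driven sparse operators. Connectivity is stored compressed sparse
# row with rows = presynaptic neurons and 0-based column indices (0-based
# neuron ids are the package-wide convention, including in exported CSVs).
# All accumulation runs in float64.

#' Construct a CSR connectivity matrix
#'
#' @param data per-edge weights (length nnz), or a single scalar for a
#'   homogeneous weight shared by all edges.
#' @param indices 0-based postsynaptic column ids, length nnz.
#' @param indptr row pointers, length `n_pre + 1`, nondecreasing.
#' @param shape integer `c(n_pre, n_post)`.
#' @return object of class `"csr_matrix"`.
#' @export
csr_matrix <- function(data, indices, indptr, shape) {
  shape <- as.integer(shape)
  indices <- as.integer(indices)
  indptr <- as.integer(indptr)
  stopifnot(length(shape) == 2L, all(shape >= 0L))
  if (length(indptr) != shape[1L] + 1L)
    stop("indptr must have length n_pre + 1", call. = FALSE)
  if (is.unsorted(indptr))
    stop("indptr must be nondecreasing", call. = FALSE)
  nnz <- indptr[length(indptr)]
  if (length(indices) != nnz)
    stop("indices length must equal nnz", call. = FALSE)
  if (nnz > 0L && (min(indices) < 0L || max(indices) >= shape[2L]))
    stop("column indices out of range [0, n_post)", call. = FALSE)
  if (length(data) != nnz && length(data) != 1L)
    stop("data must have length nnz or 1 (homogeneous weight)",
         call. = FALSE)
  structure(list(data = as.numeric(data), indices = indices,
                 indptr = indptr, shape = shape),
            class = "csr_matrix")
}

#' @export
print.csr_matrix <- function(x, ...) {
  cat(sprintf("<csr_matrix> %d x %d, nnz = %d%s\n", x$shape[1L], x$shape[2L],
              csr_nnz(x),
              if (length(x$data) == 1L) sprintf(", homogeneous weight %g", x$data) else ""))
  invisible(x)
}

#' Number of stored edges
#' @param m a `csr_matrix`.
#' @export
csr_nnz <- function(m) m$indptr[length(m$indptr)]

csr_row_ids <- function(m) {
  # 1-based presynaptic row id per stored edge
  rep.int(seq_len(m$shape[1L]), diff(m$indptr))
}

csr_edge_weights <- function(m) {
  if (length(m$data) == 1L) rep.int(m$data, csr_nnz(m)) else m$data
}

#' Convert a CSR matrix to a dense base matrix (oracle/debug use)
#' @param m a `csr_matrix`.
#' @export
csr_to_dense <- function(m) {
  out <- matrix(0, m$shape[1L], m$shape[2L])
  if (csr_nnz(m) > 0L) {
    ij <- cbind(csr_row_ids(m), m$indices + 1L)
    w <- csr_edge_weights(m)
    for (k in seq_len(nrow(ij))) out[ij[k, 1L], ij[k, 2L]] <-
        out[ij[k, 1L], ij[k, 2L]] + w[k]
  }
  out
}

#' Segment sum: accumulate per-edge values onto postsynaptic neurons
#'
#' `out[j] = sum over edges k with post_ids[k] = j of syn_values[k]`
#' (0-based ids). Duplicated ids sum.
#'
#' @param syn_values numeric per-edge values.
#' @param post_ids 0-based per-edge target ids.
#' @param n_post output length.
#' @return numeric vector of length `n_post`.
#' @export
syn2post_sum <- function(syn_values, post_ids, n_post) {
  n_post <- as.integer(n_post)
  if (length(syn_values) != length(post_ids))
    stop("syn_values and post_ids lengths differ", call. = FALSE)
  out <- numeric(n_post)
  if (!length(syn_values)) return(out)
  post_ids <- as.integer(post_ids)
  if (min(post_ids) < 0L || max(post_ids) >= n_post)
    stop("post id out of range [0, n_post)", call. = FALSE)
  s <- rowsum(as.numeric(syn_values), post_ids, reorder = TRUE)
  out[as.integer(rownames(s)) + 1L] <- s[, 1L]
  out
}

#' Gather presynaptic values onto edges
#'
#' `out[k] = pre_values[pre_ids[k]]` (0-based ids).
#'
#' @param pre_values numeric per-neuron values.
#' @param pre_ids 0-based per-edge source ids.
#' @return numeric per-edge vector.
#' @export
pre2syn_gather <- function(pre_values, pre_ids) {
  pre_ids <- as.integer(pre_ids)
  if (length(pre_ids) && (min(pre_ids) < 0L ||
                          max(pre_ids) >= length(pre_values)))
    stop("pre id out of range [0, n_pre)", call. = FALSE)
  pre_values[pre_ids + 1L]
}

#' Sparse matrix-vector product
#'
#' `transpose = FALSE` computes `m %*% v` (`v` of length `n_post`, output
#' length `n_pre`); `transpose = TRUE` computes `t(m) %*% v` without
#' materializing the transpose (`v` of length `n_pre`, output `n_post` —
#' the usual pre-to-post synaptic direction).
#'
#' @param m a `csr_matrix`.
#' @param v numeric vector matching the contracted dimension.
#' @param transpose logical flag.
#' @return numeric vector.
#' @export
csr_matvec <- function(m, v, transpose = FALSE) {
  stopifnot(inherits(m, "csr_matrix"))
  need <- if (transpose) m$shape[1L] else m$shape[2L]
  if (length(v) != need)
    stop(sprintf("shape error: v has length %d, expected %d",
                 length(v), need), call. = FALSE)
  w <- csr_edge_weights(m)
  if (transpose) {
    rows <- csr_row_ids(m)
    syn2post_sum(w * v[rows], m$indices, m$shape[2L])
  } else {
    contrib <- w * v[m$indices + 1L]
    syn2post_sum(contrib, csr_row_ids(m) - 1L, m$shape[1L])
  }
}

#' Event-driven sparse matrix-vector product
#'
#' Equivalent to [csr_matvec()] with the boolean event vector cast to 0/1,
#' but iterating only over the rows (presynaptic neurons) that spiked:
#' with `transpose = TRUE`, `out[j] = sum over active pre i of weight(i -> j)`.
#'
#' @param m a `csr_matrix`.
#' @param events logical vector (`n_pre` long when `transpose = TRUE`,
#'   `n_post` long otherwise).
#' @param transpose logical flag, as in [csr_matvec()].
#' @return numeric vector.
#' @export
event_csr_matvec <- function(m, events, transpose = TRUE) {
  stopifnot(inherits(m, "csr_matrix"), is.logical(events))
  need <- if (transpose) m$shape[1L] else m$shape[2L]
  if (length(events) != need)
    stop(sprintf("shape error: events has length %d, expected %d",
                 length(events), need), call. = FALSE)
  if (transpose) {
    active <- which(events)
    out <- numeric(m$shape[2L])
    if (!length(active)) return(out)
    lens <- m$indptr[active + 1L] - m$indptr[active]
    keep <- lens > 0L
    active <- active[keep]; lens <- lens[keep]
    if (!length(active)) return(out)
    k <- sequence(lens, from = m$indptr[active] + 1L)
    w <- if (length(m$data) == 1L) rep.int(m$data, length(k)) else m$data[k]
    syn2post_sum(w, m$indices[k], m$shape[2L])
  } else {
    # column mask: out[i] = sum over edges of row i whose column is active
    keep <- events[m$indices + 1L]
    rows <- csr_row_ids(m)
    w <- csr_edge_weights(m)
    syn2post_sum(w[keep], rows[keep] - 1L, m$shape[1L])
  }
}

# ---- deterministic JIT connectivity ---------------------------------------
#
# Matrix-free connectivity regenerated from a seed at every call. The random
# stream is fixed bit-exactly so a materialized matrix built from the same
# spec is identical: each presynaptic row r (0-based) owns an independent
# Lehmer (Park-Miller) stream
#     s_0     = ((seed * 69069 + r * 1013904223) mod 2147483646) + 1
#     s_{n+1} = (16807 * s_n) mod 2147483647,   u_n = s_n / 2147483647
# All products stay below 2^53, so the recurrence is exact in double
# arithmetic. Columns are drawn by geometric skip sampling of
# Bernoulli(prob): j <- j + 1 + floor(log(1 - u)/log(1 - prob)), and for
# normal weights one further uniform per realized edge feeds qnorm.

LEHMER_M <- 2147483647

lehmer_seed <- function(seed, row) {
  ((seed * 69069 + row * 1013904223) %% (LEHMER_M - 1)) + 1
}

lehmer_next <- function(s) (16807 * s) %% LEHMER_M

#' Specification of deterministic just-in-time connectivity
#'
#' @param n_pre,n_post shape.
#' @param prob connection probability in `[0, 1]`.
#' @param seed integer; the same spec always denotes the same connectivity.
#' @param weight a single scalar for homogeneous weights, or `c(mu, sigma)`
#'   for independent normal weights per edge.
#' @return object of class `"jitconn_spec"`.
#' @export
jitconn_spec <- function(n_pre, n_post, prob, seed, weight = 1) {
  if (!is.numeric(prob) || prob < 0 || prob > 1)
    stop("parameter error: prob must lie in [0, 1]", call. = FALSE)
  stopifnot(length(weight) %in% c(1L, 2L))
  structure(list(n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 prob = prob, seed = as.numeric(seed),
                 weight = as.numeric(weight)),
            class = "jitconn_spec")
}

# columns (0-based, sorted) and weights realized for one row
jit_row <- function(spec, row0) {
  p <- spec$prob
  n <- spec$n_post
  if (p <= 0 || n == 0L)
    return(list(cols = integer(), w = numeric()))
  s <- lehmer_seed(spec$seed, row0)
  cols <- integer(); ws <- numeric()
  normal <- length(spec$weight) == 2L
  if (p >= 1) {
    cols <- 0:(n - 1L)
    if (normal) {
      ws <- numeric(n)
      for (i in seq_len(n)) {
        s <- lehmer_next(s)
        ws[i] <- spec$weight[1L] + spec$weight[2L] * qnorm(s / LEHMER_M)
      }
    }
  } else {
    lq <- log1p(-p)
    j <- -1
    repeat {
      s <- lehmer_next(s)
      u <- s / LEHMER_M
      j <- j + 1 + floor(log1p(-u) / lq)
      if (j >= n) break
      cols[length(cols) + 1L] <- as.integer(j)
      if (normal) {
        s <- lehmer_next(s)
        ws[length(ws) + 1L] <-
          spec$weight[1L] + spec$weight[2L] * qnorm(s / LEHMER_M)
      }
    }
  }
  if (!normal) ws <- rep.int(spec$weight[1L], length(cols))
  list(cols = cols, w = ws)
}

#' Materialize JIT connectivity as a CSR matrix
#'
#' Builds the exact matrix that [jitconn_event_matvec()] acts with: the same
#' documented per-row random stream realizes the same edges and weights.
#'
#' @param spec a [jitconn_spec()].
#' @return a `csr_matrix`.
#' @export
jitconn_materialize <- function(spec) {
  stopifnot(inherits(spec, "jitconn_spec"))
  rows <- lapply(seq_len(spec$n_pre) - 1L, function(r) jit_row(spec, r))
  lens <- vapply(rows, function(r) length(r$cols), integer(1))
  homogeneous <- length(spec$weight) == 1L
  csr_matrix(
    data = if (homogeneous) spec$weight
           else unlist(lapply(rows, `[[`, "w"), use.names = FALSE),
    indices = unlist(lapply(rows, `[[`, "cols"), use.names = FALSE) %||% integer(),
    indptr = c(0L, cumsum(lens)),
    shape = c(spec$n_pre, spec$n_post))
}

#' Event-driven matrix-vector product with matrix-free JIT connectivity
#'
#' Equals [event_csr_matvec()] on [jitconn_materialize()]`(spec)`; no
#' connectivity is stored between calls. With `transpose = TRUE`
#' (pre-to-post direction) only the rows of active presynaptic neurons are
#' regenerated.
#'
#' @param spec a [jitconn_spec()].
#' @param events logical event vector.
#' @param transpose as in [event_csr_matvec()].
#' @return numeric vector.
#' @export
jitconn_event_matvec <- function(spec, events, transpose = TRUE) {
  stopifnot(inherits(spec, "jitconn_spec"), is.logical(events))
  need <- if (transpose) spec$n_pre else spec$n_post
  if (length(events) != need)
    stop(sprintf("shape error: events has length %d, expected %d",
                 length(events), need), call. = FALSE)
  if (transpose) {
    out <- numeric(spec$n_post)
    for (r in which(events)) {
      rw <- jit_row(spec, r - 1L)
      if (length(rw$cols))
        out <- out + syn2post_sum(rw$w, rw$cols, spec$n_post)
    }
    out
  } else {
    out <- numeric(spec$n_pre)
    for (r in seq_len(spec$n_pre)) {
      rw <- jit_row(spec, r - 1L)
      if (length(rw$cols)) {
        keep <- events[rw$cols + 1L]
        if (any(keep)) out[r] <- sum(rw$w[keep])
      }
    }
    out
  }
}

# ---- MTX / CSV serialization ----------------------------------------------

#' Write a CSR matrix to Matrix Market format
#' @param m a `csr_matrix`; `path` destination file.
#' @param path destination file.
#' @export
csr_write_mtx <- function(m, path) {
  stopifnot(inherits(m, "csr_matrix"))
  sp <- Matrix::sparseMatrix(
    i = csr_row_ids(m), j = m$indices + 1L, x = csr_edge_weights(m),
    dims = m$shape, repr = "T")
  Matrix::writeMM(sp, path)
  invisible(path)
}

#' Read a CSR matrix from Matrix Market format
#' @param path an MTX file written by [csr_write_mtx()] (or any coordinate
#'   real MTX).
#' @return a `csr_matrix` with row-sorted column indices.
#' @export
csr_read_mtx <- function(path) {
  sp <- methods::as(Matrix::readMM(path), "TsparseMatrix")
  i <- sp@i + 1L; j <- sp@j; x <- sp@x
  o <- order(i, j)
  i <- i[o]; j <- j[o]; x <- x[o]
  csr_matrix(data = x, indices = j,
             indptr = c(0L, cumsum(tabulate(i, nbins = nrow(sp)))),
             shape = dim(sp))
}

#' Edge list (2-column, 0-based pre/post) of a CSR matrix
#' @param m a `csr_matrix`.
#' @return data.frame with `pre`, `post`, `weight`.
#' @export
csr_edge_list <- function(m) {
  data.frame(pre = csr_row_ids(m) - 1L, post = m$indices,
             weight = csr_edge_weights(m))
}
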