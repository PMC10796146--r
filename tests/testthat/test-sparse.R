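test_that("csr_matvec matches the dense oracle and handles edge cases", {
  empty <- csr_matrix(numeric(), integer(), rep(0L, 11L), c(10L, 8L))
  expect_equal(csr_matvec(empty, rnorm(8)), numeric(10))
  expect_equal(csr_matvec(empty, rnorm(10), transpose = TRUE), numeric(8))
  ident <- one2one_conn(6)
  v <- rnorm(6)
  expect_equal(csr_matvec(ident, v), v)
  expect_equal(csr_matvec(ident, v, transpose = TRUE), v)
  set.seed(5)
  m <- random_csr(50, 40, 0.1, seed = 5)
  v40 <- rnorm(40); v50 <- rnorm(50)
  expect_lt(max(abs(csr_matvec(m, v40) - dense_matvec_oracle(m, v40))),
            1e-10)
  expect_lt(max(abs(csr_matvec(m, v50, TRUE) -
                    dense_matvec_oracle(m, v50, TRUE))), 1e-10)
  expect_error(csr_matvec(m, rnorm(39)), "shape")
})

test_that("transpose flag agrees with the dense transpose oracle on random instances", {
  set.seed(12)
  for (i in 1:100) {
    m <- random_csr(sample(5:30, 1), sample(5:30, 1), runif(1, 0, 0.4),
                    seed = 1000 + i)
    v <- rnorm(m$shape[1L])
    expect_lt(max(abs(csr_matvec(m, v, TRUE) -
                      dense_matvec_oracle(m, v, TRUE))), 1e-10)
  }
})

test_that("event_csr_matvec equals the non-event operator on 0/1 floats", {
  m0 <- random_csr(30, 20, 0.2, seed = 3)
  expect_equal(event_csr_matvec(m0, rep(FALSE, 30), TRUE), numeric(20))
  # all events with homogeneous weight w: out[j] = w * indegree(j)
  w <- 0.25
  mh <- fixed_prob_conn(40, 25, 0.3, seed = 9, weight = w)
  indeg <- tabulate(mh$indices + 1L, nbins = 25L)
  expect_equal(event_csr_matvec(mh, rep(TRUE, 40), TRUE), w * indeg)
  set.seed(31)
  for (i in 1:200) {
    m <- random_csr(sample(5:40, 1), sample(5:40, 1), runif(1, 0, 0.4),
                    seed = 2000 + i)
    tr <- i %% 2 == 0
    e <- runif(if (tr) m$shape[1L] else m$shape[2L]) < 0.3
    expect_lt(max(abs(event_csr_matvec(m, e, tr) -
                      csr_matvec(m, as.numeric(e), tr))), 1e-10)
  }
})

test_that("event operator is additive over disjoint event sets", {
  set.seed(78)
  e1 <- rep(FALSE, 60); e1[sample(1:60, 15)] <- TRUE
  e2 <- rep(FALSE, 60); e2[sample(which(!e1), 15)] <- TRUE
  # homogeneous dyadic weight: sums are exact, so additivity is bitwise
  mh <- fixed_prob_conn(60, 45, 0.15, seed = 77, weight = 0.5)
  expect_identical(event_csr_matvec(mh, e1 | e2, TRUE),
                   event_csr_matvec(mh, e1, TRUE) +
                     event_csr_matvec(mh, e2, TRUE))
  # general weights: equal up to summation-order roundoff
  m <- random_csr(60, 45, 0.15, seed = 77)
  expect_equal(event_csr_matvec(m, e1 | e2, TRUE),
               event_csr_matvec(m, e1, TRUE) +
                 event_csr_matvec(m, e2, TRUE), tolerance = 1e-12)
})

test_that("JIT connectivity is deterministic and equals its materialization", {
  sp <- jitconn_spec(100, 80, 0.1, seed = 42)
  set.seed(1)
  e <- runif(100) < 0.25
  out1 <- jitconn_event_matvec(sp, e, TRUE)
  out2 <- jitconn_event_matvec(sp, e, TRUE)
  expect_identical(out1, out2)
  m <- jitconn_materialize(sp)
  expect_identical(out1, event_csr_matvec(m, e, TRUE))
  # non-transpose direction
  ep <- runif(80) < 0.25
  expect_identical(jitconn_event_matvec(sp, ep, FALSE),
                   event_csr_matvec(m, ep, FALSE))
  # normal weights realize identically in both routes
  spn <- jitconn_spec(40, 40, 0.2, seed = 5, weight = c(0.5, 0.2))
  en <- rep(TRUE, 40)
  expect_identical(jitconn_event_matvec(spn, en, TRUE),
                   event_csr_matvec(jitconn_materialize(spn), en, TRUE))
  # different seeds give different connectivity on a 100x100 instance
  m1 <- jitconn_materialize(jitconn_spec(100, 100, 0.1, seed = 7))
  m2 <- jitconn_materialize(jitconn_spec(100, 100, 0.1, seed = 8))
  expect_false(identical(m1$indices, m2$indices))
  # degenerate probabilities
  expect_equal(jitconn_event_matvec(jitconn_spec(10, 10, 0, seed = 1),
                                    rep(TRUE, 10), TRUE), numeric(10))
  expect_equal(jitconn_event_matvec(jitconn_spec(10, 6, 1, seed = 1,
                                                 weight = 2),
                                    rep(TRUE, 10), TRUE), rep(2 * 10, 6))
  expect_error(jitconn_spec(10, 10, 1.5, seed = 1), "prob")
})

test_that("syn2post_sum and pre2syn_gather match loop oracles and compose to a matvec", {
  # identity mapping returns the input
  v <- rnorm(8)
  expect_equal(syn2post_sum(v, 0:7, 8), v)
  expect_equal(syn2post_sum(numeric(), integer(), 5), numeric(5))
  # 500-edge random instance vs brute-force accumulation
  set.seed(55)
  ids <- sample(0:39, 500, replace = TRUE)
  vals <- rnorm(500)
  oracle <- numeric(40)
  for (k in 1:500) oracle[ids[k] + 1L] <- oracle[ids[k] + 1L] + vals[k]
  expect_equal(syn2post_sum(vals, ids, 40), oracle, tolerance = 1e-12)
  expect_error(syn2post_sum(vals, ids, 30), "range")
  # gather
  pre <- rnorm(10)
  expect_equal(pre2syn_gather(pre, rep(0L, 7)), rep(pre[1], 7))
  expect_equal(pre2syn_gather(pre, 0:9), pre)
  expect_error(pre2syn_gather(pre, 10L), "range")
  # composition syn2post(gather(v)) == unit-weight csr matvec (transpose)
  m <- random_csr(25, 18, 0.2, weight_law = 1, seed = 8)
  el <- csr_edge_list(m)
  v25 <- rnorm(25)
  expect_equal(syn2post_sum(pre2syn_gather(v25, el$pre), el$post, 18),
               csr_matvec(m, v25, TRUE), tolerance = 1e-12)
})

test_that("CSR matrices round-trip through Matrix Market bit-exactly", {
  m <- random_csr(30, 22, 0.15, seed = 13)
  p <- tempfile(fileext = ".mtx")
  csr_write_mtx(m, p)
  m2 <- csr_read_mtx(p)
  expect_identical(m$indices, m2$indices)
  expect_identical(m$indptr, m2$indptr)
  expect_identical(neurodyn:::csr_edge_weights(m),
                   neurodyn:::csr_edge_weights(m2))
  expect_identical(m$shape, m2$shape)
})

test_that("event-driven cost tracks active events, not matrix size", {
  # fixed number of active rows across growing matrices: the event-driven
  # operator's share of the full-matvec cost must shrink monotonically
  sizes <- c(2000L, 8000L, 32000L)
  ratio <- vapply(sizes, function(n) {
    m <- random_csr(n, 500, 0.05, seed = n)
    e <- rep(FALSE, n); e[seq_len(50)] <- TRUE
    v <- as.numeric(e)
    t_ev <- median(vapply(1:5, function(i)
      system.time(event_csr_matvec(m, e, TRUE))[["elapsed"]], numeric(1)))
    t_full <- median(vapply(1:5, function(i)
      system.time(csr_matvec(m, v, TRUE))[["elapsed"]], numeric(1)))
    (t_ev + 1e-5) / (t_full + 1e-5)
  }, numeric(1))
  expect_true(ratio[3] < ratio[1])
  expect_true(all(diff(ratio) <= 0.05))   # monotone up to timer noise
})
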