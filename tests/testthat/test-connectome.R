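test_that("connectome validation accepts minimal input and enforces invariants", {
  cn <- connectome(matrix(c(0, 1, 1, 0), 2), matrix(c(0, 50, 50, 0), 2))
  expect_s3_class(cn, "connectome")
  expect_equal(cn$n, 2)

  w <- matrix(c(0, 1, 1, 0), 2)
  d <- matrix(c(0, 50, 50, 0), 2)
  wneg <- w; wneg[1, 2] <- -0.1
  expect_error(connectome(wneg, d), "negative weight")
  wasym <- w; wasym[1, 2] <- 1 + 1e-6
  expect_error(connectome(wasym, d), "asymmetric")
  expect_error(connectome(w, matrix(0, 3, 3)), "dimension mismatch")
  expect_error(connectome(w, d, labels = "only_one"), "dimension mismatch")
  expect_error(connectome(matrix(0, 2, 2), d), "isolated region")
  wdiag <- w; diag(wdiag) <- 1
  expect_error(connectome(wdiag, d), "nonzero diagonal")
})

test_that("connectome CSV round trip is bitwise exact", {
  conn <- gen_connectome(86, 0.3, seed = 7)
  wp <- tempfile(fileext = ".csv"); dp <- tempfile(fileext = ".csv")
  on.exit(unlink(c(wp, dp)))
  write_connectome(conn, wp, dp)
  back <- load_connectome(wp, dp, cortical_mask = conn$cortical_mask)
  expect_identical(unname(back$weights), unname(conn$weights))
  expect_identical(unname(back$distances), unname(conn$distances))
  expect_identical(back$labels, conn$labels)
})

test_that("degree_normalize matches hand arithmetic and normalizes rows", {
  m <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(degree_normalize(m, "row"), matrix(c(0, 1, 1, 0), 2))
  expect_equal(degree_normalize(m, "symmetric"), matrix(c(0, 1, 1, 0), 2))

  set.seed(3)
  r <- matrix(runif(25, 0.1, 2), 5); r <- r + t(r); diag(r) <- 0
  expect_equal(rowSums(degree_normalize(r, "row")), rep(1, 5),
               tolerance = 1e-12)

  z <- matrix(c(0, 0, 0, 0, 0, 1, 0, 1, 0), 3)
  rownames(z) <- c("isolated", "b", "c")
  expect_error(degree_normalize(z), "isolated")
})

test_that("complex Laplacian has the expected limits and hand-computed phases", {
  conn <- fix_conn3()
  expect_equal(complex_laplacian(conn, v = 10, alpha = 0, f = 10),
               diag(3) + 0i, ignore_attr = TRUE)
  L0 <- complex_laplacian(conn, v = 10, alpha = 0.5, f = 0)
  expect_equal(max(abs(Im(L0))), 0)
  expect_equal(Re(L0), diag(3) - 0.5 * degree_normalize(conn$weights),
               ignore_attr = TRUE)

  # hand computation at f = 10 Hz, v = 10 m/s: delay(j,k) = d/(10000) s,
  # phase = 2 pi 10 d / 10000; entry (1,2): d = 100 mm -> delay 0.01 s,
  # phase 0.2 pi
  L <- complex_laplacian(conn, v = 10, alpha = 0.8, f = 10)
  cn <- degree_normalize(conn$weights)
  expected <- diag(3) - 0.8 * cn *
    exp(-1i * 2 * pi * 10 * conn$distances / (1000 * 10))
  expect_equal(L, expected, tolerance = 1e-12)
  expect_equal(Arg(exp(-1i * 2 * pi * 10 * 100 / 10000)), -0.2 * pi)

  expect_error(complex_laplacian(conn, v = 2, alpha = 0.5, f = 10),
               "outside")
})

test_that("conjugate symmetry: L at -f is the entrywise conjugate of L at f", {
  conn <- fix_conn(8, seed = 5)
  for (f in c(1, 9.5, 27)) {
    expect_equal(complex_laplacian(conn, 12, 0.6, -f),
                 Conj(complex_laplacian(conn, 12, 0.6, f)))
  }
})

test_that("eigensystem sorts, normalizes and reconstructs", {
  es <- eigensystem(diag(4) + 0i)
  expect_equal(es$eigenvalues, rep(1 + 0i, 4))

  conn <- fix_conn(10, seed = 9)
  L <- complex_laplacian(conn, 10, 0.7, 12)
  es <- eigensystem(L, 12)
  expect_equal(colSums(Mod(es$modes)^2), rep(1, 10), tolerance = 1e-12)
  expect_true(all(diff(Mod(es$eigenvalues)) >= -1e-12))
  rec <- es$modes %*% diag(es$eigenvalues) %*% es$modes_inverse
  expect_lt(max(Mod(rec - L)), 1e-8)

  conn86 <- gen_connectome(86, 0.3, seed = 11)
  es86 <- eigensystem(complex_laplacian(conn86, 10, 0.8, 10), 10)
  expect_length(es86$eigenvalues, 86)
  expect_equal(dim(es86$modes), c(86, 86))
})

test_that("Gershgorin bound holds at f = 0 for row normalization", {
  set.seed(21)
  for (i in 1:10) {
    conn <- fix_conn(12, density = runif(1, 0.3, 0.8), seed = 300 + i)
    alpha <- runif(1, 0.1, 1)
    lam <- eigen(complex_laplacian(conn, 10, alpha, 0))$values
    expect_lte(max(Mod(lam - 1)), alpha + 1e-9)
  }
})

test_that("eigendecomposition reconstructs L over random (alpha, v, f) draws", {
  set.seed(33)
  conn <- fix_conn(10, seed = 12)
  for (i in 1:25) {
    L <- complex_laplacian(conn, runif(1, 5, 20), runif(1, 0.1, 1),
                           runif(1, 0, 35))
    es <- eigensystem(L)
    rec <- es$modes %*% diag(es$eigenvalues) %*% es$modes_inverse
    expect_lt(max(Mod(rec - L)), 1e-8)
  }
})
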