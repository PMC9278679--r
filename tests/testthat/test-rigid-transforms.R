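test_that("composed rotation matrices match the single-axis product oracle", {
  expect_equal(compose_rotation_matrix(c(0, 0, 0)), diag(3))
  expect_equal(compose_rotation_matrix(c(0, 90, 0))[1, 3], 1)
  for (ang in list(c(10, 20, 30), c(-3.7, 12.2, 44.9), c(87, -45, 170))) {
    expect_equal(compose_rotation_matrix(ang), oracle_rotation(ang),
                 tolerance = 1e-12)
  }
  expect_error(compose_rotation_matrix(c(1, NA, 0)), "finite")
})

test_that("composed matrices are proper rotations and decomposition round-trips", {
  set.seed(42)
  n <- 500
  ang <- cbind(runif(n, -179, 180), runif(n, -89, 89), runif(n, -179, 180))
  for (i in seq_len(n)) {
    R <- compose_rotation_matrix(ang[i, ])
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_lt(abs(det(R) - 1), 1e-12)
    back <- decompose_rotation_matrix(R)
    expect_lt(max(abs(back - ang[i, ])), 1e-9)
    # recomposition reproduces the matrix
    expect_lt(norm(compose_rotation_matrix(back) %*% t(R) - diag(3), "F"),
              1e-10)
  }
})

test_that("decomposition flags gimbal lock and absorbs yaw into pitch", {
  R <- compose_rotation_matrix(c(25, 90, 10))
  d <- decompose_rotation_matrix(R)
  expect_true(attr(d, "gimbal_lock"))
  expect_equal(unname(d["yaw_deg"]), 0)
  expect_equal(unname(d["roll_deg"]), 90)
  # the absorbed pitch still reproduces the matrix
  expect_lt(max(abs(compose_rotation_matrix(as.numeric(d)) - R)), 1e-10)
  expect_error(decompose_rotation_matrix(matrix(2 * diag(3), 3)),
               "orthonormal|proper")
})

test_that("transform inversion round-trips points", {
  expect_equal(transform_components(invert_transform(rigid_transform())),
               transform_components(rigid_transform()))
  inv <- invert_transform(rigid_transform(translation = c(5, 0, 0)))
  expect_equal(unname(transform_components(inv)), c(-5, 0, 0, 0, 0, 0))
  set.seed(7)
  t <- rigid_transform(translation = runif(3, -20, 20),
                       angles = runif(3, -30, 30),
                       center = c(12, -4, 8))
  p <- matrix(runif(300, -100, 100), ncol = 3)
  back <- apply_transform(invert_transform(t), apply_transform(t, p))
  expect_lt(max(abs(back - p)), 1e-9)
})

test_that("transform differences follow the estimate-minus-expected convention", {
  t <- rigid_transform(translation = c(3, -1, 2), angles = c(1, 2, -1),
                       center = c(5, 5, 5))
  expect_equal(unname(transform_difference(t, t)), rep(0, 6))
  d <- transform_difference(rigid_transform(translation = c(10, 0, 0)),
                            rigid_transform(translation = c(9.5, 0, 0)))
  expect_equal(unname(d), c(-0.5, 0, 0, 0, 0, 0))
  # matrix-composition oracle on random pairs
  set.seed(11)
  for (i in 1:20) {
    ctr <- runif(3, -10, 10)
    a <- rigid_transform(runif(3, -5, 5), runif(3, -4, 4), center = ctr)
    b <- rigid_transform(runif(3, -5, 5), runif(3, -4, 4), center = ctr)
    d <- transform_difference(a, b)
    Ra <- compose_rotation_matrix(a$angles)
    Rb <- compose_rotation_matrix(b$angles)
    expect_equal(unname(d[4:6]),
                 unname(as.numeric(decompose_rotation_matrix(Rb %*% t(Ra)))),
                 tolerance = 1e-9)
    expect_equal(unname(d[1:3]),
                 as.numeric(b$translation - Rb %*% t(Ra) %*% a$translation),
                 tolerance = 1e-9)
  }
  expect_error(transform_difference(
    rigid_transform(center = c(0, 0, 0)),
    rigid_transform(center = c(1, 0, 0))), "center")
})

test_that("homogeneous matrix export matches point mapping", {
  t <- rigid_transform(translation = c(2, -3, 1), angles = c(4, -5, 6),
                       center = c(10, 20, -5))
  H <- transform_to_matrix(t)
  p <- c(7, -2, 13)
  expect_equal(as.numeric(H %*% c(p, 1))[1:3], apply_transform(t, p),
               tolerance = 1e-12)
})

test_that("JSON serialization round-trips transforms", {
  t <- rigid_transform(translation = c(1.25, -0.5, 3), angles = c(0.2, -4.9, 2),
                       center = c(80, 80, 80))
  t2 <- transform_from_json(transform_to_json(t))
  expect_equal(transform_components(t2), transform_components(t),
               tolerance = 1e-12)
  expect_equal(t2$center, t$center, tolerance = 1e-12)
  f <- withr::local_tempfile(fileext = ".json")
  transform_to_json(t, f)
  expect_equal(transform_components(transform_from_json(f)),
               transform_components(t), tolerance = 1e-12)
})
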