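# Conventional per-offset engine: each pass against the reference module,
# full-run equivalence, counter exactness, and chunking independence.

test_that("difference pass equals a direct array shift", {
  params <- nlm_params(T = 2, B = 0, h = 10)
  ramp <- matrix(rep(0:3, each = 4), 4, 4)   # constant along rows? no: by col
  U1 <- diff_pass(ramp, c(1, 0), params)
  # B = 0: plane is exactly m x n; interior columns differ by the ramp step
  direct <- ramp - ramp[, c(2:4, 4)]         # mirror duplicates last column
  expect_equal(unclass(U1), direct, ignore_attr = TRUE)

  expect_true(all(diff_pass(ramp, c(0, 0), params) == 0))
  expect_true(all(diff_pass(matrix(9, 5, 5), c(2, -1),
                            nlm_params(T = 2, B = 1, h = 10)) == 0))
  expect_error(diff_pass(ramp, c(3, 0), params), "search radius")
})

test_that("weight pass reproduces reference weights per pixel", {
  img <- rand_image(6, 6, seed = 20)
  params <- nlm_params(T = 3, B = 1, h = 10)
  off <- c(2L, 1L)
  U2 <- weight_pass(img, off, params)
  padded <- pad_symmetric(img, params$B)
  kernel <- gaussian_kernel(params$B)
  for (py in 0:5) {
    for (px in 0:5) {
      qx <- px + off[1]; qy <- py + off[2]
      expected <- if (qx < 0 || qx >= 6 || qy < 0 || qy >= 6) 0 else
        nlm_weight(patch_distance(padded, c(px, py), c(qx, qy),
                                  params$B, kernel), params$h, params$B)
      expect_equal(U2[py + 1, px + 1], expected, tolerance = 1e-12)
    }
  }
})

test_that("weight pass markers: self offset all ones, constant image ones-in-bounds", {
  img <- rand_image(5, 5, seed = 21)
  params <- nlm_params(T = 2, B = 1, h = 10)
  expect_true(all(weight_pass(img, c(0, 0), params) == 1))

  const <- matrix(4, 5, 5)
  U2 <- weight_pass(const, c(2, -1), params)
  expect_true(all(U2[2:5, 1:3] == 1))      # partners in bounds
  expect_true(all(U2[1, ] == 0))           # p_y - 1 < 0
  expect_true(all(U2[, 4:5] == 0))         # p_x + 2 >= 5
})

test_that("accumulation tracks hand-accumulated reference sums", {
  img <- rand_image(4, 4, seed = 22)
  params <- nlm_params(T = 1, B = 1, h = 10)
  state <- pass_state(4, 4)

  # self offset then (1, 0), accumulated by hand from the weight pass
  offsets <- list(c(0L, 0L), c(1L, 0L))
  U3_hand <- matrix(0, 4, 4); U4_hand <- matrix(0, 4, 4)
  for (off in offsets) {
    state$U2 <- weight_pass(img, off, params)
    accumulate_pass(state, img, off)
    U3_hand <- U3_hand + state$U2
    Yq <- matrix(0, 4, 4)
    for (py in 0:3) for (px in 0:3) {
      qx <- px + off[1]; qy <- py + off[2]
      if (qx >= 0 && qx < 4 && qy >= 0 && qy < 4)
        Yq[py + 1, px + 1] <- state$U2[py + 1, px + 1] * img[qy + 1, qx + 1]
    }
    U4_hand <- U4_hand + Yq
  }
  expect_equal(state$U3, U3_hand, tolerance = 1e-14)
  expect_equal(state$U4, U4_hand, tolerance = 1e-14)

  # zero weights leave the state unchanged
  before <- list(U3 = state$U3, U4 = state$U4)
  state$U2 <- matrix(0, 4, 4)
  accumulate_pass(state, img, c(1L, 1L))
  expect_identical(state$U3, before$U3)
  expect_identical(state$U4, before$U4)
})

test_that("finalize divides the planes and enforces positive weight sums", {
  img <- rand_image(3, 3, seed = 23)
  st <- pass_state(3, 3)
  st$U3 <- matrix(1, 3, 3); st$U4 <- img
  expect_identical(finalize_state(st), img)
  st$U3 <- matrix(2, 3, 3); st$U4 <- 2 * img
  expect_equal(finalize_state(st), img)
  st$U3[2, 2] <- 0
  expect_error(finalize_state(st), "invariant")
})

test_that("full conventional run equals the naive oracle", {
  img <- rand_image(8, 8, seed = 24)
  params <- nlm_params(T = 2, B = 1, h = 10)
  expect_lt(max_rel_diff(nlm_filter_naive(img, params),
                         nlm_filter_conventional(img, params)), 1e-10)

  const <- matrix(5, 6, 6)
  expect_equal(nlm_filter_conventional(const, params), const)
  expect_equal(nlm_filter_conventional(img, nlm_params(T = 0, B = 1, h = 10)),
               img)
})

test_that("charged counts equal the closed form for every (T, B) tested", {
  img <- rand_image(5, 5, seed = 25)
  for (T in 0:2) {
    for (B in 0:2) {
      ctr <- op_counter()
      nlm_filter_conventional(img, nlm_params(T = T, B = B, h = 10), ctr)
      expect_identical(ctr$charged, conventional_complexity(T, B))
      expect_identical(ctr$passes, (2 * T + 1)^2)
    }
  }
})

test_that("state planes conserve the reference weight sums", {
  img <- rand_image(6, 6, seed = 26)
  params <- nlm_params(T = 2, B = 1, h = 10)
  kernel <- gaussian_kernel(params$B)
  padded <- pad_symmetric(img, params$B)
  offs <- enumerate_offsets(params$T, "full")
  state <- pass_state(6, 6)
  for (k in seq_len(nrow(offs))) {
    state$U2 <- weight_pass(img, offs[k, ], params, kernel = kernel)
    accumulate_pass(state, img, offs[k, ])
  }
  for (py in 0:5) {
    for (px in 0:5) {
      ws <- 0
      for (k in seq_len(nrow(offs))) {
        qx <- px + offs[k, 1]; qy <- py + offs[k, 2]
        if (qx < 0 || qx >= 6 || qy < 0 || qy >= 6) next
        ws <- ws + nlm_weight(patch_distance(padded, c(px, py), c(qx, qy),
                                             params$B, kernel),
                              params$h, params$B)
      }
      expect_equal(state$U3[py + 1, px + 1], ws, tolerance = 1e-12)
    }
  }
})

test_that("accumulating the offset list in chunks changes nothing", {
  img <- rand_image(7, 7, seed = 27)
  params <- nlm_params(T = 2, B = 1, h = 10)
  kernel <- gaussian_kernel(params$B)
  offs <- enumerate_offsets(params$T, "full")

  run_chunked <- function(chunks) {
    state <- pass_state(7, 7)
    for (idx in chunks) {
      for (k in idx) {
        state$U2 <- weight_pass(img, offs[k, ], params, kernel = kernel)
        accumulate_pass(state, img, offs[k, ])
      }
    }
    finalize_state(state)
  }
  n_off <- nrow(offs)
  whole <- run_chunked(list(seq_len(n_off)))
  # contiguous chunks: the fixed row-major accumulation order is preserved,
  # so the result must be bit-identical
  split3 <- run_chunked(unname(split(seq_len(n_off),
                                     rep(1:3, each = ceiling(n_off / 3),
                                         length.out = n_off))))
  expect_identical(whole, split3)
})
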