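# Kernel-schedule planning, parameter accounting and the assembled module's
# forward contract.

test_that("plan_schedule reproduces the four reference schedules and degenerate cases", {
  expect_equal(plan_schedule(7, 9, 5)$layers, list(c(5L, 5L), c(3L, 5L)))
  expect_equal(plan_schedule(7, 9, 5)$feature_maps,
               list(c(3L, 5L), c(1L, 1L)))
  expect_equal(plan_schedule(7, 7, 5)$layers, list(c(5L, 5L), c(3L, 3L)))
  expect_equal(plan_schedule(7, 9, 3)$layers,
               list(c(3L, 3L), c(3L, 3L), c(3L, 3L), c(1L, 3L)))
  expect_equal(plan_schedule(7, 9, 3)$feature_maps,
               list(c(5L, 7L), c(3L, 5L), c(1L, 3L), c(1L, 1L)))
  expect_equal(plan_schedule(7, 7, 3)$layers,
               list(c(3L, 3L), c(3L, 3L), c(3L, 3L)))
  expect_equal(plan_schedule(1, 1, 5)$layers, list(c(1L, 1L)))
  expect_error(plan_schedule(0, 3), class = "eegtrm_domain_error")
  expect_error(plan_schedule(3, 3, 4), class = "eegtrm_domain_error")
  expect_warning(plan_schedule(9, 9, 7), "nonstandard")
})

test_that("schedules terminate at 1x1 and obey valid-convolution arithmetic on all small grids", {
  for (k in c(3L, 5L)) for (H in 1:32) for (W in 1:32) {
    s <- plan_schedule(H, W, k)
    h <- H; w <- W
    for (i in seq_along(s$layers)) {
      kern <- s$layers[[i]]
      # kernel selection rule, checked independently
      if (h > k || w > k) expect_identical(kern, c(min(k, h), min(k, w)))
      else expect_identical(kern, c(h, w))
      expect_true(kern[1] >= 1 && kern[1] <= h && kern[2] >= 1 && kern[2] <= w)
      h <- h - kern[1] + 1L; w <- w - kern[2] + 1L   # valid-conv arithmetic
      expect_identical(s$feature_maps[[i]], c(h, w))
    }
    expect_identical(s$feature_maps[[length(s$layers)]], c(1L, 1L))
  }
})

test_that("closed-form parameter counts match brute-force enumeration and the reference totals", {
  m9 <- load_montage("ebdsdd-7x9")
  m7 <- load_montage("hgd-7x7")
  ref <- list(list(m9, 5L, 46860L), list(m7, 5L, 18612L),
              list(m9, 3L, 64130L), list(m7, 3L, 35332L))
  for (r in ref) {
    spec <- trm_spec(r[[1]], r[[2]])
    trm <- build_trm(r[[1]], r[[2]])
    expect_identical(count_parameters(spec), r[[3]])
    expect_identical(count_parameters(trm), r[[3]])   # enumeration route
  }
  # degenerate: C = 1 on a 1x1 grid -> 1 weight + affine norm scale/shift
  m1 <- montage_grid("solo", 1, 1, cbind(0, 0))
  expect_identical(count_parameters(build_trm(m1, 5)), 3L)
  # random instances: closed form == enumeration under every policy
  for (i in 1:20) {
    set.seed(i)
    H <- sample(1:9, 1); W <- sample(1:9, 1)
    C <- sample(seq_len(H * W), 1)
    k <- sample(c(3L, 5L), 1)
    m <- make_random_montage(C, H, W, seed = i + 100)
    for (bias in c(FALSE, TRUE))
      for (np in c("final-affine", "per-layer-affine", "none")) {
        spec <- trm_spec(m, k, conv_bias = bias, norm_policy = np)
        expect_identical(count_parameters(build_trm(m, k, conv_bias = bias,
                                                    norm_policy = np)),
                         count_parameters(spec))
      }
  }
})

test_that("the TRM preserves input shape across batch sizes and epoch lengths", {
  m9 <- load_montage("ebdsdd-7x9")
  trm5 <- build_trm(m9, 5)
  for (b in c(1L, 7L)) for (TP in c(1L, 50L, 280L)) {
    x <- rand_arr(b, 55, TP)
    expect_equal(dim(trm_forward(trm5, x, training = TRUE)), c(b, 55, TP))
  }
  m <- make_random_montage(5, 4, 6, seed = 3)
  trm3 <- build_trm(m, 3)
  for (b in c(1L, 7L)) for (TP in c(1L, 50L)) {
    x <- rand_arr(b, 5, TP)
    expect_equal(dim(trm_forward(trm3, x, training = TRUE)), c(b, 5, TP))
  }
  expect_error(trm_forward(trm5, rand_arr(2, 44, 50)),
               class = "eegtrm_shape_error")
})

test_that("zeroed convolution weights with normalization off give identically zero output", {
  m <- make_random_montage(6, 3, 4, seed = 4)
  trm <- build_trm(m, 3, norm_policy = "none")
  L <- trm$layers[[1]]
  p <- L$params()
  L$set_params(lapply(p, function(w) w * 0))
  y <- trm_forward(trm, rand_arr(3, 6, 11))
  expect_identical(unname(as.vector(y)), rep(0, 3 * 6 * 11))
})

test_that("the TRM is equivariant to permutations of time points", {
  m <- make_random_montage(7, 3, 4, seed = 5)
  trm <- build_trm(m, 3, seed = 9)
  set.seed(10)
  x <- rand_arr(4, 7, 13)
  perm <- sample(13)
  y <- trm_forward(trm, x, training = TRUE)
  y_perm <- trm_forward(trm, x[, , perm, drop = FALSE], training = TRUE)
  expect_equal(y_perm, y[, , perm, drop = FALSE], tolerance = 1e-12)
})

test_that("identical seeds give bit-identical modules; different seeds differ", {
  m <- load_montage("hgd-7x7")
  a <- build_trm(m, 5, seed = 42)
  b <- build_trm(m, 5, seed = 42)
  expect_identical(a$layers[[1]]$params(), b$layers[[1]]$params())
  d <- build_trm(m, 5, seed = 43)
  expect_false(identical(a$layers[[1]]$params(), d$layers[[1]]$params()))
  x <- rand_arr(2, 44, 20)
  expect_identical(trm_forward(a, x), trm_forward(b, x))
})

test_that("embedding composes with backbones without touching their parameters", {
  m7 <- load_montage("hgd-7x7")
  bb <- build_backbone("compact", 44, 128, 4, seed = 1)
  bb_count <- count_parameters(bb)
  trm <- build_trm(m7, 5, seed = 2)
  net <- embed(trm, bb)
  expect_equal(count_parameters(net), bb_count + count_parameters(trm))
  expect_identical(count_parameters(bb), bb_count)
  sc <- network_forward(net, rand_arr(3, 44, 128))
  expect_equal(dim(sc), c(3, 4))
  # contract violation: montage channel count != backbone input channels
  m9 <- load_montage("ebdsdd-7x9")
  expect_error(embed(build_trm(m9, 5), bb),
               class = "eegtrm_composition_error")
})

test_that("gradients reach the TRM's first-layer kernels during joint training", {
  m <- make_random_montage(6, 3, 4, seed = 6)
  bb <- build_backbone("shallow", 6, 100, 2, seed = 3)
  net <- embed(build_trm(m, 3, seed = 4), bb)
  set.seed(11)
  x <- rand_arr(4, 6, 100)
  y <- c(1L, 2L, 1L, 2L)
  sc <- network_forward(net, x, training = TRUE)
  l <- eegtrm:::softmax_xent(t(sc), y)
  eegtrm:::network_backward(net, t(l$grad))
  g1 <- net$layers[[1]]$inner[[1]]$grads()$W
  expect_gt(max(abs(g1)), 0)
})
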