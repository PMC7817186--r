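test_that("signed distance targets match the spec'd examples exactly", {
  dm <- c(7, 7, 7)
  eff <- array(FALSE, dm)
  eff[4, 4, 4] <- TRUE
  y <- build_signed_distance_target(cell_mask_pair(eff, array(FALSE, dm)))
  expect_equal(y$values[4, 4, 4], 1)
  expect_equal(sum(y$values != 0), 1)

  cube <- array(FALSE, dm)
  cube[3:5, 3:5, 3:5] <- TRUE
  y2 <- build_signed_distance_target(cell_mask_pair(cube, array(FALSE, dm)))
  expect_equal(y2$values[4, 4, 4], 2)
  expect_equal(y2$values[3, 4, 4], 1)

  # swapping the cells negates the map exactly
  tar <- array(FALSE, dm)
  tar[5:6, 2:3, 2:3] <- TRUE
  eff2 <- array(FALSE, dm)
  eff2[1:2, 5:6, 5:6] <- TRUE
  ya <- build_signed_distance_target(cell_mask_pair(eff2, tar))
  yb <- build_signed_distance_target(cell_mask_pair(tar, eff2))
  expect_identical(ya$values, -yb$values)
})

test_that("signed distances agree with the exhaustive oracle on random masks", {
  set.seed(31)
  for (rep in 1:20) {
    dm <- sample(5:12, 3, replace = TRUE)
    eff <- random_blob(dm, n_balls = 2, seed = 100 + rep)
    tar <- random_blob(dm, n_balls = 2, seed = 200 + rep) & !eff
    y <- build_signed_distance_target(cell_mask_pair(eff, tar))
    expect_identical(y$values, brute_force_signed(eff, tar))
  }
})

test_that("boundary-weighted L1 matches hand enumeration and its limits", {
  dm <- c(5, 5, 5)
  eff <- array(FALSE, dm)
  eff[2:4, 2:4, 2:4] <- TRUE
  yt <- build_signed_distance_target(cell_mask_pair(eff, array(FALSE, dm)))

  expect_equal(boundary_weighted_l1(yt, yt), 0)

  # w_b = 0 reduces to plain L1
  yp <- yt
  yp$values <- yt$values + 1
  expect_equal(boundary_weighted_l1(yp, yt, loss_config(w_b = 0)), 1)

  # brute-force enumeration of the weighted sum on the 5^3 grid
  cfg <- loss_config(w_b = 9, sigma_b = 1)
  fg <- yt$values != 0
  surf <- fg & !istomo:::binary_erode(fg, istomo:::cross_offsets(1L))
  db <- brute_force_edt(!surf)  # distance of every voxel to the surface set
  db[surf] <- 0
  w <- 1 + 9 * exp(-db^2 / 2)
  set.seed(4)
  ypv <- yt$values + array(rnorm(prod(dm)), dm)
  expect_equal(boundary_weighted_l1(ypv, yt$values, cfg),
               mean(w * abs(ypv - yt$values)), tolerance = 1e-12)

  expect_error(boundary_weighted_l1(array(0, c(4, 4, 4)), yt$values),
               class = "istomo_shape_error")
  # non-negative, zero iff equal
  expect_gt(boundary_weighted_l1(ypv, yt$values, cfg), 0)
})

test_that("network configuration validates shapes and the full-scale recipe", {
  cfg <- network_config(levels = 3, filters = c(8, 16, 32),
                        gcn_kernels = c(7, 5, 3), patch = c(32, 32, 32))
  expect_s3_class(cfg, "network_config")
  # the full-scale recipe (5 levels, 32..512 filters, GCN k 13,13,9,7,5)
  full <- network_config_full()
  expect_equal(full$filters, c(32L, 64L, 128L, 256L, 512L))
  expect_equal(full$gcn_kernels, c(13L, 13L, 9L, 7L, 5L))
  expect_error(network_config(levels = 3, filters = c(8, 16),
                              gcn_kernels = c(7, 5, 3)),
               class = "istomo_config_error")
  expect_error(network_config(gcn_kernels = c(8, 5, 3)),
               class = "istomo_config_error")
  expect_error(network_config(patch = c(30, 32, 32)),
               class = "istomo_shape_error")
})

test_that("the network honours its shape contract and parameter accounting", {
  cfg <- network_config(levels = 3, filters = c(4, 8, 16),
                        gcn_kernels = c(7, 5, 3), patch = c(16, 16, 16))
  model <- build_network(cfg, seed = 2)
  x <- array(rnorm(16^3), c(16, 16, 16, 1))
  y <- istomo:::net_forward(model, x)$y
  expect_identical(dim(y), c(16L, 16L, 16L, 1L))

  # analytic parameter count: conv w + b per layer
  f <- c(4, 8, 16)
  k <- c(7, 5, 3)
  cnt <- function(kk, cin, cout) prod(kk) * cin * cout + cout
  expected <- cnt(c(3, 3, 3), 1, f[1]) +                      # enc_in
    sum(vapply(1:3, function(i) 2 * cnt(c(3, 3, 3), f[i], f[i]),
               numeric(1))) +                                 # enc resblocks
    cnt(c(3, 3, 3), f[1], f[2]) + cnt(c(3, 3, 3), f[2], f[3]) + # down
    sum(vapply(1:2, function(i)
      cnt(c(k[i], 1, 1), f[i], f[i]) + cnt(c(1, k[i], 1), f[i], f[i]) +
        cnt(c(1, 1, k[i]), f[i], f[i]), numeric(1))) +        # gcn skips
    cnt(c(3, 3, 3), f[2], f[1]) + cnt(c(3, 3, 3), f[3], f[2]) + # up
    sum(vapply(1:2, function(i) 2 * cnt(c(3, 3, 3), f[i], f[i]),
               numeric(1))) +                                 # dec resblocks
    cnt(c(1, 1, 1), f[1], 1)                                  # output
  expect_equal(count_parameters(model), expected)
})

test_that("augmentation is seeded, paired, and count-preserving", {
  tr <- make_conjugate(equal_spheres_spec(grid = 24L, radius = 1100))
  # all transforms disabled: identity
  a0 <- augment(tr$tom, tr$distmap, seed = 5, rotations = FALSE,
                reflections = FALSE)
  expect_identical(a0$tom$values, tr$tom$values)
  expect_identical(a0$y_true$values, tr$distmap$values)

  a1 <- augment(tr$tom, tr$distmap, seed = 9)
  a2 <- augment(tr$tom, tr$distmap, seed = 9)
  expect_identical(a1$tom$values, a2$tom$values)
  expect_identical(a1$y_true$values, a2$y_true$values)

  # right-angle lateral rotations permute voxels: counts preserved exactly
  expect_equal(sum(a1$y_true$values > 0), sum(tr$distmap$values > 0))
  expect_equal(sum(a1$y_true$values < 0), sum(tr$distmap$values < 0))

  # elastic deformation recomputes distances from the warped masks
  ae <- augment(tr$tom, tr$distmap, seed = 3, rotations = FALSE,
                reflections = FALSE, elastic = TRUE)
  eff <- ae$y_true$values > 0
  tar <- ae$y_true$values < 0
  expect_identical(ae$y_true$values, brute_force_signed(eff, tar))

  expect_error(augment(tr$tom, tr$distmap, seed = 1,
                       crop_shape = c(64, 64, 64)),
               class = "istomo_shape_error")
})

test_that("training reduces the loss and early stopping obeys its contract", {
  cfg <- network_config(levels = 2, filters = c(4, 8), gcn_kernels = c(5, 3),
                        patch = c(16, 16, 16))
  dataset <- lapply(1:6, function(i)
    make_conjugate(istomo:::toy_phantom_spec(16L, 300 + i)))
  tc <- train_config(max_epochs = 8L, val_fraction = 1 / 3, augment = FALSE,
                     seed = 2)
  model <- train_distnet(dataset, cfg, tc)
  expect_lt(model$history$val[model$history$best_epoch],
            model$history$val[1] + 1e-12)
  expect_lte(model$history$epochs_run, 8L)

  # frozen optimizer (negligible learning rate): a validation plateau stops
  # training after exactly `patience` non-improving epochs
  tc2 <- train_config(max_epochs = 50L, patience = 3L, augment = FALSE,
                      learning_rate = 1e-15, seed = 2)
  m2 <- train_distnet(dataset, cfg, tc2)
  expect_equal(m2$history$epochs_run, 1L + 3L)
})

test_that("inference is deterministic and tiling is exact", {
  cfg <- network_config(levels = 2, filters = c(4, 6), gcn_kernels = c(5, 3),
                        patch = c(16, 16, 16))
  model <- build_network(cfg, seed = 4)
  tr <- make_conjugate(equal_spheres_spec(grid = 24L, radius = 1100))
  s1 <- infer_distnet(model, tr$tom)
  s2 <- infer_distnet(model, tr$tom)
  expect_identical(s1$values, s2$values)

  tiled <- infer_distnet(model, tr$tom, tiled = TRUE)
  untiled <- infer_distnet(model, tr$tom, tiled = FALSE)
  expect_lt(max(abs(tiled$values - untiled$values)), 1e-4)
  expect_identical(dim(s1$values), dim(tr$tom$values))
})

test_that("sign symmetry: swapped-label training yields the negated model", {
  # Swapping the cell identities negates every target; starting the swapped
  # run from the sign-flipped output layer, the two optimization
  # trajectories are exact mirrors, so the trained predictors must be exact
  # negatives of each other. This exercises the full forward/backward/Adam
  # symmetry.
  cfg <- network_config(levels = 2, filters = c(4, 8), gcn_kernels = c(5, 3),
                        patch = c(16, 16, 16))
  dataset <- lapply(1:6, function(i)
    make_conjugate(istomo:::toy_phantom_spec(16L, 500 + i)))
  swapped <- lapply(dataset, function(tr) {
    y <- tr$distmap
    y$values <- -y$values
    list(tom = tr$tom, target = y)
  })
  tc <- train_config(max_epochs = 4L, val_fraction = 1 / 3, augment = FALSE,
                     seed = 3)
  init <- build_network(cfg, seed = 3)
  init_neg <- init
  init_neg$params$out$w <- -init_neg$params$out$w
  init_neg$params$out$b <- -init_neg$params$out$b
  m_fwd <- train_distnet(dataset, cfg, tc, init_model = init)
  m_swp <- train_distnet(swapped, cfg, tc, init_model = init_neg)
  probe <- make_conjugate(istomo:::toy_phantom_spec(16L, 700))
  pf <- infer_distnet(m_fwd, probe$tom)$values
  ps <- infer_distnet(m_swp, probe$tom)$values
  expect_lt(max(abs(pf + ps)), 1e-8)
})
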