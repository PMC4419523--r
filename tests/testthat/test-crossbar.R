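test_that("crossbar initializes at mid-conductance with 192 cells", {
  xb <- init_crossbar()
  expect_equal(dim(xb$G), c(6, 32))
  expect_equal(length(xb$G), 192)
  expect_true(all(xb$G == 3.5))
  expect_error(init_crossbar(learning_config(init_g = 9.9)), "bounds")
})

test_that("line-voltage invariants of the configs are enforced", {
  expect_error(init_crossbar(learning_config(v_cm = 1.5)), "V_CM")
  expect_error(init_crossbar(learning_config(v_h = 3.5, v_l = 3)), "exceed")
})

test_that("potentiation bias reproduces the worked 4x2 assignment", {
  cfg <- toy_config()
  b <- assign_potentiation_bias(c(1, 0), c(1, 0, 1, 1), cfg)
  expect_equal(b$te, c(3, 4))
  expect_equal(b$be, c(5, 4, 5, 5))
  # targeted cell: be - te = 5 - 3 = 2 V
  expect_equal(b$be[1] - b$te[1], 2)
  # all-zero code: no column at V_H, no cell above 1 V
  b0 <- assign_potentiation_bias(c(1, 0), c(0, 0, 0, 0), cfg)
  V <- outer(-b0$te, b0$be, `+`)
  expect_true(all(abs(V) <= 1))
})

test_that("depression bias matches both targeting schemes on the 4x2 toy", {
  cfg_r <- toy_config(depress_scheme = "rival_active")
  b <- assign_depression_bias(c(1, 0), c(1, 0, 1, 1), cfg_r)
  expect_equal(b$te, c(4, 5))
  expect_equal(b$be, c(3, 4, 3, 3))
  V <- outer(-b$te, b$be, `+`)             # be - te per cell
  expect_true(all(V[2, c(1, 3, 4)] == -2)) # depressed cells, 2 V reversed
  expect_true(all(abs(V[1, ]) <= 1))       # desired row untouched
  cfg_d <- toy_config()                    # desired_inactive default
  b2 <- assign_depression_bias(c(1, 0), c(1, 0, 1, 1), cfg_d)
  V2 <- outer(-b2$te, b2$be, `+`)
  expect_equal(V2[1, ], c(-1, -2, -1, -1)) # labelled row depressed at bit 0
  expect_true(all(abs(V2[2, ]) <= 1))
})

test_that("half-select safety holds exhaustively on the toy and at full size", {
  cfg <- toy_config()
  labels <- list(c(1, 0), c(0, 1), c(1, 1), c(0, 0))
  codes <- expand.grid(rep(list(0:1), 4))
  for (lab in labels) for (i in seq_len(nrow(codes))) {
    bits <- as.integer(codes[i, ])
    bp <- assign_potentiation_bias(lab, bits, cfg)
    Vp <- outer(-bp$te, bp$be, `+`)
    target <- outer(lab == 1, bits == 1, `&`)
    expect_true(all(Vp[target] == 2))
    expect_true(all(abs(Vp[!target]) <= 1))
    bd <- assign_depression_bias(lab, bits, cfg)   # desired_inactive
    Vd <- outer(-bd$te, bd$be, `+`)
    targd <- outer(lab == 1, bits == 0, `&`)
    expect_true(all(Vd[targd] == -2))
    expect_true(all(abs(Vd[!targd]) <= 1))
  }
  # randomized assertion at 32 x 6
  cfg6 <- learning_config()
  set.seed(21)
  for (rep in 1:20) {
    lab <- label_vector(sample(c("a", "i", "u"), 1))
    bits <- rbinom(32, 1, 0.5)
    bp <- assign_potentiation_bias(lab, bits, cfg6)
    Vp <- outer(-bp$te, bp$be, `+`)
    target <- outer(lab == 1, bits == 1, `&`)
    expect_true(all(Vp[target] == 2) && all(abs(Vp[!target]) <= 1))
    bd <- assign_depression_bias(lab, bits, cfg6, scheme = "rival_active")
    Vd <- outer(-bd$te, bd$be, `+`)
    targd <- outer((1L - lab) == 1, bits == 1, `&`)
    expect_true(all(Vd[targd] == -2) && all(abs(Vd[!targd]) <= 1))
  }
})

test_that("applying a bias updates exactly the targeted cells", {
  xb <- toy_crossbar()
  b <- assign_potentiation_bias(c(1, 0), c(1, 0, 1, 1), xb$config)
  xb2 <- apply_bias(xb, b, 1)
  changed <- xb2$G != xb$G
  expect_equal(which(changed), which(outer(c(TRUE, FALSE), c(1, 0, 1, 1) == 1, `&`)))
  expect_true(all(xb2$G[changed] > xb$G[changed]))
  # all lines at common mode: nothing moves
  cm <- structure(list(te = rep(4, 2), be = rep(4, 4), phase = "potentiation"),
                  class = "bias_pattern")
  expect_identical(apply_bias(xb, cm, 5)$G, xb$G)
})

test_that("matrix update agrees with the single-device rule cell by cell", {
  xb <- init_crossbar()
  set.seed(8)
  xb$G <- matrix(runif(192, 1.5, 5.5), 6, 32)
  b <- assign_potentiation_bias(label_vector("i"), rbinom(32, 1, 0.5), xb$config)
  xb2 <- apply_bias(xb, b, 1)
  V <- outer(-b$te, b$be, `+`)
  for (r in 1:6) for (c in sample(32, 8)) {
    s <- apply_pulse(synapse_state(xb$G[r, c], xb$params), xb$params, V[r, c])
    expect_equal(xb2$G[r, c], s$g)
  }
})

test_that("row currents sum active-bit conductances", {
  xb <- init_crossbar()
  bits16 <- rep(c(1, 0), 16)
  expect_equal(row_currents(xb, bits16), rep(56, 6))
  expect_equal(row_currents(xb, rep(0, 32)), rep(0, 6))
  one <- rep(0, 32); one[5] <- 1
  xb$G[3, 5] <- 2.2
  expect_equal(row_currents(xb, one)[3], 2.2)
  expect_error(row_currents(xb, bits16, v_read = 2), "read regime")
})

test_that("training is deterministic and reaches a trained state", {
  set.seed(42)
  d <- gen_codes(code_gen_config(seed = 42))
  set.seed(42); f1 <- memhnn(d$train)
  set.seed(42); f2 <- memhnn(d$train)
  expect_identical(coef(f1), coef(f2))
  expect_equal(mean(f1$fitted == f1$classes), 1)
  expect_lte(f1$epochs_run, f1$config$epochs)
  # one epoch over one code equals the two explicit phases
  xb <- init_crossbar()
  cd <- d$train[[1]]
  lab <- label_vector(cd$class); riv <- rival_vector(cd$class)
  cfg <- xb$config
  manual <- apply_bias(xb, assign_potentiation_bias(lab, cd$bits, cfg), 1)
  manual <- apply_bias(manual,
                       assign_depression_bias(lab, cd$bits, cfg), 1)
  via_train <- memhnn:::present_code(xb, cd$bits, lab, riv, cfg)
  expect_identical(via_train$G, manual$G)
  expect_error(train_crossbar(xb, list(cd$bits), NA_character_), "unlabeled")
})

test_that("untouched rows are bit-identical across a phase with disturb off", {
  set.seed(4)
  xb <- init_crossbar()
  xb$G <- matrix(runif(192, 1.5, 5.5), 6, 32)
  lab <- label_vector("a")
  bits <- rbinom(32, 1, 0.5)
  xb2 <- apply_bias(xb, assign_potentiation_bias(lab, bits, xb$config), 1)
  expect_identical(xb2$G[lab == 0, ], xb$G[lab == 0, ])
})
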