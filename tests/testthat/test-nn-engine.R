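# Finite-difference checks of every differentiable primitive the networks are
# built from. These are the foundation the training results rest on.

ngrad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

tape <- endostitch:::nn_tape
node <- endostitch:::nn_node
const <- endostitch:::nn_const
backward <- endostitch:::nn_backward
l1 <- endostitch:::nn_l1

test_that("convolution, pooling and deconvolution gradients match finite differences", {
  set.seed(11)
  x <- array(rnorm(6 * 8 * 2), c(6, 8, 2))
  W3 <- array(rnorm(18 * 3, sd = 0.3), c(18, 3))
  b3 <- rnorm(3)
  run <- function(xx, WW, bb) {
    tp <- tape()
    xn <- node(tp, xx, name = "x")
    wn <- node(tp, WW, name = "w")
    bn <- node(tp, bb, name = "b")
    loss <- l1(tp, endostitch:::nn_conv3(tp, xn, wn, bn), array(0, c(6, 8, 3)))
    backward(tp, loss)
    list(v = loss$val, gx = xn$grad, gw = wn$grad, gb = bn$grad)
  }
  r <- run(x, W3, b3)
  expect_lt(max(abs(ngrad(function(v) run(v, W3, b3)$v, x) - r$gx)), 1e-7)
  expect_lt(max(abs(ngrad(function(v) run(x, v, b3)$v, W3) - r$gw)), 1e-7)
  expect_lt(max(abs(ngrad(function(v) run(x, W3, v)$v, b3) - r$gb)), 1e-7)

  runp <- function(xx) {
    tp <- tape()
    xn <- node(tp, xx, name = "x")
    loss <- l1(tp, endostitch:::nn_pool2(tp, xn), array(0, c(3, 4, 2)))
    backward(tp, loss)
    list(v = loss$val, gx = xn$grad)
  }
  rp <- runp(x)
  expect_lt(max(abs(ngrad(function(v) runp(v)$v, x) - rp$gx)), 1e-7)

  Wd <- array(rnorm(2 * 2 * 2 * 3, sd = 0.3), c(2, 2, 2, 3))
  bd <- rnorm(3)
  rund <- function(xx, WW) {
    tp <- tape()
    xn <- node(tp, xx, name = "x")
    wn <- node(tp, WW, name = "w")
    loss <- l1(tp, endostitch:::nn_deconv2(tp, xn, wn, const(tp, bd)),
               array(0, c(12, 16, 3)))
    backward(tp, loss)
    list(v = loss$val, gx = xn$grad, gw = wn$grad)
  }
  rd <- rund(x, Wd)
  expect_lt(max(abs(ngrad(function(v) rund(v, Wd)$v, x) - rd$gx)), 1e-7)
  expect_lt(max(abs(ngrad(function(v) rund(x, v)$v, Wd) - rd$gw)), 1e-7)
})

test_that("correlation, warp and resize gradients match finite differences", {
  set.seed(12)
  a <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  b <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  runc <- function(av, bv) {
    tp <- tape()
    an <- node(tp, av, name = "a")
    bn <- node(tp, bv, name = "b")
    loss <- l1(tp, endostitch:::nn_correlation(tp, an, bn, 2L),
               array(0, c(6, 6, 25)))
    backward(tp, loss)
    list(v = loss$val, ga = an$grad, gb = bn$grad)
  }
  rc <- runc(a, b)
  expect_lt(max(abs(ngrad(function(v) runc(v, b)$v, a) - rc$ga)), 1e-7)
  expect_lt(max(abs(ngrad(function(v) runc(a, v)$v, b) - rc$gb)), 1e-7)

  img <- array(runif(8 * 8 * 1), c(8, 8, 1))
  hv <- c(1.02, 0.02, -0.5, -0.01, 0.98, 0.3, 1e-3, -2e-3)
  runw <- function(h) {
    tp <- tape()
    hn <- node(tp, h, name = "h")
    loss <- l1(tp, endostitch:::nn_warp(tp, img, hn, 8, 8), array(0.3, c(8, 8, 1)))
    backward(tp, loss)
    list(v = loss$val, g = hn$grad)
  }
  rw <- runw(hv)
  expect_lt(max(abs(ngrad(function(v) runw(v)$v, hv) - rw$g)), 1e-6)
  runwi <- function(im) {
    tp <- tape()
    imn <- node(tp, im, name = "im")
    loss <- l1(tp, endostitch:::nn_warp(tp, imn, hv, 8, 8), array(0.3, c(8, 8, 1)))
    backward(tp, loss)
    list(v = loss$val, g = imn$grad)
  }
  rwi <- runwi(img)
  expect_lt(max(abs(ngrad(function(v) runwi(v)$v, img) - rwi$g)), 1e-7)

  Rw <- endostitch:::resize_weights(6, 4, "area")
  Cw <- endostitch:::resize_weights(6, 9, "bilinear")
  runr <- function(xx) {
    tp <- tape()
    xn <- node(tp, xx, name = "x")
    loss <- l1(tp, endostitch:::nn_resize(tp, xn, Rw, Cw), array(0.2, c(4, 9, 3)))
    backward(tp, loss)
    list(v = loss$val, g = xn$grad)
  }
  rr <- runr(a)
  expect_lt(max(abs(ngrad(function(v) runr(v)$v, a) - rr$g)), 1e-7)
})

test_that("Adam decreases a quadratic objective deterministically", {
  st <- endostitch:::param_store(list(w = c(3, -2)))
  trace1 <- numeric(50)
  for (i in 1:50) {
    g <- 2 * st$w$w
    endostitch:::adam_step(st, list(w = g), lr = 0.1)
    trace1[i] <- sum(st$w$w^2)
  }
  expect_true(all(diff(trace1) <= 1e-12))
  st2 <- endostitch:::param_store(list(w = c(3, -2)))
  for (i in 1:50) endostitch:::adam_step(st2, list(w = 2 * st2$w$w), lr = 0.1)
  expect_identical(st$w$w, st2$w$w)
})
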