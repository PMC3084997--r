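test_that("initialization is seeded and bounded", {
  m1 <- init_model(7, "PDB")
  m2 <- init_model(7, "PDB")
  m3 <- init_model(8, "PDB")
  expect_identical(m1$w_ih, m2$w_ih)
  expect_false(identical(m1$w_ih, m3$w_ih))
  expect_true(all(abs(m1$w_ih) <= 0.1) && all(abs(m1$w_ho) <= 0.1))
  expect_true(all(m1$b_h == 0) && m1$b_o == 0)
  expect_equal(dim(m1$w_ih), c(100L, 428L))
})

test_that("forward pass matches a pencil-and-paper 2-2-1 computation", {
  m <- toy_model(1, n_input = 2, n_hidden = 2)
  m$w_ih <- matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2)  # by column
  m$b_h <- c(0.1, -0.2)
  m$w_ho <- c(1.5, -0.7)
  m$b_o <- 0.25
  x <- c(0.4, 0.9)
  h <- 1 / (1 + exp(-(m$w_ih %*% x + m$b_h)))
  expected <- 1 / (1 + exp(-(sum(m$w_ho * h) + m$b_o)))
  expect_equal(forward(m, unname(x)), as.numeric(expected), tolerance = 1e-12)
  # zero weights give the neutral score on any input
  z <- toy_model(2)
  z$w_ih[] <- 0; z$b_h[] <- 0; z$w_ho[] <- 0; z$b_o <- 0
  expect_equal(forward(z, runif(5)), 0.5)
  # score range and b_o monotonicity
  set.seed(3)
  for (i in 1:20) {
    s <- forward(m, runif(2))
    expect_true(s > 0 && s < 1)
  }
  m_up <- m; m_up$b_o <- m$b_o + 0.5
  expect_gt(forward(m_up, x), forward(m, x))
})

test_that("forward rejects dimension and registry mismatches", {
  m <- toy_model(1)
  expect_error(forward(m, runif(4)), "length 4")
  bad <- stats::setNames(runif(5), paste0("g", 1:5))
  expect_error(forward(m, bad), "registry")
})

test_that("analytic gradient matches central finite differences", {
  m <- toy_model(2, n_input = 5, n_hidden = 3)
  set.seed(4)
  x <- runif(5)
  for (y in c(0, 1)) {
    g <- crystalnn:::mlp_gradient(m, x, y)
    loss <- function(mm) 0.5 * (forward(mm, x) - y)^2
    eps <- 1e-5  # central differences: truncation O(eps^2), roundoff O(1e-16/eps)
    for (field in c("w_ih", "b_h", "w_ho", "b_o")) {
      analytic <- g[[field]]
      numeric_g <- analytic
      for (i in seq_along(analytic)) {
        up <- m; up[[field]][i] <- up[[field]][i] + eps
        dn <- m; dn[[field]][i] <- dn[[field]][i] - eps
        numeric_g[i] <- (loss(up) - loss(dn)) / (2 * eps)
      }
      expect_lt(max(abs(numeric_g - analytic) / (abs(numeric_g) + 1e-8)),
                1e-6)
    }
  }
})

test_that("repeated per-example steps on one target decrease the loss", {
  m <- toy_model(5)
  set.seed(6)
  x <- runif(5)
  lr <- 0.05
  losses <- numeric(30)
  for (step in 1:30) {
    losses[step] <- 0.5 * (forward(m, x) - 1)^2
    g <- crystalnn:::mlp_gradient(m, x, 1)
    for (field in names(g)) m[[field]] <- m[[field]] - lr * g[[field]]
  }
  expect_true(all(diff(losses) <= 0))
})

test_that("training separates shifted Gaussians and is seed-deterministic", {
  d <- gaussian_data(100, shift = 1, seed = 10)
  cfg <- train_config("PDB", cycles = 200, seed = 3)
  m0 <- toy_model(4)
  fit1 <- train(m0, d$X, d$y, cfg)
  expect_gte(auroc(forward(fit1, d$X), d$y), 0.99)
  fit2 <- train(m0, d$X, d$y, cfg)
  expect_identical(fit1$w_ih, fit2$w_ih)
  expect_identical(fit1$b_o, fit2$b_o)
  expect_error(train(m0, d$X[d$y == 1, ], rep(1, 100), cfg), "both classes")
})

test_that("early stopping returns the best-validation cycle", {
  d <- gaussian_data(60, shift = 1.5, seed = 20)
  cfg <- train_config("PDB", cycles = 150, early_stopping = TRUE,
                      val_fraction = 0.2, patience = 15, seed = 5)
  fit <- train(toy_model(6), d$X, d$y, cfg)
  trace <- attr(fit, "trace")
  expect_true("val_mse" %in% names(trace))
  expect_equal(fit$cycles, which.min(trace$val_mse))
  expect_lte(nrow(trace), 150)
})

test_that("model serialization round-trips bitwise and catches tampering", {
  d <- gaussian_data(20, shift = 1, seed = 30)
  m <- train(toy_model(7), d$X, d$y, train_config("SG", cycles = 5, seed = 2))
  attr(m, "trace") <- NULL
  m$cutoff <- 0.41799999999999998
  path <- withr::local_tempfile(fileext = ".txt")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back, m)
  expect_identical(back$cutoff, m$cutoff)

  lines <- readLines(path)
  lines[6] <- "n_hidden 99"
  writeLines(lines, path)
  expect_error(load_model(path), "n_hidden")
  writeLines(lines[1:5], path)
  expect_error(load_model(path), "truncated|expected")
  writeLines(c("other-format 2", lines[-1]), path)
  expect_error(load_model(path), "unrecognized")
})
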