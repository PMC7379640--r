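test_that("Fisher's C follows the closed form and conventions", {
  expect_equal(fishers_c(rep(1, 3)), list(C = 0, df = 6L, p = 1))
  fc <- fishers_c(c(0.5, 0.5))
  expect_equal(fc$C, -2 * 2 * log(0.5), tolerance = 1e-12)
  expect_equal(fc$df, 4L)
  expect_equal(fc$p, pchisq(fc$C, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(fc$p, 4), 0.5966)
  expect_equal(fishers_c(numeric(0)), list(C = 0, df = 0L, p = 1)) # saturated
  expect_error(fishers_c(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_warning(fc0 <- fishers_c(c(0.5, 0)), "clipped")
  expect_true(is.finite(fc0$C))
})

test_that("Fisher's C of uniform p-values is chi-square distributed", {
  set.seed(77)
  k <- 12
  C <- vapply(1:10000, function(i) -2 * sum(log(runif(k))), numeric(1))
  ks <- suppressWarnings(ks.test(C, "pchisq", df = 2 * k))
  expect_gt(ks$p.value, 0.01)
})

test_that("CICc reproduces the printed worked examples and limits", {
  expect_equal(cicc(0, 0, 10), 0)
  expect_equal(round(cicc(16.53, 9, 47), 2), 39.39)
  expect_equal(round(cicc(11.46, 13, 68), 1), 44.2)
  expect_error(cicc(10, 9, 10), "n must exceed")
  expect_error(cicc(-1, 2, 30), "non-negative")
  # large-n limit: the penalty tends to 2q
  expect_equal(cicc(5, 7, 1e6), 5 + 14, tolerance = 0.01)
})

# minimal hand-built dsep_fit for selection arithmetic tests
fake_fit <- function(id, C, q, n, p = 0.5, coefs = NULL) {
  structure(list(model_id = id, claims = NULL, k = 2L, C = C, df = 4L,
                 p = p, q = q, n = n, CICc = cicc(C, q, n),
                 coef_table = coefs %||% data.frame(
                   from = character(), to = character(), estimate = numeric(),
                   se = numeric(), p_value = numeric()),
                 evaluable = TRUE, flagged = character(0)),
            class = "dsep_fit")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("model ranking, delta and CICc weights follow the definitions", {
  # the two best bat urban-visitor models: printed (C, q) pairs at n = 47
  f1 <- fake_fit("LS", 16.53, 9, 47, p = 0.87)
  f2 <- fake_fit("BR + LS", 14.68, 10, 47, p = 0.88)
  sel <- select_models(list(f2, f1))
  expect_equal(sel$model, c("LS", "BR + LS"))
  expect_equal(round(sel$delta, 1), c(0, 1.4))
  expect_equal(sum(sel$omega), 1)
  expect_true(all(sel$supported))

  # single model
  s1 <- select_models(list(f1))
  expect_equal(s1$delta, 0)
  expect_equal(s1$omega, 1)
  # equal CICc: equal weights
  s3 <- select_models(list(fake_fit("a", 10, 3, 50), fake_fit("b", 10, 3, 50),
                           fake_fit("c", 10, 3, 50)))
  expect_equal(s3$omega, rep(1 / 3, 3))
  # support needs BOTH delta < 2 and d-sep p >= alpha
  s4 <- select_models(list(fake_fit("ok", 10, 3, 50, p = 0.5),
                           fake_fit("rej", 10, 3, 50, p = 0.01)))
  expect_equal(s4$supported, c(TRUE, FALSE))
  expect_equal(s4$omega_renorm, c(1, NA_real_))
  expect_error(select_models(list()), "no model fits")
})

test_that("CICc weights are invariant to a constant shift in CICc", {
  f <- list(fake_fit("a", 12, 3, 50), fake_fit("b", 16, 3, 50),
            fake_fit("c", 20, 3, 50))
  w1 <- select_models(f)$omega
  shifted <- lapply(f, function(x) { x$CICc <- x$CICc + 123.4; x })
  w2 <- select_models(shifted)$omega
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("conditional averaging reproduces hand-computed results", {
  ct <- function(b, se) data.frame(from = "DD", to = "urban", estimate = b,
                                   se = se, p_value = 0.05)
  # one supported model: averaged coefficient is that model's coefficient
  one <- select_models(list(fake_fit("m1", 10, 3, 50, coefs = ct(0.4, 0.1))))
  avg1 <- average_paths(one)
  expect_equal(avg1$estimate, 0.4)
  expect_equal(avg1$se, 0.1)

  # two supported models with equal weights: mean of 0.4 and 0.6 is 0.5
  two <- select_models(list(fake_fit("m1", 10, 3, 50, coefs = ct(0.4, 0.1)),
                            fake_fit("m2", 10, 3, 50, coefs = ct(0.6, 0.1))))
  avg2 <- average_paths(two)
  expect_equal(avg2$estimate, 0.5, tolerance = 1e-12)
  # unconditional-variance SE folds in the between-model spread
  expect_equal(avg2$se, 0.5 * sqrt(0.1^2 + 0.1^2) + 0.5 * sqrt(0.1^2 + 0.1^2),
               tolerance = 1e-12)

  # three models with known weights: weighted mean to machine precision
  f1 <- fake_fit("m1", 10, 3, 100, coefs = ct(0.2, 0.05))
  f2 <- fake_fit("m2", 11, 3, 100, coefs = ct(0.5, 0.05))
  f3 <- fake_fit("m3", 11.5, 3, 100, coefs = ct(-0.1, 0.05))
  sel <- select_models(list(f1, f2, f3))
  w <- sel$omega[match(c("m1", "m2", "m3"), sel$model)]
  w <- w / sum(w)
  expect_equal(average_paths(sel)$estimate,
               sum(w * c(0.2, 0.5, -0.1)), tolerance = 1e-12)

  none <- select_models(list(fake_fit("m1", 10, 3, 50, p = 0.001)))
  expect_error(average_paths(none), "no supported")
})

test_that("run_dsep wires claims to the right engines", {
  set.seed(41)
  tr <- simulate_yule_tree(80, seed = 41)
  cfg <- example_simulation_config()
  sim <- simulate_traits(tr, cfg, seed = 42)
  dag <- cfg$dag
  fit <- run_dsep(dag, sim$table, phylo_cov(tr), binary = "urban",
                  model_id = "generating")
  expect_s3_class(fit, "dsep_fit")
  expect_equal(fit$k, choose(6, 2) - dag$q)
  expect_equal(fit$df, 2L * fit$k)
  expect_true(all(fit$claims$p_value >= 0 & fit$claims$p_value <= 1))
  expect_equal(fit$CICc, cicc(fit$C, dag$q, 80), tolerance = 1e-12)
  # every edge has a path coefficient
  expect_equal(nrow(fit$coef_table), dag$q)
  # claims with the binary vertex designate it as response
  urb <- fit$claims$x == "urban" | fit$claims$y == "urban"
  expect_true(all(fit$claims$response[urb] == "urban"))
})

test_that("phylo_path returns a coherent selection across 32 models", {
  tr <- simulate_yule_tree(90, seed = 51)
  sim <- simulate_traits(tr, example_simulation_config(), seed = 52)
  pp <- phylo_path(example_trait_dag(), c("BM", "DD", "BR", "WA", "LS"),
                   sim$table, sim$tree)
  expect_s3_class(pp, "phylo_path")
  expect_equal(nrow(pp$selection), 32L)
  expect_equal(pp$selection$delta[1], 0)
  expect_equal(sum(pp$selection$omega), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(pp$selection$CICc))
  # q differs from the trait-only q by the number of added links
  nlinks <- ifelse(pp$selection$model == "Trait-only", 0L,
                   lengths(strsplit(pp$selection$model, " \\+ ")))
  expect_equal(pp$selection$q, example_trait_dag()$q + nlinks)
  if (any(pp$selection$supported)) {
    expect_s3_class(pp$average, "averaged_paths")
    expect_true(all(pp$average$n_models >= 1))
  }
  expect_output(print(pp), "Model selection")
})
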