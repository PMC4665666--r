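test_that("design matrix uses treatment coding with valine baseline", {
  rec <- make_records(200, seed = 10)
  rec$label <- rep(c(0L, 1L), 100)
  des <- build_design(rec, model_spec(c("E6", "AA")))
  ## intercept + E6 + 19 AA indicators
  expect_equal(ncol(des$X), 21L)
  expect_equal(sum(startsWith(colnames(des$X), "AA:")), 19L)
  ## valine rows have all AA indicators zero
  val_rows <- rec$aa[des$rows] == "V"
  aa_cols <- startsWith(colnames(des$X), "AA:")
  expect_true(all(des$X[val_rows, aa_cols] == 0))
  ## every row's AA indicators sum to at most one
  expect_true(all(rowSums(des$X[, aa_cols]) <= 1))
  ## lysine row has exactly the LYS indicator set
  k_rows <- which(rec$aa[des$rows] == "K")[1]
  expect_equal(unname(des$X[k_rows, "AA:LYS"]), 1)
  expect_equal(sum(des$X[k_rows, aa_cols]), 1)
  ## dummy columns are alphabetical within the factor
  expect_equal(colnames(des$X)[aa_cols],
               paste0("AA:", c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN",
                               "GLU", "GLY", "HIS", "ILE", "LEU", "LYS",
                               "MET", "PHE", "PRO", "SER", "THR", "TRP",
                               "TYR")))
})

test_that("prediction rejects factor levels unseen at fit time", {
  rec <- make_records(60, seed = 11)
  rec <- rec[rec$aa != "W", ]
  rec$label <- rep_len(c(0L, 1L), nrow(rec))
  fit <- suppressMessages(fit_model(rec, model_spec(c("E6", "AA"))))
  new <- make_records(10, seed = 12)
  new$aa <- "W"
  expect_error(predict_proba(fit, new), "TRP")
})

test_that("intercept-only fits equal the logit of the accessible fraction", {
  fit50 <- fit_logistic(intercept_design(rep(c(0, 1), 50)))
  expect_equal(unname(fit50$coefficients), 0, tolerance = 1e-8)
  fit75 <- fit_logistic(intercept_design(rep(c(0, 1, 1, 1), 25)))
  expect_equal(unname(fit75$coefficients), log(3), tolerance = 1e-8)
  expect_true(fit50$converged && fit75$converged)
})

test_that("the maximum-likelihood fit agrees with an independent GLM solver", {
  rec <- make_records(2000, seed = 13)
  set.seed(14)
  eta <- -0.4 + 0.9 * rec$e6 - 1.2 * rec$fshp
  rec$label <- rbinom(2000, 1, plogis(eta))
  spec <- model_spec(c("E6", "FSHP", "AA"))
  fit <- fit_model(rec, spec)
  des <- build_design(rec, spec)
  ref <- glm.fit(des$X, des$y, family = binomial())
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-7)
  ref_se <- sqrt(diag(chol2inv(chol(
    crossprod(des$X, des$X * ref$weights)))))
  expect_equal(unname(fit$se), ref_se, tolerance = 1e-6)
  ## Wald machinery is internally consistent
  expect_equal(fit$z, fit$coefficients / fit$se, tolerance = 1e-12)
  expect_equal(fit$odds_ratio, exp(fit$coefficients), tolerance = 1e-12)
  expect_equal(fit$p_value, 2 * pnorm(-abs(fit$z)), tolerance = 1e-12)
})

test_that("mean fitted probability equals the observed accessible fraction", {
  rec <- make_records(1500, seed = 15)
  set.seed(16)
  rec$label <- rbinom(1500, 1, plogis(-0.2 + 0.7 * rec$e6))
  fit <- fit_model(rec, model_spec(c("E6", "AA")))
  expect_true(fit$converged)
  expect_equal(mean(fit$fitted), mean(rec$label), tolerance = 1e-8)
})

test_that("refitting with permuted row order reproduces the coefficients", {
  rec <- make_records(800, seed = 17)
  set.seed(18)
  rec$label <- rbinom(800, 1, plogis(0.5 * rec$e6 - 0.5 * rec$fsr))
  spec <- model_spec(c("E6", "FSR", "AA"))
  fit1 <- fit_model(rec, spec)
  set.seed(19)
  fit2 <- fit_model(rec[sample(nrow(rec)), ], spec)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-8)
})

test_that("degenerate fits are flagged rather than silently returned", {
  rec <- make_records(100, seed = 20)
  rec$label <- rep(1L, 100)
  expect_error(fit_model(rec, model_spec("E6")), "single class")
  ## perfectly separated data
  rec$label <- as.integer(rec$e6 > median(rec$e6))
  expect_warning(fit <- fit_model(rec, model_spec("E6")), "converge")
  expect_false(fit$converged)
  expect_match(paste(fit$diagnostics, collapse = " "), "separation")
  ## rank-deficient design (duplicated quantitative column via constant fsr)
  rec$label <- rep(c(0L, 1L), 50)
  rec$fsr <- rec$e6
  expect_warning(fit2 <- fit_model(rec, model_spec(c("E6", "FSR"))),
                 "converge")
  expect_false(fit2$converged)
  expect_match(paste(fit2$diagnostics, collapse = " "), "aliased")
})

test_that("odds ratios follow exp(delta * beta)", {
  fit <- manual_model(c("(Intercept)" = -0.5, E6 = 0.862, "AA:LYS" = 1.509))
  expect_equal(odds_ratio(fit, "AA:LYS"), exp(1.509), tolerance = 1e-12)
  expect_equal(round(odds_ratio(fit, "AA:LYS"), 3), 4.522)
  expect_equal(odds_ratio(fit, "E6", delta = 0), 1.0)
  expect_equal(odds_ratio(fit, "E6", delta = 2), exp(1.724),
               tolerance = 1e-12)
  expect_error(odds_ratio(fit, "E20"), "unknown model column")
})

test_that("predicted probabilities are logistic in the linear predictor and stable", {
  fit <- manual_model(c("(Intercept)" = 0, E6 = 1))
  rec <- data.frame(chain_id = "c", position = 1:3, aa = "V",
                    e6 = c(0, 40, -40), stringsAsFactors = FALSE)
  p <- predict_proba(fit, rec)
  expect_equal(p[1], 0.5)
  expect_equal(p[2], 1.0, tolerance = 1e-15)   # no overflow at eta = 40
  expect_equal(p[3], 0.0, tolerance = 1e-15)
  ## published-coefficient check: valine with all quantitative terms zero
  classic <- classic_model_1363()
  rec0 <- data.frame(chain_id = "c", position = 1L, aa = "V",
                     e20 = 0, e6 = 0, fshp = 0, fsr = 0,
                     stringsAsFactors = FALSE)
  expect_equal(predict_proba(classic, rec0), plogis(-0.528),
               tolerance = 1e-12)
  expect_equal(round(predict_proba(classic, rec0), 3), 0.371)
})

test_that("classification uses an inclusive 0.5 boundary and respects cutoffs", {
  expect_equal(classify(c(0.51, 0.5, 0.49)), c(1L, 1L, 0L))
  expect_equal(classify(0.3, cutoff = 0.25), 1L)
  expect_error(classify(1.2), "probabilities")
  ## classify(predict_proba(...)) reproduces fit-time classifications
  rec <- make_records(300, seed = 21)
  set.seed(22)
  rec$label <- rbinom(300, 1, plogis(rec$e6 - 1))
  fit <- fit_model(rec, model_spec(c("E6", "AA")))
  expect_equal(classify(predict_proba(fit, rec)),
               classify(fit$fitted))
})

test_that("Wald 95% intervals achieve nominal coverage on model-simulated data", {
  set.seed(23)
  true_b <- c(-0.5, 0.9)
  n <- 400; reps <- 300
  covered <- matrix(FALSE, reps, 2)
  x <- runif(n, 0, log(6))
  rec <- data.frame(chain_id = "c", position = 1:n, aa = "V", e6 = x,
                    stringsAsFactors = FALSE)
  for (r in seq_len(reps)) {
    rec$label <- rbinom(n, 1, plogis(true_b[1] + true_b[2] * x))
    fit <- fit_model(rec, model_spec("E6"))
    lo <- fit$coefficients - 1.96 * fit$se
    hi <- fit$coefficients + 1.96 * fit$se
    covered[r, ] <- true_b >= lo & true_b <= hi
  }
  cov <- colMeans(covered)
  ## three binomial standard errors around 0.95 at 300 replicates
  expect_true(all(cov > 0.95 - 3 * sqrt(0.95 * 0.05 / reps)))
  expect_true(all(cov < 0.95 + 3 * sqrt(0.95 * 0.05 / reps) + 1e-9))
})

test_that("the linear baseline recovers a noiseless slope and per-AA intercepts", {
  set.seed(24)
  n <- 300
  aa <- sample(AA20, n, replace = TRUE)
  e6 <- runif(n, 0, log(6))
  intercepts <- setNames(seq(5, 62, length.out = 20), AA20)
  rec <- data.frame(chain_id = "c", position = 1:n, aa = aa, e6 = e6,
                    rsa = intercepts[aa] + 10 * e6,
                    stringsAsFactors = FALSE)
  fit <- fit_linear_baseline(rec, "E6")
  expect_equal(fit$slope, 10, tolerance = 1e-10)
  expect_equal(unname(fit$intercepts[c("VAL", "ASP")]),
               unname(intercepts[c("V", "D")]), tolerance = 1e-9)
  ## prediction + threshold classification share the inclusive boundary
  pred <- predict(fit, rec, type = "rsa")
  expect_equal(pred, rec$rsa, tolerance = 1e-9)
  expect_equal(predict(fit, rec, type = "class"),
               binarize_rsa(rec$rsa, 20))
})

test_that("a single-residue-type baseline reduces to simple regression", {
  set.seed(25)
  e6 <- runif(50, 0, 1.7)
  rec <- data.frame(chain_id = "c", position = 1:50, aa = "K", e6 = e6,
                    rsa = 30 + 8 * e6 + rnorm(50, 0, 2),
                    stringsAsFactors = FALSE)
  fit <- fit_linear_baseline(rec, "E6")
  simple <- lm(rsa ~ e6, data = rec)
  expect_equal(fit$slope, unname(coef(simple)[2]), tolerance = 1e-10)
  expect_equal(unname(fit$intercepts["LYS"]), unname(coef(simple)[1]),
               tolerance = 1e-10)
})
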