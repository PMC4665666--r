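test_that("alignment columns span the conservation range set by the concentration", {
  cfg <- fixture_config(seed = 41)
  ## near-delta columns give near-zero entropy
  cfg_cons <- cfg; cfg_cons$log_conc_range <- c(-3, -3); cfg_cons$gap_prob <- 0
  set.seed(41)
  sim <- simulate_alignment("c1A", 120, 25, cfg_cons)
  prof <- build_profile(sim$query, sim$hits, "c1A")
  expect_lt(mean(entropy20(prof), na.rm = TRUE), 0.35)
  ## high concentration approaches the uniform maximum in expectation
  cfg_var <- cfg; cfg_var$log_conc_range <- c(3, 3); cfg_var$gap_prob <- 0
  set.seed(42)
  sim <- simulate_alignment("c2A", 120, 60, cfg_var)
  prof <- build_profile(sim$query, sim$hits, "c2A")
  expect_gt(mean(entropy20(prof), na.rm = TRUE), 0.85 * log(20))
})

test_that("bit scores exercise the relative filter and zero hits are handled", {
  cfg <- fixture_config(seed = 43)
  set.seed(43)
  sim <- simulate_alignment("c1A", 150, 40, cfg)
  kept <- filter_hits(sim$hits, 0.4)
  expect_lt(nrow(kept), nrow(sim$hits))  # some hits fall below the cut
  expect_gt(nrow(kept), 0L)
  set.seed(43)
  sim0 <- simulate_alignment("c0A", 50, 0, cfg)
  expect_equal(nrow(sim0$hits), 0L)
  prof <- build_profile(sim0$query, sim0$hits, "c0A")
  expect_equal(homology_status(prof), "non_optimum")
})

test_that("labels drawn at zero coefficients are balanced, and respond to E6", {
  rec <- make_records(10000, seed = 44)
  null_model <- manual_model(c("(Intercept)" = 0, E6 = 0))
  set.seed(45)
  out <- simulate_labels(rec, null_model)
  expect_lt(abs(mean(out$label) - 0.5), 0.02)
  ## strong positive E6 coefficient makes exposure increase with E6
  e6_model <- manual_model(c("(Intercept)" = -1.5, E6 = 2.5))
  set.seed(46)
  out <- simulate_labels(rec, e6_model)
  expect_gt(cor(out$e6, out$label, method = "spearman"), 0.2)
  ## labels and continuous RSA are consistent at the threshold
  expect_equal(binarize_rsa(out$rsa, 20), out$label)
})

test_that("oligomer context flags the configured interfacial fraction", {
  cfg <- fixture_config(seed = 47, n_chains = 10, oligomer_fraction = 1,
                        interfacial_fraction = 0.2,
                        interfacial_label_noise = 0)
  rec <- make_records(1000, seed = 47)
  rec$chain_id <- rep(sprintf("c%02d", 1:10), each = 100)
  null_model <- manual_model(c("(Intercept)" = 0, E6 = 0))
  set.seed(48)
  rec <- simulate_labels(rec, null_model)
  rec <- simulate_oligomer_context(rec, cfg)
  expect_equal(sum(rec$interfacial), 200L)
  ## single-chain exposure rises at interfaces, labels follow the complex
  intf <- which(rec$interfacial)
  expect_true(all(rec$rsa[intf] > rec$rsa_complex[intf]))
  expect_equal(binarize_rsa(rec$rsa_complex[intf], 20), rec$label[intf])
  ## the delta rule recovers exactly the constructed interface set
  single <- data.frame(position = rec$position[1:100], rsa = rec$rsa[1:100])
  complexed <- data.frame(position = rec$position[1:100],
                          rsa = rec$rsa_complex[1:100])
  expect_equal(flag_interfacial(single, complexed),
               which(rec$interfacial[1:100]))
  ## zero interfacial fraction flags nothing
  cfg0 <- cfg; cfg0$interfacial_fraction <- 0
  set.seed(48)
  rec0 <- simulate_oligomer_context(simulate_labels(make_records(200),
                                                    null_model), cfg0)
  expect_equal(sum(rec0$interfacial, na.rm = TRUE), 0L)
})

test_that("fixture directories are byte-identical across reruns at a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- fixture_config(n_chains = 6, seed = 49)
  simulate_fixture(cfg, d1)
  simulate_fixture(cfg, d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  expect_true(length(files) >= 5)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
})

test_that("fixture files parse back into the recorded truth table", {
  d <- withr::local_tempdir()
  cfg <- fixture_config(n_chains = 6, seed = 50)
  sim <- simulate_fixture(cfg, d)
  truth <- sim$records
  seqs <- suppressWarnings(read_fasta(file.path(d, "chains.fasta")))
  expect_equal(sum(lengths(seqs)), nrow(truth))
  hits <- read_alignment_table(file.path(d, "alignments.tsv"))
  expect_equal(nrow(hits), nrow(sim$hits))
  ## recomputing descriptors from the files reproduces the truth columns
  rec2 <- suppressMessages(compute_descriptors(
    seqs, hits, cfg$bitscore_fraction, cfg$min_hits))
  expect_equal(rec2$e6, truth$e6, tolerance = 1e-12)
  expect_equal(rec2$e20, truth$e20, tolerance = 1e-12)
  expect_equal(rec2$homology_status, truth$homology_status)
  ## .rsa files carry the single-chain accessibilities to 2 decimals
  id <- truth$chain_id[1]
  tab <- read_naccess_rsa(file.path(d, paste0(id, ".rsa")), "single_chain")
  have <- truth[truth$chain_id == id & !is.na(truth$rsa), ]
  expect_equal(tab$rsa, have$rsa, tolerance = 5e-3)
})

test_that("a fit on the simulated learning set recovers the generating coefficients", {
  sim <- suppressMessages(simulate_records(fixture_config(
    n_chains = 30, seed = 51)))
  rec <- resolve_query_x(sim$records)
  rec <- rec[rec$homology_status == "optimum", ]
  fit <- suppressMessages(fit_model(rec, "classic"))
  expect_true(fit$converged)
  truth <- sim$config$true_model$coefficients
  est <- fit$coefficients[names(truth)]
  ## every coefficient within its 3-SE Wald band around the truth
  expect_true(all(abs(est - truth) <= 3 * fit$se[names(truth)]))
})
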