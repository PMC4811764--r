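up_sig <- function(n, name = "planted") {
  gene_signature(name, sprintf("sig_%03d", seq_len(n)), 1L)
}

test_that("degenerate config reproduces baselines exactly", {
  cfg <- cohort_config(15, c(A = 3, B = 2), noise_sd = 0, seed = 4)
  sim <- simulate_expression(cfg)
  for (s in colnames(sim$expr)) {
    expect_equal(unname(sim$expr[, s]), unname(sim$truth$baseline))
  }
})

test_that("same seed is byte-identical, different seeds differ", {
  cfg <- cohort_config(30, c(ERMS = 4, MUSCLE = 4), seed = 99)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(serialize(s1$expr, NULL), serialize(s2$expr, NULL))
  cfg2 <- cohort_config(30, c(ERMS = 4, MUSCLE = 4), seed = 100)
  expect_false(identical(simulate_expression(cfg2)$expr, s1$expr))
})

test_that("planted shifts land on the right genes, samples and signs", {
  sig <- gene_signature("mix", sprintf("sig_%03d", 1:6),
                        c(1, 1, 1, -1, -1, 1))
  eff <- data.frame(signature = "mix", subtype = "ERMS", delta = 2)
  cfg <- cohort_config(10, c(ERMS = 3, MUSCLE = 3), noise_sd = 0,
                       planted_effects = eff, seed = 8)
  sim <- simulate_expression(cfg, list(sig))
  # signature genes absent from the universe were appended
  expect_true(all(sig$entries$gene %in% rownames(sim$expr)))
  expect_equal(nrow(sim$expr), 16L)
  # at zero noise the planted shift is exactly expr - baseline
  for (i in seq_len(nrow(sim$truth$planted))) {
    g <- sim$truth$planted$gene[i]
    shift <- sim$truth$planted$shift[i]
    for (s in sim$annotation$sample_id[sim$annotation$subtype == "ERMS"]) {
      expect_equal(sim$expr[g, s] - sim$truth$baseline[[g]], shift)
    }
    for (s in sim$annotation$sample_id[sim$annotation$subtype == "MUSCLE"]) {
      expect_equal(sim$expr[g, s] - sim$truth$baseline[[g]], 0)
    }
  }
  expect_equal(sim$truth$planted$shift,
               sig$entries$direction * 2)
})

test_that("Monte-Carlo: mean score difference approximates m * delta", {
  sig <- up_sig(50)
  eff <- data.frame(signature = "planted", subtype = "HOT", delta = 1)
  cfg <- cohort_config(60, c(HOT = 500, NULLG = 500), noise_sd = 1,
                       planted_effects = eff, seed = 2016)
  sim <- simulate_expression(cfg, list(sig))
  st <- signature_score(sim$expr, sig)
  v <- setNames(st$score, st$sample_id)
  hot <- v[sim$annotation$sample_id[sim$annotation$subtype == "HOT"]]
  nul <- v[sim$annotation$sample_id[sim$annotation$subtype == "NULLG"]]
  diff <- mean(hot) - mean(nul)
  # per-sample score sd = sqrt(50); SE of the difference of means
  se <- sqrt(50 / 500 + 50 / 500)
  expect_lt(abs(diff - 50), 3 * se)
})

test_that("conservation: an unshifted subtype scores like the null", {
  sig <- up_sig(50)
  cfg <- cohort_config(60, c(A = 500, B = 500), noise_sd = 1, seed = 77)
  sim <- simulate_expression(cfg, list(sig))
  st <- signature_score(sim$expr, sig)
  v <- setNames(st$score, st$sample_id)
  a <- v[sim$annotation$sample_id[sim$annotation$subtype == "A"]]
  b <- v[sim$annotation$sample_id[sim$annotation$subtype == "B"]]
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(10, c(A = 2, A = 2)), "duplicate")
  expect_error(cohort_config(10, c(A = 0, B = 2)), ">= 1")
  expect_error(cohort_config(10, c(A = 2), noise_sd = -1), "noise_sd")
  expect_error(cohort_config(10, setNames(2, "")), "named")
  eff <- data.frame(signature = "s", subtype = "ZZ", delta = 1)
  expect_error(cohort_config(10, c(A = 2), planted_effects = eff),
               "unknown subtype")
  cfg <- cohort_config(10, c(A = 2, B = 2),
                       planted_effects = data.frame(signature = "nope",
                                                    subtype = "A",
                                                    delta = 1))
  expect_error(simulate_expression(cfg, list(up_sig(3))),
               "unknown signature")
})

test_that("simulate_qpcr plug-in Ct and planted-copy identities", {
  # noise 0, slope -3.3219, intercept 30, quantity 10 -> Ct 26.6781
  curves <- data.frame(assay = c("Met", "Actl6a"), slope = -3.3219,
                       intercept = 30)
  ct <- simulate_qpcr(c(REF = 1), curves = curves, base_log10 = 1,
                      noise_sd = 0, seed = 1)
  met_ref <- ct$ct[ct$role == "sample" & ct$assay == "Met"]
  expect_equal(met_ref, 26.6781, tolerance = 1e-4)

  # planted copy number 1 everywhere -> relative CNV exactly 1 at zero noise
  ct1 <- simulate_qpcr(c(REF = 1, S1 = 1, S2 = 1), noise_sd = 0, seed = 1)
  res <- relative_copy_number(ct1, "Met", "Actl6a", "REF")
  expect_equal(res$rel_copy_number, rep(1, 3), tolerance = 1e-12)
})

test_that("noisy standards: least-squares refit recovers the slope", {
  ct <- simulate_qpcr(c(REF = 1), standard_log10 = 6:0, noise_sd = 0.1,
                      seed = 23)
  std <- ct[ct$role == "standard" & ct$assay == "Met", ]
  fit <- fit_standard_curve(std$log10_quantity, std$ct)
  expect_equal(fit$slope, -1 / log10(2), tolerance = 0.05)
})

test_that("simulate_qpcr validates its inputs", {
  expect_error(simulate_qpcr(c(1, 2)), "named")
  expect_error(simulate_qpcr(c(A = 0)), "> 0")
  expect_error(simulate_qpcr(c(A = 1), standard_log10 = c(2, 2)),
               "distinct")
  bad <- data.frame(assay = c("Met", "Actl6a"), slope = c(NA, -3),
                    intercept = 30)
  expect_error(simulate_qpcr(c(A = 1), curves = bad), "non-finite")
})

test_that("fish simulation: constants, reproducibility, mixture oracle", {
  const <- simulate_fish_cells(5, 2, 2, seed = 3)
  expect_equal(const$target_count, rep(2L, 5))
  s <- suppressWarnings(summarize_fish(const))
  expect_equal(s$ratio, 1.0)

  expect_identical(simulate_fish_cells(50, 9, 2, seed = 5),
                   simulate_fish_cells(50, 9, 2, seed = 5))

  # Poisson mixture: 30% of cells amplified
  mix <- function(n) {
    amp <- runif(n) < 0.3
    rpois(n, ifelse(amp, 9, 2))
  }
  cells <- simulate_fish_cells(200, mix, function(n) rpois(n, 2) + 1L,
                               seed = 17)
  s <- summarize_fish(cells)
  expect_equal(s$ratio, mean(cells$target_count) / mean(cells$cen_count))
  expect_equal(s$pct_gt4, 100 * sum(cells$target_count > 4) / 200)

  expect_error(simulate_fish_cells(0), ">= 1")
  expect_error(simulate_fish_cells(5, function(n) rep(-1, n), 2),
               "non-negative")
})
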