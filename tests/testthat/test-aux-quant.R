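test_that("standard curve: textbook series, exact 2-point fit, LS oracle", {
  sc <- fit_standard_curve(c(2, 1, 0), c(20.0, 23.3219, 26.6438))
  expect_equal(sc$slope, -3.3219, tolerance = 1e-4)
  expect_equal(sc$efficiency, 1.0, tolerance = 1e-4)

  two <- fit_standard_curve(c(3, 1), c(18, 24))
  expect_equal(two$slope, -3)
  expect_equal(two$intercept, 27)
  expect_equal(two$r_squared, 1)

  # noisy 5-point series vs the normal-equations closed form
  lq <- 4:0
  ct <- withr::with_seed(5, 30 - 3.4 * lq + rnorm(5, 0, 0.2))
  fit <- fit_standard_curve(lq, ct)
  slope_hat <- sum((lq - mean(lq)) * (ct - mean(ct))) / sum((lq - mean(lq))^2)
  expect_equal(fit$slope, slope_hat, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(ct) - slope_hat * mean(lq),
               tolerance = 1e-12)

  expect_error(fit_standard_curve(c(1, 1), c(20, 21)), "distinct")
  expect_error(fit_standard_curve(c(1, 2), c(NA, 21)), "non-finite")
  expect_warning(fit_standard_curve(c(0, 1, 2), c(20, 23, 26)),
                 "non-negative slope")
})

make_ct_table <- function(samples_ct, curves) {
  # standards: perfect 10-fold series per assay; samples: given Ct values
  rows <- list()
  for (a in names(curves)) {
    for (lq in 4:0) {
      rows[[length(rows) + 1]] <- data.frame(
        well = paste0("std_", a, "_", lq), sample_id = NA, assay = a,
        role = "standard", log10_quantity = lq,
        ct = curves[[a]]$intercept + curves[[a]]$slope * lq
      )
    }
  }
  for (i in seq_len(nrow(samples_ct))) {
    rows[[length(rows) + 1]] <- data.frame(
      well = paste0(samples_ct$sample_id[i], "_", samples_ct$assay[i]),
      sample_id = samples_ct$sample_id[i], assay = samples_ct$assay[i],
      role = "sample", log10_quantity = NA, ct = samples_ct$ct[i]
    )
  }
  do.call(rbind, rows)
}

test_that("relative_copy_number identity, one-decade, and hand oracle", {
  curves <- list(Met = list(slope = -3.3219, intercept = 25),
                 Actl6a = list(slope = -3.3219, intercept = 24))
  base <- data.frame(
    sample_id = c("REF", "REF", "S1", "S1", "S2", "S2"),
    assay = rep(c("Met", "Actl6a"), 3),
    ct = c(20, 19, 20, 19, 20 - 3.3219, 19)
  )
  res <- relative_copy_number(make_ct_table(base, curves),
                              "Met", "Actl6a", "REF")
  expect_equal(res$rel_copy_number[res$sample_id == "S1"], 1,
               tolerance = 1e-10)  # Cts identical to reference
  expect_equal(res$rel_copy_number[res$sample_id == "S2"], 10,
               tolerance = 1e-6)   # target Ct one |slope| lower

  # mixed table vs an explicit spreadsheet-style walk through quantities
  mixed <- data.frame(
    sample_id = c("REF", "REF", "A", "A", "B", "B"),
    assay = rep(c("Met", "Actl6a"), 3),
    ct = c(21.3, 20.1, 19.7, 20.4, 23.2, 19.9)
  )
  res2 <- relative_copy_number(make_ct_table(mixed, curves),
                               "Met", "Actl6a", "REF")
  q <- function(ct, a) 10^((ct - curves[[a]]$intercept) / curves[[a]]$slope)
  ref_ratio <- q(21.3, "Met") / q(20.1, "Actl6a")
  expect_equal(res2$rel_copy_number[res2$sample_id == "A"],
               (q(19.7, "Met") / q(20.4, "Actl6a")) / ref_ratio,
               tolerance = 1e-12)
  expect_equal(res2$rel_copy_number[res2$sample_id == "B"],
               (q(23.2, "Met") / q(19.9, "Actl6a")) / ref_ratio,
               tolerance = 1e-12)
})

test_that("a constant Ct offset on one assay is absorbed by its refit curve", {
  ct <- simulate_qpcr(c(REF = 1, S1 = 3, S2 = 7), noise_sd = 0, seed = 1)
  res <- relative_copy_number(ct, "Met", "Actl6a", "REF")
  ct2 <- ct
  shift <- ct2$assay == "Met"   # offset all Met wells, standards included
  ct2$ct[shift] <- ct2$ct[shift] + 1.7
  res2 <- relative_copy_number(ct2, "Met", "Actl6a", "REF")
  expect_equal(res2$rel_copy_number, res$rel_copy_number, tolerance = 1e-9)
})

test_that("technical replicates are collapsed by mean Ct", {
  ct <- simulate_qpcr(c(REF = 1, S1 = 2), noise_sd = 0.05, replicates = 3,
                      seed = 11)
  res <- relative_copy_number(ct, "Met", "Actl6a", "REF")
  expect_equal(nrow(res), 2L)
  expect_equal(res$rel_copy_number[res$sample_id == "REF"], 1)
})

test_that("relative_copy_number precondition errors", {
  curves <- list(Met = list(slope = -3.3219, intercept = 25),
                 Actl6a = list(slope = -3.3219, intercept = 24))
  tab <- make_ct_table(data.frame(sample_id = c("REF", "REF"),
                                  assay = c("Met", "Actl6a"),
                                  ct = c(20, 19)), curves)
  expect_error(relative_copy_number(tab, "Kras", "Actl6a", "REF"),
               "missing assay")
  expect_error(relative_copy_number(tab, "Met", "Actl6a", "S9"),
               "reference sample")
})

test_that("summarize_fish constants, loop oracle, and boundary at 4", {
  diploid <- simulate_fish_cells(110, 2, 2, seed = 1)
  s <- suppressWarnings(summarize_fish(diploid))
  expect_equal(s$ratio, 1.0)
  expect_equal(s$pct_gt4, 0)
  expect_equal(s$mean_target, 2.0)

  amp <- simulate_fish_cells(100, 9, 2, seed = 1)
  s9 <- summarize_fish(amp)
  expect_equal(s9$ratio, 4.5)
  expect_equal(s9$pct_gt4, 100)
  expect_equal(s9$mean_target, 9.0)

  # mixed 10-cell table against a brute-force loop
  cells <- data.frame(
    cell_id = sprintf("c%02d", 1:10),
    target_count = c(2L, 3L, 9L, 4L, 5L, 0L, 7L, 2L, 4L, 6L),
    cen_count = c(2L, 2L, 3L, 2L, 1L, 2L, 2L, 4L, 2L, 2L)
  )
  s10 <- suppressWarnings(summarize_fish(cells))
  tot_t <- 0; tot_c <- 0; n_gt4 <- 0
  for (i in 1:10) {
    tot_t <- tot_t + cells$target_count[i]
    tot_c <- tot_c + cells$cen_count[i]
    if (cells$target_count[i] > 4) n_gt4 <- n_gt4 + 1
  }
  expect_equal(s10$ratio, (tot_t / 10) / (tot_c / 10))
  expect_equal(s10$pct_gt4, 100 * n_gt4 / 10)
  expect_equal(s10$mean_target, tot_t / 10)
  # strict > 4: the two cells at exactly 4 are not counted
  expect_equal(sum(cells$target_count == 4), 2)
  expect_equal(n_gt4, 4)
  expect_equal(s10$pct_gt4, 40)

  # row order is irrelevant
  s_perm <- suppressWarnings(summarize_fish(cells[10:1, ]))
  expect_equal(s_perm$ratio, s10$ratio)
  expect_equal(s_perm$pct_gt4, s10$pct_gt4)

  # mean of per-cell ratios as the alternative convention
  s_mor <- suppressWarnings(summarize_fish(cells,
                                           ratio_method = "mean_of_ratios"))
  expect_equal(s_mor$ratio, mean(cells$target_count / cells$cen_count))

  expect_error(summarize_fish(cells[0, ]), "empty")
  zero <- data.frame(cell_id = "c1", target_count = 3L, cen_count = 0L)
  expect_error(suppressWarnings(summarize_fish(zero)), "centromere")
  expect_warning(summarize_fish(cells[1:5, ]), ">= 100")
})
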