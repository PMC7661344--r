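spot_row <- function(slide = "S1", block = "B1", lectin = "L1",
                     fg = 300, bg = 100, condition = NULL) {
  t <- tibble::tibble(slide = slide, block = block, lectin = lectin,
                      foreground = fg, background = bg)
  if (!is.null(condition)) t <- dplyr::mutate(t, condition = condition)
  t
}

test_that("background subtraction removes the scope-mean background", {
  spots <- dplyr::bind_rows(
    spot_row(fg = 300, bg = 90),
    spot_row(lectin = "L2", fg = 150, bg = 110)
  )
  out <- subtract_background(spots)
  expect_equal(out$bg_mean, c(100, 100))
  expect_equal(out$corrected, c(200, 50))

  # zero background: corrected equals foreground
  z <- subtract_background(dplyr::mutate(spots, background = 0))
  expect_equal(z$corrected, z$foreground)
})

test_that("per-slide and per-block scopes differ by the block-mean difference", {
  spots <- dplyr::bind_rows(
    spot_row(block = "B1", fg = 500, bg = 100),
    spot_row(block = "B2", fg = 500, bg = 200)
  )
  by_block <- suppressWarnings(subtract_background(spots, scope = "block"))
  by_slide <- subtract_background(spots, scope = "slide")
  # slide mean is 150; block means 100 and 200
  expect_equal(by_slide$corrected - by_block$corrected, c(-50, 50))
})

test_that("effectiveness filter applies the mean + k*SD rule", {
  # backgrounds {90, 100, 110}: mean 100, sd 10
  spots <- dplyr::bind_rows(
    spot_row(fg = 115, bg = 90),
    spot_row(lectin = "L2", fg = 130, bg = 100),
    spot_row(lectin = "L3", fg = 120, bg = 110)
  )
  out <- flag_effective(subtract_background(spots), k = 2)
  expect_equal(out$effective, c(FALSE, TRUE, TRUE))
  # raising k never increases the number of effective spots
  n_eff <- vapply(c(0, 1, 2, 3, 5), function(k)
    sum(flag_effective(subtract_background(spots), k = k)$effective),
    numeric(1))
  expect_true(all(diff(n_eff) <= 0))
  expect_error(flag_effective(spots), "subtract_background")
})

test_that("single background reading warns and uses SD 0", {
  expect_warning(out <- subtract_background(spot_row()), "SD undefined")
  expect_equal(out$bg_sd, 0)
})

test_that("block normalization divides medians by their block sum", {
  spots <- dplyr::bind_rows(
    spot_row(lectin = "L1", fg = 130, bg = 0),
    spot_row(lectin = "L2", fg = 170, bg = 0)
  ) |>
    dplyr::mutate(background = c(0, 0))
  prof <- spots |>
    subtract_background() |>
    flag_effective() |>
    normalize_blocks()
  expect_equal(sort(prof$nfi), c(130, 170) / 300)

  single <- suppressWarnings(subtract_background(spot_row(fg = 500, bg = 0))) |>
    flag_effective() |>
    normalize_blocks()
  expect_equal(single$nfi, 1)
})

test_that("NFIs sum to one in every block and are scale-invariant", {
  withr::with_seed(13, {
    spots <- tidyr::expand_grid(
      slide = paste0("S", 1:10), block = paste0("B", 1:10),
      lectin = paste0("L", 1:8), rep = 1:3
    ) |>
      dplyr::mutate(foreground = runif(dplyr::n(), 200, 5000),
                    background = runif(dplyr::n(), 50, 150)) |>
      dplyr::select(-rep)
  })
  prof <- spots |>
    subtract_background() |>
    flag_effective() |>
    normalize_blocks()
  sums <- prof |>
    dplyr::group_by(slide, block) |>
    dplyr::summarise(s = sum(nfi), .groups = "drop")
  expect_equal(nrow(sums), 100)
  expect_true(all(abs(sums$s - 1) < 1e-12))

  # scaling one block's foregrounds leaves its profile unchanged
  scaled <- dplyr::mutate(
    spots,
    foreground = ifelse(slide == "S1" & block == "B1",
                        foreground * 7, foreground),
    background = ifelse(slide == "S1" & block == "B1",
                        background * 7, background))
  p2 <- scaled |> subtract_background() |> flag_effective() |>
    normalize_blocks()
  b1 <- dplyr::filter(prof, slide == "S1", block == "B1") |>
    dplyr::arrange(lectin)
  b2 <- dplyr::filter(p2, slide == "S1", block == "B1") |>
    dplyr::arrange(lectin)
  expect_equal(b1$nfi, b2$nfi)
})

test_that("aggregation averages the nine block replicates per lectin", {
  sim <- sim_lectin_dataset(noise_cv = 0, bg_sd = 0, seed = 2)
  res <- lectin_analyze(sim$spots)
  expect_true(all(res$summaries$n_blocks == 9))
  expect_true(all(res$summaries$sd_nfi == 0)) # zero noise -> identical blocks

  prof <- tibble::tibble(
    condition = "c", slide = c("S1", "S1"), block = c("B1", "B2"),
    lectin = "L1", median_fi = c(1, 2), nfi = c(0.1, 0.2)
  )
  agg <- aggregate_lectins(prof)
  expect_equal(agg$mean_nfi, 0.15)
})

test_that("zero-noise planted folds are recovered exactly after normalization", {
  folds <- c("UEA-I" = 0.4, WFA = 2.5)
  sim <- sim_lectin_dataset(true_folds = folds, noise_cv = 0, bg_sd = 0,
                            seed = 5)
  res <- lectin_analyze(sim$spots)
  got <- dplyr::filter(tidy(res$differential), tier == "STRICT") |>
    dplyr::left_join(sim$truth, by = "lectin")
  expect_equal(got$fold_change, got$expected_nfi_fold, tolerance = 1e-12)
  # with no planted change and no noise the fold is exactly 1
  sim1 <- sim_lectin_dataset(noise_cv = 0, bg_sd = 0, seed = 6)
  d1 <- lectin_analyze(sim1$spots)$differential
  expect_true(all(abs(d1$fold_change - 1) < 1e-12))
  expect_true(all(d1$call == "UNCHANGED"))
})

test_that("differential calls follow fold and significance criteria by tier", {
  # crafted paired block NFIs: clear up, clear down, unchanged lectins
  base <- tidyr::expand_grid(slide = paste0("S", 1:3),
                             block = paste0("B", 1:3))
  noise <- withr::with_seed(8, runif(9, -0.001, 0.001))
  prof <- dplyr::bind_rows(
    dplyr::mutate(base, condition = "control", lectin = "up",
                  median_fi = 1, nfi = 0.10 + noise),
    dplyr::mutate(base, condition = "treatment", lectin = "up",
                  median_fi = 1, nfi = 0.22 + noise),
    dplyr::mutate(base, condition = "control", lectin = "down",
                  median_fi = 1, nfi = 0.10 + noise),
    dplyr::mutate(base, condition = "treatment", lectin = "down",
                  median_fi = 1, nfi = 0.04 + noise),
    dplyr::mutate(base, condition = "control", lectin = "flat",
                  median_fi = 1, nfi = 0.10 + noise),
    dplyr::mutate(base, condition = "treatment", lectin = "flat",
                  median_fi = 1, nfi = 0.10 + noise)
  )
  calls <- differential_glycans(prof)
  strict <- dplyr::filter(tidy(calls), tier == "STRICT")
  expect_equal(strict$call[strict$lectin == "up"], "UP")       # fold 2.2
  expect_equal(strict$call[strict$lectin == "down"], "DOWN")   # fold 0.4
  expect_equal(strict$call[strict$lectin == "flat"], "UNCHANGED")

  # REPORTED tier is looser: fold 1.8 is UP there but not at STRICT
  prof18 <- dplyr::bind_rows(
    dplyr::mutate(base, condition = "control", lectin = "mid",
                  median_fi = 1, nfi = 0.10 + noise),
    dplyr::mutate(base, condition = "treatment", lectin = "mid",
                  median_fi = 1, nfi = 0.18 + noise)
  )
  c18 <- tidy(differential_glycans(prof18))
  expect_equal(c18$call[c18$tier == "STRICT"], "UNCHANGED")
  expect_equal(c18$call[c18$tier == "REPORTED"], "UP")
})

test_that("an insignificant fold change is not called", {
  base <- tidyr::expand_grid(slide = paste0("S", 1:3),
                             block = paste0("B", 1:3))
  wild <- withr::with_seed(9, runif(9, -0.08, 0.08))
  prof <- dplyr::bind_rows(
    dplyr::mutate(base, condition = "control", lectin = "noisy",
                  median_fi = 1, nfi = pmax(0.01, 0.10 + wild)),
    dplyr::mutate(base, condition = "treatment", lectin = "noisy",
                  median_fi = 1, nfi = pmax(0.01, 0.25 - wild))
  )
  calls <- tidy(differential_glycans(prof))
  p <- calls$p_value[calls$tier == "STRICT"]
  if (p >= 0.05) {
    expect_equal(calls$call[calls$tier == "STRICT"], "UNCHANGED")
  } else {
    succeed()
  }
})

test_that("planted UP/DOWN lectins are called correctly under 5 % spot noise", {
  folds <- c("UEA-I" = 0.4, WFA = 2.5)
  ok <- vapply(1:20, function(s) {
    sim <- sim_lectin_dataset(true_folds = folds, noise_cv = 0.05, seed = s)
    strict <- dplyr::filter(tidy(lectin_analyze(sim$spots)$differential),
                            tier == "STRICT")
    flagged <- dplyr::filter(strict, call %in% c("UP", "DOWN"))
    nrow(flagged) == 2 &&
      identical(flagged$call[flagged$lectin == "UEA-I"], "DOWN") &&
      identical(flagged$call[flagged$lectin == "WFA"], "UP")
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("generator rejects invalid noise and fold parameters", {
  expect_error(sim_lectin_dataset(noise_cv = -0.1), "noise_cv")
  expect_error(sim_lectin_dataset(bg_sd = -1), "bg_sd")
  expect_error(sim_lectin_dataset(true_folds = c(WFA = -2)), "> 0")
  expect_error(sim_lectin_dataset(true_folds = c(NOPE = 2)), "unknown lectin")
})
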