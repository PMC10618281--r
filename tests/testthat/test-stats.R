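eval_row <- function(source, target, dataset, value) {
  tibble::tibble(source = source, target = target, dataset = dataset,
                 rate_cor_all = value, rate_cor_inh = value / 2,
                 rate_cor_exc = value / 3, sharp_q1 = value * 2,
                 sharp_q3 = value * 4)
}

test_that("cross-generation grids average the two datasets elementwise", {
  evals <- dplyr::bind_rows(
    eval_row("A", "A", 1, 0.9), eval_row("A", "B", 1, 0.5),
    eval_row("B", "A", 1, 0.4), eval_row("B", "B", 1, 0.8),
    eval_row("A", "A", 2, 0.7), eval_row("A", "B", 2, 0.3),
    eval_row("B", "A", 2, 0.6), eval_row("B", "B", 2, 1.0)
  )
  m <- build_matrix(evals)
  expect_true(m$averaged)
  expect_equal(m$metrics$rate_cor_all["A", "A"], 0.8)
  expect_equal(m$metrics$rate_cor_all["A", "B"], 0.4)
  expect_equal(m$metrics$sharp_q1["B", "B"], mean(c(0.8, 1.0)) * 2)

  single <- build_matrix(eval_row("A", "A", 1, 0.9))
  expect_false(single$averaged)
  expect_equal(single$metrics$rate_cor_all["A", "A"], 0.9)

  # diagonal-only input leaves off-diagonal pairs missing
  diag_only <- build_matrix(dplyr::bind_rows(eval_row("A", "A", 1, 1),
                                             eval_row("B", "B", 1, 1)))
  expect_true(is.na(diag_only$metrics$rate_cor_all["A", "B"]))

  expect_error(build_matrix(dplyr::bind_rows(eval_row("A", "A", 1, 1),
                                             eval_row("A", "A", 1, 2))),
               "duplicate")
})

test_that("cluster sorting keeps planted blocks contiguous and is a permutation", {
  regions <- paste0("R", 1:6)
  g <- matrix(0.1, 6, 6, dimnames = list(regions, regions))
  block1 <- c("R1", "R3", "R5")
  block2 <- c("R2", "R4", "R6")
  g[block1, block1] <- 0.9
  g[block2, block2] <- 0.8
  evals <- purrr::pmap_dfr(expand.grid(s = regions, t = regions,
                                       stringsAsFactors = FALSE),
                           function(s, t) eval_row(s, t, 1, g[s, t]))
  m <- build_matrix(evals)
  ord <- cluster_sort(m, "rate_cor_all")
  expect_setequal(ord, regions)
  pos1 <- sort(match(block1, ord))
  pos2 <- sort(match(block2, ord))
  expect_equal(diff(range(pos1)), 2L)  # block members are adjacent
  expect_equal(diff(range(pos2)), 2L)
  expect_identical(ord, cluster_sort(m, "rate_cor_all"))  # deterministic

  # reordering rows and columns preserves the multiset of grid values
  sorted <- m$metrics$rate_cor_all[ord, ord]
  expect_equal(sort(as.vector(sorted)), sort(as.vector(m$metrics$rate_cor_all)))

  one <- build_matrix(eval_row("A", "A", 1, 1))
  expect_equal(cluster_sort(one, "rate_cor_all"), "A")

  holes <- build_matrix(eval_row("A", "B", 1, 1))
  expect_error(cluster_sort(holes, "rate_cor_all"), "missing")
})

test_that("Mann-Whitney p values agree with exhaustive rank enumeration", {
  set.seed(8)
  for (k in 1:25) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    x <- runif(n1)
    y <- runif(n2) + runif(1, -0.5, 0.5)
    got <- wilcox.test(x, y, exact = TRUE)$p.value
    oracle <- mann_whitney_exact(x, y)
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("anatomy comparisons test angle groups and strength correlations", {
  regions <- paste0("R", 1:5)
  set.seed(21)
  # planted effect: metric equals strength plus small noise over 20+ pairs
  grid <- expand.grid(source = regions, target = regions,
                      stringsAsFactors = FALSE)
  strength <- runif(nrow(grid), 0, 5)
  value <- strength + rnorm(nrow(grid), 0, 0.3)
  evals <- purrr::pmap_dfr(cbind(grid, v = value), function(source, target, v) {
    eval_row(source, target, 1, v)
  })
  m <- build_matrix(evals)
  anatomy <- tibble::tibble(
    source = grid$source, target = grid$target,
    angle_score = ifelse(grid$source == grid$target, 0L, 1L),
    strength = strength, hemisphere = "L"
  )
  cmp <- compare_with_anatomy(m, anatomy, metric = "rate_cor_all",
                              hemisphere = "L")
  tests <- cmp$tests
  expect_true(all(tests$p_bonferroni >= tests$p_raw, na.rm = TRUE))
  expect_true(all(tests$p_bonferroni <= 1, na.rm = TRUE))
  pearson <- tests[tests$test == "pearson_strength", ]
  expect_gt(pearson$estimate, 0.9)
  expect_lt(pearson$p_bonferroni, 0.05)   # planted effect detected

  # metric identical across groups -> U test far from significant
  flat <- purrr::pmap_dfr(grid, function(source, target) {
    eval_row(source, target, 1, 0.5)
  })
  # add negligible jitter so the correlation is defined but tiny
  set.seed(22)
  flat$rate_cor_all <- flat$rate_cor_all + rnorm(nrow(flat), 0, 1e-6)
  cmp_flat <- compare_with_anatomy(build_matrix(flat), anatomy,
                                   metric = "rate_cor_all")
  u <- cmp_flat$tests[cmp_flat$tests$test == "mann_whitney_angle0_vs_angle1", ]
  expect_gt(u$p_raw, 0.5)

  # exact identity: metric equals strength -> Pearson r = 1
  ident <- purrr::pmap_dfr(cbind(grid, v = strength),
                           function(source, target, v) {
                             eval_row(source, target, 1, v)
                           })
  cmp_id <- compare_with_anatomy(build_matrix(ident), anatomy)
  expect_equal(
    cmp_id$tests$estimate[cmp_id$tests$test == "pearson_strength"], 1,
    tolerance = 1e-9)

  # groups that are too small are skipped, not crashed
  tiny <- anatomy[anatomy$source == "R1" & anatomy$target == "R1", ]
  cmp_tiny <- compare_with_anatomy(m, tiny)
  expect_true(cmp_tiny$tests$skipped[
    cmp_tiny$tests$test == "mann_whitney_angle0_vs_angle1"])
})

test_that("Bonferroni correction multiplies by four and caps at one", {
  regions <- c("A", "B", "C")
  grid <- expand.grid(source = regions, target = regions,
                      stringsAsFactors = FALSE)
  set.seed(30)
  evals <- purrr::pmap_dfr(grid, function(source, target) {
    eval_row(source, target, 1, runif(1))
  })
  anatomy <- tibble::tibble(source = grid$source, target = grid$target,
                            angle_score = ifelse(grid$source == grid$target,
                                                 0L, 1L),
                            strength = runif(nrow(grid)))
  cmp <- compare_with_anatomy(build_matrix(evals), anatomy)
  ok <- !is.na(cmp$tests$p_raw)
  expect_equal(cmp$tests$p_bonferroni[ok],
               pmin(1, 4 * cmp$tests$p_raw[ok]))
})

test_that("report bundles are deterministic and refuse accidental overwrite", {
  evals <- dplyr::bind_rows(
    eval_row("A", "A", 1, 0.9), eval_row("A", "B", 1, 0.5),
    eval_row("B", "A", 1, 0.4), eval_row("B", "B", 1, 0.8)
  )
  m <- build_matrix(evals)
  anatomy <- tibble::tibble(source = c("A", "A", "B", "B"),
                            target = c("A", "B", "A", "B"),
                            angle_score = c(0L, 1L, 1L, 0L),
                            strength = c(1, 2, 2, 1), hemisphere = "L")
  cmp <- compare_with_anatomy(m, anatomy, metric = "rate_cor_all")

  d1 <- file.path(withr::local_tempdir(), "out1")
  d2 <- file.path(withr::local_tempdir(), "out2")
  report_bundle(m, list(rate_cor_all = cmp), d1, seed = 1, figures = FALSE)
  report_bundle(m, list(rate_cor_all = cmp), d2, seed = 1, figures = FALSE)
  for (f in c("grid_rate_cor_all.csv", "anatomy_tests.json",
              "anatomy_pairs.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_error(report_bundle(m, list(), d1, figures = FALSE), "force")
  expect_silent(report_bundle(m, list(), d1, force = TRUE, figures = FALSE))
})
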