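test_that("relative yields are within-cell z-scores with degenerate cells flagged", {
  d <- data.frame(variety = c("A", "B", "C", "D", "E", "F"),
                  site = c("X", "X", "X", "Y", "Y", "Y"),
                  year = 2001L,
                  yield = c(10, 12, 14, 9, 9, 9))
  r <- relative_yields(d)
  expect_equal(r$rel_yield[1:3], c(-1, 0, 1))      # sample SD = 2
  expect_equal(r$rel_yield[4:6], c(0, 0, 0))       # zero-variance cell
  expect_false(any(r$cell_degenerate[1:3]))
  expect_true(all(r$cell_degenerate[4:6]))

  # single-record cells are degenerate too
  d1 <- data.frame(variety = "A", site = "Z", year = 2001L, yield = 5)
  r1 <- relative_yields(d1)
  expect_equal(r1$rel_yield, 0)
  expect_true(r1$cell_degenerate)
})

test_that("cell moments match a two-pass oracle over many random cells", {
  set.seed(101)
  n_cells <- 200
  d <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    n <- sample(2:8, 1)
    data.frame(variety = paste0("v", seq_len(n)),
               site = paste0("s", i %% 20), year = 2000L + i %/% 20,
               yield = abs(rnorm(n, 10, 2)))
  }))
  r <- relative_yields(d)
  for (cell in split(r, cell_key <- paste(r$site, r$year))) {
    if (any(cell$cell_degenerate)) next
    m <- moments_oracle(cell$rel_yield)
    expect_lt(abs(m$mean), 1e-9)
    expect_lt(abs(m$sd - 1), 1e-9)
  }
})

test_that("home sites are the argmax of mean relative yield with stated tie-break", {
  # singleton: only observed site is home
  d <- relative_yields(data.frame(variety = c("A", "B"), site = "X",
                                  year = 2001L, yield = c(1, 2)))
  hm <- assign_home(d)
  expect_equal(hm$home$home_site, c("X", "X"))

  # argmax over the mean_rel matrix, checked by brute force
  rel <- data.frame(variety = "V", site = c("s1", "s1", "s2"),
                    year = c(2001L, 2002L, 2001L), yield = 0,
                    rel_yield = c(0.5, 0.7, 0.9), cell_degenerate = FALSE)
  hm <- assign_home(rel)
  means <- tapply(rel$rel_yield, rel$site, mean)
  expect_equal(hm$home$home_site, names(means)[which.max(means)])
  expect_equal(hm$home$home_site, "s2")
  expect_equal(hm$home$mean_rel_at_home, 0.9)

  # exact tie -> lexicographically smallest site id
  rel <- data.frame(variety = "V", site = c("zz", "aa"), year = 2001L,
                    yield = 0, rel_yield = c(0.4, 0.4), cell_degenerate = FALSE)
  expect_equal(assign_home(rel)$home$home_site, "aa")

  # varieties under min_cells are excluded, not an error
  rel <- relative_yields(toy_trials())
  expect_message(hm <- assign_home(rel, min_cells = 3L), "excluded")
  expect_false("D" %in% hm$home$variety)
  expect_true("D" %in% hm$dropped)
})

test_that("assignment is invariant to per-cell affine maps and record order", {
  sim <- generate_trials(small_params(7, delta = 0.5))
  d <- sim$trials
  hm0 <- assign_home(relative_yields(d))

  # per-cell affine transform of raw yields leaves z-scores and homes alone
  d2 <- d
  set.seed(7)
  for (cell in split(seq_len(nrow(d2)), paste(d2$site, d2$year))) {
    a <- runif(1, 0.5, 3); b <- runif(1, 0, 5)
    d2$yield[cell] <- a * d2$yield[cell] + b
  }
  hm2 <- assign_home(relative_yields(d2))
  expect_equal(hm2$home, hm0$home)

  # shuffling record order changes nothing
  set.seed(8)
  d3 <- d[sample(nrow(d)), , drop = FALSE]
  hm3 <- assign_home(relative_yields(d3))
  expect_equal(hm3$home, hm0$home)
})

test_that("a strong planted home premium is recovered for nearly all varieties", {
  hits <- 0L; total <- 0L
  for (seed in 1:3) {
    # large cells keep the within-cell z-scores from saturating (a z-score in
    # a cell of m records is bounded by (m-1)/sqrt(m)), so a dominant premium
    # separates the home site cleanly
    sim <- generate_trials(small_params(seed, delta = 3, sigma_e = 0.2,
                                        sigma_g = 0.2, vpc = 8L,
                                        n_varieties = 16L, n_years = 4L,
                                        n_sites = 4L, ypv = 4L))
    hm <- assign_home(relative_yields(sim$trials))
    est <- setNames(hm$home$home_site, hm$home$variety)
    truth <- sim$truth$home
    hits <- hits + sum(est[names(truth)] == truth, na.rm = TRUE)
    total <- total + length(truth)
  }
  expect_gte(hits / total, 0.95)
})

test_that("home maps export as TSV", {
  hm <- assign_home(relative_yields(toy_trials()))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_home_map(hm, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$variety, hm$home$variety)
  expect_equal(back$home_site, hm$home$home_site)
})
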