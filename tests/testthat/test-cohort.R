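test_that("the tissue template is deterministic, symmetric, and contains all tissues", {
  tpl <- generate_tissue_template(c(24, 28, 24))
  expect_setequal(unique(as.vector(tpl)), 0:3)
  counts <- tabulate(tpl + 1L, 4L)
  expect_true(all(counts[2:4] > 0))
  # mirror symmetry across the midsagittal plane
  expect_equal(tpl[24:1, , ], tpl)
  # deterministic given shape, whatever the seed
  expect_identical(generate_tissue_template(c(24, 28, 24), seed = 7),
                   generate_tissue_template(c(24, 28, 24), seed = 8))
  expect_error(generate_tissue_template(c(4, 4, 4)), "too small")
  expect_error(generate_tissue_template(c(13, 12, 12)), "even")
})

test_that("lesions are connected, left-hemisphere, and uniform in size", {
  tpl <- generate_tissue_template(c(16, 16, 16))
  m <- sample_lesion(tpl, c(40, 40), seed = 3)
  expect_equal(sum(m), 40)
  # connectivity: breadth-first flood from any lesion voxel covers the mask
  idx <- which(m)
  visited <- rep(FALSE, length(idx))
  frontier <- idx[1]; seen <- frontier
  d <- dim(m)
  while (length(frontier) > 0) {
    nxt <- unique(unlist(lapply(frontier, function(v) {
      vi <- arrayInd(v, d)
      nb <- c(v - 1, v + 1, v - d[1], v + d[1], v - d[1] * d[2], v + d[1] * d[2])
      ok <- nb >= 1 & nb <= prod(d)
      nb[ok]
    })))
    nxt <- nxt[m[nxt] & !(nxt %in% seen)]
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  expect_setequal(seen, idx)
  # many draws stay in the left hemisphere and sizes look uniform
  set.seed(9)
  sizes <- replicate(300, {
    mk <- sample_lesion(tpl, c(10, 200))
    expect_true(all(which(mk, arr.ind = TRUE)[, 1] <= 8))
    sum(mk)
  })
  ks <- suppressWarnings(
    stats::ks.test(sizes + runif(300, -0.5, 0.5), "punif", 9.5, 200.5))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_lesion(tpl, c(1e5, 1e5)), "exceeds")
})

test_that("atrophy planting converts exactly n GM voxels and arrangements differ", {
  tpl <- generate_tissue_template(c(16, 16, 16))
  gm0 <- sum(tpl == 2)
  focal <- atrophy_motif("focal", "clustered")
  diffuse <- atrophy_motif("diffuse", "dispersed")
  # n = 0 is the identity
  expect_identical(plant_atrophy(tpl, focal, 0, seed = 1), tpl)
  # matched totals: both arrangements remove exactly 30 GM voxels
  a <- plant_atrophy(tpl, focal, 30, seed = 2)
  b <- plant_atrophy(tpl, diffuse, 30, seed = 2)
  expect_equal(sum(a == 2), gm0 - 30)
  expect_equal(sum(b == 2), gm0 - 30)
  expect_equal(sum(a == 2), sum(b == 2))
  # dispersed conversions are farther apart on average than clustered ones
  mean_pairdist <- function(orig, mod) {
    ix <- which(orig == 2 & mod == 1, arr.ind = TRUE)
    mean(dist(ix))
  }
  expect_gt(mean_pairdist(tpl, b), mean_pairdist(tpl, a))
  expect_error(plant_atrophy(tpl, focal, 1e6), "insufficient")
})

test_that("outcomes follow the clipped linear model and the severity cut points", {
  cfg <- tiny_cohort_config()
  benign <- atrophy_motif("x", "dispersed", harmful = FALSE)
  harmful <- atrophy_motif("y", "clustered", harmful = TRUE)
  # sigma=0, a=0, b=0 -> perfect score
  cfg0 <- cfg; cfg0$outcome_coefficients <- c(a = 0, b = 0, sigma = 0)
  o <- assign_outcome(100, benign, cfg0, n_left_brain = 1000, seed = 1)
  expect_equal(o$wab_aq, 100)
  expect_equal(o$label2, "nonsevere")
  expect_equal(o$category4, "mild")
  # a*fraction + b = 60 for a harmful-motif subject -> wab 40, severe
  cfg1 <- cfg; cfg1$outcome_coefficients <- c(a = 100, b = 40, sigma = 0)
  o1 <- assign_outcome(200, harmful, cfg1, n_left_brain = 1000, seed = 1)
  expect_equal(o1$wab_aq, 40)
  expect_equal(o1$label2, "severe")
  expect_equal(o1$category4, "severe")
  # category cut points at 25/50/75
  expect_equal(wab_category(c(10, 25.0, 30, 50, 60, 75, 80)),
               c("very severe", "very severe", "severe", "severe",
                 "moderate", "moderate", "mild"))
})

test_that("default calibration lands near the 35% severe prevalence", {
  # outcome-model simulation at n=2000 under the default coefficients
  cfg <- cohort_config()
  tpl <- generate_tissue_template(cfg$grid_shape)
  n_left <- sum(tpl != 0) / 2
  set.seed(11)
  sizes <- sample(cfg$lesion_volume_range[1]:cfg$lesion_volume_range[2],
                  2000, TRUE)
  harm <- runif(2000) < 0.5
  co <- cfg$outcome_coefficients
  wab <- pmin(100, pmax(0, 100 - co[["a"]] * sizes / n_left -
                          co[["b"]] * harm + rnorm(2000, 0, co[["sigma"]])))
  expect_gt(mean(wab <= 50), 0.32)
  expect_lt(mean(wab <= 50), 0.38)
})

test_that("cohorts are reproducible, complete, and near the prevalence target", {
  cfg <- tiny_cohort_config(seed = 5, n = 60, grid = c(16, 16, 16))
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(object_hash(co1), object_hash(co2))
  expect_length(co1$subjects, 60)
  tab <- cohort_table(co1)
  expect_true(all(tab$label2 == ifelse(tab$wab_aq <= 50, "severe", "nonsevere")))
  # lesions confined to the left hemisphere
  for (s in co1$subjects[1:5])
    expect_true(all(which(s$lesion_mask, arr.ind = TRUE)[, 1] <= 8))
  # motif ground truth recorded
  expect_true(all(tab$motif_id %in% c("focal", "diffuse")))
})

test_that("the default-config cohort shows all four categories and a ~35% severe fraction", {
  co <- generate_cohort(cohort_config(seed = 2))
  tab <- cohort_table(co)
  expect_equal(nrow(tab), 231)
  expect_setequal(unique(tab$category4),
                  c("very severe", "severe", "moderate", "mild"))
  frac <- mean(tab$label2 == "severe")
  expect_gte(frac, 0.30)
  expect_lte(frac, 0.40)
})

test_that("motif id is independent of the label when the motif coefficient is zero", {
  ps <- vapply(1:6, function(s) {
    cfg <- cohort_config(n_subjects = 150, grid_shape = c(16, 16, 16),
                         lesion_volume_range = c(10, 80), atrophy_voxels = 12,
                         outcome_coefficients = c(a = 600, b = 0, sigma = 10),
                         seed = s)
    tab <- cohort_table(generate_cohort(cfg))
    suppressWarnings(
      stats::chisq.test(table(tab$motif_id, tab$label2))$p.value)
  }, numeric(1))
  # no systematic association across seeds
  expect_gt(mean(ps > 0.05), 0.5)
  expect_gt(max(ps), 0.2)
})

test_that("cohorts serialize to NIfTI + CSV + JSON", {
  cfg <- tiny_cohort_config(seed = 3, n = 4)
  co <- generate_cohort(cfg)
  d <- tempfile()
  write_cohort(co, d)
  expect_true(file.exists(file.path(d, "participants.csv")))
  expect_true(file.exists(file.path(d, "config.json")))
  expect_length(list.files(d, pattern = "nii"), 4)
  v <- read_volume_nifti(file.path(d, "sub-0001.nii.gz"))
  expect_equal(v$grid, co$subjects[[1]]$volume$grid)
  unlink(d, recursive = TRUE)
})
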