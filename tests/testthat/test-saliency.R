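test_that("Grad-CAM++ reduces to the class-activation map for a GAP-linear head", {
  set.seed(5)
  net <- toy_net(c(8, 8, 8), seed = 11, scale = 0.3)
  set.seed(2)
  wlin <- matrix(runif(16, 0, 0.5), 2, 8)
  gnet <- gap_linear_net(net, wlin)
  am <- asNamespace("aphasiamorph")
  for (i in 1:3) {
    x <- array(rnorm(512, 0, 0.5), c(8, 8, 8))
    sal <- gradcampp(gnet, x, target_class = 2)
    fw <- am$net_forward(gnet, am$volumes_to_input(list(x), c(8, 8, 8)), FALSE)
    A <- fw$acts[[gnet$last_conv_relu_ix]][, , 1]
    cam <- pmax(colSums(wlin[2, ] * A), 0)
    conv_dims <- dim(x)  # single pool removed; feature grid = block dims
    conv_dims <- gnet$layers[[gnet$last_conv_relu_ix - 1]]$dims
    cam_up <- am$upsample_trilinear(array(cam, conv_dims), c(8, 8, 8))
    cosine <- sum(sal$grid * cam_up) /
      sqrt(sum(sal$grid^2) * sum(cam_up^2))
    expect_gt(cosine, 0.99)
    expect_true(all(sal$grid >= 0))
  }
})

test_that("Grad-CAM++ handles degenerate zero-gradient networks", {
  net <- toy_net(c(8, 8, 8))
  # zero the head: class scores are constant, gradients vanish
  last_fc <- length(net$layers)
  net$layers[[last_fc]]$W[] <- 0
  expect_warning(sal <- gradcampp(net, array(0, c(8, 8, 8)), 2), "zero")
  expect_true(all(sal$grid == 0))
})

test_that("deep SHAP matches the closed form for a linear model and vanishes at the baseline", {
  set.seed(6)
  W <- matrix(rnorm(2 * 27), 2, 27)
  net <- linear_net(c(3, 3, 3), W, b = c(0.3, -0.2))
  x <- array(rnorm(27), c(3, 3, 3))
  bg <- lapply(1:5, function(i) array(rnorm(27), c(3, 3, 3)))
  ds <- deep_shap(net, x, bg, target_class = 2)
  bgmean <- Reduce(`+`, bg) / 5
  expect_equal(unclass(ds), array(W[2, ], c(3, 3, 3)) * (x - bgmean),
               ignore_attr = TRUE, tolerance = 1e-12)
  # completeness: attributions sum to score(x) - mean background score
  comp <- attr(ds, "completeness")
  expect_equal(unname(comp["attr_sum"]), unname(comp["score_delta"]),
               tolerance = 1e-10)
  # x equal to the single background sample -> zero attributions
  ds0 <- deep_shap(net, x, list(x), 2)
  expect_true(all(ds0 == 0))
})

test_that("deep SHAP completeness holds on a pooling-free conv-relu network", {
  set.seed(7)
  spec <- architecture_spec(blocks = list(c(1, 8), c(1, 8)), dropout_rate = 0)
  net <- build_network(spec, c(6, 6, 6), seed = 4)
  # drop the pooling layers (argmax routing breaks exact completeness);
  # rebuild the head on the unpooled grid
  types <- vapply(net$layers, `[[`, "", "type")
  conv_relu <- net$layers[types %in% c("conv", "relu")]
  for (i in seq_along(conv_relu))
    if (conv_relu[[i]]$type == "conv") {
      conv_relu[[i]]$dims <- c(6L, 6L, 6L)
      conv_relu[[i]]$W <- conv_relu[[i]]$W * 0.2
    }
  ly <- conv_relu
  ly[[length(ly) + 1]] <- list(type = "flatten", c = 8, dims = c(6, 6, 6))
  set.seed(8)
  ly[[length(ly) + 1]] <- list(type = "fc",
                               W = matrix(rnorm(2 * 8 * 216, 0, 0.05), 2),
                               b = c(0, 0))
  net$layers <- ly
  x <- array(rnorm(216, 0, 0.5), c(6, 6, 6))
  bg <- lapply(1:3, function(i) array(rnorm(216, 0, 0.5), c(6, 6, 6)))
  ds <- deep_shap(net, x, bg, 2)
  comp <- attr(ds, "completeness")
  rng <- abs(comp["score_delta"])
  expect_lt(abs(comp["attr_sum"] - comp["score_delta"]),
            1e-2 * max(rng, 1))
})

test_that("kernel SHAP matches exhaustive Shapley enumeration on small models", {
  set.seed(9)
  dat <- matrix(rnorm(40), 20, 2)
  x <- c(1, -0.5)
  f <- function(M) M[, 1] + 2 * M[, 2]
  ks <- kernel_shap(f, x, dat, k_fraction = 1, n_draws = 100, seed = 2)
  v <- function(S) shap_coalition_value(f, x, dat, S, k = 20)
  phi1 <- 0.5 * ((v(c(TRUE, FALSE)) - v(c(FALSE, FALSE))) +
                   (v(c(TRUE, TRUE)) - v(c(FALSE, TRUE))))
  phi2 <- 0.5 * ((v(c(FALSE, TRUE)) - v(c(FALSE, FALSE))) +
                   (v(c(TRUE, TRUE)) - v(c(TRUE, FALSE))))
  expect_equal(as.vector(ks), c(phi1, phi2), tolerance = 1e-10)
  # a constant model attributes nothing
  kc <- kernel_shap(function(M) rep(3, nrow(M)), x, dat, 0.5, 10, seed = 1)
  expect_true(all(kc == 0))
  # exchangeable identical features receive equal attribution in expectation
  g <- function(M) M[, 1] + M[, 2]
  z <- rnorm(30)
  dats <- cbind(z, z)   # exchangeable features with identical values
  ks2 <- kernel_shap(g, c(0.7, 0.7), dats, k_fraction = 1, n_draws = 300,
                     seed = 3)
  expect_lt(abs(ks2[1] - ks2[2]), 0.05)
  expect_warning(kernel_shap(g, c(0.7, 0.7), dats, 1, n_draws = 1, seed = 1),
                 "noisy")
})

test_that("rectification and normalization behave on signed, positive and zero maps", {
  m <- array(c(-1, 1, 1, 0), c(4, 1, 1))
  r <- rectify_and_normalize(m)
  expect_equal(as.vector(r$grid), c(0, 0.5, 0.5, 0))
  expect_true(r$normalized)
  expect_equal(sum(r$grid), 1)
  m2 <- array(runif(8), c(2, 2, 2))
  r2 <- rectify_and_normalize(m2)
  expect_equal(r2$grid, m2 / sum(m2))
  z <- rectify_and_normalize(array(0, c(2, 2, 2)))
  expect_false(z$normalized)
  expect_true(all(z$grid == 0))
})

test_that("ROI partitions tile the left hemisphere and mirror to homologs", {
  tpl <- generate_tissue_template(c(12, 12, 12))
  brain <- tpl != 0
  lesion <- array(FALSE, c(12, 12, 12))
  lesion[3:4, 6:7, 6] <- brain[3:4, 6:7, 6]
  rois <- build_rois(lesion, brain, dilation_radius = 2)
  # pairwise disjoint
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(sum(rois[[i]] & rois[[j]]), 0)
  # left three tile the left-hemisphere brain
  left_brain <- brain & aphasiamorph:::left_hemi_mask(c(12, 12, 12))
  expect_equal(rois$lesion | rois$perilesional | rois$extralesional,
               left_brain)
  # homologs are midline reflections
  expect_equal(rois$lesion_homolog,
               aphasiamorph:::mirror_lr(rois$lesion) & !aphasiamorph:::left_hemi_mask(c(12, 12, 12)))
  # radius 0 leaves no perilesional shell
  rois0 <- build_rois(lesion, brain, dilation_radius = 0)
  expect_equal(sum(rois0$perilesional), 0)
  # single-voxel lesion, radius 1, 6-connectivity: perilesional = in-brain
  # face neighbours
  l1 <- array(FALSE, c(12, 12, 12)); l1[4, 6, 6] <- TRUE
  r1 <- build_rois(l1, brain, dilation_radius = 1, connectivity = 6)
  nb <- rbind(c(3, 6, 6), c(5, 6, 6), c(4, 5, 6), c(4, 7, 6),
              c(4, 6, 5), c(4, 6, 7))
  expected <- nb[apply(nb, 1, function(v) brain[v[1], v[2], v[3]]), , drop = FALSE]
  got <- which(r1$perilesional, arr.ind = TRUE)
  expect_equal(nrow(got), nrow(expected))
})

test_that("ROI group statistics detect planted differences and conserve saliency", {
  tpl <- generate_tissue_template(c(12, 12, 12))
  brain <- tpl != 0
  lesion <- array(FALSE, c(12, 12, 12))
  lesion[3:4, 6:7, 6] <- brain[3:4, 6:7, 6]
  rois <- build_rois(lesion, brain, dilation_radius = 1)
  set.seed(10)
  mk_map <- function(boost_lesion = 0) {
    g <- array(runif(12^3), c(12, 12, 12)) * brain
    g[lesion] <- g[lesion] + boost_lesion
    rectify_and_normalize(g)
  }
  maps <- c(lapply(1:8, function(i) mk_map(5)),
            lapply(1:8, function(i) mk_map(0)))
  groups <- rep(c("severe", "nonsevere"), each = 8)
  # conservation: the six ROI sums plus the out-of-mask remainder give 1
  vals <- roi_saliency(maps, rois)
  inmask <- rowSums(vals)
  remainder <- vapply(maps, function(m) {
    allroi <- Reduce(`|`, rois)
    sum(m$grid[!allroi])
  }, numeric(1))
  expect_equal(inmask + remainder, rep(1, 16), tolerance = 1e-12)
  st <- roi_group_test(maps, rois, groups)
  expect_equal(nrow(st), 6)
  # planted lesion-ROI difference is significant there and nowhere stronger
  expect_lt(st$p[st$roi == "lesion"], 0.001)
  expect_gt(st$mean_severe[st$roi == "lesion"],
            st$mean_nonsevere[st$roi == "lesion"])
  # identical maps in both groups give t = 0, p = 1
  same <- lapply(1:4, function(i) maps[[1]])
  st0 <- roi_group_test(c(same, same), rois, rep(c("severe", "nonsevere"), each = 4))
  expect_true(all(st0$t == 0))
  expect_true(all(st0$p == 1))
  expect_error(roi_group_test(maps[1:3], rois, c("severe", "severe", "nonsevere")),
               "at least 2")
})

test_that("the mean-performing repeat is the one closest to the mean F1", {
  expect_equal(mean_performing_repeat(c(0.5, 0.7, 0.9)), 2)
  expect_equal(mean_performing_repeat(c(0.6, 0.8)), 1)  # tie -> earlier
  expect_equal(mean_performing_repeat(0.4), 1)
})
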