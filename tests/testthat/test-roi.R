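# spherical ROIs, conjunction-derived ROIs, response extraction, comparisons

test_that("sphere membership follows the voxel-centre distance rule", {
  g <- acq_grid(c(20, 20, 16), voxel_size = c(2, 2, 2))
  ctr <- voxel_to_world(g, c(10, 10, 8))
  # radius below half the smallest voxel: exactly the centre voxel
  tiny <- sphere_roi(ctr, radius_mm = 0.9, grid = g)
  expect_identical(mask_size(tiny$membership), 1L)
  # 5 mm sphere on the 2 mm grid vs lattice enumeration
  roi5 <- sphere_roi(ctr, radius_mm = 5, grid = g)
  expect_identical(mask_size(roi5$membership), sphere_count_oracle(ctr, 5, g))
  # random centres and radii against the oracle
  set.seed(21)
  for (i in 1:10) {
    c_mm <- voxel_to_world(g, runif(3, 4, 12))
    r <- runif(1, 1.5, 6)
    roi <- sphere_roi(c_mm, r, g)
    expect_identical(mask_size(roi$membership),
                     sphere_count_oracle(c_mm, r, g))
  }
  # reflection symmetry through the grid centre
  mid <- voxel_to_world(g, (g$dims - 1) / 2)
  a <- sphere_roi(mid + c(6, 4, 2), 5, g)$membership$values
  b <- sphere_roi(mid - c(6, 4, 2), 5, g)$membership$values
  expect_identical(sum(a), sum(b))
  expect_identical(a[20:1, 20:1, 16:1], b)
  expect_error(sphere_roi(c(1e4, 0, 0), 5, g), "no voxel centre")
})

test_that("the a-priori catalogue builds 5 mm spheres at listed coordinates", {
  tab <- apriori_roi_catalog()
  expect_identical(nrow(tab), 16L)
  expect_true(all(c("L_striatum", "R_amygdala", "L_anterior_cingulate")
                  %in% tab$name))
  g <- acq_grid(c(64, 64, 38))
  rois <- apriori_rois(g)
  expect_length(rois, 16)
  expect_true(all(vapply(rois, function(r) r$radius_mm == 5, logical(1))))
  str <- rois[[which(tab$name == "L_striatum")]]
  expect_equal(str$center_mm, c(-12, 12, -6))
  expect_gt(mask_size(str$membership), 0)
})

test_that("conjunction ROIs honour exclusions and the periphery rule", {
  g <- tiny_grid(c(14, 8, 4))
  mk_map <- function(cells) {
    v <- array(0, g$dims)
    v[cells] <- 6
    stat_map(fmri_volume(v, g), df = 19)
  }
  # inclusive VME block at x 2:5, exclusive E-only voxel hugging it at x 6
  # and a far E-only block at x 11:13
  vme <- as.matrix(expand.grid(2:5, 3:5, 2))
  e_near <- cbind(6, 4, 2)
  e_far <- as.matrix(expand.grid(11:13, 3:4, 2))
  maps <- list(Value = mk_map(vme), Mathematical = mk_map(vme),
               Emotion = mk_map(rbind(vme, e_near, e_far)))
  parts <- partition_conjunctions(maps, voxel_p = 0.001, extent_k = 1)
  rois <- rois_from_conjunctions(parts, dilation_mm = 4)
  cats <- vapply(rois, function(r) r$category, character(1))
  expect_identical(sum(cats == "Value & Mathematical & Emotion"), 1L)
  e_rois <- rois[cats == "~Value & ~Mathematical & Emotion"]
  # the adjacent E voxel is eaten by the periphery rule; the far block stays
  expect_length(e_rois, 1)
  expect_identical(mask_size(e_rois[[1]]$membership), nrow(e_far))
  # ROIs from different categories never overlap
  overlap <- Reduce(`+`, lapply(rois, function(r) r$membership$values * 1L))
  expect_lte(max(overlap), 1L)
  # a cluster overlapping the excluded-structures mask is dropped wholesale
  excl <- array(FALSE, g$dims)
  excl[12, 3, 2] <- TRUE
  rois2 <- rois_from_conjunctions(parts, excluded_structures =
                                    fmri_mask(excl, g), dilation_mm = 4)
  cats2 <- vapply(rois2, function(r) r$category, character(1))
  expect_false("~Value & ~Mathematical & Emotion" %in% cats2)
})

test_that("one ROI per category appears when nothing is excluded", {
  g <- tiny_grid(c(16, 16, 6))
  # seven disjoint single-voxel activations, one per category, far apart
  spots <- rbind(c(2, 2, 2), c(6, 2, 2), c(10, 2, 2), c(14, 2, 2),
                 c(2, 10, 4), c(6, 10, 4), c(10, 10, 4))
  incl <- list(c(1, 2, 3), c(1, 2), c(1, 3), c(2, 3), 1, 2, 3)
  mk <- function(task_i) {
    v <- array(0, g$dims)
    for (s in seq_len(7)) if (task_i %in% incl[[s]]) v[t(spots[s, ])] <- 6
    stat_map(fmri_volume(v, g), df = 19)
  }
  maps <- list(Value = mk(1), Mathematical = mk(2), Emotion = mk(3))
  parts <- partition_conjunctions(maps, voxel_p = 0.001, extent_k = 1)
  rois <- rois_from_conjunctions(parts, dilation_mm = 0)
  expect_length(rois, 7)
  expect_identical(sort(unique(vapply(rois, function(r) r$category,
                                      character(1)))),
                   sort(conjunction_categories()))
})

test_that("response extraction averages ROI voxels per subject/task/phase", {
  g <- tiny_grid(c(6, 6, 4))
  m <- array(FALSE, g$dims)
  m[1:3, 1, 1] <- TRUE
  roi <- structure(list(name = "toy", source = "conjunction",
                        category = NA, membership = fmri_mask(m, g)),
                   class = "roi")
  vals <- array(0, g$dims)
  vals[1:3, 1, 1] <- c(1, 2, 6)
  contrasts <- list(
    sub01 = list(Value = list(choice = fmri_volume(vals, g),
                              feedback = fmri_volume(vals * 2, g))),
    sub02 = list(Value = list(choice = fmri_volume(array(3.5, g$dims), g),
                              feedback = fmri_volume(array(1, g$dims), g))))
  tab <- extract_responses(contrasts, list(roi))
  expect_identical(nrow(tab), 4L)  # 2 subjects x 1 task x 2 phases x 1 roi
  expect_equal(tab$mean_response[tab$subject == "sub01" &
                                   tab$phase == "choice"], 3)
  expect_equal(tab$mean_response[tab$subject == "sub02" &
                                   tab$phase == "choice"], 3.5)
})

test_that("roi_compare is a paired t-test on subject responses", {
  set.seed(33)
  n <- 20L
  tab <- expand.grid(subject = sprintf("s%02d", 1:n),
                     task = c("Value", "Emotion"), phase = "choice",
                     roi = "toy", stringsAsFactors = FALSE)
  tab$mean_response <- rnorm(nrow(tab), mean = ifelse(tab$task == "Value",
                                                      0.6, 0.2))
  res <- roi_compare(tab, "toy", "choice", "Value", "Emotion")
  a <- tab$mean_response[tab$task == "Value"][order(tab$subject[tab$task == "Value"])]
  b <- tab$mean_response[tab$task == "Emotion"][order(tab$subject[tab$task == "Emotion"])]
  want <- paired_t_oracle(a, b)
  expect_equal(res$t, want$t, tolerance = 1e-10)
  expect_identical(res$df, n - 1L)
  expect_equal(res$p, want$p, tolerance = 1e-10)
  # the CI brackets the mean difference and excludes it for strong effects
  expect_lt(res$ci[1], res$mean_diff)
  expect_gt(res$ci[2], res$mean_diff)
  # antisymmetry under task swap
  res2 <- roi_compare(tab, "toy", "choice", "Emotion", "Value")
  expect_equal(res2$t, -res$t, tolerance = 1e-12)
  # identical columns give t = 0, p = 1
  tab$mean_response <- rep(1.5, nrow(tab))
  res3 <- roi_compare(tab, "toy", "choice", "Value", "Emotion")
  expect_identical(res3$t, 0)
  expect_identical(res3$p, 1)
})
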