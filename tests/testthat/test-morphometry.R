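test_that("segmentation labels 26-connected components and applies the size filter", {
  img <- array(0, dim = c(5, 10, 10))
  img[2:3, 2:3, 2:3] <- 100            # 8 voxels
  img[4, 4, 4] <- 100                  # diagonal neighbour: 26-connected
  img[2, 8, 8] <- 100                  # isolated single voxel
  seg <- segment_stack(img, c(1, 1, 1), intensity_threshold = 50)
  expect_equal(seg$n_labels, 2)
  expect_equal(sort(seg$sizes$n_vox), c(1, 9))
  # the diagonal voxel joined the cube
  expect_equal(seg$labels[4, 4, 4], seg$labels[2, 2, 2])
  # size filter drops the singleton
  seg2 <- segment_stack(img, c(1, 1, 1), intensity_threshold = 50,
                        min_size_um3 = 2)
  expect_equal(seg2$n_labels, 1)
  expect_equal(seg2$sizes$n_vox, 9)
  expect_error(segment_stack(matrix(0, 2, 2), c(1, 1, 1), 0), "3D")
})

test_that("sphere-sphere volume overlap matches the closed-form lens volume", {
  r <- 5; d <- 6
  vox <- c(0.25, 0.25, 0.25)
  shape <- c(88, 88, 112)
  c1 <- c(10, 10, 10); c2 <- c(10, 10, 10 + d)
  mk <- function(center) {
    m <- array(FALSE, dim = shape)
    m[satmg:::sphere_voxels(center, r, shape, vox)] <- TRUE
    m
  }
  ov <- overlap_metrics(mk(c1), mk(c2), vox)
  lens <- pi * (4 * r + d) * (2 * r - d)^2 / 12
  expect_lt(abs(ov$overlap_um3 - lens) / lens, 0.05)
  # ratios are overlap over each object's volume
  sphere_vol <- sum(mk(c1)) * prod(vox)
  expect_equal(ov$ratio_a, ov$overlap_um3 / sphere_vol, tolerance = 1e-12)
  expect_error(overlap_metrics(array(FALSE, shape), mk(c2), vox), "zero-volume")
})

test_that("contact surface area honours anisotropic voxel faces", {
  vox <- c(0.5, 0.4, 0.4)
  shape <- c(30, 30, 30)
  a <- array(FALSE, shape); b <- array(FALSE, shape)
  a[6:15, 6:15, 6:15] <- TRUE     # 10^3 cube
  b[6:15, 6:15, 16:25] <- TRUE    # adjacent along x
  # 100 shared faces normal to x, each dz * dy = 0.5 * 0.4 um^2
  expect_equal(contact_surface_area(a, b, vox), 100 * 0.5 * 0.4)
  # stacked along z instead: faces normal to z, each dy * dx = 0.16 um^2
  b2 <- array(FALSE, shape); b2[16:25, 6:15, 6:15] <- TRUE
  expect_equal(contact_surface_area(a, b2, vox), 100 * 0.4 * 0.4)
  # disjoint objects have no contact
  b3 <- array(FALSE, shape); b3[20:25, 20:25, 20:25] <- TRUE
  expect_equal(contact_surface_area(a, b3, vox), 0)
})

test_that("satellite calls require both soma AND process contact", {
  shape <- c(24, 60, 60)
  vox <- c(0.5, 0.4, 0.4)
  n_center <- c(6, 10, 10); n_r <- 3
  m_center <- c(6, 10, 10 + n_r + 2 - 0.8); m_r <- 2  # interdigitating somata
  img_n <- array(0, shape)
  img_n[satmg:::sphere_voxels(n_center, n_r, shape, vox)] <- 100
  img_m <- array(0, shape)
  img_m[satmg:::sphere_voxels(m_center, m_r, shape, vox)] <- 100
  seg_n <- segment_stack(img_n, vox, 50)
  seg_m <- segment_stack(img_m, vox, 50)
  somata <- data.frame(id = "mg-01", z_um = m_center[1], y_um = m_center[2],
                       x_um = m_center[3], radius_um = m_r)

  # process steered away from the neuron: soma contact alone is NOT enough
  away <- rbind(m_center + c(0, 0, m_r), m_center + c(0, 0, m_r + 6))
  res_away <- classify_satellites(seg_n, seg_m, somata,
                                  list("mg-01" = list(away)))
  expect_true(res_away$calls$soma_contact[1])
  expect_false(res_away$calls$process_contact[1])
  expect_false(res_away$calls$satellite[1])
  expect_equal(res_away$percent_satellite, 0)

  # process running onto the neuron soma surface: both criteria hold
  u <- (n_center - m_center) / sqrt(sum((n_center - m_center)^2))
  touch <- rbind(m_center + m_r * u, n_center - (n_r - 0.3) * u)
  res <- classify_satellites(seg_n, seg_m, somata,
                             list("mg-01" = list(touch)))
  expect_true(res$calls$satellite[1])
  expect_equal(res$calls$partner_mg[1], "mg-01")
  expect_gt(res$calls$overlap_um3[1], 0)
  expect_gt(res$calls$contact_area_um2[1], 0)
  expect_true(res$calls$overlap_over_mg[1] > 0 &&
                res$calls$overlap_over_mg[1] < 1)
  expect_equal(res$percent_satellite, 100)
})

test_that("rendered-scene satellite classification recovers the planted truth", {
  scene <- stack_scene_config(seed = 5,
                              intensity = list(background = 0, noise_sd = 0,
                                               microglia = 100, neuron = 100,
                                               cfos_boost = 60))
  stk <- render_stack(scene)
  seg_n <- segment_stack(stk$channels$neurons, stk$voxel_um, 50,
                         min_size_um3 = 20)
  seg_m <- segment_stack(stk$channels$microglia, stk$voxel_um, 50,
                         min_size_um3 = 5)
  calls <- classify_satellites(seg_n, seg_m, stk$truth$microglia,
                               stk$truth$filaments,
                               process_radius_um = scene$process_radius_um)
  # match segmentation labels to planted neurons via the center voxel
  nn <- stk$truth$neurons
  shape <- dim(seg_n$labels)
  lab_at <- vapply(seq_len(nrow(nn)), function(i) {
    ci <- round(c(nn$z_um[i] / stk$voxel_um[1], nn$y_um[i] / stk$voxel_um[2],
                  nn$x_um[i] / stk$voxel_um[3])) + 1
    seg_n$labels[ci[1], ci[2], ci[3]]
  }, integer(1))
  expect_true(all(lab_at > 0))
  expect_equal(calls$calls$satellite[lab_at], nn$satellite)
  expect_equal(calls$percent_satellite, 100 * mean(nn$satellite))
})

test_that("cfos positivity separates boosted from baseline somata", {
  shape <- c(10, 40, 40)
  vox <- c(0.5, 0.4, 0.4)
  c1 <- c(2.5, 4, 4); c2 <- c(2.5, 4, 12)
  img_n <- array(0, shape)
  i1 <- satmg:::sphere_voxels(c1, 2, shape, vox)
  i2 <- satmg:::sphere_voxels(c2, 2, shape, vox)
  img_n[i1] <- 100; img_n[i2] <- 100
  seg <- segment_stack(img_n, vox, 50)
  expect_equal(seg$n_labels, 2)
  set.seed(1)
  cf <- array(stats::rnorm(prod(shape), 10, 2), dim = shape)
  pos_label <- seg$labels[i1[1]]
  cf[if (pos_label == 1) i1 else i2] <- 70   # planted positive is label 1
  res <- cfos_positivity(cf, seg, satellite = c(TRUE, FALSE))
  expect_equal(res$calls$positive, c(TRUE, FALSE))
  expect_equal(res$summary$percent_positive, c(100, 0))
})

test_that("percent area computes the stained fraction of the annotation", {
  img <- matrix(0, 40, 25)  # 1000 pixels
  img[seq_len(123)] <- 50
  mask <- matrix(TRUE, 40, 25)
  expect_equal(percent_area(img, mask, threshold = 25), 12.3)
  # restricting the mask changes the denominator
  mask2 <- matrix(FALSE, 40, 25); mask2[, 1:5] <- TRUE  # 200 px, 123 stained
  expect_equal(percent_area(img, mask2, 25), 100 * 123 / 200)
  expect_error(percent_area(img, matrix(FALSE, 40, 25), 25), "empty")
  expect_error(percent_area(img, matrix(TRUE, 2, 2), 25), "shape")
})
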