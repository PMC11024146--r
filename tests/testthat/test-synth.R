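# Synthetic cohort generator: determinism, noise separation, kinematics.

test_that("subject generation is bit-identical from the same seed", {
  s1 <- generate_subject(subject_params(seed = 21))
  s2 <- generate_subject(subject_params(seed = 21))
  expect_identical(s1$poses[[4]]$meniscus_medial$vertices,
                   s2$poses[[4]]$meniscus_medial$vertices)
  expect_identical(s1$observed_poses[[2]]$femur$vertices,
                   s2$observed_poses[[2]]$femur$vertices)
  expect_identical(s1$achieved_angles, s2$achieved_angles)
  expect_identical(s1$sparse_cortical_points$reference,
                   s2$sparse_cortical_points$reference)
})

test_that("observation noise never touches the ground truth", {
  s_noisy <- generate_subject(subject_params(seed = 33, noise_sigma = 0.5))
  s_clean <- generate_subject(subject_params(seed = 33, noise_sigma = 0))
  # identical truth regardless of the observation noise setting
  for (k in 1:4)
    expect_identical(s_noisy$poses[[k]]$meniscus_lateral$vertices,
                     s_clean$poses[[k]]$meniscus_lateral$vertices)
  # observed copies differ from truth by zero-mean jitter of the right scale
  jit <- s_noisy$observed_poses[[1]]$femur$vertices -
    s_noisy$poses[[1]]$femur$vertices
  expect_gt(sd(jit), 0.3)
  expect_lt(sd(jit), 0.7)
  expect_lt(abs(mean(jit)), 0.05)
  # noiseless observed poses equal the truth exactly
  expect_identical(s_clean$observed_poses[[1]]$femur$vertices,
                   s_clean$poses[[1]]$femur$vertices)
})

test_that("achieved angles increase and are recovered from the meshes", {
  s <- fixture_subject()
  expect_true(all(diff(s$achieved_angles) > 0))
  for (k in 1:4) {
    rec <- flexion_angle(s$poses[[k]]$femur, s$tibial_frame,
                         s$shaft_vertex_indices)
    expect_equal(rec, s$achieved_angles[k], tolerance = 0.5)
  }
})

test_that("meniscal volume is conserved across the flexion poses", {
  s <- fixture_subject()
  for (side in c("medial", "lateral")) {
    comp <- paste0("meniscus_", side)
    v0 <- compute_volume(s$initial_tubes[[side]])
    for (k in 1:4)
      expect_lt(abs(compute_volume(s$poses[[k]][[comp]]) - v0) / v0, 1e-3)
  }
})

test_that("the analytic motion reproduces the femur poses exactly", {
  s <- fixture_subject()
  femur0 <- s$femur_reference
  for (k in c(1, 4)) {
    expect_equal(apply_transform(femur0, s$analytic_motion[[k]])$vertices,
                 s$poses[[k]]$femur$vertices, tolerance = 1e-12)
  }
  f <- ground_truth_displacement(s, "0", "30", "femur")
  manual <- apply_transform(femur0$vertices, s$analytic_motion[[2]]) -
    apply_transform(femur0$vertices, s$analytic_motion[[1]])
  expect_equal(f$vectors, manual, tolerance = 1e-12)

  z <- ground_truth_displacement(s, "60", "60", "tibia_fibula")
  expect_true(all(z$magnitudes == 0))
  expect_error(ground_truth_displacement(s, "0", "45", "femur"),
               "unknown pose label")
})

test_that("the generator encodes a medial pivot with femoral rollback", {
  s <- fixture_subject()
  centers <- attr(s$femur_reference, "condyle_centers")
  for (k in 2:4) {
    tr <- s$analytic_motion[[k]]
    ap_med <- (apply_transform(centers["medial", , drop = FALSE], tr) -
                 centers["medial", , drop = FALSE])[1]
    ap_lat <- (apply_transform(centers["lateral", , drop = FALSE], tr) -
                 centers["lateral", , drop = FALSE])[1]
    expect_lt(ap_med, 0)              # posterior rollback
    expect_lte(ap_lat, ap_med)        # lateral excursion at least as large
  }
})

test_that("a stronger lateral pivot yields larger lateral displacement", {
  prm <- subject_params(seed = 13, pivot_medial = 0.02, pivot_lateral = 0.10,
                        noise_sigma = 0)
  s <- generate_subject(prm)
  d_med <- max_point_displacement(
    ground_truth_displacement(s, "0", "90", "meniscus_medial"))$mm
  d_lat <- max_point_displacement(
    ground_truth_displacement(s, "0", "90", "meniscus_lateral"))$mm
  expect_gt(d_lat, d_med)
})

test_that("maximal meniscal displacement sits in a horn, not the body", {
  s <- fixture_subject()
  for (side in c("medial", "lateral")) {
    f <- ground_truth_displacement(s, "0", "90", paste0("meniscus_", side))
    masks <- meniscus_region_masks(s$poses[[1]][[paste0("meniscus_", side)]])
    vmax <- max_point_displacement(f)$vertex
    expect_true(vmax %in% c(masks$anterior_horn, masks$posterior_horn))
  }
})

test_that("population draws are reproducible and length-scaled", {
  pop <- generate_population(3, cohort_seed = 77, variability = 0,
                             noise_sigma = 0)
  pop2 <- generate_population(3, cohort_seed = 77, variability = 0,
                              noise_sigma = 0)
  expect_identical(pop[[2]]$poses[[1]]$meniscus_medial$vertices,
                   pop2[[2]]$poses[[1]]$meniscus_medial$vertices)
  lens <- vapply(pop, function(s) s$params$femoral_length, 0)
  expect_gt(stats::sd(lens), 1)      # inter-subject variation present
  # zero variability: profiles identical after length normalization
  norm_peak <- vapply(pop, function(s)
    s$params$meniscus_h_peak * 432 / s$params$femoral_length, 0)
  expect_equal(max(norm_peak) - min(norm_peak), 0, tolerance = 1e-9)

  expect_error(generate_population(0), "at least 1")
  expect_length(generate_population(1, cohort_seed = 3, noise_sigma = 0), 1)
})

test_that("parameter invariants are enforced", {
  expect_error(subject_params(pivot_medial = 0.08, pivot_lateral = 0.02),
               "medial pivot")
  expect_error(subject_params(femoral_length = -1), "positive")
  expect_error(subject_params(noise_sigma = -0.1), "nonnegative")
})

test_that("sparse cortical points lie on the femur and follow the motion", {
  s <- fixture_subject()
  pts <- s$sparse_cortical_points$reference
  expect_identical(dim(pts), c(300L, 3L))
  d <- surface_distance(pts, s$femur_reference)
  expect_lt(max(d), 1e-9)
  expect_equal(s$sparse_cortical_points$per_pose[[3]],
               apply_transform(pts, s$analytic_motion[[3]]),
               tolerance = 1e-12)
})
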