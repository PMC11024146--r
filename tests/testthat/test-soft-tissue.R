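# Cartilage construction, meniscus template tubes, and the elastic
# volume-preserving fit.

test_that("thickness maps scale linearly with femoral length", {
  map <- cartilage_thickness_map(1:5, c(2, 2, 2, 1, 3), 432)
  expect_equal(scale_thickness_map(map, 432)$thickness, map$thickness)
  expect_equal(scale_thickness_map(map, 432 * 1.1)$thickness[1], 2.2)
  s <- scale_thickness_map(map, 432 * 0.9)
  expect_equal(range(s$thickness), 0.9 * range(map$thickness))
  expect_identical(s$bone_vertex_indices, map$bone_vertex_indices)
  expect_error(scale_thickness_map(map, 0), "positive")
  expect_error(cartilage_thickness_map(c(1, 1), c(1, 1), 432), "duplicate")
  expect_error(cartilage_thickness_map(1:2, c(-1, 1), 432), "negative")
})

test_that("cartilage surfaces offset articular vertices along normals", {
  bone <- mesh_box(dims = c(10, 10, 10))
  empty <- cartilage_thickness_map(integer(0), numeric(0), 432)
  expect_equal(build_cartilage_surface(bone, empty)$vertices, bone$vertices)

  patch <- mesh_flat_patch(5, 5, 1)
  allv <- cartilage_thickness_map(1:25, rep(2, 25), 432)
  lifted <- build_cartilage_surface(patch, allv)
  expect_equal(lifted$vertices[, 3], rep(2, 25))
  expect_equal(lifted$vertices[, 1:2], patch$vertices[, 1:2])
  expect_identical(lifted$faces, patch$faces)

  sph <- mesh_uv_sphere(radius = 20, n_lat = 18, n_lon = 24)
  m <- cartilage_thickness_map(seq_len(n_vertices(sph)),
                               rep(1.5, n_vertices(sph)), 432)
  off <- build_cartilage_surface(sph, m)
  radii <- sqrt(rowSums(off$vertices^2))
  expect_lt(max(abs(radii - 21.5)), 0.05)
})

test_that("excessive thickness triggers a self-intersection warning", {
  # accordion strip: a thickness far beyond the crease scale folds faces
  # over; the affected vertices must be reported
  nx <- 6
  v <- NULL
  for (j in 0:3)
    v <- rbind(v, cbind(0:(nx - 1), j, ifelse(j %% 2 == 0, 0, 0.6)))
  idx <- function(i, j) j * nx + i + 1
  f <- NULL
  for (j in 0:2) {
    for (i in 0:(nx - 2)) {
      f <- rbind(f, c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                 c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }
  }
  strip <- triangle_mesh(v, f)
  map <- cartilage_thickness_map(seq_len(nrow(v)), rep(2, nrow(v)), 432)
  expect_warning(out <- build_cartilage_surface(strip, map),
                 "self-intersects locally at vertices")
  expect_identical(out$faces, strip$faces)  # surface still returned
})

test_that("straight template tubes match the closed-form prism", {
  ns <- 12
  cl <- cbind(seq(0, 40, length.out = ns), 0, 0)
  tpl <- meniscus_template(cl, rep(5, ns), rep(5, ns),
                           reference_femoral_length = 432)
  tube <- build_template_tube(tpl, 432, cl[c(1, ns), ])
  expect_true(is_closed(tube))
  # wedge cross-section area h*w/2; prism volume = area * length
  expect_lt(abs(compute_volume(tube) - 5 * 5 / 2 * 40) / (5 * 5 / 2 * 40),
            0.01)
  # two scaled cross-section dimensions, unscaled length: volume ~ ratio^2
  tube12 <- build_template_tube(tpl, 432 * 1.2, cl[c(1, ns), ])
  expect_equal(compute_volume(tube12) / compute_volume(tube), 1.2^2,
               tolerance = 1e-6)
})

test_that("C-shaped tubes are well-formed, corresponded and deterministic", {
  scene <- fixture_fit_scene()
  tube <- scene$tube
  expect_true(is_closed(tube))
  expect_gt(compute_volume(tube), 0)
  expect_identical(build_template_tube(scene$template, 432,
                                       scene$template$centerline[c(1, 16), ]),
                   tube)
  att <- attr(tube, "attachment_vertices")
  expect_true(length(att) >= 2 * attr(tube, "ring_size"))
  expect_true(all(att >= 1 & att <= n_vertices(tube)))
})

test_that("overly tight centerline curvature is rejected with a location", {
  ns <- 24
  th <- seq(0, 1.5 * pi, length.out = ns)
  cl <- cbind(4 * cos(th), 4 * sin(th), 0)   # radius 4
  tpl <- meniscus_template(cl, rep(3, ns), rep(8, ns), 432)  # reach 16/3 > 4
  expect_error(build_template_tube(tpl, 432, cl[c(1, ns), ]),
               "curvature near arclength")
})

test_that("template validation rejects malformed inputs", {
  cl <- cbind(0:5, 0, 0)
  expect_error(meniscus_template(cl, rep(0, 6), rep(1, 6), 432),
               "strictly positive")
  expect_error(meniscus_template(cl, rep(1, 5), rep(1, 6), 432),
               "per centerline section")
  expect_error(meniscus_template(cl[c(1, 1, 2, 3), ], rep(1, 4), rep(1, 4),
                                 432), "repeated")
  tpl <- meniscus_template(cl, rep(1, 6), rep(1, 6), 432)
  expect_error(build_template_tube(tpl, 432, rbind(c(0, 0, 0), c(0, 0, 0))),
               "coincide")
})

test_that("a feasible constraint-free tube is an exact fixed point", {
  scene <- fixture_fit_scene()
  # surfaces out of reach: no penetration, no contact, rest shape at rest
  far_sphere <- mesh_uv_sphere(center = c(0, 0, 200), radius = 10,
                               n_lat = 6, n_lon = 8)
  far_plate <- mesh_box(center = c(0, 0, -200), dims = c(50, 50, 5))
  fit <- fit_meniscus(scene$tube, far_sphere, far_plate,
                      config = fit_config(max_iterations = 50))
  expect_equal(fit$mesh$vertices, scene$tube$vertices, tolerance = 1e-9)
  expect_lt(fit$report$volume_drift, 1e-6)
  expect_true(fit$report$converged)
})

test_that("refitting a converged mesh stays within the step tolerance", {
  scene <- fixture_fit_scene()
  cfg <- fit_config(max_iterations = 400)
  fit1 <- fit_meniscus(scene$tube, scene$sphere, scene$plate, config = cfg)
  # same energy (rest shape = template): the converged state is stationary
  fit2 <- fit_meniscus(fit1$mesh, scene$sphere, scene$plate, config = cfg,
                       rest_mesh = scene$tube)
  move <- max(sqrt(rowSums((fit2$mesh$vertices - fit1$mesh$vertices)^2)))
  # convergence leaves the state near, not at, equilibrium: a restart may
  # advance a little further, but stays far below the voxel scale
  expect_lt(move, 0.2)
  expect_lt(fit2$report$volume_drift, 1e-3)
})

test_that("the fit clears penetration while preserving volume and topology", {
  scene <- fixture_fit_scene()
  pen0 <- -min(surface_distance(scene$tube$vertices, scene$sphere,
                                signed = TRUE))
  expect_gt(pen0, 1.5)   # the condyle presses about 2 mm into the tube
  cfg <- fit_config(max_iterations = 400)
  fit <- fit_meniscus(scene$tube, scene$sphere, scene$plate, config = cfg)

  d_f <- surface_distance(fit$mesh$vertices, scene$sphere, signed = TRUE)
  d_t <- surface_distance(fit$mesh$vertices, scene$plate, signed = TRUE)
  expect_gte(min(c(d_f, d_t)), -cfg$penetration_tolerance)
  expect_lt(abs(compute_volume(fit$mesh) - compute_volume(scene$tube)) /
              compute_volume(scene$tube), 1e-3)
  expect_identical(fit$mesh$faces, scene$tube$faces)
  expect_identical(n_vertices(fit$mesh), n_vertices(scene$tube))

  att <- attr(scene$tube, "attachment_vertices")
  expect_identical(fit$mesh$vertices[att, ], scene$tube$vertices[att, ])
  free <- setdiff(seq_len(n_vertices(scene$tube)), att)
  expect_gt(max(abs(fit$mesh$vertices[free, ] -
                      scene$tube$vertices[free, ])), 0.1)

  expect_true(all(diff(fit$report$energies) <= 1e-12))

  # determinism: identical inputs and config give bit-identical results
  fit_again <- fit_meniscus(scene$tube, scene$sphere, scene$plate,
                            config = cfg)
  expect_identical(fit_again$mesh$vertices, fit$mesh$vertices)
})

test_that("infeasible attachments are rejected", {
  scene <- fixture_fit_scene()
  # bury the whole tube deep inside a huge sphere
  big <- mesh_uv_sphere(center = c(0, 0, 0), radius = 60, n_lat = 10,
                        n_lon = 12)
  expect_error(fit_meniscus(scene$tube, big, scene$plate),
               "infeasible geometry")
})

test_that("fit configs are validated", {
  expect_error(fit_config(penetration_tolerance = 0), "positive")
  expect_error(fit_config(elastic_weight = -1), "nonnegative")
  expect_error(fit_config(contact_weight = 0, penetration_weight = 0),
               "at least one")
})
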