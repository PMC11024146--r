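# Shared fixtures and independent oracles for the test suite.

# Exhaustive pure-R point-to-triangle distance (independent oracle for the
# C++ nearest-surface query): for each point, scans every triangle with a
# direct closest-point construction (vectorized over faces).
brute_force_surface_distance <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  apply(points, 1, function(p) {
    ap <- sweep(-a, 2, p, "+")
    d1 <- rowSums(ab * ap)
    d2 <- rowSums(ac * ap)
    bp <- ap - ab
    d3 <- rowSums(ab * bp)
    d4 <- rowSums(ac * bp)
    cp <- ap - ac
    d5 <- rowSums(ab * cp)
    d6 <- rowSums(ac * cp)
    va <- d3 * d6 - d5 * d4
    vb <- d5 * d2 - d1 * d6
    vc <- d1 * d4 - d3 * d2
    # region classification per triangle (Ericson)
    q <- matrix(NA_real_, nrow(a), 3)
    reg_a <- d1 <= 0 & d2 <= 0
    q[reg_a, ] <- a[reg_a, ]
    reg_b <- !reg_a & d3 >= 0 & d4 <= d3
    q[reg_b, ] <- (a + ab)[reg_b, ]
    reg_ab <- is.na(q[, 1]) & vc <= 0 & d1 >= 0 & d3 <= 0
    t_ab <- d1 / (d1 - d3)
    q[reg_ab, ] <- (a + t_ab * ab)[reg_ab, ]
    reg_c <- is.na(q[, 1]) & d6 >= 0 & d5 <= d6
    q[reg_c, ] <- (a + ac)[reg_c, ]
    reg_ac <- is.na(q[, 1]) & vb <= 0 & d2 >= 0 & d6 <= 0
    t_ac <- d2 / (d2 - d6)
    q[reg_ac, ] <- (a + t_ac * ac)[reg_ac, ]
    reg_bc <- is.na(q[, 1]) & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
    t_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    q[reg_bc, ] <- (a + ab + t_bc * (ac - ab))[reg_bc, ]
    inner <- is.na(q[, 1])
    denom <- va + vb + vc
    q[inner, ] <- (a + (vb / denom) * ab + (vc / denom) * ac)[inner, ]
    min(sqrt(rowSums(sweep(q, 2, p)^2)))
  })
}

# random well-formed closed test mesh (jittered icosphere), <= 500 faces
random_test_mesh <- function(subdiv = 2, seed = 1, jitter = 0.1) {
  set.seed(seed)
  m <- mesh_icosphere(radius = 10, subdivisions = subdiv)
  m$vertices <- m$vertices * (1 + jitter * stats::runif(nrow(m$vertices)))
  m
}

random_rigid_transform <- function(seed = 1) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  rigid_transform(rotation_about_axis(ax, stats::runif(1, 0, 360)),
                  stats::rnorm(3, sd = 20))
}

# lazily cached expensive fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

fixture_subject <- function(seed = 7, noise_sigma = 0.3571) {
  key <- sprintf("subj_%d_%g", seed, noise_sigma)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_subject(
      subject_params(seed = seed, noise_sigma = noise_sigma))
  .fixtures[[key]]
}

# small C-tube pressed by an analytic sphere condyle: the canonical
# elastic-fit scene
fixture_fit_scene <- function() {
  if (!is.null(.fixtures$scene)) return(.fixtures$scene)
  th <- seq(-0.6 * pi, 0.6 * pi, length.out = 16)
  cl <- cbind(11 * cos(th), 11 * sin(th), 0)
  s <- seq(0, 1, length.out = 16)
  tpl <- meniscus_template(cl, 2 + 3 * sin(pi * s), 3 + 4 * sin(pi * s),
                           reference_femoral_length = 432)
  tube <- build_template_tube(tpl, 432, cl[c(1, 16), ])
  zmin <- min(tube$vertices[, 3])
  # condyle sphere offset toward the mid-body (away from the horn gap),
  # pressing about 2 mm into the tube while the horns stay clear
  sphere <- mesh_uv_sphere(center = c(3, 0, 20 + zmin - 0.5), radius = 20,
                           n_lat = 14, n_lon = 18)
  plate <- mesh_box(center = c(0, 0, zmin - 2.55), dims = c(60, 60, 5))
  .fixtures$scene <- list(template = tpl, tube = tube, sphere = sphere,
                          plate = plate)
  .fixtures$scene
}
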