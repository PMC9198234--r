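test_that("stiffness annihilates rigid translations and has 6 zero modes", {
  tm <- single_tet_mesh()
  K <- as.matrix(assemble_stiffness(tm, fe_material()))
  expect_equal(K, t(K), tolerance = 1e-12)
  for (tr in list(c(1, 0, 0), c(0, 1, 0), c(1, 2, 3))) {
    u <- rep(tr, 4)
    expect_lt(max(abs(K %*% u)), 1e-8 * max(abs(K)))
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6L)
  expect_true(all(ev > -1e-8 * max(ev)))  # positive semi-definite
})

test_that("stiffness matches the strain-energy oracle on random tets", {
  withr::with_seed(31, {
    for (rep in 1:3) {
      nodes <- matrix(rnorm(12), 4, 3)
      # ensure decent volume / conditioning
      if (abs(det(cbind(nodes[2, ] - nodes[1, ], nodes[3, ] - nodes[1, ],
                        nodes[4, ] - nodes[1, ]))) < 0.1) next
      tm <- single_tet_mesh(nodes)
      if (tet_volumes(tm) < 0) tm$elements <- tm$elements[, c(1, 2, 4, 3),
                                                          drop = FALSE]
      mat <- fe_material(E = 1000, nu = 0.25)
      K <- as.matrix(assemble_stiffness(tm, mat))
      u <- rnorm(12, sd = 0.01)
      # energy identity: 0.5 u^T K u equals the directly integrated energy
      e_K <- 0.5 * sum(u * (K %*% u))
      e_direct <- strain_energy_direct(tm, u, mat$E, mat$nu)
      expect_equal(e_K, e_direct, tolerance = 1e-6)
      # K u matches central differences of the energy functional
      grad_fd <- vapply(seq_along(u), function(i) {
        h <- 1e-6
        up <- u; up[i] <- up[i] + h
        um <- u; um[i] <- um[i] - h
        (strain_energy_direct(tm, up, mat$E, mat$nu) -
           strain_energy_direct(tm, um, mat$E, mat$nu)) / (2 * h)
      }, numeric(1))
      expect_equal(as.numeric(K %*% u), grad_fd, tolerance = 1e-4)
    }
  })
})

test_that("consistent load sums exactly to the applied force", {
  cf <- cube_fixture(10, 6)
  tm <- tetrahedralize(binary_mask(cf$truth$bone_mask, cf$volume$spacing))
  lo <- build_load_and_constraints(tm, fe_load_case(total_force = 1800))
  f <- matrix(lo$f, ncol = 3, byrow = TRUE)
  expect_equal(colSums(f), c(0, 0, -1800), tolerance = 1e-12)
  lo0 <- build_load_and_constraints(tm, fe_load_case(total_force = 0))
  expect_equal(lo0$f, numeric(length(lo0$f)))
  # fixed set covers all three DOFs of the bottom nodes
  bot <- tm$node_sets$inferior_fixed
  expect_setequal(lo$fixed_dofs, as.integer(outer(1:3, 3L * (bot - 1L), `+`)))
  # empty selections rejected
  tm2 <- tm; tm2$node_sets$proximal_load <- tm$node_sets$proximal_load[0, ]
  expect_error(build_load_and_constraints(tm2, fe_load_case()),
               class = "femurfe_configuration_error")
})

test_that("uniaxial cube compression reproduces the closed-form solution", {
  ua <- uniaxial_cube(edge = 10, divisions = 8L, force = 1800)
  mat <- fe_material()
  K <- assemble_stiffness(ua$mesh, mat)
  sol <- solve_displacements(K, ua$loads)
  nd <- ua$mesh$nodes
  top <- which(abs(nd[, 3] - max(nd[, 3])) < 1e-9)
  delta <- mean(sol$u[3L * (top - 1L) + 3L])
  expect_lt(abs(delta - (-ua$q * ua$edge / mat$E)) /
              (ua$q * ua$edge / mat$E), 0.01)
  # uniform uniaxial state: von Mises = q, pressure = q/3 everywhere
  res <- compute_element_fields(ua$mesh, sol$u, mat)
  expect_equal(res$element_von_mises, rep(ua$q, nrow(ua$mesh$elements)),
               tolerance = 1e-9)
  expect_equal(res$element_pressure, rep(ua$q / 3, nrow(ua$mesh$elements)),
               tolerance = 1e-9)
  # equilibrium
  reac <- matrix(sol$reactions, ncol = 3, byrow = TRUE)
  expect_lt(abs(sum(reac[, 3]) - 1800) / 1800, 1e-6)
  # zero load gives zero displacement
  lo0 <- ua$loads; lo0$f[] <- 0
  expect_equal(max(abs(solve_displacements(K, lo0)$u)), 0)
})

test_that("patch test: affine boundary displacement is reproduced exactly", {
  cf <- cube_fixture(6, 4)
  tm <- tetrahedralize(binary_mask(cf$truth$bone_mask, cf$volume$spacing))
  mat <- fe_material()
  K <- assemble_stiffness(tm, mat)
  A <- matrix(c(1e-3, 2e-4, -1e-4,
                3e-4, -5e-4, 2e-4,
                -2e-4, 1e-4, 8e-4), 3, 3, byrow = TRUE)
  u_exact <- t(A %*% t(tm$nodes))
  nd <- tm$nodes
  lims <- apply(nd, 2, range)
  on_bnd <- rowSums(sapply(1:3, function(i) {
    abs(nd[, i] - lims[1, i]) < 1e-9 | abs(nd[, i] - lims[2, i]) < 1e-9
  })) > 0
  bnd <- which(on_bnd)
  loads <- list(f = numeric(3L * nrow(nd)),
                fixed_dofs = as.integer(outer(1:3, 3L * (bnd - 1L), `+`)),
                fixed_values = as.numeric(t(u_exact[bnd, ])))
  sol <- solve_displacements(K, loads)
  expect_equal(matrix(sol$u, ncol = 3, byrow = TRUE), u_exact,
               tolerance = 1e-9)
})

test_that("element fields transform correctly for rigid and volumetric modes", {
  cf <- cube_fixture(4, 3)
  tm <- tetrahedralize(binary_mask(cf$truth$bone_mask, cf$volume$spacing))
  mat <- fe_material()
  # small rigid rotation: tiny small-strain stress, Green-Lagrange 2nd order
  th <- 1e-4
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  u_rot <- t(R %*% t(tm$nodes)) - tm$nodes
  res <- compute_element_fields(tm, as.numeric(t(u_rot)), mat)
  expect_lt(max(res$element_von_mises), mat$E * th^2 * 10)
  expect_lt(max(abs(res$element_lagrange_strain)), th^2 * 10)
  # isotropic expansion u = alpha x: pressure -3 K_bulk alpha, von Mises 0
  alpha <- 1e-4
  u_iso <- alpha * tm$nodes
  res2 <- compute_element_fields(tm, as.numeric(t(u_iso)), mat)
  K_bulk <- mat$E / (3 * (1 - 2 * mat$nu))
  expect_equal(res2$element_pressure,
               rep(-3 * K_bulk * alpha, nrow(tm$elements)), tolerance = 1e-9)
  expect_lt(max(res2$element_von_mises), 1e-9 * mat$E * alpha)
})

test_that("solutions are equivariant under rigid rotation of the problem", {
  ph <- generate_phantom(toy_params(seed = 9L))
  cfg <- toy_config()
  r0 <- analyze_specimen(ph$volume, ph$truth, "KI", cfg)
  tm <- r0$tet
  mat <- cfg$material
  sol0 <- r0$solution
  axis <- c(1, 2, 3) / sqrt(14)
  th <- 0.7
  K3 <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                 axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K3 + (1 - cos(th)) * K3 %*% K3
  tmR <- tm
  tmR$nodes <- t(R %*% t(tm$nodes))
  KR <- assemble_stiffness(tmR, mat)
  lcR <- fe_load_case(direction = as.numeric(R %*% c(0, 0, -1)))
  # same node sets (they rotate with the mesh)
  loR <- build_load_and_constraints(tmR, lcR)
  solR <- solve_displacements(KR, loR)
  uR <- matrix(solR$u, ncol = 3, byrow = TRUE)
  u0R <- t(R %*% t(matrix(sol0$u, ncol = 3, byrow = TRUE)))
  scale <- max(abs(u0R))
  expect_lt(max(abs(uR - u0R)) / scale, 1e-6)
  # invariant scalars match
  resR <- compute_element_fields(tmR, solR$u, mat)
  expect_equal(resR$element_von_mises, r0$result$element_von_mises,
               tolerance = 1e-6)
  expect_equal(resR$element_pressure, r0$result$element_pressure,
               tolerance = 1e-6)
})

test_that("response scales linearly with the applied force", {
  ua <- uniaxial_cube(edge = 10, divisions = 4L, force = 900)
  mat <- fe_material()
  K <- assemble_stiffness(ua$mesh, mat)
  sol1 <- solve_displacements(K, ua$loads)
  lo2 <- ua$loads; lo2$f <- 2 * lo2$f
  sol2 <- solve_displacements(K, lo2)
  expect_equal(sol2$u, 2 * sol1$u, tolerance = 1e-9)
  r1 <- compute_element_fields(ua$mesh, sol1$u, mat)
  r2 <- compute_element_fields(ua$mesh, sol2$u, mat)
  expect_equal(r2$element_von_mises, 2 * r1$element_von_mises,
               tolerance = 1e-9)
})

test_that("uniaxial tip-displacement error decreases with refinement", {
  errs <- vapply(c(2L, 4L, 8L), function(dv) {
    ua <- uniaxial_cube(edge = 10, divisions = dv, force = 1800)
    mat <- fe_material()
    sol <- solve_displacements(assemble_stiffness(ua$mesh, mat), ua$loads)
    nd <- ua$mesh$nodes
    top <- which(abs(nd[, 3] - max(nd[, 3])) < 1e-9)
    abs(mean(sol$u[3L * (top - 1L) + 3L]) + ua$q * ua$edge / mat$E)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("floating meshes raise a solver error", {
  tm <- single_tet_mesh()
  K <- assemble_stiffness(tm, fe_material())
  loads <- list(f = c(rep(0, 11), 1), fixed_dofs = integer(0),
                fixed_values = numeric(0))
  expect_error(solve_displacements(K, loads), class = "femurfe_solver_error")
})

test_that("specimen summaries are unweighted means with provenance", {
  ua <- uniaxial_cube(edge = 4, divisions = 2L, force = 160)
  mat <- fe_material()
  sol <- solve_displacements(assemble_stiffness(ua$mesh, mat), ua$loads)
  res <- compute_element_fields(ua$mesh, sol$u, mat)
  s <- summarize_specimen(res, list(specimen_id = "cube", side = "left",
                                    method = "KI"))
  expect_equal(s$mean_stress, mean(res$element_von_mises))
  expect_equal(s$mean_pressure, mean(res$element_pressure))
  expect_equal(s$mean_strain, mean(res$element_effective_strain))
  expect_equal(s$mean_displacement,
               mean(sqrt(rowSums(matrix(sol$u, ncol = 3, byrow = TRUE)^2))))
  expect_equal(s$specimen_id, "cube")
  # uniform field: mean equals the common value
  expect_equal(s$mean_stress, res$element_von_mises[1], tolerance = 1e-9)
  # hand-mixed two-element check of the unweighted mean convention
  fake <- res
  fake$element_von_mises <- c(1, 3)
  fake$element_pressure <- c(1, 1)
  fake$element_effective_strain <- c(2, 4)
  fake$element_volumes <- c(10, 1)
  expect_equal(summarize_specimen(fake)$mean_stress, 2)
})
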