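#' Isotropic linear-elastic material
#'
#' Defaults are the standardized cortical-bone values used throughout the
#' analysis: Young's modulus 16800 MPa and Poisson's ratio 0.3.
#'
#' @param E Young's modulus, MPa (> 0).
#' @param nu Poisson's ratio, `-1 < nu < 0.5`.
#' @return An object of class `fe_material` (with Lame parameters attached).
#' @export
fe_material <- function(E = 16800, nu = 0.3) {
  assert_scalar_num(E, "E", 0, strict = TRUE)
  if (!(nu > -1 && nu < 0.5)) {
    abort_femurfe("`nu` must lie in (-1, 0.5).", "femurfe_parameter_error")
  }
  structure(list(E = E, nu = nu,
                 lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
                 mu = E / (2 * (1 + nu))),
            class = "fe_material")
}

#' Standardized compressive load case
#'
#' The default reproduces the standing joint-reaction scenario: 1800 N total
#' compressive force along -Z applied over the proximal load faces, with all
#' displacement components fixed on the inferior surface.
#'
#' @param total_force Total applied force magnitude, N (>= 0).
#' @param direction Unit load direction (default `-Z`, compressive).
#' @param load_set,fixed_set Names of the mesh node-set entries holding the
#'   load faces and the fixed nodes.
#' @return An object of class `fe_load_case`.
#' @export
fe_load_case <- function(total_force = 1800, direction = c(0, 0, -1),
                         load_set = "proximal_load",
                         fixed_set = "inferior_fixed") {
  assert_scalar_num(total_force, "total_force", 0)
  direction <- as.numeric(direction)
  direction <- direction / sqrt(sum(direction^2))
  structure(list(total_force = total_force, direction = direction,
                 load_set = load_set, fixed_set = fixed_set),
            class = "fe_load_case")
}

# Shape-function gradients of all elements: list with `grads` (ne x 4 x 3)
# and `vols` (ne). For a linear tet the gradient of barycentric coordinate
# 2..4 is the corresponding row of the inverse edge matrix; gradient 1 is
# minus their sum.
tet_gradients <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elements
  ne <- nrow(el)
  J1 <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  J2 <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  J3 <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  det <- J1[, 1] * (J2[, 2] * J3[, 3] - J2[, 3] * J3[, 2]) -
    J1[, 2] * (J2[, 1] * J3[, 3] - J2[, 3] * J3[, 1]) +
    J1[, 3] * (J2[, 1] * J3[, 2] - J2[, 2] * J3[, 1])
  if (any(abs(det) < 1e-300)) {
    bad <- which(abs(det) < 1e-300)[1]
    abort_femurfe(sprintf("Degenerate (zero-volume) element %d.", bad),
                  "femurfe_mesh_error")
  }
  # rows of inv(J) where J rows are J1,J2,J3: inv(J) = adj(J)^T / det.
  # grad(lambda_{a+1}) = inv(J)[a, ] (a = 1..3).
  inv11 <- (J2[, 2] * J3[, 3] - J2[, 3] * J3[, 2]) / det
  inv12 <- (J1[, 3] * J3[, 2] - J1[, 2] * J3[, 3]) / det
  inv13 <- (J1[, 2] * J2[, 3] - J1[, 3] * J2[, 2]) / det
  inv21 <- (J2[, 3] * J3[, 1] - J2[, 1] * J3[, 3]) / det
  inv22 <- (J1[, 1] * J3[, 3] - J1[, 3] * J3[, 1]) / det
  inv23 <- (J1[, 3] * J2[, 1] - J1[, 1] * J2[, 3]) / det
  inv31 <- (J2[, 1] * J3[, 2] - J2[, 2] * J3[, 1]) / det
  inv32 <- (J1[, 2] * J3[, 1] - J1[, 1] * J3[, 2]) / det
  inv33 <- (J1[, 1] * J2[, 2] - J1[, 2] * J2[, 1]) / det
  g <- array(0, c(ne, 4, 3))
  # With J[a, ] = x_{a+1} - x_1, barycentric coordinates satisfy
  # (x - x_1) = J^T lambda, so lambda_{a+1} = e_a^T J^{-T} (x - x_1) and
  # grad lambda_{a+1} = J^{-1} e_a = column a of inv(J).
  g[, 2, 1] <- inv11; g[, 2, 2] <- inv21; g[, 2, 3] <- inv31
  g[, 3, 1] <- inv12; g[, 3, 2] <- inv22; g[, 3, 3] <- inv32
  g[, 4, 1] <- inv13; g[, 4, 2] <- inv23; g[, 4, 3] <- inv33
  g[, 1, ] <- -(g[, 2, ] + g[, 3, ] + g[, 4, ])
  list(grads = g, vols = det / 6)
}

#' Assemble the global stiffness operator
#'
#' Standard constant-strain (4-node) tetrahedra, assembled sparsely. For
#' element gradients \eqn{g_a} the 3x3 nodal block is
#' \deqn{K_{ab} = V [\lambda g_a g_b^T + \mu g_b g_a^T + \mu (g_a\cdot g_b) I]}
#' which yields a symmetric positive-semidefinite operator with exactly six
#' rigid-body zero modes for a connected mesh.
#'
#' @param mesh A [tet_mesh()].
#' @param mat An [fe_material()].
#' @return A sparse symmetric `3N x 3N` stiffness matrix (DOF order: node 1
#'   x,y,z, node 2 x,y,z, ...).
#' @export
assemble_stiffness <- function(mesh, mat) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(mat, "fe_material"))
  tg <- tet_gradients(mesh)
  if (any(tg$vols <= 0)) {
    abort_femurfe(sprintf("Degenerate (non-positive volume) element %d.",
                          which(tg$vols <= 0)[1]),
                  "femurfe_mesh_error")
  }
  g <- tg$grads; V <- tg$vols
  el <- mesh$elements
  ne <- nrow(el)
  lam <- mat$lambda; mu <- mat$mu
  # 16 nodal blocks x 9 entries, each a length-ne triplet vector
  nblk <- 144L
  ivec <- vector("list", nblk); jvec <- vector("list", nblk); xvec <- vector("list", nblk)
  blk <- 0L
  gdot <- array(0, c(ne, 4, 4))
  for (a in 1:4) for (b in 1:4) {
    gdot[, a, b] <- g[, a, 1] * g[, b, 1] + g[, a, 2] * g[, b, 2] +
      g[, a, 3] * g[, b, 3]
  }
  for (a in 1:4) for (b in 1:4) for (i in 1:3) for (j in 1:3) {
    blk <- blk + 1L
    val <- V * (lam * g[, a, i] * g[, b, j] + mu * g[, b, i] * g[, a, j] +
                  if (i == j) mu * gdot[, a, b] else 0)
    ivec[[blk]] <- 3L * (el[, a] - 1L) + i
    jvec[[blk]] <- 3L * (el[, b] - 1L) + j
    xvec[[blk]] <- val
  }
  n_dof <- 3L * nrow(mesh$nodes)
  ii <- unlist(ivec, use.names = FALSE)
  jj <- unlist(jvec, use.names = FALSE)
  xx <- unlist(xvec, use.names = FALSE)
  # element blocks are symmetric, so assemble the lower triangle only
  lower <- ii >= jj
  Matrix::sparseMatrix(i = ii[lower], j = jj[lower], x = xx[lower],
                       dims = c(n_dof, n_dof), symmetric = TRUE)
}

#' Build the load vector and constraint set
#'
#' The total force is distributed over the load-set boundary faces as a
#' consistent traction: each face carries force proportional to its area,
#' split equally among its three nodes, and the nodal forces are rescaled so
#' their sum equals `total_force * direction` exactly. All three DOFs of
#' every fixed-set node are constrained (to zero unless `fixed_values` is
#' given).
#'
#' @param mesh A [tet_mesh()] with non-empty node sets.
#' @param lc An [fe_load_case()].
#' @param fixed_values Optional N_fixed x 3 matrix of prescribed
#'   displacements (defaults to zero).
#' @return A list with `f` (length-3N force vector), `fixed_dofs` (integer
#'   DOF indices) and `fixed_values` (their prescribed values).
#' @export
build_load_and_constraints <- function(mesh, lc, fixed_values = NULL) {
  faces <- mesh$node_sets[[lc$load_set]]
  fixed <- mesh$node_sets[[lc$fixed_set]]
  if (is.null(faces) || nrow(faces) == 0L || is.null(fixed) ||
      length(fixed) == 0L) {
    abort_femurfe("Load face set and fixed node set must both be non-empty.",
                  "femurfe_configuration_error")
  }
  nd <- mesh$nodes
  a <- nd[faces[, 2], , drop = FALSE] - nd[faces[, 1], , drop = FALSE]
  b <- nd[faces[, 3], , drop = FALSE] - nd[faces[, 1], , drop = FALSE]
  areas <- sqrt((a[, 2] * b[, 3] - a[, 3] * b[, 2])^2 +
                  (a[, 3] * b[, 1] - a[, 1] * b[, 3])^2 +
                  (a[, 1] * b[, 2] - a[, 2] * b[, 1])^2) / 2
  w <- areas / sum(areas)
  n_dof <- 3L * nrow(nd)
  f <- numeric(n_dof)
  if (lc$total_force > 0) {
    face_nodes <- as.vector(faces)                  # vertex 1,2,3 stacked
    node_w <- rep(w / 3, 3)
    for (i in 1:3) {
      if (lc$direction[i] == 0) next
      contrib <- lc$total_force * lc$direction[i] * node_w
      agg <- rowsum(contrib, group = 3L * (face_nodes - 1L) + i)
      dofs <- as.integer(rownames(agg))
      f[dofs] <- f[dofs] + as.numeric(agg)
      # rescale so the component sum is exact to machine precision
      s <- sum(f[seq(i, n_dof, by = 3L)])
      tgt <- lc$total_force * lc$direction[i]
      if (s != 0) {
        comp <- seq(i, n_dof, by = 3L)
        f[comp] <- f[comp] * (tgt / s)
      }
    }
  }
  fixed_dofs <- as.integer(outer(1:3, 3L * (fixed - 1L), `+`))
  vals <- if (is.null(fixed_values)) numeric(length(fixed_dofs))
          else as.numeric(t(fixed_values))
  list(f = f, fixed_dofs = fixed_dofs, fixed_values = vals)
}

#' Solve the constrained linear system
#'
#' Sparse direct (Cholesky) solve of the reduced system after eliminating
#' constrained DOFs. Verifies the reduced residual is below `tol` and
#' returns reactions at constrained DOFs.
#'
#' @param K Global stiffness from [assemble_stiffness()].
#' @param loads Output of [build_load_and_constraints()].
#' @param tol Relative residual tolerance.
#' @return List with `u` (length-3N displacement vector), `reactions`
#'   (length-3N, nonzero at constrained DOFs) and `residual`.
#' @export
solve_displacements <- function(K, loads, tol = 1e-8) {
  n_dof <- nrow(K)
  fixed <- loads$fixed_dofs
  free <- setdiff(seq_len(n_dof), fixed)
  u <- numeric(n_dof)
  u[fixed] <- loads$fixed_values
  Kff <- K[free, free, drop = FALSE]
  rhs <- loads$f[free]
  if (any(loads$fixed_values != 0)) {
    rhs <- rhs - as.numeric(K[free, fixed, drop = FALSE] %*% loads$fixed_values)
  }
  # CHOLMOD warns before failing on indefinite matrices; singularity is
  # detected below via finiteness and the residual check instead.
  uf <- tryCatch(
    suppressWarnings({
      ch <- Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)
      as.numeric(Matrix::solve(ch, rhs))
    }),
    error = function(e) {
      abort_femurfe(
        paste0("Singular reduced system (floating mesh or insufficient ",
               "constraints): ", conditionMessage(e)),
        "femurfe_solver_error")
    })
  if (any(!is.finite(uf))) {
    abort_femurfe("Singular reduced system: non-finite solution; check constraints.",
                  "femurfe_solver_error")
  }
  res <- sqrt(sum((as.numeric(Kff %*% uf) - rhs)^2))
  den <- sqrt(sum(rhs^2))
  rel <- if (den > 0) res / den else res
  if (den > 0 && rel > tol) {
    abort_femurfe(sprintf("Solver residual %.3e exceeds tolerance %.1e.",
                          rel, tol), "femurfe_solver_error")
  }
  u[free] <- uf
  reac <- numeric(n_dof)
  reac[fixed] <- as.numeric(K[fixed, , drop = FALSE] %*% u) - loads$f[fixed]
  list(u = u, reactions = reac, residual = rel)
}

#' Per-element stress and strain fields
#'
#' From the constant displacement gradient H of each element: small strain
#' \eqn{\varepsilon = (H + H^T)/2}, stress \eqn{\sigma = \lambda
#' \mathrm{tr}(\varepsilon) I + 2\mu\varepsilon}, von Mises stress
#' \eqn{\sqrt{3/2\, s:s}} (s the stress deviator), hydrostatic pressure
#' \eqn{-\mathrm{tr}(\sigma)/3} (compression-positive), Green-Lagrange
#' strain \eqn{E = (H + H^T + H^T H)/2} and its effective (von-Mises
#' equivalent) scalar \eqn{\sqrt{2/3\, e:e}} (e the strain deviator).
#'
#' @param mesh A [tet_mesh()].
#' @param u Displacement vector from [solve_displacements()].
#' @param mat An [fe_material()].
#' @return An object of class `fe_result`: nodal displacement matrix and
#'   per-element tensors/invariants.
#' @export
compute_element_fields <- function(mesh, u, mat) {
  stopifnot(all(is.finite(u)))
  tg <- tet_gradients(mesh)
  g <- tg$grads
  el <- mesh$elements
  ne <- nrow(el)
  U <- matrix(u, ncol = 3, byrow = TRUE)
  H <- array(0, c(ne, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    acc <- numeric(ne)
    for (a in 1:4) acc <- acc + U[el[, a], i] * g[, a, j]
    H[, i, j] <- acc
  }
  eps <- (H + aperm(H, c(1, 3, 2))) / 2
  tr_eps <- eps[, 1, 1] + eps[, 2, 2] + eps[, 3, 3]
  sig <- 2 * mat$mu * eps
  for (i in 1:3) sig[, i, i] <- sig[, i, i] + mat$lambda * tr_eps
  tr_sig <- sig[, 1, 1] + sig[, 2, 2] + sig[, 3, 3]
  pressure <- -tr_sig / 3
  s <- sig
  for (i in 1:3) s[, i, i] <- s[, i, i] - tr_sig / 3
  von_mises <- sqrt(pmax(0, 1.5 * rowSums(matrix(s^2, nrow = ne))))
  # Green-Lagrange strain E = (H + H^T + H^T H) / 2
  HtH <- array(0, c(ne, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    HtH[, i, j] <- H[, 1, i] * H[, 1, j] + H[, 2, i] * H[, 2, j] +
      H[, 3, i] * H[, 3, j]
  }
  Egl <- eps + HtH / 2
  tr_E <- Egl[, 1, 1] + Egl[, 2, 2] + Egl[, 3, 3]
  e_dev <- Egl
  for (i in 1:3) e_dev[, i, i] <- e_dev[, i, i] - tr_E / 3
  eff_strain <- sqrt(pmax(0, (2 / 3) * rowSums(matrix(e_dev^2, nrow = ne))))
  structure(
    list(nodal_displacements = U,
         element_stress = sig,
         element_von_mises = von_mises,
         element_pressure = pressure,
         element_lagrange_strain = Egl,
         element_effective_strain = eff_strain,
         element_volumes = tg$vols),
    class = "fe_result")
}

#' Summarize one FE model into the four biomechanical measures
#'
#' Whole-model averages, chosen over point values to avoid local extrema
#' dominating between-group comparisons: mean nodal displacement magnitude
#' (mm) and unweighted element means of compression-positive hydrostatic
#' pressure (MPa), von Mises stress (MPa) and effective Lagrange strain.
#' Volume-weighted element means are available via `weighted = TRUE`.
#'
#' @param result An [compute_element_fields()] result.
#' @param provenance Named list (e.g. specimen_id, side, method) carried into
#'   the output row.
#' @param weighted Use element-volume weighting for element means?
#' @return A one-row [tibble::tibble()] with columns `specimen_id`, `side`,
#'   `method`, `mean_displacement`, `mean_pressure`, `mean_stress`,
#'   `mean_strain`.
#' @export
summarize_specimen <- function(result, provenance = list(), weighted = FALSE) {
  stopifnot(inherits(result, "fe_result"))
  if (length(result$element_von_mises) == 0L) {
    abort_femurfe("Empty FE result.", "femurfe_parameter_error")
  }
  disp <- sqrt(rowSums(result$nodal_displacements^2))
  wmean <- if (weighted) {
    w <- result$element_volumes / sum(result$element_volumes)
    function(x) sum(w * x)
  } else {
    mean
  }
  tibble::tibble(
    specimen_id = provenance$specimen_id %||% NA_character_,
    side = provenance$side %||% NA_character_,
    method = provenance$method %||% NA_character_,
    mean_displacement = mean(disp),
    mean_pressure = wmean(result$element_pressure),
    mean_stress = wmean(result$element_von_mises),
    mean_strain = wmean(result$element_effective_strain)
  )
}
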