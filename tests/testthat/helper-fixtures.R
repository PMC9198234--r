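# Shared fixtures: a toy-resolution phantom parameter set (24^3 grid) that
# keeps whole-pipeline tests fast, and small mesh builders.

toy_params <- function(seed = 1L, ...) {
  phantom_params(head_radius = 6.5, neck_radius = 3.2, neck_length = 5,
                 cortical_thickness = 1.5, grid_shape = 24L, seed = seed, ...)
}

toy_config <- function(n_left = 2L, n_right = 2L, base_seed = 42L, ...) {
  pipeline_config(n_left = n_left, n_right = n_right,
                  base_params = toy_params(), base_seed = base_seed, ...)
}

# a unit regular-ish tetrahedron mesh with one element
single_tet_mesh <- function(nodes = rbind(c(0, 0, 0), c(1, 0, 0),
                                          c(0, 1, 0), c(0, 0, 1))) {
  tet_mesh(nodes, matrix(1:4, 1), node_sets = list())
}

# cube tet mesh with custom uniaxial boundary conditions:
# bottom z fixed (frictionless in-plane), 3-2-1 lateral restraint, top loaded
uniaxial_cube <- function(edge = 10, divisions = 8L, force = 1800) {
  cf <- cube_fixture(edge, divisions)
  m <- binary_mask(cf$truth$bone_mask, cf$volume$spacing)
  tm <- tetrahedralize(m, load_top_fraction = 1e-3)
  nd <- tm$nodes
  zmin <- min(nd[, 3])
  bot <- which(abs(nd[, 3] - zmin) < 1e-9)
  lo <- build_load_and_constraints(
    tm, fe_load_case(total_force = force, direction = c(0, 0, -1)))
  corner <- bot[which.min(nd[bot, 1] + nd[bot, 2])]
  other <- bot[which.max(nd[bot, 1] - nd[bot, 2])]
  lo$fixed_dofs <- c(3L * (bot - 1L) + 3L, 3L * (corner - 1L) + 1:2,
                     3L * (other - 1L) + 2L)
  lo$fixed_values <- numeric(length(lo$fixed_dofs))
  list(mesh = tm, loads = lo, edge = edge,
       area = edge^2, q = force / edge^2)
}
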