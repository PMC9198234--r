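#' Parameters for the femoral-head phantom generator
#'
#' The phantom emulates the proximal femur as imaged by CT: a roughly
#' spherical femoral head (dense cortical shell around a trabecular interior)
#' attached to a cylindrical neck, embedded in a soft-tissue background, with
#' additive Gaussian noise, a smooth trabecular intensity texture, and
#' optional bright artifact specks outside the bone. All lengths are in mm,
#' intensities in arbitrary HU-like units.
#'
#' The trabecular texture is a smooth random field with standard deviation
#' `texture_factor * noise_sd`; real trabecular bone shows a broad intensity
#' continuum (marrow spaces, partial-volume averaging), and tying the texture
#' amplitude to the noise level means a noiseless phantom degenerates to
#' exactly three intensity plateaus, which downstream oracle tests rely on.
#'
#' @param head_radius Femoral head radius, mm.
#' @param neck_radius Neck cylinder radius, mm; must be `< head_radius`.
#' @param neck_length Neck length below the head-neck junction, mm.
#' @param cortical_thickness Cortical shell thickness, mm.
#' @param bone_intensity,trabecular_intensity,background_intensity Intensity
#'   plateaus; must satisfy `bone > trabecular > background`.
#' @param noise_sd Additive i.i.d. Gaussian noise SD.
#' @param texture_factor Trabecular texture SD as a multiple of `noise_sd`.
#' @param artifact_count Number of bright ellipsoidal specks placed outside
#'   the bone (imaging artifacts).
#' @param voxel_spacing mm per voxel (scalar or length-3).
#' @param grid_shape Voxels per axis (scalar or length-3).
#' @param neck_axis Unit vector from neck towards head (inferior to superior);
#'   default `+Z`.
#' @param head_center Optional mm position of the head center; by default the
#'   head is placed as far along `neck_axis` as the grid margin allows.
#' @param jitter_fractions Named list with elements `radius` and `intensity`:
#'   relative SDs used by [generate_population()] for per-specimen variation.
#' @param seed Integer seed controlling noise, texture and artifacts.
#'
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(head_radius = 9,
                           neck_radius = 4.5,
                           neck_length = 7,
                           cortical_thickness = 2,
                           bone_intensity = 1200,
                           trabecular_intensity = 700,
                           background_intensity = 80,
                           noise_sd = 40,
                           texture_factor = 4,
                           artifact_count = 0L,
                           voxel_spacing = 1,
                           grid_shape = 32L,
                           neck_axis = c(0, 0, 1),
                           head_center = NULL,
                           jitter_fractions = list(radius = 0.05, intensity = 0.02),
                           seed = 1L) {
  assert_scalar_num(head_radius, "head_radius", 0, strict = TRUE)
  assert_scalar_num(neck_radius, "neck_radius", 0, strict = TRUE)
  if (head_radius <= neck_radius) {
    abort_femurfe("`head_radius` must exceed `neck_radius`.",
                  "femurfe_parameter_error")
  }
  assert_scalar_num(neck_length, "neck_length", 0)
  assert_scalar_num(cortical_thickness, "cortical_thickness", 0, strict = TRUE)
  if (!(bone_intensity > trabecular_intensity &&
        trabecular_intensity > background_intensity)) {
    abort_femurfe("Intensities must satisfy bone > trabecular > background.",
                  "femurfe_parameter_error")
  }
  assert_scalar_num(noise_sd, "noise_sd", 0)
  assert_scalar_num(texture_factor, "texture_factor", 0)
  assert_scalar_num(artifact_count, "artifact_count", 0)
  spacing <- rep_len(as.numeric(voxel_spacing), 3L)
  if (any(spacing <= 0)) {
    abort_femurfe("`voxel_spacing` must be positive.", "femurfe_parameter_error")
  }
  shape <- rep_len(as.integer(grid_shape), 3L)
  if (any(shape < 8L)) {
    abort_femurfe("`grid_shape` must be at least 8 voxels per axis.",
                  "femurfe_parameter_error")
  }
  neck_axis <- as.numeric(neck_axis)
  neck_axis <- neck_axis / sqrt(sum(neck_axis^2))
  p <- structure(
    list(head_radius = head_radius, neck_radius = neck_radius,
         neck_length = neck_length, cortical_thickness = cortical_thickness,
         bone_intensity = bone_intensity,
         trabecular_intensity = trabecular_intensity,
         background_intensity = background_intensity,
         noise_sd = noise_sd, texture_factor = texture_factor,
         artifact_count = as.integer(artifact_count),
         voxel_spacing = spacing, grid_shape = shape,
         neck_axis = neck_axis, head_center = head_center,
         jitter_fractions = jitter_fractions, seed = as.integer(seed)),
    class = "phantom_params"
  )
  validate_phantom_fit(p)
  p
}

# Resolve the head center and verify the phantom fits inside the grid with a
# margin of at least 2 voxels on every axis.
validate_phantom_fit <- function(p) {
  shape <- p$grid_shape
  h <- p$voxel_spacing
  half <- (shape - 1) * h / 2          # half-extent of voxel-center lattice
  center <- (shape - 1) * h / 2        # origin fixed at 0
  margin <- 2 * h
  a <- p$neck_axis
  joff <- sqrt(p$head_radius^2 - p$neck_radius^2)
  if (is.null(p$head_center)) {
    # center the head-plus-neck capsule in the grid along its axis: the
    # phantom spans [-(joff + neck_length), +head_radius] along `a`
    p$head_center <- center + a * ((joff + p$neck_length) - p$head_radius) / 2
  }
  # per-axis extent of the phantom: head sphere plus neck cylinder
  p1 <- p$head_center - joff * a
  p2 <- p$head_center - (joff + p$neck_length) * a
  cyl_r <- p$neck_radius * sqrt(pmax(0, 1 - a^2))
  lo_ext <- pmin(p$head_center - p$head_radius, p1 - cyl_r, p2 - cyl_r)
  hi_ext <- pmax(p$head_center + p$head_radius, p1 + cyl_r, p2 + cyl_r)
  if (any(lo_ext < center - half + margin - 1e-9) ||
      any(hi_ext > center + half - margin + 1e-9)) {
    abort_femurfe(
      "Phantom does not fit inside the grid with a 2-voxel margin; enlarge `grid_shape` or shrink the phantom.",
      "femurfe_parameter_error")
  }
  p$head_center_resolved <- p$head_center
  p
}

#' Generate one phantom CT volume with ground truth
#'
#' Deterministic for a fixed `params$seed`. Voxels in the cortical shell get
#' `bone_intensity`, trabecular interior `trabecular_intensity` plus a smooth
#' random texture, everything else `background_intensity`; i.i.d. Gaussian
#' noise and bright artifact specks are then added. The ground truth records
#' the exact bone mask, head center, neck axis and the analytic head-neck
#' junction plane used downstream for cropping.
#'
#' @param params A [phantom_params()] object.
#' @param specimen_id,side Labels attached to the volume.
#'
#' @return A list with elements `volume` ([ct_volume()]) and `truth`
#'   (class `ground_truth`: `bone_mask`, `head_center`, `head_radius`,
#'   `neck_axis`, `junction_point`, `junction_normal`).
#' @export
generate_phantom <- function(params, specimen_id = "phantom", side = "left") {
  stopifnot(inherits(params, "phantom_params"))
  p <- validate_phantom_fit(params)
  shape <- p$grid_shape
  h <- p$voxel_spacing
  cx <- axis_coords(shape[1], 0, h[1])
  cy <- axis_coords(shape[2], 0, h[2])
  cz <- axis_coords(shape[3], 0, h[3])
  X <- array(rep(cx, times = shape[2] * shape[3]), shape)
  Y <- array(rep(rep(cy, each = shape[1]), times = shape[3]), shape)
  Z <- array(rep(cz, each = shape[1] * shape[2]), shape)
  ctr <- p$head_center_resolved
  a <- p$neck_axis

  dxh <- X - ctr[1]; dyh <- Y - ctr[2]; dzh <- Z - ctr[3]
  r2 <- dxh^2 + dyh^2 + dzh^2
  head_mask <- r2 <= p$head_radius^2

  # neck: axial coordinate s (towards head positive), radial distance to axis
  s <- dxh * a[1] + dyh * a[2] + dzh * a[3]
  rad2 <- r2 - s^2
  joff <- sqrt(p$head_radius^2 - p$neck_radius^2)
  neck_mask <- rad2 <= p$neck_radius^2 &
    s <= -joff & s >= -(joff + p$neck_length)
  bone_mask <- head_mask | neck_mask

  # cortical shell: within `cortical_thickness` of the outer boundary
  ct <- p$cortical_thickness
  cort_head <- head_mask & r2 >= (p$head_radius - ct)^2
  cort_neck <- neck_mask & rad2 >= (p$neck_radius - ct)^2
  cortical <- cort_head | cort_neck
  trabecular <- bone_mask & !cortical

  vol <- array(p$background_intensity, shape)
  vol[trabecular] <- p$trabecular_intensity
  vol[cortical] <- p$bone_intensity

  withr::with_seed(p$seed, {
    if (p$noise_sd > 0 && p$texture_factor > 0 && any(trabecular)) {
      field <- gaussian_smooth3d(array(stats::rnorm(prod(shape)), shape), 1.5)
      field <- field / stats::sd(field)
      vol[trabecular] <- vol[trabecular] +
        p$texture_factor * p$noise_sd * field[trabecular]
    }
    if (p$artifact_count > 0) {
      margin_lo <- 2 * h
      lo <- margin_lo; hi <- (shape - 1) * h - margin_lo
      placed <- 0L; tries <- 0L
      while (placed < p$artifact_count && tries < 200L) {
        tries <- tries + 1L
        cen <- stats::runif(3, lo, hi)
        # keep specks clear of the bone
        dc <- sqrt(sum((cen - ctr)^2))
        sa <- sum((cen - ctr) * a)
        ra <- sqrt(max(0, sum((cen - ctr)^2) - sa^2))
        near_head <- dc < p$head_radius + 3 * max(h)
        near_neck <- ra < p$neck_radius + 3 * max(h) &&
          sa < 0 && sa > -(joff + p$neck_length + 3 * max(h))
        if (near_head || near_neck) next
        ax <- stats::runif(3, 1, 2) * h   # semi-axes, 1-2 voxels
        speck <- ((X - cen[1]) / ax[1])^2 + ((Y - cen[2]) / ax[2])^2 +
          ((Z - cen[3]) / ax[3])^2 <= 1
        vol[speck & !bone_mask] <- p$bone_intensity * 1.25
        placed <- placed + 1L
      }
    }
    if (p$noise_sd > 0) {
      vol <- vol + array(stats::rnorm(prod(shape), 0, p$noise_sd), shape)
    }
  })

  truth <- structure(
    list(bone_mask = bone_mask,
         head_mask = head_mask,
         head_center = ctr,
         head_radius = p$head_radius,
         neck_axis = a,
         junction_point = ctr - joff * a,
         junction_normal = a),
    class = "ground_truth"
  )
  list(volume = ct_volume(vol, spacing = h, specimen_id = specimen_id,
                          side = side),
       truth = truth)
}

#' Generate a two-sided cohort of phantoms
#'
#' Specimen `i` (1-based, across the concatenated left-then-right cohort)
#' uses seed `base_seed + i - 1`; head/neck radii and cortical thickness are
#' jittered by `jitter_fractions$radius` (relative SD) and the bone and
#' trabecular intensities by `jitter_fractions$intensity`, emulating
#' between-specimen size and density variation. Jitter multipliers are
#' clamped to 2.5 SDs so every specimen satisfies the generator invariants.
#'
#' @param n_left,n_right Number of left / right specimens (>= 0).
#' @param base_params A [phantom_params()] template.
#' @param base_seed Integer; specimen seeds are derived from it.
#'
#' @return A list of `list(volume, truth)` pairs, of length
#'   `n_left + n_right`, left specimens first.
#' @export
generate_population <- function(n_left, n_right, base_params = phantom_params(),
                                base_seed = 42L) {
  stopifnot(n_left >= 0, n_right >= 0)
  n <- n_left + n_right
  if (n == 0) return(list())
  jf <- base_params$jitter_fractions
  out <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- base_seed + i - 1L
    jitter_seed <- as.integer((as.numeric(seed_i) * 7919) %% 2147483629)
    mult <- withr::with_seed(jitter_seed, {
      m <- stats::rnorm(4, 1, c(jf$radius, jf$radius, jf$intensity, jf$intensity))
      pmin(pmax(m, 1 - 2.5 * c(jf$radius, jf$radius, jf$intensity, jf$intensity)),
           1 + 2.5 * c(jf$radius, jf$radius, jf$intensity, jf$intensity))
    })
    side <- if (i <= n_left) "left" else "right"
    idx <- if (i <= n_left) i else i - n_left
    pi_ <- base_params
    pi_$head_radius <- base_params$head_radius * mult[1]
    pi_$neck_radius <- base_params$neck_radius * mult[2]
    pi_$cortical_thickness <- base_params$cortical_thickness * mult[1]
    pi_$bone_intensity <- base_params$bone_intensity * mult[3]
    pi_$trabecular_intensity <- base_params$trabecular_intensity * mult[4]
    pi_$seed <- seed_i
    class(pi_) <- "phantom_params"
    out[[i]] <- generate_phantom(
      pi_, specimen_id = sprintf("%s_%03d", side, idx), side = side)
  }
  out
}

#' Uniform cube fixture for mesh and FE verification
#'
#' A solid cube of `divisions^3` voxels at uniform intensity, padded by two
#' background voxels per side. The ground-truth junction plane is the cube's
#' lower face, so downstream cropping and boundary-condition selection work
#' unchanged on the fixture.
#'
#' @param edge Cube edge length, mm.
#' @param divisions Voxels per edge (>= 1).
#' @param intensity Intensity of cube voxels.
#' @param background Intensity outside the cube.
#'
#' @return A list `list(volume, truth)` as from [generate_phantom()].
#' @export
cube_fixture <- function(edge = 10, divisions = 10L, intensity = 1000,
                         background = 0) {
  stopifnot(divisions >= 1)
  h <- edge / divisions
  pad <- 2L
  shape <- rep(divisions + 2L * pad, 3L)
  vol <- array(background, shape)
  idx <- (pad + 1L):(pad + divisions)
  vol[idx, idx, idx] <- intensity
  mask <- array(FALSE, shape)
  mask[idx, idx, idx] <- TRUE
  # lower face of the cube in world coordinates (voxel centers at (i-1)*h)
  zlow <- (pad + 1L - 1) * h - h / 2
  ctr <- (shape - 1) * h / 2
  truth <- structure(
    list(bone_mask = mask, head_mask = mask, head_center = ctr,
         head_radius = edge / 2, neck_axis = c(0, 0, 1),
         junction_point = c(ctr[1], ctr[2], zlow),
         junction_normal = c(0, 0, 1)),
    class = "ground_truth"
  )
  list(volume = ct_volume(vol, spacing = h, specimen_id = "cube"),
       truth = truth)
}
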