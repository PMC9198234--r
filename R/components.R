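# 3D connected-component labelling on logical arrays.
#
# Frontier breadth-first search, vectorized over the whole frontier: each
# sweep expands every frontier voxel by all neighbor offsets at once, so the
# number of R-level iterations is bounded by the component diameter.

neighbor_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L) {
    g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  } else if (connectivity != 26L) {
    abort_femurfe("`connectivity` must be 6 or 26.", "femurfe_parameter_error")
  }
  as.matrix(g)
}

#' Label connected components of a 3D logical array
#'
#' @param mask 3D logical array.
#' @param connectivity 6 (face) or 26 (face/edge/corner) neighborhood.
#' @return Integer array of the same shape: 0 for background, 1..k component
#'   labels (label order follows array scan order of component seeds).
#' @export
label_components3d <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  offs <- neighbor_offsets(connectivity)
  # linear-index offsets plus coordinate bookkeeping to reject wraparound
  labels <- array(0L, d)
  fg <- which(mask)
  if (length(fg) == 0L) return(labels)
  remaining <- array(FALSE, d)
  remaining[fg] <- TRUE
  nxy <- d[1] * d[2]
  coord_k <- function(idx) ((idx - 1L) %/% nxy) + 1L
  coord_j <- function(idx) (((idx - 1L) %% nxy) %/% d[1]) + 1L
  coord_i <- function(idx) ((idx - 1L) %% d[1]) + 1L
  lab <- 0L
  repeat {
    seed <- which(remaining)[1]
    if (is.na(seed)) break
    lab <- lab + 1L
    frontier <- seed
    remaining[seed] <- FALSE
    labels[seed] <- lab
    while (length(frontier) > 0L) {
      fi <- coord_i(frontier); fj <- coord_j(frontier); fk <- coord_k(frontier)
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        ii <- fi + offs[o, 1]; jj <- fj + offs[o, 2]; kk <- fk + offs[o, 3]
        ok <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2] &
          kk >= 1L & kk <= d[3]
        if (!any(ok)) next
        lin <- (kk[ok] - 1L) * nxy + (jj[ok] - 1L) * d[1] + ii[ok]
        lin <- lin[remaining[lin]]
        if (length(lin)) {
          remaining[lin] <- FALSE
          labels[lin] <- lab
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
    }
    if (!any(remaining)) break
  }
  labels
}

#' Largest connected component of a 3D logical array
#'
#' @inheritParams label_components3d
#' @return Logical array keeping only the largest component (ties broken by
#'   lowest label, i.e. scan order).
#' @export
largest_component3d <- function(mask, connectivity = 26L) {
  labels <- label_components3d(mask, connectivity)
  if (max(labels) <= 1L) return(mask & TRUE)
  sizes <- tabulate(labels[labels > 0L])
  labels == which.max(sizes)
}
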