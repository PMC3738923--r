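# Patch networks: centroids (optionally clustered), truncated log-normal
# areas, contiguous member cells on a terrain grid (or a virtual grid), and
# pairwise centre-to-centre distances in km.

#' Configuration for the synthetic patch-network generator
#'
#' Defaults draw areas from a log-normal whose truncated mean is 3.61 ha
#' within bounds of 39 m2 and 71 ha, the size structure of the chalk
#' grassland network the models are designed for.
#'
#' @param n_patches number of patches (>= 1).
#' @param area_meanlog,area_sdlog log-normal parameters of patch area in
#'   hectares before truncation.
#' @param area_min_m2 lower area bound in square metres.
#' @param area_max_ha upper area bound in hectares.
#' @param extent_km landscape extent (square of side \code{extent_km}).
#' @param clustering non-negative clustering strength; 0 places centroids
#'   uniformly, larger values pull patches into tighter clusters around
#'   random parent points (a Thomas-process-like pattern).  Not calibrated
#'   to any observed landscape.
#' @param seed integer seed.
#' @return a list of class \code{synth_network_config}.
#' @export
synth_network_config <- function(n_patches = 100,
                                 area_meanlog = -0.0145, area_sdlog = 1.8,
                                 area_min_m2 = 39, area_max_ha = 71,
                                 extent_km = 40, clustering = 0,
                                 seed = NULL) {
  stopifnot(n_patches >= 1, area_min_m2 / 1e4 < area_max_ha,
            extent_km > 0, clustering >= 0, area_sdlog > 0)
  structure(as.list(environment()), class = "synth_network_config")
}

#' Generate a synthetic habitat patch network
#'
#' Centroids are placed uniformly or around cluster parents; areas are drawn
#' from a truncated log-normal (rejection sampling, so the marginal law is
#' the truncated distribution itself); each patch is assigned a contiguous
#' block of raster cells whose count times the cell area approximates the
#' patch area; pairwise centre-to-centre distances are computed in km.
#'
#' @param config a \code{\link{synth_network_config}}.
#' @param terrain optional \code{terrain_grid}; when given, member cells are
#'   grown on that grid without overlap between patches (patch areas are
#'   capped by available cells), and centroids snap to the grid.  When
#'   \code{NULL}, member cells live on a virtual grid at
#'   \code{resolution} metres.
#' @param resolution cell size (m) of the virtual grid when \code{terrain}
#'   is \code{NULL} (default 5).
#' @param assign_cells set \code{FALSE} to skip cell membership (empty
#'   \code{cells}); useful when only areas and distances are needed.
#' @return an object of class \code{patch_network}: list with
#'   \code{patch_id}, \code{area_ha}, \code{centroid_km} (n x 2 matrix,
#'   columns x and y), \code{dist_km} (n x n), \code{cells} (list of
#'   data.frames with \code{row}, \code{col}), \code{resolution}.
#' @export
generate_patch_network <- function(config, terrain = NULL, resolution = 5,
                                   assign_cells = TRUE) {
  stopifnot(inherits(config, "synth_network_config"))
  cf <- config
  if (!is.null(terrain)) {
    resolution <- terrain$resolution
    avail_cells <- length(terrain$elevation)
    if (cf$n_patches > avail_cells)
      stop("more patches requested than available terrain cells")
  }
  with_seed(cf$seed, {
    n <- cf$n_patches
    # centroids (km)
    if (cf$clustering > 0) {
      n_par <- max(1L, round(n / 10))
      par_xy <- matrix(runif(2 * n_par, 0, cf$extent_km), n_par, 2)
      sig <- cf$extent_km * 0.1 / (1 + cf$clustering)
      pick <- sample.int(n_par, n, replace = TRUE)
      cent <- par_xy[pick, , drop = FALSE] + matrix(rnorm(2 * n, 0, sig), n, 2)
      cent[] <- pmin(pmax(cent, 0), cf$extent_km)
    } else {
      cent <- matrix(runif(2 * n, 0, cf$extent_km), n, 2)
    }
    # truncated log-normal areas (ha)
    lo <- cf$area_min_m2 / 1e4; hi <- cf$area_max_ha
    area <- numeric(n); need <- seq_len(n)
    while (length(need)) {
      draw <- rlnorm(length(need), cf$area_meanlog, cf$area_sdlog)
      ok <- draw >= lo & draw <= hi
      area[need[ok]] <- draw[ok]
      need <- need[!ok]
    }
    if (assign_cells) {
      cells <- assign_patch_cells(cent, area, terrain, resolution,
                                  cf$extent_km)
      if (any(vapply(cells, nrow, 0L) == 0))
        stop("terrain grid exhausted: not enough free cells for the ",
             "requested patch areas; use a larger grid or smaller areas")
      if (!is.null(terrain))  # areas capped by realized cell counts
        area <- vapply(cells, nrow, 0L) * resolution^2 / 1e4
    } else {
      cells <- rep(list(data.frame(row = integer(0), col = integer(0))), n)
    }
    d <- as.matrix(stats::dist(cent))
    dimnames(d) <- NULL
    structure(list(patch_id = seq_len(n), area_ha = area,
                   centroid_km = cent, dist_km = d, cells = cells,
                   resolution = resolution),
              class = "patch_network")
  })
}

# Grow a contiguous blob of ~target cells around a seed cell, breadth-first
# in ring order.  With a terrain grid, cells already taken are skipped.
assign_patch_cells <- function(cent, area_ha, terrain, res, extent_km) {
  n <- length(area_ha)
  if (!is.null(terrain)) {
    nr <- nrow(terrain$elevation); nc <- ncol(terrain$elevation)
  } else {
    nr <- max(3L, ceiling(extent_km * 1000 / res))
    nc <- nr
  }
  taken <- if (!is.null(terrain)) matrix(FALSE, nr, nc) else NULL
  lapply(seq_len(n), function(i) {
    target <- max(1L, round(area_ha[i] * 1e4 / res^2))
    r0 <- min(nr, max(1L, nr - floor(cent[i, 2] * 1000 / res)))
    c0 <- min(nc, max(1L, 1L + floor(cent[i, 1] * 1000 / res)))
    got <- matrix(integer(0), 0, 2)
    for (ring in 0:max(nr, nc)) {
      rr <- (r0 - ring):(r0 + ring); cc <- (c0 - ring):(c0 + ring)
      cand <- unique(rbind(
        cbind(rep(rr, length(cc)), rep(cc, each = length(rr)))))
      cand <- cand[abs(cand[, 1] - r0) == ring | abs(cand[, 2] - c0) == ring,
                   , drop = FALSE]
      cand <- cand[cand[, 1] >= 1 & cand[, 1] <= nr &
                   cand[, 2] >= 1 & cand[, 2] <= nc, , drop = FALSE]
      if (!is.null(taken) && nrow(cand))
        cand <- cand[!taken[cand], , drop = FALSE]
      if (nrow(cand)) {
        take <- head(seq_len(nrow(cand)), target - nrow(got))
        got <- rbind(got, cand[take, , drop = FALSE])
        if (!is.null(taken)) taken[got] <<- TRUE
      }
      if (nrow(got) >= target) break
      if (ring > 0 && nrow(cand) == 0 && ring > max(nr, nc) / 2) break
    }
    data.frame(row = got[, 1], col = got[, 2])
  })
}

#' @export
print.patch_network <- function(x, ...) {
  cat(sprintf("patch_network: %d patches, areas %0.4f..%0.1f ha (mean %0.2f)\n",
              length(x$patch_id), min(x$area_ha), max(x$area_ha),
              mean(x$area_ha)))
  invisible(x)
}

validate_network <- function(nw) {
  stopifnot(inherits(nw, "patch_network"),
            all(nw$area_ha > 0),
            isTRUE(all.equal(nw$dist_km, t(nw$dist_km))),
            all(diag(nw$dist_km) == 0),
            all(nw$dist_km >= 0))
  invisible(TRUE)
}
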