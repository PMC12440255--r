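#' Default optical properties of the toy head medium
#'
#' Homogeneous semi-infinite medium: absorption `mua` (mm^-1), reduced
#' scattering `musp` (mm^-1), refractive index `n_index`.
#'
#' @param mua,musp,n_index Medium parameters.
#' @return Named list.
#' @export
default_medium <- function(mua = 0.017, musp = 0.74, n_index = 1.4) {
  if (mua <= 0 || musp <= 0) stop_arg("mua and musp must be positive")
  list(mua = mua, musp = musp, n_index = n_index)
}

#' Node grid under the probe
#'
#' Regular 3D grid of reconstruction nodes beneath the optode patch
#' (scalp plane z = 0, z increasing into the head).
#'
#' @param probe A `probe_layout`.
#' @param spacing_mm Grid spacing (default 7 mm).
#' @param depths_mm Node depths (default 8, 15, 22 mm).
#' @param margin_mm Lateral margin beyond the optode bounding box.
#' @return Matrix with columns `x`, `y`, `z` (mm) and attribute
#'   `node_volume_mm3`.
#' @export
default_node_grid <- function(probe, spacing_mm = 7,
                              depths_mm = c(8, 15, 22), margin_mm = 10) {
  opt <- rbind(probe$sources, probe$detectors)
  xs <- seq(min(opt[, 1]) - margin_mm, max(opt[, 1]) + margin_mm, by = spacing_mm)
  ys <- seq(min(opt[, 2]) - margin_mm, max(opt[, 2]) + margin_mm, by = spacing_mm)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = depths_mm))
  attr(g, "node_volume_mm3") <- spacing_mm^2 * diff(range(depths_mm)) /
    max(1L, length(depths_mm) - 1L)
  g
}

# CW diffusion Green's function for a semi-infinite medium with extrapolated
# boundary: point source at depth z0, image source mirrored about z = -zb.
# `pos` is the surface (x, y, 0) position of the optode; `pts` an n x 3 matrix.
greens_semi_inf <- function(pos, pts, medium, source = TRUE) {
  mua <- medium$mua; musp <- medium$musp
  D <- 1 / (3 * (mua + musp))
  mueff <- sqrt(mua / D)
  n <- medium$n_index
  Reff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  zb <- 2 * D * (1 + Reff) / (1 - Reff)
  z0 <- if (source) 1 / (mua + musp) else 0
  p_real <- c(pos[1], pos[2], z0)
  p_img <- c(pos[1], pos[2], -(z0 + 2 * zb))
  r1 <- sqrt(colSums((t(pts) - p_real)^2))
  r2 <- sqrt(colSums((t(pts) - p_img)^2))
  r1 <- pmax(r1, 1e-6); r2 <- pmax(r2, 1e-6)
  (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
}

#' Sensitivity (Jacobian) matrix for absorption perturbations
#'
#' Rytov/adjoint formulation on the analytic semi-infinite diffusion model:
#' `J[c, n] = G(source, node) * G(node, detector) / G(source, detector) * V`,
#' where `G` is the extrapolated-boundary Green's function and `V` the node
#' volume. Entries are in OD (natural log) per unit absorption change
#' (mm^-1) at a node. This analytic model stands in for finite-element
#' fluence modelling on a segmented infant mesh; interfaces are identical.
#'
#' @param probe A `probe_layout`; one row of `J` is produced per row of
#'   `probe$channels` (the geometry is wavelength-independent for a single
#'   medium, so rows for the two wavelengths of a pair are equal).
#' @param medium See [default_medium()].
#' @param nodes n x 3 matrix of node positions (mm), all strictly below the
#'   surface (`z > 0`).
#' @param node_volume_mm3 Node volume; default from the `nodes` attribute
#'   or 1.
#' @return Object of class `sensitivity`: list with `J` (channels x nodes),
#'   `nodes`, `medium`, `channels` (the probe channel table).
#' @export
compute_sensitivity <- function(probe, medium = default_medium(), nodes,
                                node_volume_mm3 = NULL) {
  nodes <- as.matrix(nodes)
  if (any(nodes[, 3] <= 0)) stop_arg("all nodes must lie below the surface (z > 0)")
  V <- node_volume_mm3 %||% attr(nodes, "node_volume_mm3") %||% 1
  ch <- probe$channels
  ns <- nrow(probe$sources)
  Gs <- matrix(0, ns, nrow(nodes))
  for (s in seq_len(ns))
    Gs[s, ] <- greens_semi_inf(probe$sources[s, ], nodes, medium, source = TRUE)
  nd <- nrow(probe$detectors)
  Gd <- matrix(0, nd, nrow(nodes))
  for (d in seq_len(nd))
    Gd[d, ] <- greens_semi_inf(probe$detectors[d, ], nodes, medium, source = FALSE)
  # source -> detector amplitude (detector on the surface)
  G_sd <- matrix(0, ns, nd)
  for (s in seq_len(ns))
    G_sd[s, ] <- greens_semi_inf(probe$sources[s, ],
                                 cbind(probe$detectors[, 1], probe$detectors[, 2],
                                       1e-3), medium, source = TRUE)
  J <- Gs[ch$source_id, , drop = FALSE] * Gd[ch$detector_id, , drop = FALSE] /
    G_sd[cbind(ch$source_id, ch$detector_id)] * V
  structure(list(J = J, nodes = nodes, medium = medium, channels = ch,
                 node_volume_mm3 = V),
            class = "sensitivity")
}

#' Zeroth-order Tikhonov image reconstruction
#'
#' Solves `x = J' (J J' + lam * s_max * I)^-1 y` where `s_max` is the largest
#' diagonal entry of `J J'` (scaling convention recorded in the result so
#' that the dimensionless hyperparameter, default 0.01, is comparable across
#' probes).
#'
#' @param J Sensitivity matrix (channels x nodes), or a `sensitivity` object.
#' @param y Measurement vector (length = channels) or matrix
#'   (channels x timepoints) of OD changes.
#' @param lam Regularization hyperparameter (> 0, default 0.01).
#' @return Object of class `image_result`: list with `x` (nodes, or nodes x
#'   timepoints), `lam`, `scaling`.
#' @export
tikhonov_reconstruct <- function(J, y, lam = 0.01) {
  if (inherits(J, "sensitivity")) J <- J$J
  if (lam <= 0) stop_arg("lam must be positive")
  if (all(J == 0)) stop_arg("sensitivity matrix is identically zero")
  y <- as.matrix(y)
  if (nrow(y) != nrow(J)) stop_arg("y must have one row per retained channel")
  JJt <- J %*% t(J)
  smax <- max(diag(JJt))
  x <- t(J) %*% solve(JJt + lam * smax * diag(nrow(J)), y)
  structure(list(x = drop(x), lam = lam, scaling = "lam * max(diag(JJt))"),
            class = "image_result")
}

#' Unmix two-wavelength absorption images into hemoglobin images
#'
#' Per node, solves `dmua(lambda) = eps_HbO(lambda) dHbO + eps_HbR(lambda)
#' dHbR` for the chromophore concentration changes.
#'
#' @param mua_images Nodes x 2 matrix of absorption-change images, columns in
#'   the order of the extinction matrix rows.
#' @param extinction 2 x 2 extinction matrix (default
#'   [extinction_coefficients()]).
#' @return Nodes x 2 matrix with columns `HbO`, `HbR` (uM).
#' @export
unmix_images <- function(mua_images, extinction = extinction_coefficients()) {
  mua_images <- as.matrix(mua_images)
  if (ncol(mua_images) != 2L) stop_arg("expected two wavelength images")
  out <- t(solve(extinction, t(mua_images)))
  colnames(out) <- c("HbO", "HbR")
  out
}

#' Sensitivity-weighted ROI definition
#'
#' Channel weights for a region of interest: `w_c` proportional to the summed
#' absolute sensitivity of channel `c` over the ROI's nodes, normalized to
#' sum 1 over admitted channels (source-detector separation within
#' `sep_range_mm`, default 12 to 45 mm). Channels with zero ROI sensitivity
#' get weight 0.
#'
#' @param sens A `sensitivity` object (or list with `J` and `channels`).
#' @param roi_mask Logical vector over nodes (TRUE = node in ROI).
#' @param name ROI name.
#' @param sep_range_mm Admitted separation window (default `c(12, 45)`).
#' @return Object of class `roi_definition`: list with `name`, `mask`, and
#'   `weights` (data frame: `source_id`, `detector_id`, `weight` over the
#'   unique source-detector pairs).
#' @export
roi_weights <- function(sens, roi_mask, name = "ROI", sep_range_mm = c(12, 45)) {
  ch <- sens$channels
  # collapse to unique pairs (geometry is wavelength-independent)
  pair_key <- paste(ch$source_id, ch$detector_id)
  first <- !duplicated(pair_key)
  J <- sens$J[first, , drop = FALSE]
  ch <- ch[first, ]
  admitted <- ch$sd_distance_mm >= sep_range_mm[1] &
    ch$sd_distance_mm <= sep_range_mm[2]
  raw <- rowSums(abs(J[, roi_mask, drop = FALSE]))
  raw[!admitted] <- 0
  if (sum(raw) <= 0) stop_arg("ROI '", name, "' has zero total sensitivity")
  structure(list(name = name, mask = roi_mask,
                 weights = data.frame(source_id = ch$source_id,
                                      detector_id = ch$detector_id,
                                      sd_distance_mm = ch$sd_distance_mm,
                                      weight = raw / sum(raw))),
            class = "roi_definition")
}

#' Default regions of interest on the toy cortex
#'
#' Six lateral disks standing in for the atlas parcels analyzed in frontal
#' infant work: left/right medial prefrontal cortex (mPFC), left/right
#' medial superior frontal gyrus (mSFG), left/right middle prefrontal
#' cortex.
#'
#' @param nodes Node matrix from [default_node_grid()].
#' @param radius_mm Disk radius (default 18 mm).
#' @param depth_range_mm Depth band of ROI nodes (default 8 to 18 mm).
#' @return Named list of logical node masks.
#' @export
default_rois <- function(nodes, radius_mm = 18, depth_range_mm = c(8, 18)) {
  cx <- mean(range(nodes[, 1])); cy <- mean(range(nodes[, 2]))
  centers <- list(
    "L mPFC"   = c(cx - 12, cy - 12), "R mPFC"   = c(cx + 12, cy - 12),
    "L mSFG"   = c(cx - 16, cy + 22), "R mSFG"   = c(cx + 16, cy + 22),
    "L midPFC" = c(cx - 45, cy),      "R midPFC" = c(cx + 45, cy))
  lapply(centers, function(cc) {
    sqrt((nodes[, 1] - cc[1])^2 + (nodes[, 2] - cc[2])^2) <= radius_mm &
      nodes[, 3] >= depth_range_mm[1] & nodes[, 3] <= depth_range_mm[2]
  })
}

#' ROI timeseries from hemoglobin channel data
#'
#' Weighted average of channel Hb series per ROI and chromophore; weights of
#' channels missing from the data (pruned pairs) are renormalized out.
#'
#' @param ts A `channel_timeseries` of kind `"hb"` (rows per pair and
#'   chromophore, from [mbll()]).
#' @param rois List of `roi_definition` objects.
#' @return Object of class `roi_series`: list with `data` (ROI-chromophore
#'   rows x time matrix), `table` (data frame `roi`, `chromophore`),
#'   `rate_hz`, `t0_s`.
#' @export
roi_timeseries <- function(ts, rois) {
  if (ts$kind != "hb") stop_arg("roi_timeseries expects hemoglobin data")
  ch <- ts$channel_table
  rows <- list(); tab <- list()
  for (roi in rois) {
    w <- roi$weights
    for (chrom in c("HbO", "HbR")) {
      sel <- which(ch$chromophore == chrom)
      key_data <- paste(ch$source_id[sel], ch$detector_id[sel])
      key_w <- paste(w$source_id, w$detector_id)
      m <- match(key_w, key_data)
      ok <- !is.na(m) & w$weight > 0
      if (!any(ok)) {
        warning("all channels of ROI '", roi$name, "' (", chrom,
                ") are missing; ROI series skipped")
        next
      }
      ww <- w$weight[ok] / sum(w$weight[ok])
      rows[[length(rows) + 1L]] <-
        as.numeric(ww %*% ts$data[sel[m[ok]], , drop = FALSE])
      tab[[length(tab) + 1L]] <- data.frame(roi = roi$name, chromophore = chrom)
    }
  }
  structure(list(data = do.call(rbind, rows), table = do.call(rbind, tab),
                 rate_hz = ts$rate_hz, t0_s = ts$t0_s),
            class = "roi_series")
}
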