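toy_probe <- function() default_probe(n_tiles = 2)

test_that("sensitivity is symmetric under mirrored geometry and decays with depth", {
  probe <- toy_probe()
  med <- default_medium()
  ch <- probe$channels[probe$channels$wavelength_nm == 735 &
                         probe$channels$sd_distance_mm > 20, ][1, ]
  s <- probe$sources[ch$source_id, ]; d <- probe$detectors[ch$detector_id, ]
  mid <- (s + d) / 2
  axis <- (d - s); axis <- axis / sqrt(sum(axis^2))
  n1 <- mid + 7 * axis; n2 <- mid - 7 * axis
  nodes <- rbind(n1, n2); nodes[, 3] <- 12
  row <- which(probe$channels$source_id == ch$source_id &
                 probe$channels$detector_id == ch$detector_id &
                 probe$channels$wavelength_nm == 735)
  sv <- compute_sensitivity(probe, med, nodes, node_volume_mm3 = 1)
  # mirroring the whole geometry (swap source and detector positions) must
  # mirror the sensitivity profile along the channel axis
  probe_m <- probe
  probe_m$sources[ch$source_id, ] <- d
  probe_m$detectors[ch$detector_id, ] <- s
  sv_m <- compute_sensitivity(probe_m, med, nodes, node_volume_mm3 = 1)
  expect_equal(sv$J[row, 1], sv_m$J[row, 2], tolerance = 1e-10)
  expect_equal(sv$J[row, 2], sv_m$J[row, 1], tolerance = 1e-10)
  # depth scan under the channel midpoint: beyond the turning depth, |J|
  # decreases monotonically
  zs <- seq(2, 40, 1)
  sd2 <- compute_sensitivity(probe, med, cbind(mid[1], mid[2], zs),
                             node_volume_mm3 = 1)
  Jd <- sd2$J[row, ]
  pk <- which.max(Jd)
  expect_lt(zs[pk], 15)
  expect_true(all(diff(Jd[pk:length(zs)]) < 0))
  expect_error(compute_sensitivity(probe, med, cbind(0, 0, -1)), "below the surface")
})

test_that("J matches finite-difference perturbation of the Born forward model", {
  probe <- toy_probe()
  med <- default_medium()
  nodes <- cbind(c(-5, 5, 0, 10), c(0, 5, -5, 0), c(10, 14, 12, 16))
  sv <- compute_sensitivity(probe, med, nodes, node_volume_mm3 = 1)
  row <- which(probe$channels$wavelength_nm == 735 &
                 probe$channels$sd_distance_mm > 15)[1]
  ch <- probe$channels[row, ]
  spos <- probe$sources[ch$source_id, ]; dpos <- probe$detectors[ch$detector_id, ]
  # independent Born forward: fluence at the detector with a point absorber
  born_od <- function(dmua, node) {
    G <- function(a, b, src) nidot:::greens_semi_inf(a, rbind(b), med, src)
    phi0 <- G(spos, c(dpos[1], dpos[2], 1e-3), TRUE)
    dphi <- G(spos, nodes[node, ], TRUE) *
      nidot:::greens_semi_inf(dpos, rbind(nodes[node, ]), med, FALSE) * dmua
    -log((phi0 - dphi) / phi0)
  }
  for (nd in 1:4) {
    h <- 1e-9
    fd <- unname((born_od(h, nd) - born_od(0, nd)) / h)
    expect_equal(sv$J[row, nd], fd, tolerance = 0.05)
  }
})

test_that("Tikhonov reconstruction matches closed forms and localizes", {
  set.seed(1)
  J <- matrix(rnorm(40), 5, 8)
  y <- rnorm(5)
  x <- tikhonov_reconstruct(J, y, 0.01)$x
  smax <- max(diag(J %*% t(J)))
  oracle <- solve(t(J) %*% J + 0.01 * smax * diag(8), t(J) %*% y)
  expect_lt(max(abs(x - oracle)), 1e-8)
  # lambda -> 0 limit on a well-conditioned square system
  Js <- matrix(rnorm(16), 4, 4) + 3 * diag(4)
  ys <- rnorm(4)
  expect_lt(max(abs(tikhonov_reconstruct(Js, ys, 1e-12)$x - solve(Js, ys))), 1e-6)
  expect_error(tikhonov_reconstruct(J, y, 0), "lam")
  expect_error(tikhonov_reconstruct(matrix(0, 3, 4), rnorm(3)), "zero")
  # localization on the toy geometry at lambda = 0.01, 20 dB SNR
  probe <- toy_probe()
  nodes <- default_node_grid(probe)
  sv <- compute_sensitivity(probe, default_medium(), nodes)
  sel <- probe$channels$wavelength_nm == 735
  Jw <- sv$J[sel, ]
  node0 <- which(nodes[, 3] == 8)[25]
  y0 <- Jw[, node0] * 0.01
  set.seed(2)
  y0 <- y0 + rnorm(length(y0), 0, sqrt(mean(y0^2)) / 10)   # 20 dB SNR
  xr <- tikhonov_reconstruct(Jw, y0, 0.01)$x
  peak <- which.max(abs(xr))
  dist <- sqrt(sum((nodes[peak, ] - nodes[node0, ])^2))
  expect_lte(dist, 7.01)        # within one node spacing
})

test_that("unmixing and re-mixing hemoglobin images is exact", {
  set.seed(3)
  E <- extinction_coefficients()
  hb <- cbind(HbO = rnorm(20), HbR = rnorm(20))
  mua <- t(E %*% t(hb))
  back <- unmix_images(mua, E)
  expect_lt(max(abs(back - hb)), 1e-12)
})

test_that("ROI weights follow sensitivity normalization and admission rules", {
  probe <- toy_probe()
  nodes <- default_node_grid(probe)
  sv <- compute_sensitivity(probe, default_medium(), nodes)
  mask <- nodes[, 3] == 8
  rd <- roi_weights(sv, mask, name = "toy")
  w <- rd$weights
  expect_equal(sum(w$weight), 1)
  expect_true(all(w$weight >= 0))
  expect_true(all(w$weight[w$sd_distance_mm < 12 | w$sd_distance_mm > 45] == 0))
  # two channels with ROI sensitivities 3 and 1 -> weights 0.75 / 0.25
  fake <- list(J = rbind(c(3, 0), c(1, 0)),
               channels = data.frame(source_id = 1:2, detector_id = 1,
                                     wavelength_nm = 735,
                                     sd_distance_mm = c(20, 25)))
  fw <- roi_weights(fake, c(TRUE, FALSE))
  expect_equal(fw$weights$weight, c(0.75, 0.25))
  # single admitted channel -> weight 1
  fake1 <- list(J = rbind(c(3, 1), c(1, 1)),
                channels = data.frame(source_id = 1:2, detector_id = 1,
                                      wavelength_nm = 735,
                                      sd_distance_mm = c(20, 80)))
  expect_equal(roi_weights(fake1, c(TRUE, TRUE))$weights$weight, c(1, 0))
  expect_error(roi_weights(fake, c(FALSE, FALSE)), "zero total sensitivity")
})

test_that("ROI timeseries is the weighted channel average, robust to pruning", {
  tab <- data.frame(source_id = rep(1:2, each = 2), detector_id = 1,
                    chromophore = rep(c("HbO", "HbR"), 2),
                    sd_distance_mm = 20)
  dat <- rbind(rep(4, 10), rep(-4, 10), rep(0, 10), rep(0, 10))
  ts <- channel_timeseries(dat, 4, 0, tab, "hb")
  rd <- structure(list(name = "toy", mask = TRUE,
                       weights = data.frame(source_id = 1:2, detector_id = 1,
                                            sd_distance_mm = 20,
                                            weight = c(0.75, 0.25))),
                  class = "roi_definition")
  rs <- roi_timeseries(ts, list(rd))
  expect_equal(rs$data[rs$table$chromophore == "HbO", ], rep(3, 10))
  # identical channels -> ROI equals any channel; permutation invariance
  dat2 <- dat; dat2[c(3, 4), ] <- dat[c(1, 2), ]
  ts2 <- channel_timeseries(dat2, 4, 0, tab, "hb")
  rs2 <- roi_timeseries(ts2, list(rd))
  expect_equal(rs2$data[1, ], dat2[1, ])
  # missing channel weights are renormalized out
  ts3 <- channel_timeseries(dat[1:2, ], 4, 0, tab[1:2, ], "hb")
  rs3 <- roi_timeseries(ts3, list(rd))
  expect_equal(rs3$data[1, ], rep(4, 10))
  w <- testthat::capture_warnings(
    roi_timeseries(channel_timeseries(dat[1:2, ], 4, 0,
                                      transform(tab[1:2, ], source_id = 9), "hb"),
                   list(rd)))
  expect_true(any(grepl("missing", w)))
})

test_that("six default ROIs cover the probe and feed the pipeline naming", {
  probe <- default_probe()
  nodes <- default_node_grid(probe)
  rois <- default_rois(nodes)
  expect_setequal(names(rois),
                  c("L mPFC", "R mPFC", "L mSFG", "R mSFG", "L midPFC", "R midPFC"))
  expect_true(all(vapply(rois, sum, integer(1)) > 0))
})
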