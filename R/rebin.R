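# Fan <-> parallel rebinning utilities.
#
# A flat-detector fan ray (beta, u) equals the parallel ray at view
# theta = beta - gamma and signed offset t = RF * sin(gamma), with
# gamma = atan(u / RFD) (a constant view relabeling is dropped).  The
# parallel view set uses the same angular grid as the fan scan; offsets
# are uniform with dt = du * RF / RFD.  Per-view sums of parallel rows
# are true object projections, so their mass (sum * dt) is identical for
# every view of an untruncated scan -- the measure in which the mass
# consistency condition is exact.

parallel_grid <- function(geometry) {
  rf <- geometry$source_to_isocenter_mm
  rfd <- geometry$source_to_detector_mm
  dt <- geometry$channel_spacing_mm * rf / rfd
  umax <- max(abs(channel_offsets(geometry)))
  tmax <- rf * sin(atan(umax / rfd))
  nh <- floor(tmax / dt)
  list(t = (-nh:nh) * dt, dt = dt, n = 2L * nh + 1L)
}

# fan sinogram slice (na x nu, on geometry's grid) -> parallel (na x nt)
rebin_fan_to_parallel <- function(vals, geometry, tgrid) {
  rf <- geometry$source_to_isocenter_mm
  rfd <- geometry$source_to_detector_mm
  uoff <- channel_offsets(geometry)
  du <- geometry$channel_spacing_mm
  angles <- geometry$angles_rad
  na <- length(angles)
  db <- angles[2] - angles[1]
  out <- matrix(0, na, length(tgrid$t))
  for (j in seq_along(tgrid$t)) {
    gam <- asin(tgrid$t[j] / rf)
    u <- rfd * tan(gam)
    cu <- (u - uoff[1]) / du
    j0 <- floor(cu)
    wu <- cu - j0
    if (j0 < 0 || j0 + 2 > length(uoff)) next
    ai <- (angles + gam - angles[1]) / db        # beta = theta + gamma
    i0 <- floor(ai)
    wa <- ai - i0
    i0 <- ((i0 %% na) + na) %% na
    i1 <- (i0 + 1L) %% na
    out[, j] <- (1 - wa) * ((1 - wu) * vals[i0 + 1L, j0 + 1L] +
                              wu * vals[i0 + 1L, j0 + 2L]) +
      wa * ((1 - wu) * vals[i1 + 1L, j0 + 1L] +
              wu * vals[i1 + 1L, j0 + 2L])
  }
  out
}

# parallel sinogram (na x nt) -> fan values at the given channel columns
# (indices into geometry's channel grid); returns na x length(cols)
rebin_parallel_to_fan <- function(par, geometry, tgrid, cols) {
  rf <- geometry$source_to_isocenter_mm
  rfd <- geometry$source_to_detector_mm
  uoff <- channel_offsets(geometry)
  angles <- geometry$angles_rad
  na <- length(angles)
  db <- angles[2] - angles[1]
  nt <- length(tgrid$t)
  out <- matrix(0, na, length(cols))
  for (jj in seq_along(cols)) {
    u <- uoff[cols[jj]]
    gam <- atan(u / rfd)
    tk <- rf * sin(gam)
    ct <- (tk - tgrid$t[1]) / tgrid$dt
    j0 <- floor(ct)
    wt <- ct - j0
    if (j0 < 0) { j0 <- 0L; wt <- 0 }
    if (j0 + 2 > nt) { j0 <- nt - 2L; wt <- 1 }
    ai <- (angles - gam - angles[1]) / db        # theta = beta - gamma
    i0 <- floor(ai)
    wa <- ai - i0
    i0 <- ((i0 %% na) + na) %% na
    i1 <- (i0 + 1L) %% na
    out[, jj] <- (1 - wa) * ((1 - wt) * par[i0 + 1L, j0 + 1L] +
                               wt * par[i0 + 1L, j0 + 2L]) +
      wa * ((1 - wt) * par[i1 + 1L, j0 + 1L] +
              wt * par[i1 + 1L, j0 + 2L])
  }
  out
}
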