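#' Half-sine smooth transition
#'
#' `s(x) = sin(pi * x / 2)`, the S-shaped transition used by both redundancy
#' weight families; the argument is clamped to `[-1, 1]`.
#'
#' @param x unitless (vectorized).
#' @return value in `[-1, 1]`.
#' @export
smooth_s <- function(x) sin(0.5 * pi * pmin(pmax(x, -1), 1))

# Rising S-ramp: 0 at t = 0, 1 at t = 1, flat entry/exit.
.s_ramp <- function(t) 0.5 * (1 + smooth_s(2 * pmin(pmax(t, 0), 1) - 1))

#' Redundancy weight parameters
#'
#' `gamma_t` is the truncation position (fan angle of the truncation edge of
#' the offset detector) and `gamma_s` (< `gamma_t`) ends the smooth
#' transition; both are magnitudes. Under the default `unit_pair`
#' normalization complementary rays receive weights summing to exactly 1
#' (`w(gamma) + w(-gamma) = 1` for the offset weight); `literal` reproduces
#' the printed quarter-scale form whose pairs sum to 2 (the factor is
#' absorbed in the FDK normalization) and which is retained for fidelity
#' experiments only.
#'
#' @param gamma_max half-fan angle, radians.
#' @param gamma_t truncation fan angle, radians (0 < `gamma_t` <= `gamma_max`).
#' @param gamma_s end of the smooth transition, radians; default is the
#'   midpoint of `[0, gamma_t]`.
#' @param normalization `"unit_pair"` (default) or `"literal"`.
#' @return An object of class `weight_params`.
#' @export
weight_params <- function(gamma_max, gamma_t = gamma_max,
                          gamma_s = gamma_t / 2,
                          normalization = c("unit_pair", "literal")) {
  normalization <- match.arg(normalization)
  stopifnot(gamma_s > 0, gamma_s < gamma_t, gamma_t <= gamma_max)
  structure(list(gamma_max = gamma_max, gamma_t = gamma_t, gamma_s = gamma_s,
                 normalization = normalization), class = "weight_params")
}

#' Offset-detector (laterally shifted detector) column weight
#'
#' Piecewise S-shaped weight over the fan angle compensating one-sided
#' detector truncation in a full scan: 0 on the fully truncated side
#' (`gamma <= -gamma_t`), a half-sine transition on `[-gamma_t, -gamma_s]`
#' (argument mapped as `x = 2 (gamma + gamma_t) / (gamma_t - gamma_s) - 1` so
#' that the branch boundaries are continuous), a central plateau, and the
#' mirrored complement on the measured side. Under `unit_pair` the plateau is
#' 1/2 and `w(gamma) + w(-gamma) = 1` exactly; under `literal` the printed
#' quarter-scale form (pair sum 2) is used.
#'
#' @param params a [weight_params()].
#' @param gamma fan angle(s), radians (vectorized).
#' @return weight(s).
#' @export
offset_detector_weight <- function(params, gamma) {
  stopifnot(inherits(params, "weight_params"))
  gt <- params$gamma_t; gs <- params$gamma_s
  wl <- function(g) {  # left half on the unit_pair scale: 0 -> 1/4(1+s) -> 1/2
    x <- 2 * (g + gt) / (gt - gs) - 1
    ifelse(g <= -gt, 0,
           ifelse(g <= -gs, 0.25 * (1 + smooth_s(x)), 0.5))
  }
  if (params$normalization == "unit_pair") {
    ifelse(gamma <= 0, wl(gamma), 1 - wl(-gamma))
  } else {
    # literal printed scale: w_L = 1/4 {0, 1 + s, 2}; w_R(gamma) = 2 - w_L(-gamma)
    ifelse(gamma <= 0, wl(gamma), 2 - wl(-gamma))
  }
}

#' Modified Parker short-scan weight (analytic form)
#'
#' View/fan-angle weight restoring unit redundancy for a short scan over an
#' arc `Lambda >= pi + 2*gamma_max`, built from the same S-shaped transition
#' family as the offset-detector weight but applied in the view-angle
#' dimension. For each fan angle the redundantly measured interval at the
#' start (end) of the arc carries a ramp `0 -> 1/2` (`1 -> 1/2`) of angular
#' width `gamma_max - gamma` joined by a 1/2-plateau; rays whose complement
#' is unacquired receive weight 1. Complementary pairs
#' `(beta, gamma) <-> (beta + pi + 2*gamma, -gamma)` inside the arc sum to
#' exactly 1, and the weight is continuous at the arc boundaries (0 there).
#' The 1/2-plateau has positive width exactly when the arc exceeds
#' `180 deg + 2*gamma_max` (over-scan); at the classic Parker limit it has
#' zero width. A full 360-degree arc has no boundary and yields the constant
#' 1/2 (pure two-fold redundancy averaging).
#'
#' @param beta view angle(s) measured from the start of the arc, radians.
#' @param gamma fan angle(s), radians (same length as `beta` or scalar).
#' @param arc angular coverage, radians.
#' @param gmax half-fan angle, radians.
#' @return weight(s) in `[0, 1]`.
#' @export
parker_weight <- function(beta, gamma, arc, gmax) {
  if (arc < pi + 2 * gmax - 1e-12)
    stop("insufficient short-scan coverage: arc must be >= 180 deg + fan angle")
  n <- max(length(beta), length(gamma))
  beta <- rep_len(beta, n); gamma <- rep_len(gamma, n)
  if (arc >= 2 * pi - 1e-12) return(rep(0.5, n))

  early <- function(b, g) {  # ramp/plateau/ramp over the early paired interval
    a <- arc - pi - 2 * g
    tw <- pmax(pmin(gmax - g, a / 2), 1e-9)
    ifelse(b < tw, 0.5 * .s_ramp(b / tw),
           ifelse(b <= a - tw, 0.5, 0.5 + 0.5 * .s_ramp((b - (a - tw)) / tw)))
  }
  a <- arc - pi - 2 * gamma  # early-paired rays: complement later in the arc
  b0 <- pi - 2 * gamma       # late-paired rays: complement earlier in the arc
  w <- ifelse(beta < -1e-12 | beta > arc + 1e-12, 0,
       ifelse(beta <= a, early(beta, gamma),
       ifelse(beta < b0, 1, 1 - early(beta - b0, -gamma))))
  as.numeric(w)
}

#' Per-view, per-column redundancy weight map
#'
#' A `weight_map` holds unitless weights `w(beta, gamma(u))` on the full
#' detector grid, identical across detector rows (the same fan-beam weight is
#' applied to each row of the cone-beam data independently). Built by
#' [parker_weight_map()], [offset_weight_map()] or [combined_weight_map()].
#'
#' @name weight_map
NULL

.weight_map <- function(w, geom, arc_deg, type) {
  structure(list(w = w, geom = geom, arc_deg = arc_deg, type = type),
            class = "weight_map")
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf("weight_map (%s) %d cols x %d views, arc %.1f deg, range [%.3g, %.3g]\n",
              x$type, nrow(x$w), ncol(x$w), x$arc_deg, min(x$w), max(x$w)))
  invisible(x)
}

#' Short-scan (modified Parker) weight map
#'
#' Evaluates [parker_weight()] on the view/column grid of a geometry for a
#' short-scan arc centered on `beta = pi/2`; views outside the arc get weight
#' 0. Errors if the arc is below `180 deg + 2*gamma_max`.
#'
#' @param geom a [cone_beam_geometry()].
#' @param arc_deg acquired angular coverage, degrees.
#' @return a [weight_map].
#' @export
parker_weight_map <- function(geom, arc_deg) {
  arc <- arc_deg * pi / 180
  gmax <- gamma_max(geom)
  gam <- gamma_of_column(geom)
  beta_start <- pi / 2 - arc / 2
  # view angle measured from the arc start, wrapped into [0, 2*pi)
  b <- (geom$view_angles - beta_start) %% (2 * pi)
  w <- outer(gam, b, function(g, bb) parker_weight(bb, g, arc, gmax))
  w[, b > arc + 1e-9] <- 0
  .weight_map(w, geom, arc_deg, "parker")
}

#' Offset-detector weight map
#'
#' Evaluates [offset_detector_weight()] per column, identical for every view
#' (full-scan assumption of the offset-detector compensation).
#'
#' @param geom a [cone_beam_geometry()].
#' @param params a [weight_params()]; default places `gamma_t` at the
#'   truncation edge implied by `n_trunc_cols` (or, if 0, at the detector
#'   edge nearer the axis).
#' @param n_trunc_cols number of truncated (missing) low-`u` columns used to
#'   locate the truncation fan angle `gamma_t`.
#' @return a [weight_map].
#' @export
offset_weight_map <- function(geom, params = NULL, n_trunc_cols = 0) {
  if (is.null(params)) {
    gmax <- gamma_max(geom)
    # fan angle of the truncation edge (outer edge of the last missing column)
    edge <- -geom$n_u * geom$pitch_u / 2 + n_trunc_cols * geom$pitch_u +
      geom$lateral_offset
    gt <- min(abs(atan(edge / geom$d_sd)), gmax)
    if (gt <= 0) gt <- gmax
    params <- weight_params(gamma_max = gmax, gamma_t = gt)
  }
  gam <- gamma_of_column(geom)
  wcol <- offset_detector_weight(params, gam)
  w <- matrix(wcol, nrow = geom$n_u, ncol = length(geom$view_angles))
  m <- .weight_map(w, geom, 360, "offset")
  m$params <- params
  m
}

#' Product of two weight maps
#'
#' Elementwise product, e.g. Parker times offset-detector weights. Applying
#' both to doubly incomplete data intentionally reproduces the classical
#' failing baseline: each weight is wrongly modulated by the other, so the
#' product map violates the unit pair-sum property.
#'
#' @param a,b [weight_map]s on the same grid.
#' @return a [weight_map].
#' @export
combined_weight_map <- function(a, b) {
  stopifnot(identical(dim(a$w), dim(b$w)))
  m <- .weight_map(a$w * b$w, a$geom, min(a$arc_deg, b$arc_deg), "both")
  parts <- list(a, b)
  names(parts) <- c(a$type, b$type)
  m$parts <- parts
  m
}

# Interpolated lookup w(beta, gamma) in a weight map; NA outside the column
# range. Linear in gamma over the column grid and in beta over the view grid
# (nearest pair of views, wrapping at 360 degrees).
.lookup_weight <- function(wm, beta, gamma) {
  geom <- wm$geom
  gam <- gamma_of_column(geom)
  betas <- geom$view_angles
  nb <- length(betas)
  out <- rep(NA_real_, length(beta))
  gi <- findInterval(gamma, gam)
  ok <- gi >= 1 & gi < length(gam)
  beta <- beta %% (2 * pi)
  step <- 2 * pi / nb  # factory grid is uniform over the full circle
  bi0 <- floor(beta / step)
  fb <- beta / step - bi0
  i0 <- (bi0 %% nb) + 1
  i1 <- (bi0 + 1) %% nb + 1
  fg <- (gamma - gam[gi]) / (gam[pmin(gi + 1, length(gam))] - gam[gi])
  idx <- which(ok)
  for (j in idx) {
    w00 <- wm$w[gi[j], i0[j]];  w10 <- wm$w[gi[j] + 1, i0[j]]
    w01 <- wm$w[gi[j], i1[j]];  w11 <- wm$w[gi[j] + 1, i1[j]]
    out[j] <- (1 - fb[j]) * ((1 - fg[j]) * w00 + fg[j] * w10) +
      fb[j] * ((1 - fg[j]) * w01 + fg[j] * w11)
  }
  out
}

# Analytic evaluation of the weight family behind a map (no grid lookup).
.weight_fun <- function(wm, beta, gamma) {
  arc <- wm$arc_deg * pi / 180
  beta_start <- if (wm$arc_deg >= 360) 0 else pi / 2 - arc / 2
  b <- (beta - beta_start) %% (2 * pi)
  switch(wm$type,
    parker = {
      w <- parker_weight(b, gamma, arc, gamma_max(wm$geom))
      w[b > arc + 1e-12] <- 0
      w
    },
    offset = offset_detector_weight(wm$params, gamma),
    both = .weight_fun(wm$parts$parker, beta, gamma) *
      .weight_fun(wm$parts$offset, beta, gamma),
    stop("no analytic form for this weight map"))
}

#' Check the complementary-ray sum of a weight map
#'
#' For a dense grid of rays `(beta, gamma)` whose complementary ray
#' `(beta + pi + 2*gamma, -gamma)` also falls inside the acquired arc and
#' column range, evaluates both weights and returns the maximum deviation of
#' their sum from 1 (the unit-redundancy condition).
#'
#' With `method = "analytic"` (default) the weight family behind the map is
#' evaluated exactly at both rays. With `method = "interp"` the gridded map
#' itself is sampled by nearest-view lookup with angular interpolation
#' (bilinear in view angle and column fan angle); because the Parker-family
#' transition width shrinks to zero toward the edge fan angle, the
#' interpolated check is limited by the view spacing near the edge columns
#' and reports a much larger deviation there even for a weight family whose
#' analytic complementarity is exact.
#'
#' @param wm a [weight_map].
#' @param n_beta,n_gamma grid density.
#' @param margin_deg margin (degrees) kept away from both acquired-arc
#'   boundaries.
#' @param method `"analytic"` or `"interp"`.
#' @return maximum `|w + w_complement - 1|` over the grid.
#' @export
verify_complementarity <- function(wm, n_beta = 400, n_gamma = 200,
                                   margin_deg = 0,
                                   method = c("analytic", "interp")) {
  method <- match.arg(method)
  geom <- wm$geom
  gam <- gamma_of_column(geom)
  arc <- wm$arc_deg * pi / 180
  beta_start <- if (wm$arc_deg >= 360) 0 else pi / 2 - arc / 2
  m <- margin_deg * pi / 180
  bs <- beta_start + seq(m, arc - m, length.out = n_beta)
  gs <- seq(gam[1] + 1e-6, gam[length(gam)] - 1e-6, length.out = n_gamma)
  grid <- expand.grid(beta = bs, gamma = gs)
  bc <- grid$beta + pi + 2 * grid$gamma
  gc <- -grid$gamma
  in_arc <- function(b) {
    if (wm$arc_deg >= 360) rep(TRUE, length(b))
    else {
      br <- (b - beta_start) %% (2 * pi)
      br >= m & br <= arc - m
    }
  }
  if (method == "analytic") {
    w1 <- .weight_fun(wm, grid$beta, grid$gamma)
    w2 <- .weight_fun(wm, bc, gc)
  } else {
    w1 <- .lookup_weight(wm, grid$beta, grid$gamma)
    w2 <- .lookup_weight(wm, bc, gc)
  }
  keep <- in_arc(bc) & !is.na(w1) & !is.na(w2)
  if (!any(keep)) return(NA_real_)
  max(abs(w1[keep] + w2[keep] - 1))
}
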