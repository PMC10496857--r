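#' Pixel-wise decomposition of a Mueller image
#'
#' Applies the full per-pixel chain to an image: optional substrate
#' correction, m11 normalization, Cloude filtering, and one or both
#' decompositions. Pixels that cannot be processed (non-positive m11,
#' non-finite input, no principal logarithm, singular factors) are
#' masked with a reason code; the rest of the image is unaffected. The
#' result is deterministic given the input.
#'
#' @param img a [mueller_image()].
#' @param method `"differential"`, `"lu_chipman"`, or `"both"`.
#' @param config list of options: `noise_floor_deg` (retardance below
#'   which the azimuth is flagged noise-dominated, default 3),
#'   `cloude_tol` (realizability tolerance, default 1e-6),
#'   `substrate_ref` (4x4 reference matrix or `NULL`).
#' @return a list with per-method property grids (`differential` and/or
#'   `lu_chipman`, each holding H x W matrices `rt_deg`, `theta_deg`,
#'   `alpha_t`, ... ), the shared `mask` ([pixel_mask()]), a
#'   `below_floor` logical grid, and the Cloude `min_eigenvalue`
#'   diagnostic grid.
#' @export
decompose_image <- function(img,
                            method = c("differential", "lu_chipman", "both"),
                            config = list()) {
  stopifnot(inherits(img, "mueller_image"))
  method <- match.arg(method)
  floor_deg <- config$noise_floor_deg %||% 3
  tol <- config$cloude_tol %||% 1e-6
  ref <- config$substrate_ref
  d <- dim(img$pixels)
  H <- d[1]; W <- d[2]
  do_diff <- method %in% c("differential", "both")
  do_lc <- method %in% c("lu_chipman", "both")
  zero <- matrix(NA_real_, H, W)
  diff_fields <- c(paste0("p", 1:6), paste0("alpha", 0:3),
                   "rt_deg", "theta_deg", "alpha_t")
  lc_fields <- c("rt_deg", "theta_deg", "alpha_t", "D", "P")
  dgrids <- if (do_diff) stats::setNames(rep(list(zero), length(diff_fields)),
                                         diff_fields)
  lgrids <- if (do_lc) stats::setNames(rep(list(zero), length(lc_fields)),
                                       lc_fields)
  valid <- matrix(TRUE, H, W)
  reason <- matrix("ok", H, W)
  below <- matrix(FALSE, H, W)
  min_ev <- matrix(NA_real_, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    M <- img$pixels[i, j, , ]
    if (!all(is.finite(M)) || M[1, 1] <= 0) {
      valid[i, j] <- FALSE; reason[i, j] <- "non-physical"; next
    }
    if (!is.null(ref)) M <- substrate_correct(M, ref)
    M <- M / M[1, 1]
    fl <- tryCatch(cloude_filter(M, tol = tol), error = function(e) NULL)
    if (is.null(fl)) {
      valid[i, j] <- FALSE; reason[i, j] <- "non-physical"; next
    }
    M <- fl$M
    min_ev[i, j] <- fl$min_eigenvalue
    rt <- NA_real_
    if (do_diff) {
      dp <- differential_decompose(M)
      if (!dp$valid) {
        valid[i, j] <- FALSE; reason[i, j] <- "decomposition-failed"
      } else {
        for (f in diff_fields) dgrids[[f]][i, j] <- dp[[f]]
        rt <- dp$rt_deg
      }
    }
    if (do_lc && valid[i, j]) {
      lp <- lu_chipman_decompose(M)
      if (!lp$valid || !lp$valid_retarder) {
        valid[i, j] <- FALSE; reason[i, j] <- "decomposition-failed"
      } else {
        for (f in lc_fields) lgrids[[f]][i, j] <- lp[[f]]
        if (is.na(rt)) rt <- lp$rt_deg
      }
    }
    if (valid[i, j] && !is.na(rt) && rt < floor_deg) {
      below[i, j] <- TRUE
      reason[i, j] <- "below-noise-floor"
    }
  }
  out <- list(mask = pixel_mask(valid, reason), below_floor = below,
              min_eigenvalue = min_ev, noise_floor_deg = floor_deg)
  if (do_diff) out$differential <- dgrids
  if (do_lc) out$lu_chipman <- lgrids
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Box-whisker summary of a property map
#'
#' Median and quartiles (linear-interpolation convention,
#' `stats::quantile` type 7) over the valid, finite pixels; whiskers at
#' the most extreme observations within 1.5 x IQR of the quartiles
#' (Tukey rule); observations beyond the whiskers are counted as
#' outliers.
#'
#' @param map numeric H x W matrix.
#' @param mask a [pixel_mask()] or logical matrix (`NULL` = all valid).
#' @param name label for the `map_name` column.
#' @return a one-row data frame with columns `map_name`, `n_valid`,
#'   `median`, `q1`, `q3`, `whisker_low`, `whisker_high`, `n_outliers`.
#' @export
boxwhisker_summary <- function(map, mask = NULL, name = "map") {
  sel <- if (is.null(mask)) rep(TRUE, length(map))
  else if (inherits(mask, "pixel_mask")) as.vector(mask$valid)
  else as.vector(mask)
  x <- as.vector(map)[sel]
  x <- x[is.finite(x)]
  if (length(x) == 0) {
    return(data.frame(map_name = name, n_valid = 0L, median = NA_real_,
                      q1 = NA_real_, q3 = NA_real_, whisker_low = NA_real_,
                      whisker_high = NA_real_, n_outliers = NA_integer_))
  }
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  data.frame(map_name = name, n_valid = length(x), median = q[2],
             q1 = q[1], q3 = q[3],
             whisker_low = min(inside), whisker_high = max(inside),
             n_outliers = sum(x < lo_fence | x > hi_fence))
}

#' Box-whisker summary of an azimuth map with retardance floor
#'
#' Summarizes the optical-axis azimuth over pixels whose scalar
#' retardance is at least `floor_deg` (default 3 degrees, the upper end
#' of a 2-3 degree instrument noise floor): where the retardance is
#' noise-dominated, the azimuth is meaningless and would only inflate
#' the spread. Default statistics are linear quantiles on `[0, 180)`;
#' `circular = TRUE` instead centres the 180-degree-periodic angles on
#' their circular mean (doubled-angle convention) before taking the
#' quantiles, for distributions that straddle the wrap point.
#'
#' @param theta_map azimuth map in degrees on `[0, 180)`.
#' @param rt_map matching scalar-retardance map in degrees.
#' @param mask a [pixel_mask()] or logical matrix (`NULL` = all valid).
#' @param floor_deg retardance floor in degrees (0 disables).
#' @param circular logical; use circular centring.
#' @return a one-row data frame as in [boxwhisker_summary()].
#' @export
azimuth_summary <- function(theta_map, rt_map, mask = NULL, floor_deg = 3,
                            circular = FALSE) {
  stopifnot(all(dim(theta_map) == dim(rt_map)))
  sel <- if (is.null(mask)) matrix(TRUE, nrow(theta_map), ncol(theta_map))
  else if (inherits(mask, "pixel_mask")) mask$valid
  else mask
  sel <- sel & is.finite(rt_map) & rt_map >= floor_deg & is.finite(theta_map)
  if (!circular)
    return(boxwhisker_summary(theta_map, sel, name = "azimuth_deg"))
  x <- theta_map[sel]
  if (length(x) == 0)
    return(boxwhisker_summary(theta_map, sel, name = "azimuth_deg"))
  centre <- (atan2(mean(sin(2 * x * pi / 180)),
                   mean(cos(2 * x * pi / 180))) / 2 * 180 / pi) %% 180
  folded <- ((x - centre + 90) %% 180) - 90
  out <- boxwhisker_summary(matrix(folded + centre, ncol = 1),
                            name = "azimuth_deg")
  out
}

#' Sparse azimuth quiver field
#'
#' Samples the azimuth map on a sparse grid (default step 20 pixels)
#' for stick-plot visualization of fiber orientation. Each stick
#' carries the azimuth angle and a length normalized by the maximum
#' scalar retardance over all valid pixels of the map, so stick length
#' encodes local anisotropy strength.
#'
#' @inheritParams azimuth_summary
#' @param grid_step_px grid step in pixels (>= 1).
#' @return a data frame with columns `row`, `col`, `angle_deg`,
#'   `length_norm` (in `[0, 1]`), of class `quiver_field`, with the
#'   grid step stored in attribute `grid_step_px`.
#' @export
quiver_export <- function(theta_map, rt_map, mask = NULL,
                          grid_step_px = 20L) {
  stopifnot(all(dim(theta_map) == dim(rt_map)), grid_step_px >= 1)
  H <- nrow(theta_map); W <- ncol(theta_map)
  sel <- if (is.null(mask)) matrix(TRUE, H, W)
  else if (inherits(mask, "pixel_mask")) mask$valid
  else mask
  ok <- sel & is.finite(rt_map)
  max_rt <- if (any(ok)) max(rt_map[ok]) else 0
  rows <- seq(ceiling(grid_step_px / 2), H, by = grid_step_px)
  cols <- seq(ceiling(grid_step_px / 2), W, by = grid_step_px)
  grid <- expand.grid(row = rows, col = cols)
  keep <- mapply(function(i, j) ok[i, j] && is.finite(theta_map[i, j]),
                 grid$row, grid$col)
  grid <- grid[keep, , drop = FALSE]
  out <- data.frame(row = grid$row, col = grid$col,
                    angle_deg = theta_map[cbind(grid$row, grid$col)],
                    length_norm = if (max_rt > 0)
                      rt_map[cbind(grid$row, grid$col)] / max_rt
                    else rep(0, nrow(grid)))
  attr(out, "grid_step_px") <- as.integer(grid_step_px)
  class(out) <- c("quiver_field", class(out))
  out
}

#' Compare differential and Lu-Chipman decompositions of one image
#'
#' Per-pixel retardance difference, azimuth difference folded modulo
#' 180 degrees to `[-90, 90]`, and the Spearman rank correlation of the
#' two depolarization maps (the two conventions live on different
#' scales - `[0, infinity)` versus `[0, 1]` - but must order pixels
#' identically for consistent media).
#'
#' @param props_diff `differential` grids from [decompose_image()].
#' @param props_lc `lu_chipman` grids from [decompose_image()].
#' @param mask optional [pixel_mask()] restricting the comparison.
#' @return a list with matrices `delta_rt_deg`, `delta_theta_deg` and a
#'   one-row data frame `stats` (`max_abs_delta_rt_deg`,
#'   `max_abs_delta_theta_deg`, `depol_rank_cor`, `n`).
#' @export
compare_methods <- function(props_diff, props_lc, mask = NULL) {
  drt <- props_diff$rt_deg - props_lc$rt_deg
  dth <- ((props_diff$theta_deg - props_lc$theta_deg + 90) %% 180) - 90
  sel <- if (is.null(mask)) matrix(TRUE, nrow(drt), ncol(drt))
  else if (inherits(mask, "pixel_mask")) mask$valid else mask
  v_rt <- drt[sel & is.finite(drt)]
  v_th <- dth[sel & is.finite(dth)]
  a_d <- props_diff$alpha_t[sel]
  a_l <- props_lc$alpha_t[sel]
  keep <- is.finite(a_d) & is.finite(a_l)
  rho <- if (sum(keep) > 2 && stats::sd(a_d[keep]) > 0 &&
             stats::sd(a_l[keep]) > 0)
    stats::cor(a_d[keep], a_l[keep], method = "spearman")
  else NA_real_
  list(delta_rt_deg = drt, delta_theta_deg = dth,
       stats = data.frame(
         max_abs_delta_rt_deg = if (length(v_rt)) max(abs(v_rt)) else NA_real_,
         max_abs_delta_theta_deg = if (length(v_th)) max(abs(v_th)) else NA_real_,
         depol_rank_cor = rho,
         n = sum(sel)))
}
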