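# Phenotypic-space analysis of stomatal traits: 2-D kernel densities over
# (log amax, log D), Jensen-Shannon divergence between communities, and
# iso-conductance contour lines.

#' 2-D kernel density of stomatal traits on a probability grid
#'
#' Estimates a Gaussian-kernel density of the specimen point pattern in the
#' plane spanned by log maximum pore area and log stomatal density, on an
#' `n x n` grid (default 100 x 100), and normalises the cell values to a
#' probability distribution (cells sum to one). Bandwidths default to the
#' per-axis normal-reference rule. Points outside the declared grid range
#' leak mass and trigger a warning, not an error.
#'
#' @param amax_um2 maximum pore areas, um^2 (positive).
#' @param density_mm2 stomatal densities, mm^-2 (positive).
#' @param n grid cells per axis.
#' @param xlim,ylim grid ranges on the log scale; default the data range
#'   padded by `pad` of the span on each side.
#' @param pad fractional padding of the data range.
#' @param h bandwidth pair (log-amax, log-D); default normal-reference.
#' @return list of class `"density_grid"`: `x`, `y` (cell-centre coordinates
#'   on the log scales), `z` (n x n matrix of cell probabilities), `h`.
#' @export
density_grid <- function(amax_um2, density_mm2, n = 100,
                         xlim = NULL, ylim = NULL, pad = 0.1, h = NULL) {
  keep <- !is.na(amax_um2) & !is.na(density_mm2)
  amax_um2 <- amax_um2[keep]
  density_mm2 <- density_mm2[keep]
  if (length(amax_um2) < 2) stop("need at least 2 points")
  if (any(amax_um2 <= 0) || any(density_mm2 <= 0)) {
    stop("trait values must be positive")
  }
  lx <- log(amax_um2)
  ly <- log(density_mm2)
  span_pad <- function(v) {
    r <- range(v)
    w <- diff(r)
    if (w == 0) w <- max(abs(r[1]), 1) * 0.1
    r + c(-1, 1) * pad * w
  }
  if (is.null(xlim)) xlim <- span_pad(lx)
  if (is.null(ylim)) ylim <- span_pad(ly)
  if (any(lx < xlim[1] | lx > xlim[2] | ly < ylim[1] | ly > ylim[2])) {
    warning("points outside the declared grid range: density mass leaks")
  }
  if (is.null(h)) {
    h <- c(MASS::bandwidth.nrd(lx), MASS::bandwidth.nrd(ly))
    # degenerate spread (e.g. all points identical): fall back to a sliver
    h[h <= 0] <- 0.01 * c(diff(xlim), diff(ylim))[h <= 0]
  }
  kd <- MASS::kde2d(lx, ly, h = h, n = n, lims = c(xlim, ylim))
  z <- kd$z / sum(kd$z)
  out <- list(x = kd$x, y = kd$y, z = z, h = h)
  class(out) <- "density_grid"
  out
}

#' Jensen-Shannon divergence between two density grids
#'
#' Standard base-2 Jensen-Shannon divergence
#' \deqn{JSD(p, q) = \tfrac12 KL(p \| m) + \tfrac12 KL(q \| m), \quad m = (p+q)/2}
#' bounded in [0, 1]: 0 for complete overlap, 1 for complete divergence.
#' Zero cells contribute nothing (`0 log 0 = 0`); a cell empty in one
#' distribution but not the other contributes finitely through the mixture.
#' Grids must share axes.
#'
#' @param p,q [density_grid()] objects (or plain normalised numeric
#'   arrays of identical shape).
#' @return divergence in [0, 1] (dimensionless).
#' @export
jsd <- function(p, q) {
  pz <- if (inherits(p, "density_grid")) p$z else p
  qz <- if (inherits(q, "density_grid")) q$z else q
  if (!identical(dim(pz), dim(qz)) || length(pz) != length(qz)) {
    stop("density grids have mismatched shapes")
  }
  if (inherits(p, "density_grid") && inherits(q, "density_grid") &&
      (!isTRUE(all.equal(p$x, q$x)) || !isTRUE(all.equal(p$y, q$y)))) {
    stop("density grids have mismatched axes")
  }
  m <- (pz + qz) / 2
  term <- function(w) {
    i <- w > 0
    sum(w[i] * log2(w[i] / m[i]))
  }
  (term(pz) + term(qz)) / 2
}

#' Iso-conductance contour lines in the (amax, D) plane
#'
#' For each requested conductance level, returns the locus of (maximum pore
#' area, stomatal density) pairs that solve the anatomical conductance
#' equation under a pore-depth rule. Because the equation is linear in
#' density, each contour is `D(amax) = level / k(amax, p(amax))` with
#' `k` the per-stoma conductance factor.
#'
#' @param levels_mmol conductance levels, mmol m^-2 s^-1
#'   (default 500, 1000, 2000).
#' @param amax_range range of pore areas to span, um^2.
#' @param pore_depth_rule function mapping amax (um^2) to pore depth (um).
#'   The default assumes the guard-cell width equals half the pore length
#'   implied by the elliptical pore, `p = sqrt(8 amax / pi) / 2`.
#' @param n points per contour.
#' @param constants constant set from [eb_constants()].
#' @return data.frame with columns `level_mmol`, `amax_um2`, `density_mm2`.
#' @export
iso_gsmax_contours <- function(levels_mmol = c(500, 1000, 2000),
                               amax_range = c(5, 500),
                               pore_depth_rule = function(amax_um2)
                                 sqrt(8 * amax_um2 / pi) / 2,
                               n = 200, constants = eb_constants()) {
  if (any(amax_range <= 0) || any(levels_mmol <= 0)) {
    stop("ranges and levels must be positive")
  }
  amax <- exp(seq(log(amax_range[1]), log(amax_range[2]), length.out = n))
  p <- pore_depth_rule(amax)
  # conductance per unit density, mol m^-2 s^-1 per mm^-2: the 1e6 (mm^-2 ->
  # m^-2), 1e-12 (um^2 -> m^2) and 1e6 (um -> m in the depth term) cancel
  k <- (constants$dw / constants$v) * amax / (p + (pi / 2) * sqrt(amax / pi))
  out <- do.call(rbind, lapply(levels_mmol, function(lv) {
    data.frame(level_mmol = lv, amax_um2 = amax,
               density_mm2 = (lv / 1000) / k)
  }))
  rownames(out) <- NULL
  out
}

#' Phenotypic-space overlap between two plant communities
#'
#' Builds kernel densities of (log amax, log D) for two communities on a
#' shared grid spanning their joint range (padded), and returns the
#' Jensen-Shannon divergence between them.
#'
#' @param community_a,community_b data.frames with columns `amax_um2` and
#'   `density_mm2` (a specimen table augmented by [augment_gsmax()] works).
#' @param n grid cells per axis.
#' @param pad fractional padding of the joint range.
#' @param h optional shared bandwidth pair; default: the mean of the two
#'   communities' normal-reference bandwidths, per axis.
#' @return list with `jsd`, `grid_a`, `grid_b`.
#' @export
community_overlap <- function(community_a, community_b, n = 100, pad = 0.1,
                              h = NULL) {
  get <- function(df, what) {
    v <- df[[what]]
    v <- v[!is.na(v)]
    if (!length(v)) stop("empty community: no '", what, "' values")
    v
  }
  ax <- get(community_a, "amax_um2"); ad <- get(community_a, "density_mm2")
  bx <- get(community_b, "amax_um2"); bd <- get(community_b, "density_mm2")
  lx <- log(c(ax, bx)); ly <- log(c(ad, bd))
  span <- function(v) range(v) + c(-1, 1) * pad * diff(range(v))
  xlim <- span(lx); ylim <- span(ly)
  if (is.null(h)) {
    h <- c(mean(c(MASS::bandwidth.nrd(log(ax)), MASS::bandwidth.nrd(log(bx)))),
           mean(c(MASS::bandwidth.nrd(log(ad)), MASS::bandwidth.nrd(log(bd)))))
    h[h <= 0] <- 0.01 * c(diff(xlim), diff(ylim))[h <= 0]
  }
  ga <- density_grid(ax, ad, n = n, xlim = xlim, ylim = ylim, h = h)
  gb <- density_grid(bx, bd, n = n, xlim = xlim, ylim = ylim, h = h)
  list(jsd = jsd(ga, gb), grid_a = ga, grid_b = gb)
}

#' Write a density grid as a dense CSV matrix with axis headers
#'
#' @param grid a [density_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_grid <- function(grid, path) {
  m <- grid$z
  dimnames(m) <- list(sprintf("%.6f", grid$x), sprintf("%.6f", grid$y))
  utils::write.csv(m, path)
  invisible(path)
}
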