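#' Define a 2-D projection plane of conductance space
#'
#' The eight channels are partitioned into a group mapped to the x axis and
#' a group mapped to the y axis. A point (x, y) scales the group-X channels
#' by `x / x_ref` and the group-Y channels by `y / y_ref`, where the
#' reference coordinates are the group sums of the reference model's
#' densities. The diagonal through the origin and the reference point
#' scales all densities uniformly — a pure size change.
#'
#' @param model Reference [neuron_model()].
#' @param group_y Channel names mapped to y (default: the channels that
#'   directly set intracellular calcium, CaS and CaT; use
#'   `c("CaS", "CaT", "KCa")` for the alternative grouping).
#' @param group_x Channel names mapped to x (default: the rest).
#' @param extent Axis extents as multiples of the reference coordinates,
#'   `c(lo, hi)`.
#' @return List of class `plane_def` with `x_ref`, `y_ref`, the groups, the
#'   extent (in axis units) and the reference model.
#' @export
plane_def <- function(model = reference_model(),
                      group_y = c("CaS", "CaT"),
                      group_x = setdiff(channel_names(), group_y),
                      extent = c(0.01, 2.5)) {
  stopifnot(inherits(model, "neuron_model"),
            length(intersect(group_x, group_y)) == 0,
            setequal(c(group_x, group_y), channel_names()))
  x_ref <- sum(model$gbar[group_x])
  y_ref <- sum(model$gbar[group_y])
  stopifnot(x_ref > 0, y_ref > 0)
  structure(
    list(model = model, group_x = group_x, group_y = group_y,
         x_ref = x_ref, y_ref = y_ref,
         xlim = extent * x_ref, ylim = extent * y_ref),
    class = "plane_def"
  )
}

#' The three standard projections
#'
#' The calcium/non-calcium split used by the main plane analyses, an
#' arbitrary-subset split, and an outward/inward split.
#'
#' @param model Reference [neuron_model()].
#' @param extent Passed to [plane_def()].
#' @return Named list of three `plane_def`s.
#' @export
standard_planes <- function(model = reference_model(), extent = c(0.01, 2.5)) {
  list(
    calcium = plane_def(model, group_y = c("CaS", "CaT"), extent = extent),
    arbitrary = plane_def(model, group_y = c("A", "CaS", "H", "KCa"),
                          extent = extent),
    inward_outward = plane_def(
      model,
      group_y = c("CaS", "CaT", "NaV", "H"),   # inward currents
      group_x = c("A", "Kd", "KCa", "Leak"),   # outward currents
      extent = extent)
  )
}

#' Conductance vector at a plane point
#'
#' @param plane A [plane_def()].
#' @param x,y Plane coordinates (group-summed densities, uS/mm^2).
#' @return Named density vector.
#' @export
plane_gbar <- function(plane, x, y) {
  g <- plane$model$gbar
  g[plane$group_x] <- g[plane$group_x] * (x / plane$x_ref)
  g[plane$group_y] <- g[plane$group_y] * (y / plane$y_ref)
  g
}

#' Mean-calcium field of a plane
#'
#' Returns the function (x, y) -> time-averaged calcium used by the
#' adaptive level-set sampler.
#'
#' @param plane A [plane_def()].
#' @param t_total,burnin Simulation window, ms.
#' @return A function of (x, y) returning mean calcium (uM, NA on
#'   divergence).
#' @export
plane_calcium_field <- function(plane, t_total = 15000, burnin = 5000) {
  force(plane)
  function(x, y) {
    m <- with_gbar(plane$model, plane_gbar(plane, x, y))
    r <- simulate_neuron(m, t_total = t_total, burnin = burnin,
                         record = FALSE)
    if (isTRUE(r$diverged)) NA_real_ else r$mean_Ca
  }
}

# Delaunay triangles (index triplets) of a point set, via deldir
triangulation <- function(x, y) {
  dd <- deldir::deldir(x, y, suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  t(vapply(tl, function(tr) as.integer(tr$ptNum), integer(3)))
}

tri_area <- function(px, py, tri) {
  abs((px[tri[, 2]] - px[tri[, 1]]) * (py[tri[, 3]] - py[tri[, 1]]) -
        (px[tri[, 3]] - px[tri[, 1]]) * (py[tri[, 2]] - py[tri[, 1]])) / 2
}

#' Adaptive Delaunay sampling of a calcium level set
#'
#' Starts from a few random points in the plane, builds a Delaunay
#' triangulation, and repeatedly refines the largest triangle whose nodes
#' straddle the target level (at least one node above and one below),
#' placing the new sample at its centroid, until the sampling budget is
#' spent or no straddling triangle larger than the mesh criterion remains.
#' The level set is then extracted by linear interpolation along every
#' triangulation edge that straddles the target.
#'
#' @param field Function (x, y) -> scalar (e.g. [plane_calcium_field()]).
#' @param plane A [plane_def()] (supplies the extent).
#' @param target Target level (e.g. the calcium target, uM).
#' @param budget Total number of field evaluations allowed.
#' @param n_init Initial uniform random sample size.
#' @param seed RNG seed for the initial sample.
#' @param min_edge Stop refining a triangle whose longest edge is below
#'   this fraction of the plane diagonal (default 0.02).
#' @return List of class `plane_map`: `points` (data.frame x, y, value),
#'   `triangles` (index matrix), `level_set` (data.frame of segment
#'   endpoints x1, y1, x2, y2 and midpoints), `target`, `plane`,
#'   `n_evals`.
#' @export
adaptive_level_set <- function(field, plane, target, budget = 120,
                               n_init = 25, seed = 1, min_edge = 0.02) {
  stopifnot(budget >= n_init, n_init >= 5)
  set.seed(seed)
  px <- runif(n_init, plane$xlim[1], plane$xlim[2])
  py <- runif(n_init, plane$ylim[1], plane$ylim[2])
  pv <- mapply(field, px, py)
  diag_len <- sqrt(diff(plane$xlim)^2 + diff(plane$ylim)^2)
  repeat {
    if (length(px) >= budget) break
    tri <- triangulation(px, py)
    cand <- straddling(pv, tri, target)
    if (!any(cand)) break
    areas <- tri_area(px, py, tri)
    # drop triangles already below the mesh-size criterion
    long_edge <- apply(tri, 1, function(ix) {
      max(sqrt(diff(px[ix][c(1, 2, 3, 1)])[1:3]^2 +
                 diff(py[ix][c(1, 2, 3, 1)])[1:3]^2))
    })
    cand <- cand & long_edge > min_edge * diag_len
    if (!any(cand)) break
    k <- which(cand)[which.max(areas[cand])]
    cx <- mean(px[tri[k, ]])
    cy <- mean(py[tri[k, ]])
    px <- c(px, cx)
    py <- c(py, cy)
    pv <- c(pv, field(cx, cy))
  }
  tri <- triangulation(px, py)
  seg <- extract_level_segments(px, py, pv, tri, target)
  if (nrow(seg) == 0) {
    warning("no level-set segments found: target outside sampled range")
  }
  structure(
    list(points = data.frame(x = px, y = py, value = pv),
         triangles = tri, level_set = seg, target = target,
         plane = plane, n_evals = length(px)),
    class = "plane_map"
  )
}

straddling <- function(pv, tri, target) {
  v1 <- pv[tri[, 1]]; v2 <- pv[tri[, 2]]; v3 <- pv[tri[, 3]]
  above <- function(v) !is.na(v) & v > target
  below <- function(v) !is.na(v) & v < target
  (above(v1) | above(v2) | above(v3)) & (below(v1) | below(v2) | below(v3))
}

extract_level_segments <- function(px, py, pv, tri, target) {
  segs <- list()
  for (k in seq_len(nrow(tri))) {
    ix <- tri[k, ]
    v <- pv[ix]
    if (any(is.na(v))) next
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      va <- v[e[1]]; vb <- v[e[2]]
      if ((va - target) * (vb - target) < 0) {
        w <- (target - va) / (vb - va)
        pts[[length(pts) + 1]] <- c(
          px[ix[e[1]]] + w * (px[ix[e[2]]] - px[ix[e[1]]]),
          py[ix[e[1]]] + w * (py[ix[e[2]]] - py[ix[e[1]]]))
      }
    }
    if (length(pts) == 2) {
      segs[[length(segs) + 1]] <- c(pts[[1]], pts[[2]])
    }
  }
  if (length(segs) == 0) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0)))
  }
  m <- do.call(rbind, segs)
  data.frame(x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4])
}

#' Count level-set crossings of the plane diagonal
#'
#' The diagonal (uniform scaling, i.e. size changes) is the line
#' `y / y_ref = x / x_ref`. Counts distinct intersections of the sampled
#' level-set segments with it, merging intersections closer than
#' `merge_tol` (fraction of the diagonal length) which belong to adjacent
#' triangles cut by the same crossing.
#'
#' @param map A `plane_map` from [adaptive_level_set()].
#' @param merge_tol Merge tolerance, fraction of the reference diagonal.
#' @param field Optional scalar field (the one the map was sampled from).
#'   When supplied, every candidate intersection is validated against the
#'   definition of a crossing: the field's restriction to the diagonal must
#'   change sign across the candidate position. This rejects spurious
#'   intersections produced by linear interpolation where the level-set
#'   curve merely approaches the diagonal within mesh resolution.
#' @param delta Relative offset along the diagonal used for validation.
#' @return Integer crossing count.
#' @export
diagonal_crossings <- function(map, merge_tol = 0.05, field = NULL,
                               delta = 0.05) {
  seg <- map$level_set
  if (nrow(seg) == 0) return(0L)
  plane <- map$plane
  # signed distance of endpoints from the diagonal in normalised coords
  f <- function(x, y) y / plane$y_ref - x / plane$x_ref
  d1 <- f(seg$x1, seg$y1)
  d2 <- f(seg$x2, seg$y2)
  hit <- d1 * d2 <= 0 & !(d1 == 0 & d2 == 0)
  if (!any(hit)) return(0L)
  w <- d1[hit] / (d1[hit] - d2[hit])
  sx <- (seg$x1[hit] + w * (seg$x2[hit] - seg$x1[hit])) / plane$x_ref
  pos <- sort(sx)
  keep <- c(TRUE, diff(pos) > merge_tol)
  pos <- pos[keep]
  if (!is.null(field)) {
    ok <- vapply(pos, function(s) {
      lo <- field(s * (1 - delta) * plane$x_ref,
                  s * (1 - delta) * plane$y_ref)
      hi <- field(s * (1 + delta) * plane$x_ref,
                  s * (1 + delta) * plane$y_ref)
      is.finite(lo) && is.finite(hi) &&
        (lo - map$target) * (hi - map$target) < 0
    }, logical(1))
    pos <- pos[ok]
  }
  length(pos)
}

#' Acute classification field of a plane
#'
#' Classification of the fixed-parameter model at each plane point, with no
#' regulation — the "acute" response to a perturbation that moves the
#' neuron to that point.
#'
#' @param plane A [plane_def()].
#' @param cfg A [classifier_config()] with targets set.
#' @param t_total,burnin Simulation window, ms.
#' @return Function (x, y) -> state label.
#' @export
plane_acute_field <- function(plane, cfg, t_total = 15000, burnin = 5000) {
  force(plane); force(cfg)
  function(x, y) {
    m <- with_gbar(plane$model, plane_gbar(plane, x, y))
    r <- simulate_neuron(m, t_total = t_total, burnin = burnin)
    trace_metrics(r, cfg)$state_label
  }
}

#' Closed-loop terminal-state field of a plane
#'
#' Each plane point initialises the full regulated system (no growth),
#' which is run until the conductances converge; the terminal model is then
#' simulated without regulation and classified. This is the field whose
#' basins of attraction the basin map samples.
#'
#' @param plane A [plane_def()].
#' @param reg A [regulation_state()] (timescales and target from the
#'   reference model).
#' @param cfg A [classifier_config()] with targets set.
#' @param t_max Maximum closed-loop time per point, ms.
#' @param t_total,burnin Classification window, ms.
#' @return Function (x, y) -> state label (`"nonconvergent"` if the loop
#'   neither converges nor survives).
#' @export
plane_basin_field <- function(plane, reg, cfg, t_max = 300000,
                              t_total = 15000, burnin = 5000) {
  force(plane); force(reg); force(cfg)
  function(x, y) {
    m0 <- with_gbar(plane$model, plane_gbar(plane, x, y))
    tr <- integrate_closed_loop(m0, reg, t_total = t_max)
    if (tr$diverged) return("nonconvergent")
    r <- simulate_neuron(tr$model_final, t_total = t_total, burnin = burnin)
    trace_metrics(r, cfg)$state_label
  }
}

#' Adaptive sampling of basins of attraction
#'
#' Same refinement skeleton as [adaptive_level_set()], but the field is
#' categorical: refinement targets the largest triangle whose nodes carry
#' at least two distinct labels (a basin boundary).
#'
#' @param label_field Function (x, y) -> character label (e.g.
#'   [plane_basin_field()] or [plane_acute_field()]).
#' @param plane A [plane_def()].
#' @param budget Total number of field evaluations.
#' @param n_init Initial uniform random sample size.
#' @param seed RNG seed.
#' @param min_edge Mesh-size stop criterion (fraction of plane diagonal).
#' @return List of class `basin_map`: `points` (x, y, label), `triangles`,
#'   `plane`, `n_evals`.
#' @export
basin_map <- function(label_field, plane, budget = 80, n_init = 25,
                      seed = 1, min_edge = 0.02) {
  stopifnot(budget >= n_init, n_init >= 5)
  set.seed(seed)
  px <- runif(n_init, plane$xlim[1], plane$xlim[2])
  py <- runif(n_init, plane$ylim[1], plane$ylim[2])
  pl <- mapply(label_field, px, py)
  diag_len <- sqrt(diff(plane$xlim)^2 + diff(plane$ylim)^2)
  repeat {
    if (length(px) >= budget) break
    tri <- triangulation(px, py)
    lab <- matrix(pl[tri], ncol = 3)
    mixed <- apply(lab, 1, function(l) length(unique(l[l != "nonconvergent"])) >= 2)
    long_edge <- apply(tri, 1, function(ix) {
      max(sqrt(diff(px[ix][c(1, 2, 3, 1)])[1:3]^2 +
                 diff(py[ix][c(1, 2, 3, 1)])[1:3]^2))
    })
    cand <- mixed & long_edge > min_edge * diag_len
    if (!any(cand)) break
    areas <- tri_area(px, py, tri)
    k <- which(cand)[which.max(areas[cand])]
    cx <- mean(px[tri[k, ]])
    cy <- mean(py[tri[k, ]])
    px <- c(px, cx)
    py <- c(py, cy)
    pl <- c(pl, label_field(cx, cy))
  }
  structure(
    list(points = data.frame(x = px, y = py, label = pl,
                             stringsAsFactors = FALSE),
         triangles = triangulation(px, py), plane = plane,
         n_evals = length(px)),
    class = "basin_map"
  )
}

#' Nearest-sample label interpolation
#'
#' @param map A `basin_map`.
#' @param x,y Query coordinates.
#' @return Label of the nearest sampled point.
#' @export
basin_label_at <- function(map, x, y) {
  sx <- diff(map$plane$xlim)
  sy <- diff(map$plane$ylim)
  d2 <- ((map$points$x - x) / sx)^2 + ((map$points$y - y) / sy)^2
  map$points$label[which.min(d2)]
}

#' Four-way robustness segmentation
#'
#' Pairs the acute response at a point (is the unregulated model still
#' canonical?) with the compensation outcome (does the regulated system end
#' canonical?) into four classes: `robust_restorative`,
#' `sensitive_restorative`, `sensitive_pathological`,
#' `robust_pathological`.
#'
#' @param acute_labels,basin_labels Character vectors of state labels at
#'   the same points.
#' @return Character vector of segmentation labels.
#' @export
segment_robustness <- function(acute_labels, basin_labels) {
  stopifnot(length(acute_labels) == length(basin_labels))
  robust <- acute_labels == "canonical"
  restorative <- basin_labels == "canonical"
  out <- character(length(robust))
  out[robust & restorative] <- "robust_restorative"
  out[!robust & restorative] <- "sensitive_restorative"
  out[!robust & !restorative] <- "sensitive_pathological"
  out[robust & !restorative] <- "robust_pathological"
  out
}

#' @export
print.plane_map <- function(x, ...) {
  cat(sprintf("<plane_map> %d samples, %d level-set segments (target %.3g)\n",
              x$n_evals, nrow(x$level_set), x$target))
  invisible(x)
}

#' @export
print.basin_map <- function(x, ...) {
  cat(sprintf("<basin_map> %d samples\n", x$n_evals))
  print(table(x$points$label))
  invisible(x)
}
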